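# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

# standard mid-size fixture: 2 chromosomes, genes, a planted hotspot,
# shared background variants and filter-failing decoys
shared_fixture <- function() {
  if (!is.null(.fixture_cache$fx)) return(.fixture_cache$fx)
  dir <- file.path(tempdir(), "cibmut-shared-fixture")
  fx <- simulate_fixture(dir, n_chromosomes = 2, chrom_length = 60000,
                         gene_count = 8, n_mutations = 1200, seed = 11,
                         params = spectrum_params(),
                         hotspots = hotspot_spec("chr2", 0, 3000, 30),
                         line_ids = c("mA", "mB"),
                         n_background = 200, n_fail = 4)
  .fixture_cache$fx <- fx
  fx
}

# tiny hand-built genome with one plus-strand and one minus-strand gene at
# known coordinates, for exact codon-level assertions
tiny_gene_fixture <- function() {
  if (!is.null(.fixture_cache$tiny)) return(.fixture_cache$tiny)
  # chr1: 60 bp; gene P: + strand, single exon, CDS 11..19 = ATG AAA TAA
  # gene M: - strand, single exon, CDS 41..49; coding strand reads
  #         ATG CCC TGA, so genomic 41..49 is its reverse complement
  seq <- paste(rep("G", 60), collapse = "")
  substr(seq, 11, 19) <- "ATGAAATAA"
  substr(seq, 41, 49) <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("ATGCCCTGA")))
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  rows <- rbind(
    data.frame(chrom = "chr1", type = c("gene", "mRNA", "exon", "CDS"),
               start = c(8, 8, 8, 11), end = c(22, 22, 22, 19), strand = "+",
               transcript_id = "tP.1", gene_id = "tP"),
    data.frame(chrom = "chr1", type = c("gene", "mRNA", "exon", "CDS"),
               start = c(38, 38, 38, 41), end = c(52, 52, 52, 49), strand = "-",
               transcript_id = "tM.1", gene_id = "tM"))
  ann <- annotation_from_features(c(chr1 = 60L), rows)
  .fixture_cache$tiny <- list(genome = genome, annotation = ann,
                              models = transcript_models(ann))
  .fixture_cache$tiny
}

# write a small VCF from literal body lines (header supplied)
write_test_vcf <- function(body, path = tempfile(fileext = ".vcf"),
                           sample = "S1", contigs = c(chr1 = 100000L)) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"fs\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"mq\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

# construct a bare record table like read_vcf() output
make_records <- function(chrom = "chr1", pos, ref, alt, qd = 20, fs = 1,
                         mq = 60, gq = 99L, gt = "1/1", line_id = "L") {
  data.frame(line_id = line_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, qd = qd, fs = fs, mq = mq, gq = gq, gt = gt,
             stringsAsFactors = FALSE)
}

# mutation table with given SBS / INS / DEL counts (for count arithmetic)
make_count_mutations <- function(line_id, n_sbs, n_indel) {
  n <- n_sbs + n_indel
  if (n == 0) {
    return(data.frame(line_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      mclass = character(), indel_len = integer()))
  }
  data.frame(line_id = line_id, chrom = "chr1", pos = seq_len(n),
             ref = c(rep("A", n_sbs), rep("AT", n_indel)),
             alt = c(rep("G", n_sbs), rep("A", n_indel)),
             mclass = c(rep("SBS", n_sbs), rep("DEL", n_indel)),
             indel_len = c(rep(0L, n_sbs), rep(1L, n_indel)),
             stringsAsFactors = FALSE)
}

# full pipeline run on the shared fixture, cached (used by the pipeline and
# acceptance suites)
pipeline_fixture <- function() {
  if (!is.null(.fixture_cache$pipeline)) return(.fixture_cache$pipeline)
  fx <- shared_fixture()
  out <- file.path(tempdir(), "cibmut-pipeline-out")
  unlink(out, recursive = TRUE)
  cfg <- pipeline_config(fx$paths$fasta, fx$paths$gff3, fx$paths$vcf,
                         ponds = list(WT = c("mA", "mB")), outdir = out,
                         window_sizes = c(10000, 2000))
  .fixture_cache$pipeline <- list(fx = fx, cfg = cfg,
                                  run = run_pipeline(cfg, quiet = TRUE),
                                  out = out)
  .fixture_cache$pipeline
}

md5_of_dir <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE, recursive = TRUE))
  setNames(as.character(tools::md5sum(files)), basename(files))
}
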