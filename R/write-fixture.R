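#' Write a synthetic fixture to disk
#'
#' Emits the genome FASTA (60-column wrap), the gene models as GFF3, one VCF
#' 4.2 file per line (the wild-type VCF holds only the shared background
#' variants; each mutant VCF holds background + induced + decoy records),
#' the truth TSV and a metadata JSON echoing the seed. All files are plain
#' text and re-readable by the variant-io layer with a lossless round trip
#' of (chrom, pos, ref, alt).
#'
#' @param dir output directory (created if missing).
#' @param genome named [Biostrings::DNAStringSet].
#' @param annotation `genome_annotation`.
#' @param planted result of [plant_mutations()].
#' @return named list of file paths (`fasta`, `gff3`, `truth`, `metadata`,
#'   and `vcf` = named vector of per-line VCF paths).
#' @export
write_fixture <- function(dir, genome, annotation, planted) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop_badarg("cannot create output directory: ", dir)
  }
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fasta, width = 60)

  gff3 <- file.path(dir, "genes.gff3")
  write_gff3(annotation, gff3)

  lines <- c(planted$wildtype_id, planted$line_ids)
  vcfs <- setNames(file.path(dir, paste0(lines, ".vcf")), lines)
  for (l in lines) {
    rec <- planted$records[planted$records$line_id == l, , drop = FALSE]
    write_vcf_records(rec, vcfs[[l]], annotation$contig_lengths, sample_id = l)
  }

  truth_path <- file.path(dir, "truth.tsv")
  write.table(planted$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta_path <- file.path(dir, "metadata.json")
  jsonlite::write_json(list(seed = planted$seed, lines = planted$line_ids,
                            wildtype = planted$wildtype_id,
                            n_mutations = nrow(planted$truth)),
                       meta_path, auto_unbox = TRUE, pretty = TRUE)
  list(fasta = fasta, gff3 = gff3, vcf = vcfs, truth = truth_path,
       metadata = meta_path)
}

write_gff3 <- function(annotation, path) {
  f <- annotation$features
  if (!nrow(f)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  id <- ifelse(f$type == "gene", f$gene_id,
               ifelse(f$type == "mRNA", f$transcript_id, NA))
  parent <- ifelse(f$type == "gene", NA,
                   ifelse(f$type == "mRNA", f$gene_id, f$transcript_id))
  gr <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start, f$end),
                               strand = f$strand)
  gr$type <- f$type
  gr$ID <- id
  gr$Parent <- IRanges::CharacterList(
    lapply(parent, function(p) if (is.na(p)) character() else p))
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}

#' Read a GFF3 annotation file
#'
#' Parses gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR features
#' (1-based inclusive) into the package's annotation container.
#'
#' @param path GFF3 file.
#' @param contig_lengths named lengths; if `NULL`, taken from the maximum
#'   feature end per chromosome (a FASTA-derived vector is preferred).
#' @return a `genome_annotation`.
#' @export
read_gff3_annotation <- function(path, contig_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- gr$type %in% c("gene", "mRNA", "exon", "CDS",
                         "five_prime_UTR", "three_prime_UTR")
  gr <- gr[keep]
  parent <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  id <- if (!is.null(gr$ID)) gr$ID else rep(NA_character_, length(gr))
  type <- as.character(gr$type)
  tid <- ifelse(type == "mRNA", id, ifelse(type == "gene", NA, parent))
  gid <- ifelse(type == "gene", id, ifelse(type == "mRNA", parent, NA))
  # fill transcript_id for gene rows / gene_id for sub-features via mRNA rows
  mrna <- type == "mRNA"
  tid[type == "gene"] <- tid[mrna][match(id[type == "gene"], gid[mrna])]
  gid[!(type %in% c("gene", "mRNA"))] <-
    gid[mrna][match(tid[!(type %in% c("gene", "mRNA"))], tid[mrna])]
  f <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  type = type,
                  start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  transcript_id = tid, gene_id = gid,
                  stringsAsFactors = FALSE)
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(f$end, f$chrom, max)
    contig_lengths <- setNames(as.integer(contig_lengths), names(contig_lengths))
  }
  annotation_from_features(contig_lengths, f)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# minimal single-sample VCF 4.2 emitter (records fully under our control;
# files are re-read through VariantAnnotation as the conformance check)
write_vcf_records <- function(records, path, contig_lengths, sample_id) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                   as.integer(contig_lengths)),
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_id), collapse = "\t"))
  if (nrow(records)) {
    records <- records[order(records$chrom, records$pos), , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\tQD=%s;FS=%s;MQ=%s\tGT:GQ\t%s:%d",
                    records$chrom, records$pos, records$ref, records$alt,
                    format(records$qd, trim = TRUE), format(records$fs, trim = TRUE),
                    format(records$mq, trim = TRUE), records$gt, records$gq)
  } else body <- character()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a fixture truth table
#' @param path truth TSV written by [write_fixture()].
#' @return data.frame.
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Generate and write a complete synthetic fixture in one call
#'
#' Convenience wrapper chaining [generate_genome()], [plant_mutations()] and
#' [write_fixture()]; all randomness flows from the single `seed`.
#'
#' @inheritParams generate_genome
#' @inheritParams plant_mutations
#' @param dir output directory.
#' @param ... passed to [plant_mutations()].
#' @return list with `paths` (from [write_fixture()]), `genome`,
#'   `annotation`, `planted`.
#' @export
simulate_fixture <- function(dir, n_chromosomes = 2, chrom_length = 100000,
                             gene_count = 10, n_mutations = 1000, seed = 1,
                             params = spectrum_params(), hotspots = NULL,
                             line_ids = c("mut1", "mut2"), ...) {
  gen <- generate_genome(n_chromosomes, chrom_length, gene_count, seed)
  planted <- plant_mutations(gen$genome, gen$annotation, params = params,
                             hotspots = hotspots, n_mutations = n_mutations,
                             seed = seed + 1L, line_ids = line_ids, ...)
  paths <- write_fixture(dir, gen$genome, gen$annotation, planted)
  list(paths = paths, genome = gen$genome, annotation = gen$annotation,
       planted = planted)
}
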