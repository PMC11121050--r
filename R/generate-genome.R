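#' Generate a toy genome with non-overlapping gene models
#'
#' Produces uppercase ACGT chromosome sequences and a strand-assigned
#' annotation in which every transcript has >= 1 exon and a CDS whose spliced
#' sequence starts with ATG, ends with a stop codon, contains no internal
#' stop and has length divisible by 3. Gene loci are packed left to right
#' with random gaps; an explicit error is raised when the requested gene
#' count cannot fit. Deterministic given `seed`.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bp (>= 10000).
#' @param gene_count total number of genes across the genome.
#' @param seed integer RNG seed.
#' @param gc_fraction background GC content (default 0.5, uniform ACGT).
#' @return a list with elements `genome` (a named
#'   [Biostrings::DNAStringSet]) and `annotation` (see
#'   [annotation_from_features()]): contig lengths plus a feature table with
#'   1-based inclusive `gene`/`mRNA`/`exon`/`CDS`/UTR intervals.
#' @export
generate_genome <- function(n_chromosomes, chrom_length, gene_count, seed,
                            gc_fraction = 0.5) {
  if (chrom_length < 10000) stop_badarg("chrom_length must be >= 10000")
  if (gene_count < 0) stop_badarg("gene_count must be >= 0")
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chromosomes))
  base_probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
                  gc_fraction / 2, (1 - gc_fraction) / 2)
  seqs <- lapply(chroms, function(ch) {
    sample(BASES, chrom_length, replace = TRUE, prob = base_probs)
  })
  names(seqs) <- chroms

  feats <- list()
  if (gene_count > 0) {
    per_chrom <- tabulate(rep_len(seq_len(n_chromosomes), gene_count),
                          nbins = n_chromosomes)
    # worst-case gene span: 3 exons * 450 + 2 introns * 300 + UTRs + margins
    max_span <- 3000
    for (i in seq_len(n_chromosomes)) {
      if (per_chrom[i] * (max_span + 100) + 200 > chrom_length) {
        stop_badarg(sprintf(
          "cannot pack %d genes into a %d bp chromosome", per_chrom[i],
          chrom_length))
      }
      cursor <- 100L
      slack <- chrom_length - 200L - per_chrom[i] * max_span
      gaps <- if (per_chrom[i] > 0) {
        g <- runif(per_chrom[i]); floor(g / sum(g) * slack)
      } else integer()
      for (j in seq_len(per_chrom[i])) {
        cursor <- cursor + gaps[j]
        gid <- sprintf("%s_g%d", chroms[i], j)
        gene <- random_gene(gid, chroms[i], cursor)
        seqs[[i]][gene$coding_pos] <- gene$coding_bases
        feats[[length(feats) + 1L]] <- gene$features
        cursor <- cursor + max_span
      }
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else empty_features()
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(genome) <- chroms
  list(genome = genome,
       annotation = annotation_from_features(
         setNames(rep(chrom_length, n_chromosomes), chroms), features))
}

# lay out one gene starting at `start`: optional UTRs, 1-3 exons, CDS
# multiple of 3; returns genomic positions to overwrite so the spliced CDS
# translates ATG..stop with no internal stop.
random_gene <- function(gene_id, chrom, start) {
  n_exons <- sample(1:3, 1)
  n_codons <- sample(50:140, 1)                 # incl. start and stop codon
  cds_len <- 3L * n_codons
  utr5_len <- sample(20:80, 1)
  utr3_len <- sample(20:80, 1)
  strand <- sample(c("+", "-"), 1)

  # split CDS length across exons (each piece >= 3 bp)
  cuts <- if (n_exons > 1) sort(sample(seq(3, cds_len - 3, by = 3), n_exons - 1)) else integer()
  pieces <- diff(c(0L, cuts, cds_len))
  introns <- if (n_exons > 1) sample(80:300, n_exons - 1, replace = TRUE) else integer()

  # genomic layout (plus-strand order): utr5' | cds pieces with introns | utr3'
  cds_iv <- matrix(0L, n_exons, 2)
  cursor <- start + utr5_len
  for (k in seq_len(n_exons)) {
    cds_iv[k, ] <- c(cursor, cursor + pieces[k] - 1L)
    cursor <- cds_iv[k, 2] + 1L + if (k < n_exons) introns[k] else 0L
  }
  tx_start <- start
  tx_end <- cursor + utr3_len - 1L
  # UTRs are part of the first/last exon
  exon_iv <- cds_iv
  exon_iv[1, 1] <- tx_start
  exon_iv[n_exons, 2] <- tx_end
  utr_left <- c(tx_start, cds_iv[1, 1] - 1L)
  utr_right <- c(cds_iv[n_exons, 2] + 1L, tx_end)

  # coding sequence: ATG + internal codons with no stop + stop codon
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(matrix(sample(BASES, 3 * (n_codons - 2), replace = TRUE), ncol = 3),
                  1, paste, collapse = "")
  while (any(codons %in% stops)) {
    codons[codons %in% stops] <- replicate(sum(codons %in% stops),
      paste(sample(BASES, 3, replace = TRUE), collapse = ""))
  }
  coding <- paste0("ATG", paste(codons, collapse = ""), sample(stops, 1))
  genomic_cds <- if (strand == "+") coding else reverse_complement(coding)
  coding_pos <- unlist(lapply(seq_len(n_exons), function(k) cds_iv[k, 1]:cds_iv[k, 2]))

  tid <- paste0(gene_id, ".1")
  rows <- list(
    feature_row(chrom, "gene", tx_start, tx_end, strand, tid, gene_id),
    feature_row(chrom, "mRNA", tx_start, tx_end, strand, tid, gene_id))
  for (k in seq_len(n_exons)) {
    rows[[length(rows) + 1L]] <- feature_row(chrom, "exon", exon_iv[k, 1],
                                             exon_iv[k, 2], strand, tid, gene_id)
    rows[[length(rows) + 1L]] <- feature_row(chrom, "CDS", cds_iv[k, 1],
                                             cds_iv[k, 2], strand, tid, gene_id)
  }
  utr5 <- if (strand == "+") utr_left else utr_right
  utr3 <- if (strand == "+") utr_right else utr_left
  rows[[length(rows) + 1L]] <- feature_row(chrom, "five_prime_UTR", utr5[1],
                                           utr5[2], strand, tid, gene_id)
  rows[[length(rows) + 1L]] <- feature_row(chrom, "three_prime_UTR", utr3[1],
                                           utr3[2], strand, tid, gene_id)
  list(features = do.call(rbind, rows),
       coding_pos = coding_pos,
       coding_bases = strsplit(genomic_cds, "")[[1]])
}

feature_row <- function(chrom, type, start, end, strand, transcript_id, gene_id) {
  data.frame(chrom = chrom, type = type, start = as.integer(start),
             end = as.integer(end), strand = strand,
             transcript_id = transcript_id, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

empty_features <- function() {
  data.frame(chrom = character(), type = character(), start = integer(),
             end = integer(), strand = character(), transcript_id = character(),
             gene_id = character(), stringsAsFactors = FALSE)
}

#' Assemble a genome annotation from contig lengths and a feature table
#'
#' @param contig_lengths named integer vector of chromosome lengths (bp).
#' @param features data.frame with columns chrom, type, start, end, strand,
#'   transcript_id, gene_id; coordinates 1-based inclusive.
#' @return an object of class `genome_annotation`.
#' @export
annotation_from_features <- function(contig_lengths, features = empty_features()) {
  stopifnot(!is.null(names(contig_lengths)))
  structure(list(contig_lengths = contig_lengths, features = features),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d contigs (%.3g bp), %d transcripts\n",
              length(x$contig_lengths), sum(as.numeric(x$contig_lengths)),
              length(unique(x$features$transcript_id[x$features$type == "mRNA"]))))
  invisible(x)
}

#' Strand-aware transcript models from an annotation
#'
#' @param annotation a `genome_annotation`.
#' @return named list of transcript models; each has `transcript_id`,
#'   `chrom`, `strand` and sorted interval matrices `exons`, `cds`, `utr5`,
#'   `utr3` (1-based inclusive, genomic order).
#' @export
transcript_models <- function(annotation) {
  f <- annotation$features
  tids <- unique(f$transcript_id[f$type == "mRNA"])
  iv <- function(rows) {
    m <- as.matrix(rows[order(rows$start), c("start", "end"), drop = FALSE])
    dimnames(m) <- NULL
    m
  }
  models <- lapply(tids, function(tid) {
    ft <- f[f$transcript_id == tid, , drop = FALSE]
    list(transcript_id = tid,
         chrom = ft$chrom[1],
         strand = ft$strand[1],
         tx_start = min(ft$start), tx_end = max(ft$end),
         exons = iv(ft[ft$type == "exon", ]),
         cds = iv(ft[ft$type == "CDS", ]),
         utr5 = iv(ft[ft$type == "five_prime_UTR", ]),
         utr3 = iv(ft[ft$type == "three_prime_UTR", ]))
  })
  setNames(models, tids)
}
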