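IMPACT_ORDER <- c(frameshift = 5, nonsense = 4, nonsynonymous = 3,
                  inframe_indel = 2, synonymous = 1)

#' Genomic-context category of mutations
#'
#' Assigns exactly one of `exonic` (CDS), `UTR5`, `UTR3`, `intron`,
#' `upstream`, `downstream`, `intergenic` to each mutation position using
#' the precedence exonic > UTR5 > UTR3 > intron > upstream > downstream >
#' intergenic. Upstream/downstream are measured from the transcript bounds
#' on the transcript's strand within the given windows.
#'
#' @param mutations data.frame with columns chrom, pos (1-based).
#' @param annotation `genome_annotation`.
#' @param upstream_bp,downstream_bp window sizes in bp (default 1000, the
#'   ANNOVAR convention).
#' @return character vector of categories.
#' @export
locate_mutations <- function(mutations, annotation, upstream_bp = 1000,
                             downstream_bp = 1000) {
  unknown <- setdiff(unique(mutations$chrom), names(annotation$contig_lengths))
  if (length(unknown)) stop_badarg("unknown chromosome: ", unknown[1])
  n <- nrow(mutations)
  cat_rank <- c(exonic = 1, UTR5 = 2, UTR3 = 3, intron = 4,
                upstream = 5, downstream = 6, intergenic = 7)
  best <- rep(7L, n)
  f <- annotation$features
  if (nrow(f)) {
    pts <- GenomicRanges::GRanges(mutations$chrom,
                                  IRanges::IRanges(mutations$pos, mutations$pos))
    assign_cat <- function(gr, rank) {
      if (!length(gr)) return()
      hits <- GenomicRanges::findOverlaps(pts, gr, ignore.strand = TRUE)
      idx <- unique(S4Vectors::queryHits(hits))
      best[idx] <<- pmin(best[idx], rank)
    }
    ftype_gr <- function(types) {
      r <- f[f$type %in% types, , drop = FALSE]
      GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start, r$end))
    }
    assign_cat(ftype_gr("CDS"), 1L)
    assign_cat(ftype_gr("five_prime_UTR"), 2L)
    assign_cat(ftype_gr("three_prime_UTR"), 3L)
    assign_cat(ftype_gr("mRNA"), 4L)   # inside transcript, below exon ranks
    tx <- f[f$type == "mRNA", , drop = FALSE]
    if (nrow(tx)) {
      plus <- tx$strand == "+"
      up_start <- ifelse(plus, pmax(1, tx$start - upstream_bp), tx$end + 1)
      up_end <- ifelse(plus, tx$start - 1, tx$end + upstream_bp)
      dn_start <- ifelse(plus, tx$end + 1, pmax(1, tx$start - downstream_bp))
      dn_end <- ifelse(plus, tx$end + downstream_bp, tx$start - 1)
      valid_up <- up_end >= up_start
      valid_dn <- dn_end >= dn_start
      assign_cat(GenomicRanges::GRanges(tx$chrom[valid_up],
                   IRanges::IRanges(up_start[valid_up], up_end[valid_up])), 5L)
      assign_cat(GenomicRanges::GRanges(tx$chrom[valid_dn],
                   IRanges::IRanges(dn_start[valid_dn], dn_end[valid_dn])), 6L)
    }
  }
  names(cat_rank)[best]
}

#' Coding effect of an SBS within one transcript
#'
#' Rebuilds the affected codon on the coding strand (reverse-complementing
#' for minus-strand transcripts), translates it with the standard nuclear
#' codon table and compares amino acids: same residue is synonymous, a new
#' stop codon is nonsense, any other change (including loss of the
#' reference stop) is nonsynonymous.
#'
#' @param chrom,pos,ref,alt the SBS (1-based; `ref` must match the genome).
#' @param model one transcript model from [transcript_models()].
#' @param genome named [Biostrings::DNAStringSet].
#' @return list: category, transcript_id, codon_change (e.g. `"AAA>TAA"`),
#'   aa_change (e.g. `"K>*"`).
#' @export
coding_effect_sbs <- function(chrom, pos, ref, alt, model, genome) {
  if (chrom != model$chrom) stop_badarg("mutation and transcript on different chromosomes")
  cum <- c(0L, cumsum(model$cds[, 2] - model$cds[, 1] + 1L))
  k <- which(pos >= model$cds[, 1] & pos <= model$cds[, 2])
  if (!length(k)) stop_badarg("position not in a CDS interval of ", model$transcript_id)
  gbase <- substr(as.character(genome[[chrom]]), pos, pos)
  if (gbase != ref) {
    stop_badarg(sprintf("ref allele %s does not match genome base %s at %s:%d",
                        ref, gbase, chrom, pos))
  }
  # position within the spliced CDS on the coding strand (1-based)
  plus_offset <- cum[k] + (pos - model$cds[k, 1] + 1L)
  total <- cum[length(cum)]
  cds_pos <- if (model$strand == "+") plus_offset else total - plus_offset + 1L
  cds_seq <- spliced_cds(model, genome)
  codon_i <- (cds_pos - 1L) %/% 3L
  codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  within <- (cds_pos - 1L) %% 3L + 1L
  alt_coding <- if (model$strand == "+") alt else reverse_complement(alt)
  new_codon <- codon
  substr(new_codon, within, within) <- alt_coding
  aa0 <- translate_dna(codon)
  aa1 <- translate_dna(new_codon)
  category <- if (aa0 == aa1) "synonymous"
              else if (aa1 == "*") "nonsense"
              else "nonsynonymous"       # includes stop-loss (no class of its own)
  list(category = category, transcript_id = model$transcript_id,
       codon_change = paste0(codon, ">", new_codon),
       aa_change = paste0(aa0, ">", aa1))
}

#' Coding effect of an InDel within one transcript
#'
#' The frame is affected only by the coding-length change: the number of
#' coding bases inserted or removed, mod 3. InDels spanning a CDS boundary
#' are classified by their CDS overlap.
#'
#' @inheritParams coding_effect_sbs
#' @return list: category (`frameshift` or `inframe_indel`), transcript_id,
#'   codon_change `""`, aa_change `""`.
#' @export
coding_effect_indel <- function(chrom, pos, ref, alt, model) {
  if (chrom != model$chrom) stop_badarg("mutation and transcript on different chromosomes")
  clen <- coding_overlap_len(pos, ref, alt, model)
  if (clen == 0) stop_badarg("InDel does not overlap the CDS of ", model$transcript_id)
  list(category = if (clen %% 3 == 0) "inframe_indel" else "frameshift",
       transcript_id = model$transcript_id, codon_change = "", aa_change = "")
}

#' Coding-effect calls and the per-line effect table
#'
#' Calls one effect per coding mutation, resolving multiple overlapping
#' transcripts by highest impact (frameshift > nonsense > nonsynonymous >
#' inframe_indel > synonymous), ties by lexicographic transcript id. The
#' per-line table counts synonymous / nonsynonymous / nonsense / frameshift
#' and reports the high-impact total (nonsense + frameshift) and its
#' per-line average.
#'
#' @param mutations induced-mutation data.frame (line_id, chrom, pos, ref,
#'   alt, mclass, indel_len).
#' @param annotation `genome_annotation`.
#' @param genome named [Biostrings::DNAStringSet].
#' @return list with `calls` (one row per coding mutation: line_id, chrom,
#'   pos, ref, alt, category, transcript_id, codon_change, aa_change),
#'   `table` (per-line counts plus Total and Average rows) and
#'   `high_impact_average`.
#' @export
effect_table <- function(mutations, annotation, genome) {
  models <- transcript_models(annotation)
  calls <- list()
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    cand <- list()
    for (mod in models) {
      if (mod$chrom != m$chrom) next
      eff <- if (m$mclass == "SBS") {
        if (any(m$pos >= mod$cds[, 1] & m$pos <= mod$cds[, 2])) {
          coding_effect_sbs(m$chrom, m$pos, m$ref, m$alt, mod, genome)
        } else NULL
      } else {
        if (coding_overlap_len(m$pos, m$ref, m$alt, mod) > 0) {
          coding_effect_indel(m$chrom, m$pos, m$ref, m$alt, mod)
        } else NULL
      }
      if (!is.null(eff)) cand[[length(cand) + 1L]] <- eff
    }
    if (length(cand)) {
      imp <- vapply(cand, function(e) IMPACT_ORDER[[e$category]], 0)
      tid <- vapply(cand, function(e) e$transcript_id, "")
      pick <- cand[[order(-imp, tid)[1]]]
      calls[[length(calls) + 1L]] <- data.frame(
        line_id = m$line_id, chrom = m$chrom, pos = m$pos, ref = m$ref,
        alt = m$alt, category = pick$category,
        transcript_id = pick$transcript_id, codon_change = pick$codon_change,
        aa_change = pick$aa_change, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(line_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), category = character(),
               transcript_id = character(), codon_change = character(),
               aa_change = character(), stringsAsFactors = FALSE)
  lines <- sort(unique(mutations$line_id))
  cats <- c("synonymous", "nonsynonymous", "nonsense", "frameshift")
  tab <- effect_count_table(calls, lines, cats)
  list(calls = calls, table = tab,
       high_impact_average = attr(tab, "high_impact_average"))
}

effect_count_table <- function(calls, lines, cats) {
  counts <- sapply(cats, function(cc) {
    vapply(lines, function(l) sum(calls$line_id == l & calls$category == cc), 0L)
  })
  counts <- matrix(counts, nrow = length(lines),
                   dimnames = list(lines, cats))
  tab <- data.frame(line_id = lines, counts, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  totals <- colSums(counts)
  tab <- rbind(tab,
               data.frame(line_id = "Total", t(totals), check.names = FALSE),
               data.frame(line_id = "Average", t(round(totals / max(length(lines), 1), 1)),
                          check.names = FALSE))
  hi <- (totals[["nonsense"]] + totals[["frameshift"]]) / max(length(lines), 1)
  attr(tab, "high_impact_average") <- hi
  tab
}

#' Per-line effect table from precomputed effect counts
#'
#' Aggregates an already-tabulated per-line count table (e.g. re-encoded
#' published counts) into totals, per-category averages and the
#' high-impact (nonsense + frameshift) per-line average, rounded to the
#' nearest integer for the headline figure.
#'
#' @param counts data.frame with columns line_id, synonymous,
#'   nonsynonymous, nonsense, frameshift.
#' @return list: totals (named), averages (named, 1 decimal),
#'   high_impact_average (exact), high_impact_headline (nearest integer).
#' @export
summarize_effect_counts <- function(counts) {
  cats <- c("synonymous", "nonsynonymous", "nonsense", "frameshift")
  stopifnot(all(cats %in% names(counts)))
  totals <- vapply(cats, function(cc) sum(counts[[cc]]), 0)
  n <- nrow(counts)
  hi <- (totals[["nonsense"]] + totals[["frameshift"]]) / n
  list(totals = totals, averages = round(totals / n, 1),
       high_impact_average = hi, high_impact_headline = round(hi))
}
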