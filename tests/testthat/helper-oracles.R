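# independent oracles: deliberately separate implementations from the
# package code paths they check

# -- translation oracle (plain lookup in the standard genetic code) ----------

oracle_translate <- function(dna) {
  codons <- substring(dna, seq(1, nchar(dna) - 2, by = 3),
                      seq(3, nchar(dna), by = 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# splice the CDS of `model` out of a plain character chromosome sequence,
# optionally substituting one genomic base
oracle_spliced_cds <- function(model, chrom_seq, sub_pos = NULL, sub_base = NULL) {
  if (!is.null(sub_pos)) substr(chrom_seq, sub_pos, sub_pos) <- sub_base
  parts <- apply(model$cds, 1, function(iv) substr(chrom_seq, iv[1], iv[2]))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") oracle_revcomp(s) else s
}

# full-CDS retranslation effect call for a coding SBS
oracle_sbs_effect <- function(pos, alt, model, chrom_seq) {
  p0 <- oracle_translate(oracle_spliced_cds(model, chrom_seq))
  p1 <- oracle_translate(oracle_spliced_cds(model, chrom_seq, pos, alt))
  if (identical(p0, p1)) return("synonymous")
  d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])[1]
  if (substr(p1, d, d) == "*") "nonsense" else "nonsynonymous"
}

# coding-length change of an anchored InDel, computed directly
oracle_indel_effect <- function(pos, ref, alt, model) {
  if (nchar(alt) > nchar(ref)) {
    inside <- any(pos >= model$cds[, 1] & pos < model$cds[, 2])
    clen <- if (inside) nchar(alt) - nchar(ref) else 0L
  } else {
    span <- (pos + 1L):(pos + nchar(ref) - nchar(alt))
    clen <- sum(vapply(span, function(p)
      any(p >= model$cds[, 1] & p <= model$cds[, 2]), TRUE))
  }
  if (clen == 0) return(NA_character_)
  if (clen %% 3 == 0) "inframe_indel" else "frameshift"
}

# -- Mendelian selfing simulator ---------------------------------------------

# propagate n_mut heterozygous M1 mutations through `generations - 1`
# rounds of single-seed-descent selfing; returns the fraction of the
# original mutations that are homozygous mutant at the end
oracle_selfing_hom_fraction <- function(n_mut, generations, seed) {
  set.seed(seed)
  state <- rep("het", n_mut)                 # het / hom / lost
  for (g in seq_len(generations - 1)) {
    het <- state == "het"
    u <- stats::runif(sum(het))
    state[het] <- ifelse(u < 0.25, "hom", ifelse(u < 0.75, "het", "lost"))
  }
  mean(state == "hom")
}

# -- hypergeometric overlap by exhaustive enumeration ------------------------

# P(|A ∩ B| >= k) when B is a uniform random size-b subset of n windows and
# A is a fixed size-a subset (symmetry makes fixing A lossless)
oracle_overlap_tail <- function(n, a, b, k) {
  A <- seq_len(a)
  sets <- utils::combn(n, b)
  hits <- apply(sets, 2, function(s) sum(s %in% A) >= k)
  mean(hits)
}
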