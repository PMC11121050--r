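#' Parameters of a planted mutation spectrum
#'
#' Describes the statistical structure of a synthetic induced-mutation set:
#' the transition share among single base substitutions (SBSs), the twelve
#' directional substitution weights, the InDel fraction, the InDel length
#' distribution over 1..50 bp and the insertion/deletion balance.
#'
#' Defaults emulate a carbon-ion-beam mutagenesis spectrum: Ti/(Ti+Tv) =
#' 0.565 (a Ti/Tv ratio of ~1.3), G>A and C>T carrying two thirds of the
#' transitions, InDels ~11.8% of mutations with lengths skewed so that 1-2 bp
#' events are ~65% of InDels (truncated geometric, p = 1 - sqrt(0.35)).
#'
#' @param ti_fraction proportion of SBSs that are transitions, in [0,1].
#' @param sub_weights named nonnegative weights over the 12 directional
#'   substitutions (names as in [substitution_type()] output, e.g. `"G>A"`).
#'   Must be consistent with `ti_fraction`: the transition weights
#'   (A>G, G>A, C>T, T>C) must sum to `ti_fraction` of the total within 1e-9.
#'   If `NULL`, weights are built from `ti_fraction` with G>A/C>T taking 2/3
#'   of the transition mass and uniform transversions.
#' @param indel_fraction proportion of mutations that are InDels, in [0,1].
#' @param indel_len_dist probability vector over lengths 1..50 bp, summing
#'   to 1 within 1e-9. Default: truncated geometric with P(len<=2) ~ 0.655.
#' @param ins_del_balance proportion of InDels that are insertions.
#' @return an object of class `spectrum_params`.
#' @export
spectrum_params <- function(ti_fraction = 0.565,
                            sub_weights = NULL,
                            indel_fraction = 0.118,
                            indel_len_dist = NULL,
                            ins_del_balance = 0.5) {
  for (p in c(ti_fraction, indel_fraction, ins_del_balance)) {
    if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1) {
      stop_badarg("proportions must be single numbers in [0,1]")
    }
  }
  if (is.null(sub_weights)) {
    sub_weights <- default_sub_weights(ti_fraction)
  }
  if (is.null(names(sub_weights)) || !setequal(names(sub_weights), SUB_TYPES)) {
    stop_badarg("sub_weights must be named with the 12 directional types")
  }
  sub_weights <- sub_weights[SUB_TYPES]
  if (any(sub_weights < 0)) stop_badarg("sub_weights must be nonnegative")
  ti_types <- c("A>G", "G>A", "C>T", "T>C")
  ti_mass <- sum(sub_weights[ti_types]) / sum(sub_weights)
  if (abs(ti_mass - ti_fraction) > 1e-9) {
    stop_badarg(sprintf(
      "sub_weights transition mass (%.6f) inconsistent with ti_fraction (%.6f)",
      ti_mass, ti_fraction))
  }
  if (is.null(indel_len_dist)) {
    p <- 1 - sqrt(0.35)            # P(1)+P(2) = 2p - p^2 = 0.65
    indel_len_dist <- p * (1 - p)^(0:49)
    indel_len_dist <- indel_len_dist / sum(indel_len_dist)
  }
  if (length(indel_len_dist) != 50 || any(indel_len_dist < 0) ||
      abs(sum(indel_len_dist) - 1) > 1e-9) {
    stop_badarg("indel_len_dist must be 50 nonnegative probabilities summing to 1")
  }
  structure(list(ti_fraction = ti_fraction,
                 sub_weights = sub_weights,
                 indel_fraction = indel_fraction,
                 indel_len_dist = indel_len_dist,
                 ins_del_balance = ins_del_balance),
            class = "spectrum_params")
}

default_sub_weights <- function(ti_fraction) {
  w <- setNames(numeric(12), SUB_TYPES)
  # G>A and C>T carry 2/3 of the transition mass, A>G/T>C the rest
  w[c("G>A", "C>T")] <- ti_fraction * (2 / 3) / 2
  w[c("A>G", "T>C")] <- ti_fraction * (1 / 3) / 2
  tv <- setdiff(SUB_TYPES, c("A>G", "G>A", "C>T", "T>C"))
  w[tv] <- (1 - ti_fraction) / length(tv)
  w
}

#' Planted high-frequency (hotspot) regions
#'
#' Regions whose per-bp mutation sampling weight is multiplied by `fold`
#' relative to the uniform background, emulating the localized
#' high-frequency mutation regions seen in heavy-ion mutagenesis panels.
#' Coordinates are 0-based half-open (BED convention).
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open bounds, recycled to a common length.
#' @param fold per-bp rate multiplier, >= 1.
#' @return an object of class `hotspot_spec` (a data.frame).
#' @export
hotspot_spec <- function(chrom = character(), start = integer(),
                         end = integer(), fold = numeric()) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), fold = as.numeric(fold),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$fold < 1)) stop_badarg("hotspot fold must be >= 1")
    if (any(df$end <= df$start)) stop_badarg("hotspot end must exceed start")
    for (ch in unique(df$chrom)) {
      r <- df[df$chrom == ch, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)])) {
        stop_badarg("hotspot regions overlap on ", ch)
      }
    }
  }
  class(df) <- c("hotspot_spec", "data.frame")
  df
}
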