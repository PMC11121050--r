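#' Bundled example: per-line M6 mutation totals of a CIB-irradiated rice panel
#'
#' A re-encoding of the published per-line mutation summary of eight M6 rice
#' mutant lines derived from three wild-type backgrounds after carbon-ion-beam
#' irradiation of dehulled seeds: total variants, SBSs and InDels per line.
#' Useful as a desk-scale input for back-projection and spectrum arithmetic.
#'
#' @return data.frame with columns wildtype_id, line_id, total, sbs, indels.
#' @export
cib_line_summary <- function() {
  read.delim(system.file("extdata", "line_summary.tsv", package = "cibmut"),
             stringsAsFactors = FALSE)
}

#' Bundled example: per-line coding-effect counts of the same rice panel
#'
#' Synonymous / nonsynonymous / nonsense / frameshift counts per mutant
#' line, grouped by mutation pond.
#'
#' @return data.frame with columns pond, line_id, synonymous,
#'   nonsynonymous, nonsense, frameshift.
#' @export
cib_effect_counts <- function() {
  read.delim(system.file("extdata", "effect_counts.tsv", package = "cibmut"),
             stringsAsFactors = FALSE)
}
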