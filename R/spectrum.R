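#' Is a substitution a transition?
#'
#' Transitions stay within a base class (purine>purine A<->G or
#' pyrimidine>pyrimidine C<->T); the remaining eight ordered pairs are
#' transversions.
#'
#' @param ref,alt single uppercase bases, `ref != alt`; vectorized.
#' @return logical vector.
#' @export
is_transition <- function(ref, alt) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L)) {
    stop_badarg("is_transition expects single bases")
  }
  check_bases(ref); check_bases(alt)
  if (any(ref == alt)) stop_badarg("ref and alt must differ")
  unname(TRANSITION_PARTNER[ref] == alt)
}

#' Directional substitution type
#'
#' Returns the ordered label `"ref>alt"` among the 12 directional
#' substitution types; no pyrimidine-strand collapsing is applied.
#'
#' @inheritParams is_transition
#' @param collapse if `TRUE`, fold to the 6 pyrimidine-reference types
#'   (C>A, C>G, C>T, T>A, T>C, T>G) by complementing purine-reference pairs.
#' @return character vector of labels.
#' @export
substitution_type <- function(ref, alt, collapse = FALSE) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L)) {
    stop_badarg("substitution_type expects single bases")
  }
  check_bases(ref); check_bases(alt)
  if (any(ref == alt)) stop_badarg("ref and alt must differ")
  if (collapse) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    flip <- ref %in% c("A", "G")
    ref[flip] <- comp[ref[flip]]
    alt[flip] <- comp[alt[flip]]
  }
  paste0(ref, ">", alt)
}

#' Summarize a mutation set into its spectrum
#'
#' Tallies SBS/INS/DEL counts, transition/transversion counts and their
#' ratio, the 12 directional substitution counts and the InDel length
#' histogram (1..50 bp, split insertion/deletion) for one line or pond.
#'
#' @param mutations induced-mutation data.frame (columns chrom, pos, ref,
#'   alt, mclass, indel_len); may be empty.
#' @param scope scope identifier (line or pond id).
#' @return an object of class `spectrum_summary`: scope, n_total, n_sbs,
#'   n_ins, n_del, ti, tv, ti_tv_ratio (2 decimals; `NA` when `tv == 0`),
#'   sub_counts (named, 12), indel_hist (50 x 2 matrix, columns ins/del),
#'   short_indel_fraction_ins, short_indel_fraction_del (share of 1-2 bp
#'   events; `NA` when that class is empty).
#' @export
summarize_spectrum <- function(mutations, scope = "all") {
  sbs <- mutations[mutations$mclass == "SBS", , drop = FALSE]
  ins <- mutations[mutations$mclass == "INS", , drop = FALSE]
  del <- mutations[mutations$mclass == "DEL", , drop = FALSE]
  ti <- if (nrow(sbs)) sum(is_transition(sbs$ref, sbs$alt)) else 0L
  tv <- nrow(sbs) - ti
  sub_counts <- setNames(integer(12), SUB_TYPES)
  if (nrow(sbs)) {
    tab <- table(factor(substitution_type(sbs$ref, sbs$alt), levels = SUB_TYPES))
    sub_counts <- setNames(as.integer(tab), SUB_TYPES)
  }
  hist <- matrix(0L, nrow = 50, ncol = 2, dimnames = list(1:50, c("ins", "del")))
  if (nrow(ins)) {
    t1 <- table(factor(ins$indel_len, levels = 1:50))
    hist[, "ins"] <- as.integer(t1)
  }
  if (nrow(del)) {
    t2 <- table(factor(del$indel_len, levels = 1:50))
    hist[, "del"] <- as.integer(t2)
  }
  short_frac <- function(col, n) if (n > 0) sum(hist[1:2, col]) / n else NA_real_
  structure(list(
    scope = scope,
    n_total = nrow(mutations), n_sbs = nrow(sbs),
    n_ins = nrow(ins), n_del = nrow(del),
    ti = as.integer(ti), tv = as.integer(tv),
    ti_tv_ratio = if (tv > 0) round(ti / tv, 2) else NA_real_,
    sub_counts = sub_counts,
    indel_hist = hist,
    short_indel_fraction_ins = short_frac("ins", nrow(ins)),
    short_indel_fraction_del = short_frac("del", nrow(del))),
    class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("spectrum_summary [%s]: %d mutations (%d SBS, %d INS, %d DEL); Ti/Tv = %s\n",
              x$scope, x$n_total, x$n_sbs, x$n_ins, x$n_del,
              ifelse(is.na(x$ti_tv_ratio), "NA", format(x$ti_tv_ratio))))
  invisible(x)
}

#' Define a mutation pond
#'
#' A pond is the pooled mutant group derived from one wild-type background.
#'
#' @param pond_id pond name (e.g. `"MP1"`).
#' @param wildtype_id the shared wild-type line.
#' @param member_line_ids >= 1 mutant line ids.
#' @return an object of class `mutation_pond`.
#' @export
mutation_pond <- function(pond_id, wildtype_id, member_line_ids) {
  if (length(member_line_ids) < 1) stop_badarg("a pond needs >= 1 member line")
  structure(list(pond_id = pond_id, wildtype_id = wildtype_id,
                 member_line_ids = member_line_ids),
            class = "mutation_pond")
}

#' Aggregate per-line spectrum summaries into a pond summary
#'
#' Field-wise sums over the pond's member lines; the Ti/Tv ratio is
#' recomputed from the summed counts (not averaged).
#'
#' @param summaries named list of `spectrum_summary`, one per member line.
#' @param pond a [mutation_pond()].
#' @return a `spectrum_summary` scoped to the pond.
#' @export
pond_aggregate <- function(summaries, pond) {
  missing <- setdiff(pond$member_line_ids, names(summaries))
  if (length(missing)) {
    stop_badarg("missing member summaries: ", paste(missing, collapse = ", "))
  }
  ss <- summaries[pond$member_line_ids]
  acc <- ss[[1]]
  acc$scope <- pond$pond_id
  for (s in ss[-1]) {
    for (f in c("n_total", "n_sbs", "n_ins", "n_del", "ti", "tv")) {
      acc[[f]] <- acc[[f]] + s[[f]]
    }
    acc$sub_counts <- acc$sub_counts + s$sub_counts
    acc$indel_hist <- acc$indel_hist + s$indel_hist
  }
  acc$ti_tv_ratio <- if (acc$tv > 0) round(acc$ti / acc$tv, 2) else NA_real_
  n_ins <- acc$n_ins; n_del <- acc$n_del
  acc$short_indel_fraction_ins <-
    if (n_ins > 0) sum(acc$indel_hist[1:2, "ins"]) / n_ins else NA_real_
  acc$short_indel_fraction_del <-
    if (n_del > 0) sum(acc$indel_hist[1:2, "del"]) / n_del else NA_real_
  acc
}

#' SBS share of all mutations, as a percentage
#'
#' @param n_sbs,n_total counts, `n_total > 0`.
#' @return list with `percent` (exact), `internal` (1 decimal) and
#'   `headline` (nearest integer).
#' @export
sbs_share <- function(n_sbs, n_total) {
  if (n_total <= 0) stop_badarg("n_total must be > 0")
  pct <- 100 * n_sbs / n_total
  list(percent = pct, internal = round(pct, 1), headline = round(pct))
}

#' Write the 12-type substitution spectrum and InDel histogram as TSV
#' @param summary a `spectrum_summary`.
#' @param spectrum_path,hist_path output TSV paths (either may be `NULL`).
#' @return invisibly, a list of the written paths.
#' @export
write_spectrum_tables <- function(summary, spectrum_path = NULL, hist_path = NULL) {
  if (!is.null(spectrum_path)) {
    write.table(data.frame(sub_type = names(summary$sub_counts),
                           count = as.integer(summary$sub_counts)),
                spectrum_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(hist_path)) {
    write.table(data.frame(length = 1:50,
                           ins_count = summary$indel_hist[, "ins"],
                           del_count = summary$indel_hist[, "del"]),
                hist_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(spectrum = spectrum_path, hist = hist_path))
}
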