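#' Per-window mutation counts along one chromosome
#'
#' Bins mutations into fixed windows (0-based half-open): a mutation at
#' 1-based position `p` falls in bin `floor((p - 1) / window_size)`. The
#' last window may be shorter than `window_size`.
#'
#' @param mutations data.frame with columns chrom, pos (1-based), mclass.
#' @param chrom chromosome to scan.
#' @param chrom_length chromosome length in bp.
#' @param window_size bin width in bp (>= 1); 1 Mb and 100 kb are the
#'   conventional scales.
#' @param mclass_filter `"all"`, `"SBS"` or `"InDel"` (INS + DEL).
#' @return object of class `window_track`: chrom, window_size,
#'   chrom_length, mclass, counts (one per window), widths.
#' @export
window_counts <- function(mutations, chrom, chrom_length, window_size,
                          mclass_filter = c("all", "SBS", "InDel")) {
  mclass_filter <- match.arg(mclass_filter)
  if (window_size < 1) stop_badarg("window_size must be >= 1")
  m <- mutations[mutations$chrom == chrom, , drop = FALSE]
  if (mclass_filter == "SBS") m <- m[m$mclass == "SBS", , drop = FALSE]
  if (mclass_filter == "InDel") m <- m[m$mclass %in% c("INS", "DEL"), , drop = FALSE]
  if (nrow(m) && any(m$pos > chrom_length)) {
    stop_badarg("mutation position beyond chromosome length")
  }
  n_win <- ceiling(chrom_length / window_size)
  bins <- if (nrow(m)) (m$pos - 1L) %/% window_size else integer()
  counts <- tabulate(bins + 1L, nbins = n_win)
  widths <- rep(window_size, n_win)
  if (chrom_length %% window_size != 0) widths[n_win] <- chrom_length %% window_size
  structure(list(chrom = chrom, window_size = window_size,
                 chrom_length = chrom_length, mclass = mclass_filter,
                 counts = counts, widths = widths),
            class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  cat(sprintf("window_track %s [%s]: %d windows of %g bp, %d mutations\n",
              x$chrom, x$mclass, length(x$counts), x$window_size,
              sum(x$counts)))
  invisible(x)
}

#' Per-window per-bp mutation frequencies
#'
#' `count / window width`; a short terminal window uses its true length as
#' denominator.
#'
#' @param track a [window_counts()] track.
#' @return numeric vector of per-bp frequencies.
#' @export
window_frequency <- function(track) {
  track$counts / track$widths
}

#' Chromosome-mean per-bp mutation frequency of a track
#' @param track a [window_counts()] track.
#' @return total count / chromosome length.
#' @export
chrom_mean_frequency <- function(track) {
  sum(track$counts) / track$chrom_length
}

#' Call high-frequency (HF) mutation regions on a window track
#'
#' Flags windows whose per-bp frequency is at least `fold_threshold` times
#' the chromosome-mean frequency, merges adjacent flagged windows, and
#' reports per merged region the fold enrichment over the chromosome mean
#' and the fraction of the pond's total mutations it carries. Terminal
#' windows shorter than 10% of `window_size` are never flagged (their tiny
#' denominator would blow up). Coordinates are 0-based half-open (BED).
#'
#' @param track a [window_counts()] track.
#' @param fold_threshold minimum fold over the chromosome mean (> 1;
#'   default 20, the classical hotspot bound).
#' @param pond_total total mutation count of the pond, the denominator of
#'   `fraction_of_total` (default: the track's own total).
#' @param robust_mean if `TRUE`, recompute the reference mean excluding
#'   flagged windows and re-flag once (guards against hotspots inflating
#'   the chromosome mean).
#' @return data.frame: chrom, start, end, mclass, n_mut, fold,
#'   fraction_of_total; zero rows when the chromosome is empty or nothing
#'   exceeds the threshold.
#' @export
call_hf_regions <- function(track, fold_threshold = 20,
                            pond_total = sum(track$counts),
                            robust_mean = FALSE) {
  if (fold_threshold <= 1) stop_badarg("fold_threshold must be > 1")
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      mclass = character(), n_mut = integer(), fold = numeric(),
                      fraction_of_total = numeric(), stringsAsFactors = FALSE)
  mean_f <- chrom_mean_frequency(track)
  if (mean_f == 0) return(empty)
  freq <- window_frequency(track)
  eligible <- track$widths >= 0.1 * track$window_size
  flag <- eligible & freq >= fold_threshold * mean_f
  if (robust_mean && any(flag)) {
    mean_f2 <- sum(track$counts[!flag]) / sum(track$widths[!flag])
    if (mean_f2 > 0) flag <- eligible & freq >= fold_threshold * mean_f2
    mean_f <- mean_f2
  }
  if (!any(flag)) return(empty)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- lapply(runs, function(k) {
    w1 <- starts[k]; w2 <- ends[k]
    bp1 <- (w1 - 1) * track$window_size
    bp2 <- min(w2 * track$window_size, track$chrom_length)
    n <- sum(track$counts[w1:w2])
    data.frame(chrom = track$chrom, start = bp1, end = bp2,
               mclass = track$mclass, n_mut = n,
               fold = (n / (bp2 - bp1)) / mean_f,
               fraction_of_total = n / pond_total, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' SBS-InDel colocalization of HF regions
#'
#' Converts two HF-region sets called on the same chromosome geometry back
#' to flagged-window sets and reports the shared window count, the Jaccard
#' index, and the hypergeometric upper-tail probability of seeing at least
#' that many shared windows if the two sets were placed independently.
#'
#' @param hf_sbs,hf_indel HF-region data.frames from [call_hf_regions()].
#' @param chrom_length,window_size the common track geometry.
#' @return list: n_windows, n_sbs_windows, n_indel_windows, shared,
#'   jaccard (`NA` when both sets are empty), p_hyper.
#' @export
colocalization <- function(hf_sbs, hf_indel, chrom_length, window_size) {
  wins <- function(hf) {
    if (nrow(hf) == 0) return(integer())
    if (any(hf$start %% window_size != 0)) {
      stop_badarg("HF regions do not align to the window geometry")
    }
    unlist(lapply(seq_len(nrow(hf)), function(i) {
      seq(hf$start[i] %/% window_size,
          (hf$end[i] - 1) %/% window_size)
    }))
  }
  a <- wins(hf_sbs)
  b <- wins(hf_indel)
  n_win <- ceiling(chrom_length / window_size)
  if (length(a) && max(a) >= n_win || length(b) && max(b) >= n_win) {
    stop_badarg("HF regions exceed the stated chromosome geometry")
  }
  shared <- length(intersect(a, b))
  uni <- length(union(a, b))
  jac <- if (uni > 0) shared / uni else NA_real_
  # P[X >= shared], X ~ Hypergeometric(|A| marked, N - |A|, |B| drawn)
  p <- phyper(shared - 1, length(a), n_win - length(a), length(b),
              lower.tail = FALSE)
  list(n_windows = n_win, n_sbs_windows = length(a),
       n_indel_windows = length(b), shared = shared, jaccard = jac,
       p_hyper = p)
}

#' Write HF regions as a BED file
#'
#' Columns: chrom, start, end, name (mclass), score (rounded fold).
#'
#' @param hf HF-region data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hf_bed <- function(hf, path) {
  bed <- data.frame(chrom = hf$chrom, start = format(hf$start, scientific = FALSE, trim = TRUE),
                    end = format(hf$end, scientific = FALSE, trim = TRUE),
                    name = hf$mclass, score = round(hf$fold))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a window track as TSV (chrom, start, end, count, frequency)
#' @param track a [window_counts()] track.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_window_track <- function(track, path) {
  n <- length(track$counts)
  start <- (seq_len(n) - 1) * track$window_size
  df <- data.frame(chrom = track$chrom,
                   start = format(start, scientific = FALSE, trim = TRUE),
                   end = format(pmin(start + track$window_size, track$chrom_length),
                                scientific = FALSE, trim = TRUE),
                   count = track$counts, frequency = window_frequency(track))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
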