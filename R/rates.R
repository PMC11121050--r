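#' Probability that an M1 heterozygous mutation is detected in generation Mn
#'
#' Under selfing without selection, a mutation heterozygous in M1 is
#' homozygous mutant in Mn with probability `(1 - 2^-(n-1)) / 2`
#' (`mode = "exact"`). `mode = "table"` uses the asymptotic value 1/2 (the
#' doubling convention used in published M6 back-projections).
#' `mode = "with_het"` additionally counts the still-heterozygous carriers:
#' `(1 - 2^-(n-1))/2 + 2^-(n-1)`.
#'
#' @param n generation index (>= 2).
#' @param mode `"table"`, `"exact"` or `"with_het"`.
#' @return retention probability in (0, 1].
#' @export
retention_probability <- function(n, mode = c("table", "exact", "with_het")) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || n < 2) stop_badarg("generation n must be >= 2")
  hom <- (1 - 2^-(n - 1)) / 2
  switch(mode,
         table = 0.5,
         exact = hom,
         with_het = hom + 2^-(n - 1))
}

#' Back-project an Mn mutation count to the M1 generation
#'
#' `N1 = round(Nn / retention_probability(n, mode))`. The default table
#' mode doubles the Mn count; the exact M6 factor is 64/31.
#'
#' @param Nn mutation count detected in Mn (>= 0).
#' @param n generation index (default 6).
#' @param mode see [retention_probability()].
#' @return estimated M1 mutation count (integer-valued).
#' @export
back_project <- function(Nn, n = 6, mode = "table") {
  if (any(Nn < 0)) stop_badarg("Nn must be >= 0")
  round(Nn / retention_probability(n, mode))
}

#' Per-bp M1 mutation rate of a pond
#'
#' `sum(N1) / (n_lines * genome_length)`.
#'
#' @param N1 back-projected M1 counts of the pond's member lines.
#' @param n_lines number of member lines (>= 1).
#' @param genome_length assembly span in bp (> 0), e.g.
#'   [RICE_GENOME_LENGTH].
#' @return per-bp rate.
#' @export
pond_rate <- function(N1, n_lines, genome_length) {
  if (n_lines < 1) stop_badarg("n_lines must be >= 1")
  if (!is.numeric(genome_length) || genome_length <= 0) {
    stop_badarg("genome_length must be > 0")
  }
  sum(N1) / (n_lines * genome_length)
}

#' Format a per-bp rate in units of 1e-5, 1 decimal (display convention)
#' @param rate per-bp rate.
#' @return character like `"11.3e-5"`.
#' @export
format_rate <- function(rate) {
  sprintf("%.1fe-5", rate * 1e5)
}

#' Summarize a pond's M6 counts into M1 estimates and a rate
#'
#' @param pond_id pond name.
#' @param m6_counts named vector of per-line Mn totals.
#' @param n generation index.
#' @param mode back-projection mode.
#' @param genome_length denominator in bp.
#' @return object of class `pond_summary`: pond_id, m6_counts, N1
#'   (per line), N1_sum, n_lines, genome_length, rate, p_detect.
#' @export
pond_summary <- function(pond_id, m6_counts, n = 6, mode = "table",
                         genome_length = RICE_GENOME_LENGTH) {
  N1 <- back_project(m6_counts, n, mode)
  structure(list(pond_id = pond_id, m6_counts = m6_counts, N1 = N1,
                 N1_sum = sum(N1), n_lines = length(m6_counts),
                 genome_length = genome_length,
                 rate = pond_rate(N1, length(m6_counts), genome_length),
                 p_detect = retention_probability(n, mode)),
            class = "pond_summary")
}

#' @export
print.pond_summary <- function(x, ...) {
  cat(sprintf("pond_summary %s: %d lines, sum(N1) = %d, rate = %s/bp\n",
              x$pond_id, x$n_lines, x$N1_sum, format_rate(x$rate)))
  invisible(x)
}

#' Phenotype screening statistic for a candidate mutant
#'
#' `|mutant - mean(wt)| / sd(wt)` with the sample standard deviation
#' (n - 1 denominator); the candidate passes when the statistic is >= 3
#' (inclusive).
#'
#' @param wt_values >= 2 wild-type trait measurements with nonzero spread.
#' @param mutant_value the candidate's trait value.
#' @param trait trait name carried through to the result.
#' @return object of class `trait_screen`: trait, statistic, pass,
#'   wt_mean, wt_sd.
#' @export
screen_trait <- function(wt_values, mutant_value, trait = "trait") {
  if (length(wt_values) < 2) stop_badarg("need >= 2 wild-type values")
  s <- sd(wt_values)
  if (!is.finite(s) || s == 0) stop_badarg("wild-type values have zero spread")
  stat <- abs(mutant_value - mean(wt_values)) / s
  structure(list(trait = trait, statistic = stat, pass = stat >= 3,
                 wt_mean = mean(wt_values), wt_sd = s),
            class = "trait_screen")
}

#' @export
print.trait_screen <- function(x, ...) {
  cat(sprintf("trait_screen %s: statistic = %.2f (%s)\n", x$trait,
              x$statistic, if (x$pass) "pass" else "fail"))
  invisible(x)
}
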