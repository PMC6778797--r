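#' Rate-independent crossover patterning profile
#'
#' Map distances confound crossover rate with crossover placement. The
#' patterning profile removes the rate: it is the fraction of all observed
#' crossovers that fell in each interval, together with the range
#' (max - min proportion) as a scalar summary of how uneven placement is.
#' A uniform landscape gives range 0; strong medial concentration with
#' telomeric/centromeric suppression gives a large range.
#'
#' @param tab a `crossover_tabulation` with at least one crossover.
#' @return list with `proportions` (named over intervals, sums to 1),
#'   `n_crossovers_total`, and `range`.
#' @export
crossover_proportions <- function(tab) {
  stopifnot(inherits(tab, "crossover_tabulation"))
  total <- sum(tab$interval_counts)
  if (total < 1L)
    stop("patterning profile undefined: zero crossovers", call. = FALSE)
  p <- tab$interval_counts / total
  list(proportions = p, n_crossovers_total = total,
       range = max(p) - min(p))
}

#' Chi-square test of patterning heterogeneity between two genotypes
#'
#' Pearson chi-square on the 2 x (k-1) contingency table of per-interval
#' crossover counts (counts, not proportions, so the degrees of freedom
#' and sampling variance are well defined; df = k-2 for k-1 intervals).
#' No continuity correction. If any expected cell is below 1 a warning
#' string is attached to the result.
#'
#' @param tab_a,tab_b `crossover_tabulation`s over the same intervals.
#' @return list with `chi2`, `df`, `p`, and optionally `warning`.
#' @export
compare_patterning_chi2 <- function(tab_a, tab_b) {
  stopifnot(inherits(tab_a, "crossover_tabulation"),
            inherits(tab_b, "crossover_tabulation"))
  if (!identical(names(tab_a$interval_counts), names(tab_b$interval_counts)))
    stop("tabulations are over different interval sets", call. = FALSE)
  if (sum(tab_a$interval_counts) < 1L || sum(tab_b$interval_counts) < 1L)
    stop("both genotypes need at least one crossover", call. = FALSE)
  m <- rbind(tab_a$interval_counts, tab_b$interval_counts)
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  out <- list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
              p = ht$p.value)
  if (any(ht$expected < 1))
    out$warning <- "expected cell count < 1; chi-square approximation weak"
  out
}
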