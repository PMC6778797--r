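#' Interval crossover frequencies in map units
#'
#' A map unit (cM) here is the raw crossover frequency: crossovers per 100
#' recovered chromatids in an interval. No mapping-function (Haldane or
#' Kosambi) correction is applied; interval lengths add along the arm.
#'
#' @param tab a `crossover_tabulation` from [tabulate_crossovers()].
#' @return list with `per_interval_cM` (named), `total_cM`, `n_progeny`.
#' @export
interval_frequencies <- function(tab) {
  stopifnot(inherits(tab, "crossover_tabulation"))
  if (tab$n_progeny < 1L) stop("no progeny", call. = FALSE)
  cm <- 100 * tab$interval_counts / tab$n_progeny
  list(per_interval_cM = cm, total_cM = sum(cm), n_progeny = tab$n_progeny)
}

#' Replicate-cross genetic-map summary
#'
#' Computes per-cross interval frequencies and summarises them across the
#' independent replicate crosses with unweighted means and sample
#' (n-1 denominator) standard deviations, for each interval and for the
#' arm total. The pooled (all progeny together) estimate is also carried
#' for comparison, since a genotype-level total can be quoted either way.
#'
#' @param coll a [cross_collection()].
#' @return Object of class `replicate_summary`: list with `per_cross`
#'   (matrix crosses x (intervals, total) of cM values), `mean`, `sd`
#'   (named vectors over intervals + "total"), `n_crosses`, `pooled`
#'   (the [interval_frequencies()] of the pooled tabulation), and
#'   `genotype_label`. With a single cross the SDs are `NA`.
#' @export
summarize_replicates <- function(coll) {
  stopifnot(inherits(coll, "cross_collection"))
  tabs <- tabulate_by_cross(coll)
  per <- t(vapply(tabs, function(tb) {
    f <- interval_frequencies(tb)
    c(f$per_interval_cM, total = f$total_cM)
  }, numeric(n_intervals(coll$map) + 1L)))
  structure(
    list(per_cross = per,
         mean = colMeans(per),
         sd = if (nrow(per) >= 2L) apply(per, 2L, stats::sd)
              else stats::setNames(rep(NA_real_, ncol(per)), colnames(per)),
         n_crosses = nrow(per),
         progeny_per_cross = vapply(tabs, function(tb) tb$n_progeny, 0L),
         pooled = interval_frequencies(pool_crosses(coll)),
         genotype_label = coll$genotype_label),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("Genetic map for '", x$genotype_label, "' (", x$n_crosses,
      " replicate crosses)\n", sep = "")
  print(data.frame(mean_cM = round(x$mean, 3), sd_cM = round(x$sd, 3)))
  cat("pooled total:", round(x$pooled$total_cM, 3), "cM over",
      x$pooled$n_progeny, "progeny\n")
  invisible(x)
}

#' Map summary as a data frame report
#'
#' @param rs a `replicate_summary`.
#' @return data frame: one row per interval plus total, columns
#'   `which`, `mean_cM`, `sd_cM`, `pooled_cM`, `n_crosses`.
#' @export
map_report <- function(rs) {
  stopifnot(inherits(rs, "replicate_summary"))
  data.frame(
    which = names(rs$mean),
    mean_cM = unname(rs$mean),
    sd_cM = unname(rs$sd),
    pooled_cM = unname(c(rs$pooled$per_interval_cM, rs$pooled$total_cM)),
    n_crosses = rs$n_crosses
  )
}

#' Compare two genotypes' crossover frequencies by t-test
#'
#' Two-sample unpaired Student t-test (equal variances pooled, df =
#' nA + nB - 2) on the per-cross cM values of one interval or of the arm
#' total, treating each replicate cross as one observation. A Welch test
#' is available as an option.
#'
#' @param a,b `replicate_summary` objects on the same marker map.
#' @param which interval label (e.g. `"dp-b"`) or `"total"`.
#' @param welch if `TRUE` use the Welch (unequal-variance) test.
#' @return list with `statistic`, `df`, `p`, `which`, `method`, plus the
#'   two group means.
#' @export
compare_t <- function(a, b, which = "total", welch = FALSE) {
  stopifnot(inherits(a, "replicate_summary"), inherits(b, "replicate_summary"))
  if (a$n_crosses < 2L || b$n_crosses < 2L)
    stop("need >= 2 crosses per genotype for a t-test", call. = FALSE)
  if (!which %in% colnames(a$per_cross) || !which %in% colnames(b$per_cross))
    stop("unknown interval: ", which, call. = FALSE)
  xa <- a$per_cross[, which]
  xb <- b$per_cross[, which]
  ht <- stats::t.test(xa, xb, var.equal = !welch)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, which = which,
       method = if (welch) "Welch t" else "Student t",
       mean_a = mean(xa), mean_b = mean(xb),
       labels = c(a$genotype_label, b$genotype_label))
}

#' Signed fold-difference
#'
#' Directional fold-change between two positive quantities: `+x/y` when
#' `x >= y`, otherwise `-y/x`, so the magnitude is always >= 1 and the
#' sign says which way the difference runs (positive: first exceeds
#' second).
#'
#' @param x,y positive numbers; `x` is read relative to `y`.
#' @return signed fold, magnitude >= 1.
#' @export
#' @examples
#' fold_difference(0.389, 0.205)  # +1.90
#' fold_difference(0.094, 0.685)  # -7.29
fold_difference <- function(x, y) {
  if (!is.finite(x) || !is.finite(y) || x <= 0 || y <= 0)
    stop("fold_difference needs positive finite inputs", call. = FALSE)
  unname(if (x >= y) x / y else -y / x)
}
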