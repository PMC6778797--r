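#' Chromatid-sampling mixing matrix
#'
#' Under the no-chromatid-interference assumption each exchange in a
#' tetrad is carried by the single recovered chromatid independently with
#' probability 1/2, so a tetrad with n exchanges yields a chromatid with
#' j observable crossovers with probability C(n, j) / 2^n. Column n of the
#' returned matrix is that binomial kernel.
#'
#' @param n_max highest exchange rank (classes 0..n_max).
#' @return (n_max+1) x (n_max+1) upper-triangular matrix M with
#'   `M[j+1, n+1] = choose(n, j) * 2^-n`.
#' @keywords internal
weinstein_matrix <- function(n_max) {
  n <- 0:n_max
  outer(n, n, function(j, nn) ifelse(j <= nn, choose(nn, j) * 2^-nn, 0))
}

#' Forward model: tetrad exchange classes to gamete crossover classes
#'
#' Given tetrad exchange-class frequencies E_0..E_N, computes the gamete
#' (recovered-chromatid) crossover-class frequencies
#' `a_j = sum_{n >= j} C(n, j) 2^-n E_n`.
#'
#' @param E nonnegative numeric vector of exchange-class frequencies
#'   (E_0 first), typically summing to 1.
#' @return numeric vector `a` of the same length, named `a0`...;
#'   `sum(a) == sum(E)`.
#' @export
#' @examples
#' forward_gamete_distribution(c(0, 1, 0, 0))  # half of chromatids recombinant
forward_gamete_distribution <- function(E) {
  E <- as.numeric(E)
  if (length(E) == 0L) stop("empty E", call. = FALSE)
  if (any(!is.finite(E)) || any(E < 0))
    stop("E frequencies must be nonnegative", call. = FALSE)
  a <- as.numeric(weinstein_matrix(length(E) - 1L) %*% E)
  names(a) <- paste0("a", seq_along(a) - 1L)
  a
}

#' Weinstein inversion: gamete classes to tetrad exchange classes
#'
#' Algebraically inverts the chromatid-sampling model: given observed
#' gamete crossover-class frequencies a_0..a_J it solves the triangular
#' system `a_j = sum_n C(n, j) 2^-n E_n` for the tetrad exchange-class
#' frequencies, using the closed form
#' `E_n = 2^n sum_{j >= n} (-1)^(j-n) C(j, n) a_j`.
#' The maximum exchange rank equals the highest supplied gamete class J
#' (the system is only determined up to J). Being a method-of-moments
#' style point estimate, individual E_n can come out negative on noisy
#' data; such values are reported unmodified with a warning flag so the
#' default output matches the classical method. See
#' [constrain_nonnegative()] for an optional constrained variant.
#'
#' @param a numeric vector of gamete-class frequencies (or counts; they
#'   are used as given -- normalisation is preserved, not imposed).
#' @return Object of class `tetrad_distribution`: list with `E` (named
#'   `E0`..), `mean`, `variance`, `relative_variance`, and `negative`
#'   (TRUE if any class estimate is negative).
#' @export
#' @examples
#' weinstein_invert(c(0.5, 0.5))            # all tetrads single-exchange
#' weinstein_invert(c(0.57475, 0.3975, 0.02825, 0.0005))
weinstein_invert <- function(a) {
  a <- as.numeric(a)
  if (length(a) == 0L) stop("empty gamete-class vector", call. = FALSE)
  if (any(!is.finite(a)) || any(a < 0))
    stop("gamete-class frequencies must be nonnegative", call. = FALSE)
  J <- length(a) - 1L
  E <- vapply(0:J, function(n) {
    j <- n:J
    2^n * sum((-1)^(j - n) * choose(j, n) * a[j + 1L])
  }, 0)
  tetrad_distribution(E)
}

#' Construct a tetrad exchange-class distribution
#'
#' @param E numeric vector of exchange-class frequencies, E_0 first.
#'   Negative entries are permitted (they arise from Weinstein inversion
#'   of noisy data) and flagged.
#' @return Object of class `tetrad_distribution`; see [weinstein_invert()].
#' @export
tetrad_distribution <- function(E) {
  E <- as.numeric(E)
  if (length(E) == 0L) stop("empty E", call. = FALSE)
  if (any(!is.finite(E))) stop("non-finite E", call. = FALSE)
  names(E) <- paste0("E", seq_along(E) - 1L)
  mom <- tetrad_moments(E)
  neg <- any(E < 0)
  if (neg)
    warning("negative exchange-class estimate(s): ",
            paste(names(E)[E < 0], collapse = ", "), call. = FALSE)
  structure(
    list(E = E, mean = mom[["mean"]], variance = mom[["variance"]],
         relative_variance = mom[["relative_variance"]], negative = neg),
    class = "tetrad_distribution"
  )
}

#' @export
print.tetrad_distribution <- function(x, digits = 3, ...) {
  cat("Tetrad exchange-class distribution",
      if (x$negative) "(contains negative estimates)", "\n")
  print(round(x$E, digits))
  cat("mean", round(x$mean, digits),
      " variance", round(x$variance, digits),
      " relative variance", round(x$relative_variance, digits), "\n")
  invisible(x)
}

#' Moments of a tetrad exchange-class distribution
#'
#' Mean `sum(n * E_n)`, variance `sum(n^2 * E_n) - mean^2`, and relative
#' variance (variance/mean; the dispersion index: below 1 indicates
#' under-dispersion from assurance plus interference, above 1
#' over-dispersion). Relative variance is `NA` when the mean is 0.
#'
#' @param E numeric vector of exchange-class frequencies (E_0 first), or
#'   a `tetrad_distribution`.
#' @return named numeric vector `mean`, `variance`, `relative_variance`.
#' @export
#' @examples
#' tetrad_moments(c(0.389, 0.467, 0.124, 0.020))  # mean 0.775
tetrad_moments <- function(E) {
  if (inherits(E, "tetrad_distribution")) E <- E$E
  E <- as.numeric(E)
  n <- seq_along(E) - 1
  m <- sum(n * E)
  v <- sum(n^2 * E) - m^2
  c(mean = m, variance = v,
    relative_variance = if (m == 0) NA_real_ else v / m)
}

#' Clip a tetrad distribution to the nonnegative simplex
#'
#' Optional alternative to the raw algebraic estimate: negative class
#' frequencies are set to 0 and the remainder rescaled to the original
#' total. Provided separately so the default [weinstein_invert()] output
#' stays faithful to the classical method.
#'
#' @param td a `tetrad_distribution`.
#' @return a nonnegative `tetrad_distribution` with the same total mass.
#' @export
constrain_nonnegative <- function(td) {
  stopifnot(inherits(td, "tetrad_distribution"))
  E <- pmax(td$E, 0)
  s <- sum(td$E)
  if (sum(E) > 0) E <- E * s / sum(E)
  tetrad_distribution(E)
}

#' Table of pairwise fold-differences between tetrad distributions
#'
#' For each exchange class and each ordered pair of genotypes, the signed
#' fold-difference ([fold_difference()]) of the first genotype's class
#' frequency relative to the second's. Cells with a nonpositive entry on
#' either side are reported as `NA` (undefined).
#'
#' @param E_list named list of `tetrad_distribution`s (or plain E
#'   vectors) with equal class counts.
#' @param pairs optional list of 2-element character vectors naming the
#'   comparisons; default all ordered pairs in list order.
#' @return data frame: rows = exchange classes, one column per pair named
#'   `"A-B"` (A relative to B).
#' @export
fold_difference_table <- function(E_list, pairs = NULL) {
  if (length(E_list) < 2L) stop("need >= 2 distributions", call. = FALSE)
  Es <- lapply(E_list, function(x)
    if (inherits(x, "tetrad_distribution")) x$E else as.numeric(x))
  len <- unique(lengths(Es))
  if (length(len) != 1L)
    stop("distributions have different class counts", call. = FALSE)
  labs <- names(E_list)
  if (is.null(pairs)) {
    idx <- utils::combn(labs, 2L, simplify = FALSE)
    pairs <- lapply(idx, rev)  # later genotype relative to earlier
  }
  out <- data.frame(class = paste0("E", seq_len(len) - 1L))
  for (pr in pairs) {
    x <- Es[[pr[1L]]]; y <- Es[[pr[2L]]]
    out[[paste(pr, collapse = "-")]] <- mapply(function(xi, yi) {
      if (xi <= 0 || yi <= 0) NA_real_ else fold_difference(xi, yi)
    }, x, y)
  }
  out
}

#' Dispersion of the exchange distribution relative to Poisson
#'
#' Tests whether the inferred number of exchanges per tetrad is under- or
#' over-dispersed relative to a Poisson distribution with the same mean.
#' Tetrad-class counts (inferred class frequencies times the number of
#' sampled tetrads, one per progeny chromatid) are compared to Poisson
#' expectations by Pearson chi-square over classes 0..K, where K extends
#' beyond the observed classes and the top classes are pooled until every
#' expected count is at least 1; df = (classes after pooling) - 1. The
#' direction is called from the relative variance (under if < 1).
#'
#' @param x a `crossover_tabulation` (tetrads inferred from its pooled
#'   gamete classes) or a `tetrad_distribution`.
#' @param n_tetrads number of tetrads sampled; defaults to the
#'   tabulation's progeny count, required for a bare distribution.
#' @return list with `chi2`, `df`, `p`, `direction` ("under"/"over"),
#'   `relative_variance`, `classes_used`, `n_tetrads`.
#' @export
dispersion_test <- function(x, n_tetrads = NULL) {
  if (inherits(x, "crossover_tabulation")) {
    if (is.null(n_tetrads)) n_tetrads <- x$n_progeny
    td <- weinstein_invert(x$class_counts / x$n_progeny)
  } else if (inherits(x, "tetrad_distribution")) {
    td <- x
    if (is.null(n_tetrads))
      stop("n_tetrads required for a bare tetrad distribution", call. = FALSE)
  } else stop("unsupported input", call. = FALSE)
  lambda <- td$mean
  if (lambda <= 0) stop("mean exchange count is 0; no dispersion test",
                        call. = FALSE)
  # observed counts per class; extend with zeros to cover the Poisson tail
  obs <- td$E * n_tetrads
  k_max <- max(length(obs) - 1L,
               stats::qpois(1 - 1 / (2 * n_tetrads), lambda)) + 1L
  obs <- c(obs, rep(0, k_max + 1L - length(obs)))
  p_exp <- stats::dpois(0:k_max, lambda)
  p_exp[k_max + 1L] <- p_exp[k_max + 1L] + stats::ppois(k_max, lambda,
                                                        lower.tail = FALSE)
  exp_cnt <- p_exp * n_tetrads
  # pool top classes until all expected counts >= 1
  while (length(exp_cnt) > 2L && exp_cnt[length(exp_cnt)] < 1) {
    k <- length(exp_cnt)
    exp_cnt[k - 1L] <- exp_cnt[k - 1L] + exp_cnt[k]
    obs[k - 1L] <- obs[k - 1L] + obs[k]
    exp_cnt <- exp_cnt[-k]; obs <- obs[-k]
  }
  chi2 <- sum((obs - exp_cnt)^2 / exp_cnt)
  df <- length(exp_cnt) - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       direction = if (!is.na(td$relative_variance) &&
                       td$relative_variance < 1) "under" else "over",
       relative_variance = td$relative_variance,
       classes_used = length(exp_cnt), n_tetrads = n_tetrads)
}

#' Chi-square comparison of crossover-class distributions
#'
#' Pearson chi-square on the 2 x C table of gamete crossover-class counts
#' (NCO/SCO/DCO/... chromosomes) of two genotypes. Top classes are pooled
#' until every expected count is at least 1, so sparse high classes do
#' not break the approximation.
#'
#' @param tab_a,tab_b `crossover_tabulation`s with the same class
#'   structure.
#' @return list with `chi2`, `df`, `p`, `classes_used`.
#' @export
compare_class_chi2 <- function(tab_a, tab_b) {
  stopifnot(inherits(tab_a, "crossover_tabulation"),
            inherits(tab_b, "crossover_tabulation"))
  oa <- as.numeric(tab_a$class_counts)
  ob <- as.numeric(tab_b$class_counts)
  if (length(oa) != length(ob))
    stop("class structures differ", call. = FALSE)
  # drop shared trailing zero classes, then pool until expected >= 1
  keep <- max(which(oa + ob > 0))
  if (keep < 2L) stop("degenerate single-class table", call. = FALSE)
  oa <- oa[seq_len(keep)]; ob <- ob[seq_len(keep)]
  expected <- function(a, b) {
    tot <- a + b
    rbind(tot * sum(a) / sum(tot), tot * sum(b) / sum(tot))
  }
  while (length(oa) > 2L && any(expected(oa, ob)[, length(oa)] < 1)) {
    k <- length(oa)
    oa[k - 1L] <- oa[k - 1L] + oa[k]; oa <- oa[-k]
    ob[k - 1L] <- ob[k - 1L] + ob[k]; ob <- ob[-k]
  }
  ht <- suppressWarnings(stats::chisq.test(rbind(oa, ob), correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, classes_used = length(oa))
}
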