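#' Tetrad exchange-class table across genotypes
#'
#' Assembles the standard tetrad-analysis summary: one column per
#' genotype with E_0..E_N, mean, variance and relative variance, plus
#' signed fold-difference columns for each genotype pair (later genotype
#' relative to earlier). Values are stored at full precision; `digits`
#' only controls a rounded copy.
#'
#' @param tds named list of `tetrad_distribution`s (or E vectors).
#' @param digits if non-`NULL`, round the returned table for display.
#' @return data frame: rows `E0`.., `mean`, `variance`,
#'   `relative_variance`; one column per genotype and per pair.
#' @export
tetrad_class_table <- function(tds, digits = NULL) {
  if (length(tds) < 1L) stop("need >= 1 distribution", call. = FALSE)
  tds <- lapply(tds, function(x)
    if (inherits(x, "tetrad_distribution")) x else tetrad_distribution(x))
  n_class <- unique(vapply(tds, function(t) length(t$E), 0L))
  if (length(n_class) != 1L)
    stop("distributions have different class counts", call. = FALSE)
  rows <- c(paste0("E", seq_len(n_class) - 1L),
            "mean", "variance", "relative_variance")
  out <- data.frame(row.names = rows)
  for (nm in names(tds)) {
    t <- tds[[nm]]
    out[[nm]] <- c(unname(t$E), t$mean, t$variance, t$relative_variance)
  }
  if (length(tds) >= 2L) {
    ft <- fold_difference_table(lapply(tds, `[[`, "E"))
    for (cn in setdiff(names(ft), "class"))
      out[[paste0(cn, " fold-diff")]] <- c(ft[[cn]], rep(NA_real_, 3L))
  }
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Run the full crossover analysis over one or more genotypes
#'
#' Ties the stages together the way a complete experiment is analysed:
#' replicate-cross genetic maps, patterning profiles, Weinstein tetrad
#' inference with dispersion tests, interference for a chosen interval
#' pair, and all pairwise genotype comparisons (t-tests on map totals and
#' intervals, patterning and crossover-class chi-square tests,
#' Mann-Whitney on per-cross interference). Every value in the returned
#' tables is reproducible by calling the underlying function directly;
#' this assembler adds no computation of its own.
#'
#' @param colls named list of [cross_collection()]s on the same map.
#' @param interference_pair list of two character vectors of contiguous
#'   interval labels (each run merged parity-aware), or `NULL` to skip.
#' @return list of data frames: `map` (per genotype x interval),
#'   `patterning`, `tetrads` (the [tetrad_class_table()]),
#'   `dispersion`, `interference`, and `comparisons` (one row per test).
#'   Genotypes with zero crossovers get `NA` patterning rows rather than
#'   an error.
#' @export
analyze_genotypes <- function(colls, interference_pair = NULL) {
  if (is.null(names(colls)) || any(!nzchar(names(colls))))
    names(colls) <- vapply(colls, function(x) x$genotype_label, "")
  stopifnot(all(vapply(colls, inherits, TRUE, "cross_collection")))
  labs <- names(colls)
  tabs <- lapply(colls, pool_crosses)
  sums <- lapply(colls, summarize_replicates)

  map_df <- do.call(rbind, lapply(labs, function(l) {
    r <- map_report(sums[[l]])
    cbind(genotype = l, r)
  }))

  patt_df <- do.call(rbind, lapply(labs, function(l) {
    tb <- tabs[[l]]
    if (sum(tb$interval_counts) == 0L)
      return(data.frame(genotype = l,
                        interval = names(tb$interval_counts),
                        proportion = NA_real_, range = NA_real_))
    pr <- crossover_proportions(tb)
    data.frame(genotype = l, interval = names(pr$proportions),
               proportion = unname(pr$proportions), range = pr$range)
  }))

  tds <- lapply(tabs, function(tb)
    suppressWarnings(weinstein_invert(tb$class_counts / tb$n_progeny)))
  tet_df <- tetrad_class_table(tds)

  disp_df <- do.call(rbind, lapply(labs, function(l) {
    d <- tryCatch(dispersion_test(tabs[[l]]), error = function(e) NULL)
    if (is.null(d))
      return(data.frame(genotype = l, chi2 = NA_real_, df = NA_integer_,
                        p = NA_real_, direction = NA_character_,
                        relative_variance = NA_real_))
    data.frame(genotype = l, chi2 = d$chi2, df = d$df, p = d$p,
               direction = d$direction,
               relative_variance = d$relative_variance)
  }))

  intf_df <- NULL
  if (!is.null(interference_pair)) {
    intf_df <- do.call(rbind, lapply(labs, function(l) {
      r <- coincidence_for_pair(colls[[l]], interference_pair[[1L]],
                                interference_pair[[2L]])
      data.frame(genotype = l, pair = paste(r$pair, collapse = " / "),
                 obs_dco = r$obs_dco, exp_dco = r$exp_dco,
                 coincidence = r$coincidence, I = r$I)
    }))
  }

  comp <- list()
  if (length(labs) >= 2L) {
    prs <- utils::combn(labs, 2L, simplify = FALSE)
    for (pr in prs) {
      a <- pr[1L]; b <- pr[2L]
      tt <- compare_t(sums[[a]], sums[[b]], "total")
      comp[[length(comp) + 1L]] <- data.frame(
        test = "t_total", a = a, b = b,
        statistic = tt$statistic, df = tt$df, p = tt$p)
      pc <- tryCatch(compare_patterning_chi2(tabs[[a]], tabs[[b]]),
                     error = function(e) NULL)
      if (!is.null(pc))
        comp[[length(comp) + 1L]] <- data.frame(
          test = "patterning_chi2", a = a, b = b,
          statistic = pc$chi2, df = pc$df, p = pc$p)
      cc <- tryCatch(compare_class_chi2(tabs[[a]], tabs[[b]]),
                     error = function(e) NULL)
      if (!is.null(cc))
        comp[[length(comp) + 1L]] <- data.frame(
          test = "class_chi2", a = a, b = b,
          statistic = cc$chi2, df = cc$df, p = cc$p)
      if (!is.null(interference_pair)) {
        mw <- tryCatch(
          compare_interference(colls[[a]], colls[[b]],
                               interference_pair[[1L]],
                               interference_pair[[2L]]),
          error = function(e) NULL)
        if (!is.null(mw))
          comp[[length(comp) + 1L]] <- data.frame(
            test = "interference_mw", a = a, b = b,
            statistic = mw$U, df = NA_real_, p = mw$p)
      }
    }
  }
  list(map = map_df, patterning = patt_df, tetrads = tet_df,
       dispersion = disp_df, interference = intf_df,
       comparisons = if (length(comp)) do.call(rbind, comp) else NULL)
}
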