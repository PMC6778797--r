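#' Merge contiguous scoring intervals
#'
#' Builds a coarser tabulation in which a contiguous run of intervals is
#' replaced by a single merged interval (e.g. merging ho-dp and dp-b into
#' ho-b). The merged crossover indicator is recomputed per progeny from
#' the raw genotypes by comparing the states at the group's flanking
#' markers -- parity-aware, NOT a sum of sub-interval counts, so a double
#' crossover inside the merged region correctly scores 0.
#'
#' @param coll a [cross_collection()] (raw genotypes are required).
#' @param groups list of character vectors; each a contiguous run of
#'   interval labels to merge. Ungrouped intervals are kept as they are.
#' @return list with `tab` (the merged `crossover_tabulation`), `map`
#'   (the merged [marker_map()]), and `coll` (the collection restricted
#'   to the merged map's markers).
#' @export
merge_intervals <- function(coll, groups) {
  stopifnot(inherits(coll, "cross_collection"))
  map <- coll$map
  if (!is.list(groups)) groups <- list(groups)
  drop_markers <- integer(0)
  for (g in groups) {
    idx <- sort(interval_index(map, g))
    if (length(idx) < 2L) next
    if (!all(diff(idx) == 1L))
      stop("interval group is not contiguous: ",
           paste(g, collapse = ", "), call. = FALSE)
    # merging intervals idx..max(idx) removes the interior markers
    drop_markers <- c(drop_markers, (min(idx) + 1L):max(idx))
  }
  keep <- setdiff(seq_len(n_markers(map)), drop_markers)
  sub <- restrict_markers(coll, keep)
  list(tab = pool_crosses(sub), map = sub$map, coll = sub)
}

# Restrict a collection to a subset of marker columns (indices into the map).
restrict_markers <- function(coll, keep) {
  keep <- sort(unique(as.integer(keep)))
  map2 <- marker_map(coll$map$markers[keep], chromosome = coll$map$chromosome)
  crosses <- lapply(coll$crosses, function(m) m[, keep, drop = FALSE])
  out <- coll
  out$map <- map2
  out$crosses <- crosses
  out
}

#' Coincidence and interference for a pair of intervals
#'
#' Classical coefficient-of-coincidence construction: for two disjoint
#' intervals (each possibly a merged run of scoring intervals), the
#' expected number of double crossovers under independence is
#' `n * f1 * f2`, where f1 and f2 are the same-sample single-interval
#' crossover frequencies. Coincidence is observed/expected doubles and
#' interference is `I = 1 - coincidence` (positive I: fewer doubles than
#' independence predicts; negative I is possible).
#'
#' @param coll a [cross_collection()].
#' @param pair_a,pair_b character vectors of contiguous interval labels;
#'   each run is scored parity-aware between its flanking markers.
#' @return list with `pair`, `n_progeny`, `f1`, `f2`, `obs_dco`,
#'   `exp_dco`, `coincidence`, `I`. With `f1` or `f2` equal to 0 the
#'   coincidence and `I` are `NA` (undefined).
#' @export
#' @examples
#' # the two largest adjacent regions ho-b (= ho-dp + dp-b) and b-pr:
#' # coincidence_for_pair(coll, c("ho-dp", "dp-b"), "b-pr")
coincidence_for_pair <- function(coll, pair_a, pair_b) {
  stopifnot(inherits(coll, "cross_collection"))
  ind_a <- merged_indicator(coll, pair_a)
  ind_b <- merged_indicator(coll, pair_b)
  if (any(ind_a$markers %in% ind_b$inner) || any(ind_b$markers %in% ind_a$inner) ||
      length(intersect(ind_a$span, ind_b$span)) > 0L)
    stop("interval pair must be disjoint", call. = FALSE)
  n <- length(ind_a$x)
  f1 <- mean(ind_a$x)
  f2 <- mean(ind_b$x)
  obs <- sum(ind_a$x & ind_b$x)
  expd <- n * f1 * f2
  undef <- f1 == 0 || f2 == 0
  list(pair = c(paste(pair_a, collapse = "+"), paste(pair_b, collapse = "+")),
       n_progeny = n, f1 = f1, f2 = f2,
       obs_dco = obs, exp_dco = expd,
       coincidence = if (undef) NA_real_ else obs / expd,
       I = if (undef) NA_real_ else 1 - obs / expd)
}

# Per-progeny crossover indicator for a contiguous run of intervals,
# computed from the flanking-marker states of the pooled genotype matrix.
merged_indicator <- function(coll, labels) {
  map <- coll$map
  idx <- sort(interval_index(map, labels))
  if (length(idx) > 1L && !all(diff(idx) == 1L))
    stop("interval run is not contiguous: ",
         paste(labels, collapse = ", "), call. = FALSE)
  left <- min(idx); right <- max(idx) + 1L
  geno <- all_genotypes(coll)
  list(x = geno[, left] != geno[, right],
       markers = map$markers[c(left, right)],
       inner = if (right - left > 1L) map$markers[(left + 1L):(right - 1L)]
               else character(0),
       span = left:(right - 1L))
}

#' Per-cross interference values
#'
#' Computes [coincidence_for_pair()] separately for each replicate cross.
#'
#' @inheritParams coincidence_for_pair
#' @return data frame: `cross_id`, `n_progeny`, `obs_dco`, `exp_dco`, `I`
#'   (`NA` where undefined).
#' @export
interference_by_cross <- function(coll, pair_a, pair_b) {
  stopifnot(inherits(coll, "cross_collection"))
  rows <- lapply(names(coll$crosses), function(cid) {
    sub <- coll
    sub$crosses <- coll$crosses[cid]
    r <- coincidence_for_pair(sub, pair_a, pair_b)
    data.frame(cross_id = cid, n_progeny = r$n_progeny,
               obs_dco = r$obs_dco, exp_dco = r$exp_dco, I = r$I)
  })
  do.call(rbind, rows)
}

#' Mann-Whitney comparison of per-cross interference between genotypes
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the per-cross
#' interference values of two genotypes for the same interval pair.
#' Crosses where I is undefined (a zero single-interval frequency) are
#' dropped and counted.
#'
#' @param coll_a,coll_b [cross_collection()]s on the same map.
#' @inheritParams coincidence_for_pair
#' @return list with `U`, `p`, `n_used` (per genotype), `n_dropped`,
#'   `I_a`, `I_b` (the usable per-cross values).
#' @export
compare_interference <- function(coll_a, coll_b, pair_a, pair_b) {
  ia <- interference_by_cross(coll_a, pair_a, pair_b)
  ib <- interference_by_cross(coll_b, pair_a, pair_b)
  xa <- ia$I[!is.na(ia$I)]
  xb <- ib$I[!is.na(ib$I)]
  if (length(xa) < 2L || length(xb) < 2L)
    stop("need >= 2 crosses with defined interference per genotype",
         call. = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(xa, xb, exact = NULL))
  list(U = unname(ht$statistic), p = ht$p.value,
       n_used = c(length(xa), length(xb)),
       n_dropped = c(sum(is.na(ia$I)), sum(is.na(ib$I))),
       I_a = xa, I_b = xb)
}
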