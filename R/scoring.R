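#' Score crossovers on one recovered chromatid
#'
#' In a testcross each progeny phenotype vector is the maternal chromatid,
#' so a crossover is visible as a phase switch between adjacent markers:
#' interval i carries a crossover call iff the states at markers i and
#' i+1 differ. This is the minimal-crossover interpretation -- an even
#' number of exchanges within one interval cancels and is unobservable.
#'
#' @param genotype character vector of states "M"/"W", one per marker.
#' @param map a [marker_map()].
#' @return list with `per_interval` (named 0/1 integer vector over the
#'   map's intervals) and `n_crossovers` (their sum).
#' @export
#' @examples
#' m <- marker_map(c("net", "ho", "dp", "b", "pr", "cn"))
#' score_chromatid(c("M", "M", "W", "W", "W", "W"), m)  # one switch, ho-dp
score_chromatid <- function(genotype, map) {
  stopifnot(inherits(map, "marker_map"))
  if (length(genotype) != n_markers(map))
    stop("genotype length ", length(genotype), " != marker count ",
         n_markers(map), call. = FALSE)
  if (!all(genotype %in% c("M", "W")))
    stop("genotype states must be 'M' or 'W'", call. = FALSE)
  k <- length(genotype)
  sw <- as.integer(genotype[-k] != genotype[-1L])
  names(sw) <- map$intervals
  list(per_interval = sw, n_crossovers = sum(sw))
}

# Vectorised switch matrix: progeny x intervals, 0/1.
switch_matrix <- function(geno, map) {
  k <- n_markers(map)
  if (ncol(geno) != k) stop("genotype width mismatch", call. = FALSE)
  sw <- (geno[, -k, drop = FALSE] != geno[, -1L, drop = FALSE]) + 0L
  colnames(sw) <- map$intervals
  sw
}

#' Tabulate crossovers over a set of progeny
#'
#' Aggregates per-chromatid crossover calls into the two summaries all
#' downstream statistics use: per-interval crossover counts, and gamete
#' crossover-class counts a_0..a_{k-1} (number of progeny chromosomes with
#' j observed crossovers: NCO, SCO, DCO, ...). The class vector always has
#' k-1+1 entries so distributions align across genotypes.
#'
#' @param geno character genotype matrix (progeny x markers) or a
#'   [cross_collection()] (all progeny of all crosses pooled).
#' @param map a [marker_map()]; taken from the collection if omitted.
#' @return Object of class `crossover_tabulation`: list with `n_progeny`,
#'   `interval_counts` (named, length k-1), `class_counts` (named
#'   `a0`.., length k).
#' @export
tabulate_crossovers <- function(geno, map = NULL) {
  if (inherits(geno, "cross_collection")) {
    if (is.null(map)) map <- geno$map
    geno <- all_genotypes(geno)
  }
  stopifnot(inherits(map, "marker_map"))
  geno <- as.matrix(geno)
  if (nrow(geno) == 0L) stop("no progeny to tabulate", call. = FALSE)
  if (!all(geno %in% c("M", "W")))
    stop("genotype states must be 'M' or 'W'", call. = FALSE)
  sw <- switch_matrix(geno, map)
  n_int <- ncol(sw)
  per_progeny <- rowSums(sw)
  class_counts <- tabulate(per_progeny + 1L, nbins = n_int + 1L)
  names(class_counts) <- paste0("a", 0:n_int)
  structure(
    list(n_progeny = nrow(sw),
         interval_counts = stats::setNames(as.integer(colSums(sw)),
                                           colnames(sw)),
         class_counts = class_counts),
    class = "crossover_tabulation"
  )
}

#' @export
print.crossover_tabulation <- function(x, ...) {
  cat("Crossover tabulation:", x$n_progeny, "progeny,",
      sum(x$interval_counts), "crossovers\n")
  print(x$interval_counts)
  print(x$class_counts)
  invisible(x)
}

#' Pool a cross collection into one tabulation
#'
#' Tabulates all progeny of all replicate crosses together. Pooled counts
#' feed the Weinstein inversion and the chi-square comparisons; equals the
#' elementwise sum of per-cross tabulations.
#'
#' @param coll a [cross_collection()].
#' @return A `crossover_tabulation`.
#' @export
pool_crosses <- function(coll) {
  stopifnot(inherits(coll, "cross_collection"))
  tabulate_crossovers(coll)
}

#' Per-cross tabulations
#'
#' @param coll a [cross_collection()].
#' @return named list of `crossover_tabulation`, one per replicate cross.
#' @export
tabulate_by_cross <- function(coll) {
  stopifnot(inherits(coll, "cross_collection"))
  lapply(coll$crosses, tabulate_crossovers, map = coll$map)
}

#' Export a tabulation as a data frame
#'
#' @param tab a `crossover_tabulation`.
#' @return data frame with a per-interval block (interval, crossovers) and
#'   a class-count block (class, count), stable column names.
#' @export
tabulation_report <- function(tab) {
  stopifnot(inherits(tab, "crossover_tabulation"))
  rbind(
    data.frame(block = "interval", label = names(tab$interval_counts),
               count = unname(tab$interval_counts)),
    data.frame(block = "class", label = names(tab$class_counts),
               count = unname(tab$class_counts))
  )
}
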