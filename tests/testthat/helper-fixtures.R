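# Shared fixtures and independent oracles, built in code.

map6 <- function() marker_map(c("net", "ho", "dp", "b", "pr", "cn"), "2L")

# Independent brute-force switch counter: plain loop, no vectorisation,
# kept deliberately separate from the implementation's path.
brute_switches <- function(g) {
  n <- 0L
  for (i in seq_len(length(g) - 1L)) {
    if (g[i] != g[i + 1L]) n <- n + 1L
  }
  n
}

# All 2^k genotype vectors over k markers, as a character matrix.
all_genotypes_k <- function(k) {
  grid <- as.matrix(expand.grid(rep(list(c("M", "W")), k),
                                stringsAsFactors = FALSE))
  colnames(grid) <- NULL
  grid[, k:1, drop = FALSE]
}

# Genotype with a phase switch only in interval i (1-based).
single_switch_genotype <- function(i, k = 6L) {
  c(rep("M", i), rep("W", k - i))
}

# Collection with one cross holding the given genotype matrix.
coll_of <- function(geno, map = map6(), label = "fix",
                    cross_id = rep("c1", nrow(geno))) {
  cross_collection(geno, cross_id = cross_id, map = map,
                   genotype_label = label)
}

# Construct a crossover_tabulation directly from counts (for tests of
# statistics that consume tabulations without raw genotypes).
make_tab <- function(interval_counts, class_counts, n = sum(class_counts)) {
  structure(list(n_progeny = as.integer(n),
                 interval_counts = interval_counts,
                 class_counts = class_counts),
            class = "crossover_tabulation")
}

# Collection of pure-parental progeny split over crosses.
parental_coll <- function(n_per_cross, map = map6()) {
  k <- length(map$markers)
  geno <- matrix("M", sum(n_per_cross), k)
  coll_of(geno, map,
          cross_id = rep(paste0("c", seq_along(n_per_cross)), n_per_cross))
}
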