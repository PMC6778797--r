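#' Published tetrad exchange-class estimates for mei-217/-218 transgenes
#'
#' Exchange-class frequencies (E_0..E_3) inferred by Weinstein analysis of
#' net-cn testcross data for D. melanogaster females carrying mei-217/-218
#' transgenes from different species in a mei-218 null background: the
#' D. melanogaster control allele ("mel"), the D. pseudoobscura allele
#' ("pse"), the D. virilis allele ("vir"), and the mei-218^1 mutant
#' ("mei-218"). These distributions summarise the benchmark phenotypes --
#' wildtype-like assurance and interference (mel), weakened assurance and
#' interference (pse), and near-loss of crossover formation (vir, mutant)
#' -- and serve as realistic generative inputs for [sim_config()] and as
#' worked-example data.
#'
#' @return named list of numeric E vectors (`E0`..`E3`).
#' @export
#' @examples
#' tetrad_moments(reference_tetrads()$pse)["mean"]  # 0.775
reference_tetrads <- function() {
  lapply(list(
    "mei-218" = c(0.958, 0.042, 0.000, 0.000),
    mel = c(0.205, 0.685, 0.107, 0.004),
    pse = c(0.389, 0.467, 0.124, 0.020),
    vir = c(0.885, 0.094, 0.015, 0.006)
  ), function(E) stats::setNames(E, paste0("E", 0:3)))
}

#' Published interval intensity profiles for the transgene genotypes
#'
#' Approximate per-interval crossover proportions over the five net-cn
#' scoring intervals (net-ho, ho-dp, dp-b, b-pr, pr-cn) consistent with
#' the reported patterning of the mel (medially concentrated, range 0.44)
#' and pse (more uniform, range 0.24) transgene genotypes. Used as
#' simulator intensity profiles.
#'
#' @return named list of numeric weight vectors over the five intervals.
#' @export
reference_intensity <- function() {
  list(
    mel = c(0.04, 0.22, 0.48, 0.17, 0.09),
    pse = c(0.10, 0.20, 0.34, 0.20, 0.16),
    uniform = rep(0.2, 5)
  )
}

#' Marker map of the net-cn region of chromosome arm 2L
#'
#' The six classical visible markers net, ho, dp, b, pr, cn spanning
#' chromosome arm 2L and the centromere, giving the five scoring
#' intervals net-ho ... pr-cn.
#'
#' @return a [marker_map()].
#' @export
net_cn_map <- function() {
  marker_map(c("net", "ho", "dp", "b", "pr", "cn"), chromosome = "2L")
}
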