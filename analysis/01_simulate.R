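#!/usr/bin/env Rscript

# Step 1: generate the synthetic testcross experiment.
#
# Simulates net-cn testcross progeny for four maternal genotypes whose
# tetrad exchange distributions and crossover patterning emulate the
# benchmark transgene phenotypes: the D. melanogaster control allele
# ("mel", wildtype-like rates, medially concentrated crossovers), the
# D. pseudoobscura allele ("pse", near-wildtype rate, flatter
# patterning), the D. virilis allele ("vir", strongly reduced rate), and
# the mei-218 null ("mei-218", residual uniform class II crossovers).
# Replicate-cross counts and progeny numbers per cross follow the
# experimental design (13-14 crosses, roughly 100-160 progeny each;
# fewer progeny for vir, which shows reduced fecundity).
#
# Writes one progeny TSV and one truth log per genotype under
# results/sim/.

suppressPackageStartupMessages(library(meiocross))

args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(i <- which(args == "--seed"))) args[i + 1L] else 2019L)

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

m <- net_cn_map()
E <- reference_tetrads()
w <- reference_intensity()

designs <- list(
  mel = list(E = E$mel, w = w$mel, n_crosses = 13L, progeny = c(130L, 190L)),
  pse = list(E = E$pse, w = w$pse, n_crosses = 13L, progeny = c(120L, 190L)),
  vir = list(E = E$vir, w = w$mel, n_crosses = 14L, progeny = c(60L, 125L)),
  "mei-218" = list(E = E$"mei-218", w = w$uniform, n_crosses = 13L,
                   progeny = c(100L, 160L))
)

for (g in names(designs)) {
  d <- designs[[g]]
  cfg <- sim_config(m, n_crosses = d$n_crosses, progeny_per_cross = d$progeny,
                    model = "explicit", E = d$E, intensity = d$w,
                    genotype_label = g, seed = seed + match(g, names(designs)))
  sim <- simulate_experiment(cfg)
  write_progeny_table(sim$collection, file.path(out_dir, paste0(g, ".tsv")))
  utils::write.table(sim$truth, file.path(out_dir, paste0(g, "_truth.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-8s %2d crosses, %4d progeny, %4d true exchanges\n",
              g, d$n_crosses, n_progeny(sim$collection),
              sum(sim$truth$n_exchanges)))
}
cat("wrote", out_dir, "\n")
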