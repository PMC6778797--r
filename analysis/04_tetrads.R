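#!/usr/bin/env Rscript

# Step 4: Weinstein tetrad inference.
#
# Pools each genotype's gamete crossover classes, inverts them to tetrad
# exchange-class frequencies E_0..E_N, and assembles the summary table:
# class frequencies, mean/variance/relative variance of exchanges per
# tetrad, and pairwise signed fold-differences. Also runs the Poisson
# dispersion test per genotype and chi-square comparisons of the
# crossover-class distributions, and checks the inferred distributions
# against the simulator's generative truth.
#
# Writes results/tetrad_table.tsv and results/dispersion.tsv.

suppressPackageStartupMessages(library(meiocross))

m <- net_cn_map()
files <- list.files("results/sim", pattern = "\\.tsv$", full.names = TRUE)
files <- files[!grepl("_truth", files)]
colls <- lapply(files, function(f)
  read_progeny_table(f, m, sub("\\.tsv$", "", basename(f))))
names(colls) <- vapply(colls, function(x) x$genotype_label, "")
tabs <- lapply(colls, pool_crosses)

tds <- lapply(tabs, function(tb)
  suppressWarnings(weinstein_invert(tb$class_counts / tb$n_progeny)))
tab1 <- tetrad_class_table(tds)
utils::write.table(cbind(quantity = rownames(tab1), round(tab1, 3)),
                   "results/tetrad_table.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("Inferred exchange-class table (3 dp display):\n")
print(round(tab1, 3))

gen <- reference_tetrads()
cat("\nRecovery of the generative class frequencies (inferred - true):\n")
for (g in intersect(names(tds), names(gen)))
  cat(sprintf("  %-8s %s\n", g,
              paste(sprintf("%+.3f", tds[[g]]$E[1:4] - gen[[g]]), collapse = " ")))

disp <- do.call(rbind, lapply(names(tabs), function(g) {
  d <- tryCatch(dispersion_test(tabs[[g]]), error = function(e) NULL)
  if (is.null(d)) return(NULL)
  data.frame(genotype = g, relative_variance = d$relative_variance,
             direction = d$direction, chi2 = d$chi2, df = d$df, p = d$p)
}))
utils::write.table(disp, "results/dispersion.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nDispersion vs Poisson:\n")
print(transform(disp, relative_variance = round(relative_variance, 3),
                chi2 = round(chi2, 1), p = signif(p, 3)), row.names = FALSE)

prs <- utils::combn(names(tabs), 2L, simplify = FALSE)
cat("\nCrossover-class chi-square comparisons:\n")
for (pr in prs) {
  r <- tryCatch(compare_class_chi2(tabs[[pr[1]]], tabs[[pr[2]]]),
                error = function(e) NULL)
  if (!is.null(r))
    cat(sprintf("  %-8s vs %-8s chi2 %7.1f df %d p %.3g\n",
                pr[1], pr[2], r$chi2, r$df, r$p))
}
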