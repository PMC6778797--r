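#!/usr/bin/env Rscript

# Step 3: crossover patterning, independent of rate.
#
# Computes the proportion of all crossovers falling in each interval per
# genotype (with the max-min range as a flatness summary) and compares
# genotype pairs with Pearson chi-square tests on the interval crossover
# counts (df = 4 for the five net-cn intervals).
#
# Writes results/patterning.tsv and results/patterning_comparisons.tsv.

suppressPackageStartupMessages(library(meiocross))

m <- net_cn_map()
files <- list.files("results/sim", pattern = "\\.tsv$", full.names = TRUE)
files <- files[!grepl("_truth", files)]
colls <- lapply(files, function(f)
  read_progeny_table(f, m, sub("\\.tsv$", "", basename(f))))
names(colls) <- vapply(colls, function(x) x$genotype_label, "")
tabs <- lapply(colls, pool_crosses)

prof <- do.call(rbind, lapply(names(tabs), function(g) {
  pr <- crossover_proportions(tabs[[g]])
  data.frame(genotype = g, interval = names(pr$proportions),
             proportion = unname(pr$proportions),
             n_crossovers = pr$n_crossovers_total, range = pr$range)
}))
utils::write.table(prof, "results/patterning.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("Patterning ranges (max-min interval proportion):\n")
for (g in names(tabs)) {
  pr <- crossover_proportions(tabs[[g]])
  cat(sprintf("  %-8s range %.2f over %4d crossovers\n",
              g, pr$range, pr$n_crossovers_total))
}

prs <- utils::combn(names(tabs), 2L, simplify = FALSE)
cmp <- do.call(rbind, lapply(prs, function(pr) {
  r <- compare_patterning_chi2(tabs[[pr[1]]], tabs[[pr[2]]])
  data.frame(a = pr[1], b = pr[2], chi2 = r$chi2, df = r$df, p = r$p,
             note = if (is.null(r$warning)) "" else r$warning)
}))
utils::write.table(cmp, "results/patterning_comparisons.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nPatterning chi-square comparisons:\n")
print(transform(cmp, chi2 = round(chi2, 1), p = signif(p, 3)),
      row.names = FALSE)
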