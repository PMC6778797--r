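#!/usr/bin/env Rscript

# Step 2: replicate-cross genetic maps.
#
# Reads the simulated progeny tables, estimates per-interval and total
# map lengths (crossovers per 100 progeny) with means and SDs across
# replicate crosses, and compares genotype pairs by unpaired Student
# t-tests on the per-cross totals and on every interval.
#
# Writes results/maps.tsv and results/map_comparisons.tsv.

suppressPackageStartupMessages(library(meiocross))

m <- net_cn_map()
files <- list.files("results/sim", pattern = "^[^_]+\\.tsv$|^mei-218\\.tsv$",
                    full.names = TRUE)
files <- files[!grepl("_truth", files)]
stopifnot(length(files) > 0)

colls <- lapply(files, function(f)
  read_progeny_table(f, m, sub("\\.tsv$", "", basename(f))))
names(colls) <- vapply(colls, function(x) x$genotype_label, "")
sums <- lapply(colls, summarize_replicates)

maps <- do.call(rbind, lapply(names(sums), function(g)
  cbind(genotype = g, map_report(sums[[g]]))))
utils::write.table(maps, "results/maps.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

cat("Total net-cn map lengths (replicate means, cM):\n")
for (g in names(sums))
  cat(sprintf("  %-8s %6.2f (SD %5.2f, pooled %6.2f)\n", g,
              sums[[g]]$mean[["total"]], sums[[g]]$sd[["total"]],
              sums[[g]]$pooled$total_cM))

prs <- utils::combn(names(sums), 2L, simplify = FALSE)
rows <- list()
for (pr in prs) {
  for (wh in c(m$intervals, "total")) {
    r <- compare_t(sums[[pr[1]]], sums[[pr[2]]], wh)
    rows[[length(rows) + 1L]] <- data.frame(
      a = pr[1], b = pr[2], which = wh, t = r$statistic, df = r$df, p = r$p)
  }
}
cmp <- do.call(rbind, rows)
utils::write.table(cmp, "results/map_comparisons.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
sig <- cmp[cmp$which == "total", ]
cat("\nTotal-map t-tests:\n")
print(transform(sig, t = round(t, 2), p = signif(p, 3)), row.names = FALSE)
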