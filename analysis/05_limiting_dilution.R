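#!/usr/bin/env Rscript

# Step 5: clonogenic frequency from the limiting-dilution assays.
#
# Fits the single-hit Poisson model to each group's well counts, reports
# the frequencies with 95% confidence intervals, and compares the two
# groups with the likelihood-ratio test.

suppressPackageStartupMessages(library(sexconcord))
assays <- read_ld_csv("results/data/ld_assay.csv")

fits <- lapply(assays, fit_frequency)
for (g in names(fits)) {
  cat(g, ": ", sep = "")
  print(fits[[g]])
}
cmp <- compare_frequencies(assays$male, assays$female)
message(sprintf("male vs female: LRT = %.2f on %d df, p = %.3g",
                cmp$lrt_stat, cmp$df, cmp$p_value))

jsonlite::write_json(
  list(groups = lapply(fits, function(f) {
         list(f_hat = f$f_hat, one_in = 1 / f$f_hat,
              ci_low = f$ci_low, ci_high = f$ci_high,
              boundary = f$boundary_flag)
       }),
       comparison = list(lrt_stat = cmp$lrt_stat, df = cmp$df,
                         p_value = cmp$p_value)),
  "results/limiting_dilution.json", auto_unbox = TRUE, digits = NA)
message("wrote results/limiting_dilution.json")
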