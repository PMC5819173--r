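#!/usr/bin/env Rscript

# Step 1: simulate the study's input data.
#
# Generates a paired mouse/human expression bundle with sex effects
# planted at the study rates (49% cross-species sign concordance among
# the sex-differential genes over a 28% background), plus two
# limiting-dilution assay tables with a male/female difference in
# clonogenic frequency, and writes everything as plain-text fixtures
# under results/data/.

suppressPackageStartupMessages(library(sexconcord))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(concordance_rate = 0.49, background_concordance = 0.28,
                  seed = seed)
bundle <- generate_paired_expression(cfg)
write_fixture(bundle, out)

message(sprintf("simulated %d genes: %d planted sex-DE, realized concordance among them %.1f%%",
                cfg$n_genes, sum(bundle$truth$de_flags),
                100 * bundle$truth$planted_concordance))

# clonogenic frequencies: male cells more clonogenic than female
male <- generate_ld_assay(1 / 80, seed = seed + 1L, group = "male")
female <- generate_ld_assay(1 / 400, seed = seed + 2L, group = "female")
write_ld_csv(list(male, female), file.path(out, "ld_assay.csv"))
message(sprintf("wrote limiting-dilution tables (true f: male 1/80, female 1/400) to %s",
                file.path(out, "ld_assay.csv")))

# a small gene-set collection over the simulated mouse genes, including
# one set enriched for planted DE genes, for the over-representation step
set.seed(seed + 3L)
de_genes <- names(bundle$truth$de_flags)[bundle$truth$de_flags]
all_genes <- names(bundle$truth$de_flags)
sets <- c(
  list(planted_sex_program = sample(de_genes, 60)),
  lapply(stats::setNames(1:8, sprintf("random_set_%02d", 1:8)),
         function(i) sample(all_genes, 60))
)
write_gmt(sets, file.path(out, "gene_sets.gmt"))
message("wrote gene_sets.gmt (1 planted + 8 random sets)")
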