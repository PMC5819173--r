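#!/usr/bin/env Rscript

# Step 4: over-representation of the concordant sex-differential genes.
#
# Takes the significant mouse genes whose human direction agrees,
# tests them against the GMT collection from step 1 with the one-sided
# hypergeometric test (universe = all expressed, tested genes), and
# writes the BH-adjusted enrichment table. The planted set should rank
# first; the random sets should not be enriched.

suppressPackageStartupMessages(library(sexconcord))
bundle <- read_fixture("results/data")

mouse <- filter_unexpressed(bundle$mouse)
human <- filter_unexpressed(bundle$human)
mouse_lcpm <- log_cpm(mouse, tmm_factors(mouse))
tab <- sex_de_test(mouse_lcpm, mouse$sex)
sel <- select_de(tab)

human_dirs <- sex_direction(log_cpm(human, tmm_factors(human)), human$sex)
pairs <- map_orthologs(sel$genes, bundle$map)$pairs
hs <- human_dirs$sign[pairs$human_gene]
concordant <- pairs$mouse_gene[!is.na(hs) & hs == sel$directions[pairs$mouse_gene]]
message(sprintf("%d of %d significant genes are concordant with the human data",
                length(concordant), sel$n_selected))

sets <- read_gmt("results/data/gene_sets.gmt")
enr <- hypergeometric_ora(concordant, sets, universe = tab$gene)
print(utils::head(as.data.frame(enr), 4))
utils::write.table(enr, "results/enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("wrote results/enrichment.tsv")
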