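#!/usr/bin/env Rscript

# Step 1: simulate the study. Builds the cross-species pathway database and
# a 26-chemical treated/control expression study with two-year-bioassay-
# style tumor outcomes, then writes the data files the later steps read.
#
# All downstream numbers are deterministic given this seed.

suppressPackageStartupMessages(library(carcinopath))

seed <- 1L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = seed)
truth <- generate_study(cfg)
db <- truth$db

write_pathways(db$collections[[db$reference]],
               file.path(out, "pathways_mouse.tsv"))
write_pathways(db$collections$rat, file.path(out, "pathways_rat.tsv"))
utils::write.table(db$orthology, file.path(out, "orthology.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

bio <- write_bioassay(truth$bioassay, file.path(out, "bioassay.tsv"))
utils::write.table(truth$chemicals, file.path(out, "ground_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(truth$causal_pathways, file.path(out, "causal_pathways.txt"))

# one example expression study on disk for inspection; the enrichment step
# regenerates all 26 in memory from the same seed
write_expression_study(truth$studies[[1]],
                       file.path(out, "expression_chem01.tsv"),
                       file.path(out, "groups_chem01.tsv"))

cat(sprintf("Simulated %d chemicals over %d pathways (%d genes).\n",
            cfg$n_chemicals, cfg$n_pathways, cfg$n_genes))
cat(sprintf("Carcinogens: %d; causal pathways: %s\n",
            sum(truth$chemicals$carcinogen),
            paste(truth$causal_pathways, collapse = ", ")))
cat(sprintf("Bioassay calls at p <= 0.01: %d positive, %d negative.\n",
            sum(bio$call == "positive"), sum(bio$call == "negative")))
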