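#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a 2v2 hypercholesterolemic-vs-normal
# diet expression matrix (source namespace), an unreplicated 0/3/16 h
# cholesterol-depletion time course (target namespace), a complete 1:1
# ortholog map, an interactome with one planted degree-5 hub regulator
# among the discordant genes, and a small annotation collection.
#
# Writes every input in the pipeline's on-disk formats under results/inputs/.

suppressPackageStartupMessages(library(cholnet))

seed <- 20260929L %% 100000L   # fixed study seed
out <- file.path("results", "inputs")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- simulate_study(seed = seed)

write_expression_matrix(study$source$expr,
                        file.path(out, "source_expression.tsv"),
                        file.path(out, "source_design.tsv"))
write_expression_matrix(study$target$expr,
                        file.path(out, "target_expression.tsv"),
                        file.path(out, "target_design.tsv"))
write_ortholog_map(study$map, file.path(out, "ortholog_map.tsv"))
write_edge_list(study$interactome$network, file.path(out, "interactome.sif"))
write_gene_sets(study$gene_sets, file.path(out, "gene_sets.gmt"))
write.table(study$truth$shared_discordant,
            file.path(out, "truth_shared_discordant.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(study$truth$hubs, file.path(out, "truth_hubs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tr <- study$truth
message(sprintf(
  "simulated study (seed %d): %d genes/namespace; %d shared discordant, %d shared concordant pairs; hub %s wired to %d DEGs",
  seed, nrow(study$source$expr$values), nrow(tr$shared_discordant),
  nrow(tr$shared_concordant), tr$hubs$hub[1], tr$hubs$planted_degree[1]))
message("inputs written under ", out)
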