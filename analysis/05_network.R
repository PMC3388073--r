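#!/usr/bin/env Rscript
# Network modeling: seed the interactome with the discordant genes, expand
# to first neighbors, prune neighbors that do not bridge >= 2 DEGs, label
# functional modules from the enrichment, and rank regulators by degree
# centrality over the DEG set.

suppressPackageStartupMessages(library(cholnet))

inp <- file.path("results", "inputs")
disc <- read.delim(file.path("results", "discordant_set.tsv"))
inter <- read_edge_list(file.path(inp, "interactome.sif"))
enr <- read.delim(file.path("results", "enrichment.tsv"))
sets <- read_gene_sets(file.path(inp, "gene_sets.gmt"))

seeds <- unique(disc$target_gene)
net0 <- build_initial_network(seeds, inter)
net <- prune_network(net0)
net <- assign_modules(net, enr, sets)
message(sprintf("network: %d -> %d nodes after pruning (%d DEG, %d bridge)",
                nrow(net0$nodes), nrow(net$nodes),
                sum(net$nodes$role == "deg"),
                sum(net$nodes$role == "neighbor")))

ranking <- rank_regulators(net, net$nodes$node[net$nodes$role == "deg"])
write.table(ranking, file.path("results", "regulator_ranking.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_graphml(net, file.path("results", "network.graphml"),
              direction_mouse = stats::setNames(disc$sign_source,
                                                disc$target_gene),
              direction_human = stats::setNames(disc$sign_target,
                                                disc$target_gene))

truth_hubs <- read.delim(file.path(inp, "truth_hubs.tsv"))
message("top regulators by DEG-degree centrality:")
for (i in seq_len(min(5L, nrow(ranking))))
  message(sprintf("  %d. %s (degree %d, total %d)%s", ranking$rank[i],
                  ranking$gene[i], ranking$degree[i],
                  ranking$total_degree[i],
                  if (ranking$gene[i] %in% truth_hubs$hub)
                    "  <- planted hub" else ""))
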