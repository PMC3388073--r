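#!/usr/bin/env Rscript
# Annotation-term over-representation of the discordant set against the
# measured-gene universe (hypergeometric upper tail, BH adjustment).

suppressPackageStartupMessages(library(cholnet))

inp <- file.path("results", "inputs")
disc <- read.delim(file.path("results", "discordant_set.tsv"))
sets <- read_gene_sets(file.path(inp, "gene_sets.gmt"))
tgt <- read_expression_matrix(file.path(inp, "target_expression.tsv"),
                              file.path(inp, "target_design.tsv"))

res <- enrich(unique(disc$target_gene), sets, rownames(tgt$values))
write.table(res, file.path("results", "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("enrichment over ", nrow(res), " terms; top hits:")
for (i in seq_len(min(3L, nrow(res))))
  message(sprintf("  %s: k=%d/%d, p=%.3g, q=%.3g",
                  res$term[i], res$k[i], res$K[i], res$p[i], res$q[i]))
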