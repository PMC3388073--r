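#!/usr/bin/env Rscript
# Cross-dataset integration: map the two DEG lists through the ortholog
# table, classify the shared genes into four sign-concordance groups, and
# extract the discordant (cholesterol-sensing candidate) set.

suppressPackageStartupMessages(library(cholnet))

inp <- file.path("results", "inputs")
degs <- read.delim(file.path("results", "deg_two_group.tsv"))
calls_df <- read.delim(file.path("results", "deg_timecourse.tsv"))
calls <- structure(calls_df, timepoints = c("3h", "16h"), baseline = "0h",
                   class = c("timecourse_calls", "data.frame"))
map <- read_ortholog_map(file.path(inp, "ortholog_map.tsv"))

rec <- map_and_intersect(degs, calls, map)
write_concordance(rec, file.path("results", "concordance.tsv"))
disc <- discordant_set(rec)
write_concordance(disc, file.path("results", "discordant_set.tsv"))

message(sprintf("shared DEGs: %d; groups: %s", nrow(rec),
                paste(names(table(rec$group)), table(rec$group),
                      sep = "=", collapse = ", ")))
truth <- read.delim(file.path(inp, "truth_shared_discordant.tsv"))
tp <- length(intersect(disc$target_gene, truth$target_gene))
message(sprintf(
  "discordant set: %d genes (%d of %d planted recovered, %d spurious)",
  nrow(disc), tp, nrow(truth), nrow(disc) - tp))
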