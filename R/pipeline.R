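#' Run the full integrative analysis end to end
#'
#' Orchestrates both differential-expression analyses, cross-dataset
#' integration, enrichment, network construction/pruning and regulator
#' ranking from one set of inputs, writing every stage's output under
#' `out_dir` and returning a machine-readable run summary. Deterministic
#' given identical inputs and configuration.
#'
#' Inputs may be given as in-memory objects or file paths (file paths are
#' read with the package's readers): `expr_group` / `expr_time` as
#' [expr_matrix()] or `list(matrix =, design =)` paths; `ortholog_map` as a
#' data frame or TSV path; `interactions` as an [interaction_network()] or
#' SIF path; `gene_sets` as a named list or GMT path (optional);
#' `regulators` as a character vector (optional; defaults to all DEG nodes
#' of the pruned network).
#'
#' @param expr_group Two-group dataset (source namespace, e.g. mouse diet
#'   study).
#' @param expr_time Two-timepoint dataset (target namespace, e.g. human
#'   cells under cholesterol depletion).
#' @param ortholog_map Source-to-target symbol map.
#' @param interactions Interactome edge list (target namespace symbols).
#' @param gene_sets Optional annotation sets for enrichment and module
#'   labels.
#' @param regulators Optional candidate regulator identifiers.
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param baseline Baseline timepoint of the time course (default `"0h"`).
#' @param group_a Test-group label of the two-group design (default: first
#'   label in design order).
#' @return A list of class `run_summary`; also written as YAML to
#'   `out_dir/run_summary.yaml`.
#' @export
run_pipeline <- function(expr_group, expr_time, ortholog_map, interactions,
                         gene_sets = NULL, regulators = NULL,
                         config = run_config(), out_dir = ".",
                         baseline = "0h", group_a = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!inherits(expr_group, "expr_matrix"))
    expr_group <- stage("load_two_group",
                        read_expression_matrix(expr_group$matrix,
                                               expr_group$design,
                                               config$missing_policy))
  if (!inherits(expr_time, "expr_matrix"))
    expr_time <- stage("load_timecourse",
                       read_expression_matrix(expr_time$matrix,
                                              expr_time$design,
                                              config$missing_policy))
  if (!is.data.frame(ortholog_map))
    ortholog_map <- stage("load_ortholog_map", read_ortholog_map(ortholog_map))
  if (!inherits(interactions, "interaction_network"))
    interactions <- stage("load_interactions", read_edge_list(interactions))
  if (!is.null(gene_sets) && !is.list(gene_sets))
    gene_sets <- stage("load_gene_sets", read_gene_sets(gene_sets))

  message("stage deg_two_group: ", nrow(expr_group$values), " genes")
  degs1 <- stage("deg_two_group", deg_two_group(expr_group, config, group_a))
  write_deg_table(degs1, file.path(out_dir, "deg_two_group.tsv"))

  message("stage deg_timecourse: ", nrow(expr_time$values), " genes")
  calls2 <- stage("deg_timecourse",
                  call_timecourse(expr_time, baseline, config))
  calls2 <- stage("assign_patterns", assign_patterns(calls2))
  write_timecourse(calls2, file.path(out_dir, "deg_timecourse.tsv"))

  records <- stage("integration",
                   map_and_intersect(degs1, calls2, ortholog_map))
  write_concordance(records, file.path(out_dir, "concordance.tsv"))
  disc <- discordant_set(records)
  write_concordance(disc, file.path(out_dir, "discordant_set.tsv"))
  message("stage integration: ", nrow(records), " shared DEGs, ",
          nrow(disc), " discordant")

  enr <- NULL
  if (!is.null(gene_sets)) {
    universe <- rownames(expr_time$values)
    enr <- stage("enrichment",
                 enrich(unique(disc$target_gene), gene_sets, universe))
    write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  seeds <- unique(disc$target_gene)
  net0 <- stage("network_build", build_initial_network(seeds, interactions))
  net <- stage("network_prune", prune_network(net0))
  if (!is.null(enr) && nrow(enr))
    net <- stage("assign_modules", assign_modules(net, enr, gene_sets,
                                                  config$alpha))
  if (is.null(regulators))
    regulators <- net$nodes$node[net$nodes$role == "deg"]
  ranking <- stage("rank_regulators", rank_regulators(net, regulators))
  write.table(ranking, file.path(out_dir, "regulator_ranking.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dir_h <- timecourse_direction(calls2)
  write_graphml(net, file.path(out_dir, "network.graphml"),
                direction_mouse = stats::setNames(
                  disc$sign_source, disc$target_gene),
                direction_human = stats::setNames(
                  dir_h$direction[dir_h$direction != "none"],
                  dir_h$gene[dir_h$direction != "none"]))
  message("stage network: ", nrow(net$nodes), " nodes after pruning; top ",
          "regulator ", ranking$gene[1L], " (degree ", ranking$degree[1L], ")")

  tps <- attr(calls2, "timepoints")
  n2 <- lapply(tps, function(tp) {
    st <- calls2[[paste0("state_", tp)]]
    list(up = sum(st == "up"), down = sum(st == "down"))
  })
  names(n2) <- tps
  summary <- structure(list(
    n_deg_dataset1 = list(up = sum(degs1$direction == "up"),
                          down = sum(degs1$direction == "down")),
    n_deg_dataset2 = n2,
    n_intersection = nrow(records),
    n_discordant = nrow(disc),
    n_concordant = nrow(records) - nrow(disc),
    top_regulators = head(ranking, 10L),
    config_echo = unclass(config),
    seed = config$seed
  ), class = "run_summary")
  ysum <- summary
  ysum$top_regulators <- as.list(
    stats::setNames(ranking$degree[seq_len(min(10L, nrow(ranking)))],
                    ranking$gene[seq_len(min(10L, nrow(ranking)))]))
  yaml::write_yaml(unclass(ysum), file.path(out_dir, "run_summary.yaml"))
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat("run_summary\n")
  cat(sprintf("  dataset 1 DEGs: %d up, %d down\n",
              x$n_deg_dataset1$up, x$n_deg_dataset1$down))
  for (tp in names(x$n_deg_dataset2))
    cat(sprintf("  dataset 2 %s: %d up, %d down\n", tp,
                x$n_deg_dataset2[[tp]]$up, x$n_deg_dataset2[[tp]]$down))
  cat(sprintf("  intersection: %d (%d discordant, %d concordant)\n",
              x$n_intersection, x$n_discordant, x$n_concordant))
  if (nrow(x$top_regulators))
    cat(sprintf("  top regulator: %s (degree %d)\n",
                x$top_regulators$gene[1L], x$top_regulators$degree[1L]))
  invisible(x)
}
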