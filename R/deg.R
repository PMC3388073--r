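#' Apply the joint DEG selection rule to a DEG table
#'
#' A gene is called differentially expressed when its overall FDR is
#' strictly below `alpha` *and* its absolute log2 fold change is strictly
#' above `fc_threshold` (defaults 0.05 and 0.585, i.e. 1.5-fold). The
#' `direction` column is `"up"`/`"down"` by the sign of the fold change for
#' called genes and `"none"` otherwise.
#'
#' @param table Data frame with columns `fdr_overall` and `log2fc`.
#' @param config A [run_config()].
#' @return `table` with `is_deg` (logical) and `direction` columns set.
#' @export
select_degs <- function(table, config = run_config()) {
  stopifnot(all(c("fdr_overall", "log2fc") %in% colnames(table)))
  is_deg <- table$fdr_overall < config$alpha &
    abs(table$log2fc) > config$fc_threshold
  table$is_deg <- is_deg
  table$direction <- ifelse(!is_deg, "none",
                            ifelse(table$log2fc > 0, "up", "down"))
  table
}

#' Integrative two-group differential expression
#'
#' The full integrative hypothesis-testing procedure for a replicated
#' two-group design: (1) pooled-variance t and log2-median-ratio statistics
#' per gene; (2) permutation p-values for each statistic over all distinct
#' sample relabelings (sampled above `permutation_cap`); (3) Storey
#' q-values per statistic as per-test FDRs; (4) Stouffer combination of the
#' two per-test FDRs into an overall FDR; (5) joint selection on overall
#' FDR and absolute log2 fold change.
#'
#' @param em An [expr_matrix()], two-group design, >= 2 samples per group.
#' @param config A [run_config()].
#' @param group_a Which design label is the test group (fold changes are
#'   `mean(group_a) - mean(group_b)` on the log2 scale); defaults to the
#'   first label in design order.
#' @return A DEG table: data frame with columns `gene`, `log2fc`, `stat_t`,
#'   `stat_m`, `p_t`, `p_m`, `fdr_t`, `fdr_m`, `fdr_overall`, `direction`,
#'   `is_deg`.
#' @export
deg_two_group <- function(em, config = run_config(), group_a = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  grp <- two_group_split(em, group_a)
  perm_t <- permutation_pvalues(em, "t", config, group_a = grp$label_a)
  perm_m <- permutation_pvalues(em, "m", config, group_a = grp$label_a)
  st_t <- storey_qvalues(perm_t$p, config$storey_lambda)
  st_m <- storey_qvalues(perm_m$p, config$storey_lambda)
  fdr_mat <- cbind(st_t$qvalues, st_m$qvalues)
  fdr_overall <- stouffer_combine(fdr_mat)
  log2fc <- rowMeans(em$values[, grp$a, drop = FALSE]) -
    rowMeans(em$values[, grp$b, drop = FALSE])
  out <- data.frame(
    gene = rownames(em$values),
    log2fc = unname(log2fc),
    stat_t = unname(perm_t$observed),
    stat_m = unname(perm_m$observed),
    p_t = unname(perm_t$p),
    p_m = unname(perm_m$p),
    fdr_t = unname(st_t$qvalues),
    fdr_m = unname(st_m$qvalues),
    fdr_overall = unname(fdr_overall),
    stringsAsFactors = FALSE
  )
  select_degs(out, config)
}

#' Write a DEG table to TSV
#'
#' @param table A DEG table from [deg_two_group()].
#' @param path Output path.
#' @return `table`, invisibly.
#' @export
write_deg_table <- function(table, path) {
  cols <- c("gene", "log2fc", "stat_t", "stat_m", "p_t", "p_m",
            "fdr_t", "fdr_m", "fdr_overall", "direction", "is_deg")
  write.table(table[, intersect(cols, colnames(table))], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(table)
}
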