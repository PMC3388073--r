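# Direction of the time-course response per gene under the
# union-of-timepoints rule: a gene counts as differentially expressed if it
# is called at either timepoint; its direction comes from the later
# timepoint when called there, else the earlier; when both are called in
# opposite directions the larger |log2fc| wins (tie -> later timepoint).
timecourse_direction <- function(calls, timepoints = NULL) {
  stopifnot(inherits(calls, "timecourse_calls"))
  if (is.null(timepoints)) timepoints <- attr(calls, "timepoints")
  if (length(timepoints) != 2L)
    stop("direction rule requires exactly 2 non-baseline timepoints")
  early <- timepoints[1L]; late <- timepoints[2L]
  s1 <- calls[[paste0("state_", early)]]
  s2 <- calls[[paste0("state_", late)]]
  f1 <- calls[[paste0("log2fc_", early)]]
  f2 <- calls[[paste0("log2fc_", late)]]
  dir <- rep("none", nrow(calls))
  both_conflict <- s1 != "none" & s2 != "none" & s1 != s2
  dir[s2 != "none"] <- s2[s2 != "none"]
  only_early <- s2 == "none" & s1 != "none"
  dir[only_early] <- s1[only_early]
  dir[both_conflict] <- ifelse(abs(f1[both_conflict]) > abs(f2[both_conflict]),
                               s1[both_conflict], s2[both_conflict])
  fc <- ifelse(dir == s2 & s2 != "none", f2,
               ifelse(dir == s1 & s1 != "none", f1,
                      ifelse(abs(f2) >= abs(f1), f2, f1)))
  data.frame(gene = calls$gene, direction = dir, log2fc = fc,
             stringsAsFactors = FALSE)
}

# Normalize either a DEG table or timecourse calls to
# (gene, direction, log2fc) restricted to called genes.
direction_table <- function(x) {
  if (inherits(x, "timecourse_calls")) {
    d <- timecourse_direction(x)
  } else {
    stopifnot(all(c("gene", "direction", "log2fc") %in% colnames(x)))
    d <- x[, c("gene", "direction", "log2fc")]
  }
  d[d$direction %in% c("up", "down"), , drop = FALSE]
}

#' Map and intersect DEG calls across two datasets
#'
#' Joins the DEG calls of a source-namespace dataset (e.g. mouse,
#' hypercholesterolemic diet vs normal) and a target-namespace dataset
#' (e.g. human cells under cholesterol depletion, a two-timepoint course)
#' through an ortholog map, keeping genes called differentially expressed
#' in *both*, and classifies each shared gene by sign concordance into
#' four groups: `both_up`, `both_down`, `source_up_target_down`,
#' `source_down_target_up`. The two discordant groups together form the
#' cholesterol-sensing candidate set.
#'
#' Many-to-many ortholog mappings are resolved by `policy`: for each source
#' gene the target partner with the largest absolute log2 fold change is
#' kept (`"max_abs_fc"`, default; alphabetical tiebreak), or the
#' alphabetically first partner (`"first_alphabetical"`); then symmetrically
#' for each target gene among the surviving records.
#'
#' @param degs_source DEG table ([deg_two_group()] output) for the source
#'   dataset; rows with `direction` `"up"`/`"down"` are its DEGs.
#' @param degs_target DEG table or `timecourse_calls`
#'   ([call_timecourse()] output) for the target dataset. Time-course calls
#'   use the union-of-timepoints rule: called at either timepoint; direction
#'   from the later timepoint if called there, else the earlier; direction
#'   conflicts resolved by larger absolute fold change.
#' @param map Ortholog map data frame (`source`, `target`), as read by
#'   [read_ortholog_map()].
#' @param policy One-to-many resolution policy.
#' @return Data frame of concordance records: `source_gene`, `target_gene`,
#'   `sign_source`, `sign_target`, `fc_source`, `fc_target`, `group`,
#'   `discordant`.
#' @export
map_and_intersect <- function(degs_source, degs_target, map,
                              policy = c("max_abs_fc", "first_alphabetical")) {
  policy <- match.arg(policy)
  if (is.null(map) || !nrow(map)) stop("empty ortholog map")
  src <- direction_table(degs_source)
  tgt <- direction_table(degs_target)
  rec <- merge(map, src, by.x = "source", by.y = "gene")
  names(rec)[names(rec) == "direction"] <- "sign_source"
  names(rec)[names(rec) == "log2fc"] <- "fc_source"
  rec <- merge(rec, tgt, by.x = "target", by.y = "gene")
  names(rec)[names(rec) == "direction"] <- "sign_target"
  names(rec)[names(rec) == "log2fc"] <- "fc_target"
  if (!nrow(rec)) {
    return(data.frame(source_gene = character(), target_gene = character(),
                      sign_source = character(), sign_target = character(),
                      fc_source = numeric(), fc_target = numeric(),
                      group = character(), discordant = logical(),
                      stringsAsFactors = FALSE))
  }
  resolve <- function(df, by, other_gene, other_fc) {
    pick <- vapply(split(seq_len(nrow(df)), df[[by]]), function(idx) {
      if (length(idx) == 1L) return(idx)
      cand <- df[idx, ]
      if (policy == "max_abs_fc") {
        best <- abs(cand[[other_fc]]) == max(abs(cand[[other_fc]]))
        idx <- idx[best]
        cand <- cand[best, ]
      }
      idx[order(cand[[other_gene]])[1L]]
    }, integer(1L))
    df[sort(pick), , drop = FALSE]
  }
  rec <- resolve(rec, "source", "target", "fc_target")
  rec <- resolve(rec, "target", "source", "fc_source")
  group <- ifelse(rec$sign_source == "up" & rec$sign_target == "up",
                  "both_up",
           ifelse(rec$sign_source == "down" & rec$sign_target == "down",
                  "both_down",
           ifelse(rec$sign_source == "up", "source_up_target_down",
                  "source_down_target_up")))
  out <- data.frame(source_gene = rec$source, target_gene = rec$target,
                    sign_source = rec$sign_source,
                    sign_target = rec$sign_target,
                    fc_source = rec$fc_source, fc_target = rec$fc_target,
                    group = group,
                    discordant = rec$sign_source != rec$sign_target,
                    stringsAsFactors = FALSE)
  out <- out[order(out$source_gene, out$target_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the discordant (cholesterol-sensing candidate) set
#'
#' Genes whose expression moved in opposite directions in the two
#' experimental settings — the signature of cholesterol sensing — i.e. the
#' records with `discordant = TRUE`, identities in both namespaces
#' preserved.
#'
#' @param records Concordance records from [map_and_intersect()].
#' @return The discordant subset of `records`.
#' @export
discordant_set <- function(records) {
  stopifnot("discordant" %in% colnames(records))
  out <- records[records$discordant, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write concordance records to TSV
#'
#' @param records Concordance records.
#' @param path Output path.
#' @return `records`, invisibly.
#' @export
write_concordance <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(records)
}
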