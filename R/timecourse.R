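#' Fold-change DEG calling for an unreplicated time course
#'
#' For a design whose labels are timepoints with exactly one sample each,
#' computes per-gene log2 fold changes of every non-baseline timepoint
#' against the baseline sample and calls a three-level state per
#' timepoint: `"up"` when `log2fc > fc_threshold`, `"down"` when
#' `log2fc < -fc_threshold`, otherwise `"none"` (strict inequalities; the
#' default threshold 0.585 corresponds to 1.5-fold).
#'
#' @param em An [expr_matrix()] whose design labels are timepoints, one
#'   sample per timepoint.
#' @param baseline Baseline timepoint label (e.g. `"0h"`).
#' @param config A [run_config()] (supplies `fc_threshold`).
#' @return A `timecourse_calls` data frame: `gene`, then `log2fc_<tp>` and
#'   `state_<tp>` per non-baseline timepoint, with attributes `timepoints`
#'   (in design order) and `baseline`.
#' @export
call_timecourse <- function(em, baseline = "0h", config = run_config()) {
  stopifnot(inherits(em, "expr_matrix"))
  labs <- em$design
  if (!baseline %in% labs)
    stop("baseline timepoint '", baseline, "' absent from design")
  reps <- table(labs)
  if (any(reps > 1L))
    stop("timepoint(s) with replicates: ",
         paste(names(reps)[reps > 1L], collapse = ", "),
         "; replicated designs belong to deg_two_group()")
  tps <- setdiff(unique(labs), baseline)
  base_col <- which(labs == baseline)
  out <- data.frame(gene = rownames(em$values), stringsAsFactors = FALSE)
  for (tp in tps) {
    fc <- em$values[, which(labs == tp)] - em$values[, base_col]
    state <- ifelse(fc > config$fc_threshold, "up",
                    ifelse(fc < -config$fc_threshold, "down", "none"))
    out[[paste0("log2fc_", tp)]] <- unname(fc)
    out[[paste0("state_", tp)]] <- unname(state)
  }
  structure(out, timepoints = tps, baseline = baseline,
            class = c("timecourse_calls", "data.frame"))
}

#' The 8 two-timepoint expression-pattern classes
#'
#' With three states (up / none / down) at each of two timepoints there are
#' 3^2 - 1 = 8 patterns once the all-none pair is excluded; genes in that
#' excluded cell are simply not differentially expressed. Patterns are
#' numbered in lexicographic order over (state at first timepoint, state at
#' second timepoint) with up < none < down, so pattern 1 is sustained
#' up-regulation (up, up) and pattern 8 sustained down-regulation
#' (down, down); late-only responses are patterns 4 (none, up) and
#' 5 (none, down).
#'
#' @return Data frame with columns `pattern_id`, `state_first`,
#'   `state_second`.
#' @export
pattern_table <- function() {
  states <- c("up", "none", "down")
  grid <- expand.grid(state_second = states, state_first = states,
                      stringsAsFactors = FALSE)[, 2:1]
  grid <- grid[!(grid$state_first == "none" & grid$state_second == "none"), ]
  data.frame(pattern_id = seq_len(nrow(grid)), grid,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign expression-pattern identifiers to time-course calls
#'
#' Maps every gene with at least one non-`"none"` state to one of the 8
#' pattern classes of [pattern_table()]; genes flat at both timepoints get
#' `NA`.
#'
#' @param calls A `timecourse_calls` object from [call_timecourse()].
#' @param timepoints The two non-baseline timepoints, ordered (defaults to
#'   the calls' own timepoint order).
#' @return `calls` with a `pattern_id` column added.
#' @export
assign_patterns <- function(calls, timepoints = NULL) {
  stopifnot(inherits(calls, "timecourse_calls"))
  if (is.null(timepoints)) timepoints <- attr(calls, "timepoints")
  if (length(timepoints) != 2L)
    stop("pattern assignment requires exactly 2 non-baseline timepoints, ",
         "found ", length(timepoints))
  s1 <- calls[[paste0("state_", timepoints[1L])]]
  s2 <- calls[[paste0("state_", timepoints[2L])]]
  if (is.null(s1) || is.null(s2))
    stop("calls lack state columns for: ",
         paste(timepoints, collapse = ", "))
  pt <- pattern_table()
  key <- paste(s1, s2, sep = "|")
  pid <- pt$pattern_id[match(key, paste(pt$state_first, pt$state_second,
                                        sep = "|"))]
  calls$pattern_id <- pid   # (none, none) is absent from the table -> NA
  calls
}

#' Write time-course calls to TSV
#'
#' @param calls A `timecourse_calls` data frame.
#' @param path Output path.
#' @return `calls`, invisibly.
#' @export
write_timecourse <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(calls)
}
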