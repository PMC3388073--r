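#' Permutation p-values for a two-group design
#'
#' Evaluates a per-gene statistic ([stat_t()] or [stat_m()]) over group
#' relabelings of the samples. A relabeling assigns the group-A label to a
#' subset of samples of the observed group-A size; when the number of
#' distinct relabelings `choose(n, nA)` is at most `config$permutation_cap`
#' all of them are enumerated (`exhaustive = TRUE`), otherwise
#' `permutation_cap` relabelings are sampled with the configured seed, with
#' the identity relabeling always included.
#'
#' Two null models are available:
#' \describe{
#'   \item{`"per_gene"`}{Each gene is compared with its own relabeling
#'     ensemble: two-sided `p = #\{|stat*| >= |stat_obs|\} / n_perm`,
#'     counting the identity relabeling, so `p > 0` always. With balanced
#'     tiny designs this p-value is floor-limited (for 2v2 the identity and
#'     its label swap always tie the observed statistic, so `p >= 2/6`).}
#'   \item{`"pooled"`}{Permuted statistics from the *non-trivial*
#'     relabelings (those not equal to the observed grouping, nor its label
#'     swap for balanced designs) are pooled across all genes into one
#'     empirical null; `p = (1 + #\{|null| >= |stat_obs|\}) / (1 + N_null)`.
#'     Pooling borrows resolution across genes, which is what makes FDR
#'     thresholds like 0.05 attainable with n = 2 per group.}
#' }
#'
#' @param em An [expr_matrix()] with a two-group design, each group >= 2
#'   samples.
#' @param statistic `"t"` or `"m"`.
#' @param config A [run_config()] (supplies `permutation_cap`, `seed`,
#'   `null_model`).
#' @param group_a Which design label is group A (sign reference); defaults
#'   to the first label in design order.
#' @return Object of class `permutation_null`: list with `observed`
#'   (named numeric), `permuted` (genes x relabelings matrix), `n_perm`,
#'   `exhaustive`, `null_model`, and `p` (named numeric p-values).
#' @export
permutation_pvalues <- function(em, statistic = c("t", "m"),
                                config = run_config(), group_a = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(em, "expr_matrix"))
  grp <- two_group_split(em, group_a)
  n <- ncol(em$values)
  na <- length(grp$a)
  if (na < 2L || length(grp$b) < 2L)
    stop("each group needs >= 2 samples")
  n_distinct <- choose(n, na)
  if (n_distinct <= config$permutation_cap) {
    sel <- combn(n, na)        # each column: which samples get label A
    exhaustive <- TRUE
  } else {
    sel <- with_seed(config$seed, {
      cbind(sort(grp$a),
            replicate(config$permutation_cap - 1L, sort(sample(n, na))))
    })
    exhaustive <- FALSE
  }
  n_perm <- ncol(sel)
  genes <- rownames(em$values)
  perm <- matrix(NA_real_, nrow(em$values), n_perm,
                 dimnames = list(genes, NULL))
  for (j in seq_len(n_perm)) {
    ia <- sel[, j]
    perm[, j] <- row_stat(em$values, ia, setdiff(seq_len(n), ia), statistic)
  }
  obs_set <- sort(grp$a)
  is_identity <- colSums(sel != obs_set) == 0L
  # label swap of a balanced design induces the same partition
  is_swap <- rep(FALSE, n_perm)
  if (na == length(grp$b)) {
    swap_set <- sort(grp$b)
    is_swap <- colSums(sel != swap_set) == 0L
  }
  obs <- perm[, which(is_identity)[1L]]
  if (config$null_model == "per_gene") {
    p <- rowSums(abs(perm) >= abs(obs)) / n_perm
  } else {
    null_stats <- abs(perm[, !(is_identity | is_swap), drop = FALSE])
    nv <- sort(as.numeric(null_stats))
    n_null <- length(nv)
    if (!n_null)
      stop("no non-trivial relabelings available for the pooled null")
    count_ge <- n_null - findInterval(abs(obs), nv, left.open = TRUE)
    p <- (1 + count_ge) / (1 + n_null)
  }
  names(p) <- genes
  structure(list(observed = obs, permuted = perm, n_perm = n_perm,
                 exhaustive = exhaustive, statistic = statistic,
                 null_model = config$null_model, p = p),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "permutation_null: stat '%s', %d genes, %d relabelings (%s), %s null\n",
    x$statistic, length(x$observed), x$n_perm,
    if (x$exhaustive) "exhaustive" else "sampled", x$null_model))
  invisible(x)
}
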