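#' Storey q-values
#'
#' Estimates the null proportion pi0 from the flat right tail of the
#' p-value distribution and converts p-values to q-values. pi0 is the
#' median over the lambda grid of `#\{p > lambda\} / ((1 - lambda) * n)`,
#' clamped to (0, 1] — a deliberately simple aggregation that is more
#' robust than spline smoothing at small gene counts. The q-value of the
#' i-th smallest p is `min_{j >= i} pi0 * n * p_(j) / j`, capped at 1,
#' which makes q-values monotone in p-value rank by construction.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param lambda_grid Lambda grid in \[0, 1); default `seq(0, 0.90, 0.05)`.
#' @return Object of class `storey_estimate`: list with `pvalues`, `pi0`,
#'   `qvalues` (same order as input), `lambda_grid`.
#' @export
storey_qvalues <- function(pvalues, lambda_grid = seq(0, 0.90, by = 0.05)) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || anyNA(pvalues))
    stop("p-values must lie in [0,1] with no NA")
  if (any(lambda_grid < 0 | lambda_grid >= 1))
    stop("lambda grid must lie in [0,1)")
  n <- length(pvalues)
  pi0 <- median(vapply(lambda_grid,
                       function(l) mean(pvalues > l) / (1 - l),
                       numeric(1L)))
  pi0 <- min(max(pi0, 1e-8), 1)
  o <- order(pvalues)
  q_sorted <- pi0 * n * pvalues[o] / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  qvalues <- numeric(n)
  qvalues[o] <- q_sorted
  names(qvalues) <- names(pvalues)
  structure(list(pvalues = pvalues, pi0 = pi0, qvalues = qvalues,
                 lambda_grid = lambda_grid),
            class = "storey_estimate")
}

#' @export
print.storey_estimate <- function(x, ...) {
  cat(sprintf("storey_estimate: %d p-values, pi0 = %.3f\n",
              length(x$pvalues), x$pi0))
  invisible(x)
}

#' Combine per-test FDRs with Stouffer's method
#'
#' Each FDR is clamped to \[1e-15, 1 - 1e-15\], probit-transformed
#' (`z_i = qnorm(1 - fdr_i)`), summed and rescaled by `sqrt(k)`; the
#' combined value is `1 - pnorm(z)`. With one test this is the identity;
#' combining identical values below 0.5 always strengthens the evidence
#' (the combined value is smaller). The z-scores are unsigned: the two
#' statistics share the sign of the effect, and discordant-direction genes
#' are handled downstream by the fold-change gate.
#'
#' @param fdrs Numeric vector (one gene's per-test FDRs) or a genes x tests
#'   matrix.
#' @return A single combined FDR, or a vector (one per row of the matrix).
#' @examples
#' stouffer_combine(c(0.05, 0.05))  # 0.0100
#' @export
stouffer_combine <- function(fdrs) {
  if (is.matrix(fdrs)) {
    if (!ncol(fdrs)) stop("no tests to combine")
    f <- pmin(pmax(fdrs, 1e-15), 1 - 1e-15)
    z <- rowSums(qnorm(1 - f)) / sqrt(ncol(fdrs))
    out <- pnorm(z, lower.tail = FALSE)
    names(out) <- rownames(fdrs)
    return(out)
  }
  if (!length(fdrs)) stop("no tests to combine")
  if (any(fdrs < 0 | fdrs > 1)) stop("FDRs must lie in [0,1]")
  f <- pmin(pmax(fdrs, 1e-15), 1 - 1e-15)
  z <- sum(qnorm(1 - f)) / sqrt(length(f))
  pnorm(z, lower.tail = FALSE)
}
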