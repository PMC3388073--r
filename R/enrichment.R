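#' Hypergeometric gene-set over-representation
#'
#' For each annotation term, tests whether the query set overlaps the term
#' more than expected when drawing `n = |query|` genes from the universe of
#' `N` genes containing `K` term members: `p = P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)` (upper tail, `k = |overlap|`). The
#' universe should be the genes actually measured (the platform/matrix),
#' not the genome. Benjamini-Hochberg q-values are reported across the
#' tested terms alongside raw p.
#'
#' @param query Character vector of query genes (e.g. a DEG set); genes
#'   outside the universe are dropped.
#' @param sets Named list term -> member genes, as from [read_gene_sets()];
#'   members are intersected with the universe, and terms left empty are
#'   skipped with a message.
#' @param universe Character vector of background genes.
#' @return Data frame sorted by `p` then term: `term`, `k`, `K`, `n`, `N`,
#'   `p`, `q`.
#' @examples
#' sets <- list(T1 = paste0("g", 1:5))
#' enrich(paste0("g", 1:5), sets, paste0("g", 1:20))
#' @export
enrich <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- intersect(unique(query), universe)
  N <- length(universe)
  n <- length(query)
  keep <- names(sets)
  rows <- lapply(keep, function(tm) {
    members <- intersect(unique(sets[[tm]]), universe)
    K <- length(members)
    if (K == 0L) {
      message("term '", tm, "' has no members in the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(query, members))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
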