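#' Expression matrix with sample design
#'
#' Container for a log2-scale genes-by-samples expression matrix together
#' with its sample design (a label per sample: a group such as `"Hyper"` /
#' `"Normo"`, or a timepoint such as `"0h"` / `"3h"` / `"16h"`).
#'
#' Invariants enforced at construction: unique gene and sample identifiers,
#' a design label for every sample, and no missing values (the missing-value
#' policy is applied at read time, see [read_expression_matrix()]).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers). Values are assumed
#'   log2 scale.
#' @param design Named character vector mapping sample identifier to its
#'   group/timepoint label. Must cover every column of `values`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `design` (named character vector, in column order).
#' @examples
#' m <- matrix(rnorm(12, 7, 1.5), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expr_matrix(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
#' dim(em$values)
#' @export
expr_matrix <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("'values' must have rownames (genes) and colnames (samples)")
  dup_g <- genes[duplicated(genes)]
  if (length(dup_g))
    stop("duplicate gene identifier(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- samples[duplicated(samples)]
  if (length(dup_s))
    stop("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", "))
  if (anyNA(values))
    stop("expression matrix contains missing values")
  missing_design <- setdiff(samples, names(design))
  if (length(missing_design))
    stop("sample(s) missing from design: ", paste(missing_design, collapse = ", "))
  design <- design[samples]
  if (any(!nzchar(design)) || anyNA(design))
    stop("every design label must be non-empty")
  structure(list(values = values, design = design), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$design)
  cat("design:", paste(sprintf("%s(n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read an expression matrix and its design from TSV files
#'
#' The matrix file has a header row of sample identifiers and a first column
#' of gene identifiers; the design file has a header and two columns,
#' `sample_id` and `label`. File order of genes and samples is preserved.
#'
#' @param path Path to the expression TSV.
#' @param design_path Path to the two-column design TSV.
#' @param missing_policy `"error"` (default) stops on any non-numeric or
#'   missing cell, naming the gene and sample; `"drop_gene"` silently drops
#'   genes with any missing cell.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, design_path,
                                   missing_policy = c("error", "drop_gene")) {
  missing_policy <- match.arg(missing_policy)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs a gene column plus >=1 sample")
  genes <- raw[[1L]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  samples <- colnames(raw)[-1L]
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(genes, samples))
  if (anyNA(vals)) {
    if (missing_policy == "error") {
      bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                   genes[bad[["row"]]], samples[bad[["col"]]]))
    }
    keep <- rowSums(is.na(vals)) == 0L
    vals <- vals[keep, , drop = FALSE]
  }
  des <- read.delim(design_path, header = TRUE, sep = "\t",
                    colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% colnames(des)))
    stop("design file must have columns 'sample_id' and 'label'")
  design <- stats::setNames(des$label, des$sample_id)
  expr_matrix(vals, design)
}

#' Write an expression matrix (and optionally its design) to TSV
#'
#' @param em An [expr_matrix()].
#' @param path Output TSV path for the matrix.
#' @param design_path Optional output path for the design TSV.
#' @return `em`, invisibly.
#' @export
write_expression_matrix <- function(em, path, design_path = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path)) {
    dd <- data.frame(sample_id = names(em$design), label = unname(em$design),
                     stringsAsFactors = FALSE)
    write.table(dd, design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(em)
}

# Split sample indices by design label; error unless exactly two groups.
two_group_split <- function(em, group_a = NULL) {
  labels <- unique(em$design)
  if (length(labels) != 2L)
    stop("design must have exactly 2 groups, found ",
         length(labels), ": ", paste(labels, collapse = ", "))
  if (is.null(group_a)) group_a <- labels[1L]
  if (!group_a %in% labels) stop("group_a '", group_a, "' not in design")
  group_b <- setdiff(labels, group_a)
  list(a = which(em$design == group_a),
       b = which(em$design == group_b),
       label_a = group_a, label_b = group_b)
}
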