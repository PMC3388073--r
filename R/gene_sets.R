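#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `term<TAB>description<TAB>member1<TAB>member2...`. Member lists are
#' deduplicated; duplicate term names and lines with fewer than 3 fields
#' are errors.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (term -> gene members). An empty
#'   file yields an empty list.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(stats::setNames(list(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L], ": expected >=3 tab-separated ",
         "fields, found ", nf[nf < 3L][1L])
  terms <- vapply(parts, `[[`, character(1L), 1L)
  dup <- unique(terms[duplicated(terms)])
  if (length(dup))
    stop("duplicate term name(s): ", paste(dup, collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  stats::setNames(sets, terms)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (term -> members).
#' @param path Output path.
#' @param descriptions Optional named character vector of term descriptions;
#'   defaults to `"na"`.
#' @return `sets`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(tm) {
    desc <- if (!is.null(descriptions) && tm %in% names(descriptions))
      descriptions[[tm]] else "na"
    paste(c(tm, desc, sets[[tm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(sets)
}

#' Read an ortholog mapping table
#'
#' A two-column TSV with a header row; column 1 holds source-namespace gene
#' symbols (e.g. mouse), column 2 the target namespace (e.g. human). The
#' mapping may be many-to-many; duplicated pairs are collapsed. Matching is
#' exact, case-sensitive string match.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `source` and `target`.
#' @export
read_ortholog_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ortholog map needs 2 columns (source, target)")
  out <- data.frame(source = df[[1L]], target = df[[2L]],
                    stringsAsFactors = FALSE)
  out[!duplicated(paste(out$source, out$target, sep = "\r")), , drop = FALSE]
}

#' Write an ortholog mapping table
#'
#' @param map Data frame with columns `source`, `target`.
#' @param path Output path.
#' @return `map`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  write.table(map[, c("source", "target")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(map)
}
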