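#' Analysis run configuration
#'
#' Collects the thresholds and numerical settings used across the pipeline.
#'
#' @param alpha Overall-FDR significance threshold for DEG calls
#'   (strict `<`); default 0.05.
#' @param fc_threshold Absolute log2 fold-change threshold for DEG calls
#'   (strict `>`); default 0.585, i.e. 1.5-fold.
#' @param permutation_cap Maximum number of relabelings to evaluate; designs
#'   with more distinct relabelings are sampled with `seed`. Default 10000.
#' @param seed Integer RNG seed used wherever sampling occurs.
#' @param storey_lambda Lambda grid for the Storey pi0 estimate;
#'   default `seq(0, 0.90, 0.05)`.
#' @param missing_policy How to treat non-numeric cells at load time:
#'   `"error"` (default) or `"drop_gene"`.
#' @param null_model Permutation null for p-values: `"pooled"` (default;
#'   permuted statistics from non-trivial relabelings pooled across genes)
#'   or `"per_gene"` (each gene compared with its own relabeling ensemble,
#'   identity included).
#' @return A list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, fc_threshold = 0.585,
                       permutation_cap = 10000L, seed = 1L,
                       storey_lambda = seq(0, 0.90, by = 0.05),
                       missing_policy = c("error", "drop_gene"),
                       null_model = c("pooled", "per_gene")) {
  missing_policy <- match.arg(missing_policy)
  null_model <- match.arg(null_model)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  if (fc_threshold < 0) stop("fc_threshold must be >= 0")
  if (permutation_cap < 1) stop("permutation_cap must be >= 1")
  if (any(storey_lambda < 0 | storey_lambda >= 1))
    stop("storey_lambda values must lie in [0,1)")
  structure(list(alpha = alpha, fc_threshold = fc_threshold,
                 permutation_cap = as.integer(permutation_cap),
                 seed = as.integer(seed),
                 storey_lambda = storey_lambda,
                 missing_policy = missing_policy,
                 null_model = null_model),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; absent keys take the [run_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}
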