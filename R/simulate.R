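#' Simulate a replicated two-group expression matrix with planted effects
#'
#' Emulates the hypercholesterolemic-vs-normal diet design: log2-scale
#' baseline expression per gene drawn from Normal(7, 1.5) — a conventional
#' normalized-microarray scale — with Gaussian measurement noise on the
#' log2 scale, tiny replicate counts (default 2 per group), and a planted
#' fraction of differentially expressed genes shifted by `+/-effect_size`
#' in group A, directions split 50/50. Fully reproducible from `seed`.
#'
#' @param n_genes Number of genes (default 1000).
#' @param n_per_group Samples per group, >= 2 (default 2, as in the diet
#'   study).
#' @param frac_deg Fraction of genes with a planted effect, in \[0, 1)
#'   (default 0.05).
#' @param effect_size Planted shift, log2 units (default 2.0).
#' @param noise_sd Noise standard deviation, log2 units (default 0.25).
#' @param seed RNG seed.
#' @param group_labels Two design labels, group A first (default
#'   `c("Hyper", "Normo")`).
#' @param gene_ids Optional gene identifiers (length `n_genes`); default
#'   `g0001...`.
#' @param deg_genes Optional named character vector gene -> `"up"`/`"down"`
#'   fixing exactly which genes carry the planted effect (overrides
#'   `frac_deg`'s random placement).
#' @return List with `expr` (an [expr_matrix()]) and `truth` (data frame
#'   `gene`, `direction` in up/down/none, where "up" means higher in group
#'   A, i.e. positive log2 fold change A - B).
#' @export
simulate_two_group <- function(n_genes = 1000L, n_per_group = 2L,
                               frac_deg = 0.05, effect_size = 2.0,
                               noise_sd = 0.25, seed = 1L,
                               group_labels = c("Hyper", "Normo"),
                               gene_ids = NULL, deg_genes = NULL) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  if (frac_deg < 0 || frac_deg >= 1) stop("frac_deg must lie in [0,1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(length(group_labels) == 2L)
  with_seed(seed, {
    genes <- if (is.null(gene_ids)) sprintf("g%04d", seq_len(n_genes))
             else as.character(gene_ids)
    stopifnot(length(genes) == n_genes)
    samples <- c(paste0(group_labels[1L], "_", seq_len(n_per_group)),
                 paste0(group_labels[2L], "_", seq_len(n_per_group)))
    design <- stats::setNames(rep(group_labels, each = n_per_group), samples)
    baseline <- rnorm(n_genes, mean = 7, sd = 1.5)
    vals <- matrix(baseline, n_genes, 2L * n_per_group,
                   dimnames = list(genes, samples))
    direction <- rep("none", n_genes)
    if (!is.null(deg_genes)) {
      bad <- setdiff(names(deg_genes), genes)
      if (length(bad)) stop("unknown deg_genes: ", paste(bad, collapse = ", "))
      planted <- match(names(deg_genes), genes)
      dirs <- unname(deg_genes)
      direction[planted] <- dirs
    } else {
      n_deg <- round(frac_deg * n_genes)
      planted <- if (n_deg > 0L) sample(n_genes, n_deg) else integer()
      n_up <- ceiling(n_deg / 2)
      dirs <- if (n_deg > 0L) sample(rep(c("up", "down"), c(n_up, n_deg - n_up)))
              else character()
      direction[planted] <- dirs
    }
    if (length(planted)) {
      shift <- ifelse(dirs == "up", effect_size, -effect_size)
      vals[planted, seq_len(n_per_group)] <-
        vals[planted, seq_len(n_per_group), drop = FALSE] + shift
    }
    vals <- vals + matrix(rnorm(length(vals), sd = noise_sd),
                          nrow = n_genes)
    list(expr = expr_matrix(vals, design),
         truth = data.frame(gene = genes, direction = direction,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate an unreplicated two-timepoint time course
#'
#' Emulates the cholesterol-depletion time course (one sample at baseline
#' and at each of two later timepoints). Genes are assigned expression
#' patterns according to `pattern_mix`; an "up"/"down" state at a timepoint
#' shifts that sample by `+/-effect_size` log2 units from the gene's
#' baseline. Gaussian noise is added to every sample independently.
#'
#' @param n_genes Number of genes.
#' @param pattern_mix Named numeric vector of pattern fractions summing to
#'   <= 1; names are `"<state1>_<state2>"` over states up/none/down, e.g.
#'   `c(up_up = 0.05, none_down = 0.1)`. The all-none key is not a pattern.
#' @param effect_size Planted shift, log2 units (default 1.0).
#' @param noise_sd Per-sample noise SD, log2 units (default 0.2).
#' @param seed RNG seed.
#' @param timepoints Three timepoint labels, baseline first (default
#'   `c("0h", "3h", "16h")`).
#' @param gene_ids Optional gene identifiers (length `n_genes`).
#' @param pattern_genes Optional named character vector gene -> pattern key
#'   (e.g. `c(g0001 = "up_up")`) fixing patterns for specific genes;
#'   `pattern_mix` then applies to the remaining genes.
#' @return List with `expr` (an [expr_matrix()], one sample per timepoint)
#'   and `truth` (data frame `gene`, `state_<tp1>`, `state_<tp2>`,
#'   `pattern_id`; `pattern_id` is `NA` for unplanted genes).
#' @export
simulate_timecourse <- function(n_genes = 1000L, pattern_mix = c(up_up = 0.05),
                                effect_size = 1.0, noise_sd = 0.2,
                                seed = 1L,
                                timepoints = c("0h", "3h", "16h"),
                                gene_ids = NULL, pattern_genes = NULL) {
  stopifnot(length(timepoints) == 3L)
  pt <- pattern_table()
  valid_keys <- paste(pt$state_first, pt$state_second, sep = "_")
  if (length(pattern_mix)) {
    bad <- setdiff(names(pattern_mix), valid_keys)
    if (length(bad))
      stop("unknown pattern key(s): ", paste(bad, collapse = ", "),
           "; valid keys: ", paste(valid_keys, collapse = ", "))
    if (sum(pattern_mix) > 1) stop("pattern fractions sum to > 1")
  }
  if (!is.null(pattern_genes)) {
    bad_key <- setdiff(unique(pattern_genes), valid_keys)
    if (length(bad_key))
      stop("unknown pattern key(s): ", paste(bad_key, collapse = ", "))
  }
  with_seed(seed, {
    genes <- if (is.null(gene_ids)) sprintf("g%04d", seq_len(n_genes))
             else as.character(gene_ids)
    stopifnot(length(genes) == n_genes)
    samples <- paste0("s_", timepoints)
    design <- stats::setNames(timepoints, samples)
    baseline <- rnorm(n_genes, mean = 7, sd = 1.5)
    vals <- matrix(baseline, n_genes, 3L, dimnames = list(genes, samples))
    s1 <- rep("none", n_genes); s2 <- rep("none", n_genes)
    fixed <- integer()
    if (!is.null(pattern_genes)) {
      bad <- setdiff(names(pattern_genes), genes)
      if (length(bad))
        stop("unknown pattern_genes: ", paste(bad, collapse = ", "))
      fixed <- match(names(pattern_genes), genes)
      key_mat <- do.call(rbind, strsplit(unname(pattern_genes), "_",
                                         fixed = TRUE))
      s1[fixed] <- key_mat[, 1L]; s2[fixed] <- key_mat[, 2L]
    }
    if (length(pattern_mix)) {
      counts <- round(pattern_mix * n_genes)
      pool <- setdiff(seq_len(n_genes), fixed)
      pool <- pool[sample.int(length(pool))]
      offset <- 0L
      for (i in seq_along(counts)) {
        ct <- counts[i]
        if (ct == 0L) next
        idx <- pool[offset + seq_len(ct)]
        offset <- offset + ct
        key <- strsplit(names(counts)[i], "_", fixed = TRUE)[[1L]]
        s1[idx] <- key[1L]; s2[idx] <- key[2L]
      }
    }
    shift_of <- function(state) ifelse(state == "up", effect_size,
                                       ifelse(state == "down", -effect_size, 0))
    vals[, 2L] <- vals[, 2L] + shift_of(s1)
    vals[, 3L] <- vals[, 3L] + shift_of(s2)
    if (noise_sd > 0)
      vals <- vals + matrix(rnorm(length(vals), sd = noise_sd), n_genes)
    pid <- pt$pattern_id[match(paste(s1, s2, sep = "|"),
                               paste(pt$state_first, pt$state_second,
                                     sep = "|"))]
    truth <- data.frame(gene = genes, s1, s2, pattern_id = pid,
                        stringsAsFactors = FALSE)
    names(truth)[2:3] <- paste0("state_", timepoints[2:3])
    list(expr = expr_matrix(vals, design), truth = truth)
  })
}

#' Simulate an interactome with planted hub regulators
#'
#' Emulates a KEGG/NCBI-style interaction edge list: background
#' protein-protein edges drawn Erdos-Renyi over all node pairs at
#' `background_edge_prob`, plus planted regulator hubs each wired
#' (protein-DNA edges) to a stated number of distinct DEG nodes — the
#' heavy-tailed feature that matters for degree-centrality recovery.
#' No self-loops or duplicate edges; bit-reproducible from `seed`.
#'
#' @param n_background Number of background (non-DEG, non-hub) genes.
#' @param degs Character vector of DEG node identifiers.
#' @param hubs Named integer vector regulator -> intended DEG-degree.
#'   Hub identifiers may themselves be DEG members (a DEG regulator).
#' @param background_edge_prob Erdos-Renyi edge probability (default
#'   0.005).
#' @param seed RNG seed.
#' @return List with `network` (an [interaction_network()]; roles set,
#'   hubs flagged as regulators) and `truth` (data frame `hub`,
#'   `planted_degree`).
#' @export
simulate_interactome <- function(n_background = 200L, degs,
                                 hubs = integer(), background_edge_prob = 0.005,
                                 seed = 1L) {
  degs <- unique(as.character(degs))
  if (!length(degs)) stop("empty DEG set")
  if (background_edge_prob < 0 || background_edge_prob > 1)
    stop("background_edge_prob must lie in [0,1]")
  hub_names <- names(hubs)
  if (length(hubs) && is.null(hub_names)) stop("hubs must be named")
  for (h in hub_names) {
    avail <- setdiff(degs, h)
    if (hubs[[h]] > length(avail))
      stop("hub '", h, "' requests degree ", hubs[[h]], " but only ",
           length(avail), " DEG partners exist")
  }
  with_seed(seed, {
    background <- sprintf("bg%04d", seq_len(n_background))
    nodes <- unique(c(degs, hub_names, background))
    edges <- data.frame(from = character(), to = character(),
                        kind = character(), stringsAsFactors = FALSE)
    for (h in hub_names) {
      targets <- sample(setdiff(degs, h), hubs[[h]])
      edges <- rbind(edges,
                     data.frame(from = h, to = targets, kind = "pd",
                                stringsAsFactors = FALSE))
    }
    if (background_edge_prob > 0 && length(nodes) > 1L) {
      pairs <- combn(nodes, 2L)
      pick <- runif(ncol(pairs)) < background_edge_prob
      if (any(pick)) {
        edges <- rbind(edges,
                       data.frame(from = pairs[1L, pick],
                                  to = pairs[2L, pick], kind = "pp",
                                  stringsAsFactors = FALSE))
      }
    }
    roles <- stats::setNames(ifelse(nodes %in% degs, "deg", "neighbor"),
                             nodes)
    net <- interaction_network(edges, nodes = nodes, roles = roles,
                               regulators = hub_names)
    list(network = net,
         truth = data.frame(hub = hub_names,
                            planted_degree = as.integer(unname(hubs)),
                            stringsAsFactors = FALSE))
  })
}
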