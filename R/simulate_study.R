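#' Simulate a complete cross-dataset study bundle
#'
#' Produces coordinated inputs for the whole pipeline: a replicated
#' two-group matrix in a source namespace (`m...` genes; diet-study-like,
#' 2 samples per group), an unreplicated two-timepoint matrix in a target
#' namespace (`h...` genes; depletion-course-like), a complete one-to-one
#' ortholog map between the namespaces, an interactome over the target
#' namespace with planted hub regulators wired to the shared discordant
#' genes, and a small annotation collection containing one term
#' concentrated on the discordant set.
#'
#' Planted structure: `n_shared_discordant` orthologous gene pairs are
#' differentially expressed in both datasets with *opposite* signs (half
#' source-down/target-up, as for a cholesterol-repressed stress regulator,
#' half the mirror image); `n_shared_concordant` pairs move in the same
#' direction in both; additional dataset-private DEGs are planted in each.
#' Hubs are drawn from the target-namespace discordant genes.
#'
#' @param n_genes Genes per namespace (default 1000).
#' @param n_shared_discordant,n_shared_concordant Planted shared DEG pair
#'   counts (defaults 30 and 20).
#' @param n_private Dataset-private planted DEGs in each dataset
#'   (default 25).
#' @param hub_degrees Named integer vector hub -> intended DEG-degree;
#'   names are indices into the discordant set (e.g. `c("1" = 5)`) or full
#'   target gene identifiers. Default plants one degree-5 hub.
#' @param effect_group,noise_group Effect size and noise SD (log2) of the
#'   two-group dataset (defaults 2.0, 0.25).
#' @param effect_time,noise_time Effect size and noise SD (log2) of the
#'   time course (defaults 1.0, 0.2).
#' @param n_background Background interactome genes (default 150).
#' @param background_edge_prob Background edge probability (default 0.01).
#' @param seed RNG seed.
#' @return List: `source` and `target` (each `list(expr, truth)`), `map`,
#'   `interactome` (list `network`, `truth`), `gene_sets`, and `truth`
#'   (list `shared_discordant` data frame (`source_gene`, `target_gene`,
#'   `sign_source`, `sign_target`), `shared_concordant` likewise, `hubs`).
#' @export
simulate_study <- function(n_genes = 1000L, n_shared_discordant = 30L,
                           n_shared_concordant = 20L, n_private = 25L,
                           hub_degrees = c("1" = 5L),
                           effect_group = 2.0, noise_group = 0.25,
                           effect_time = 1.0, noise_time = 0.2,
                           n_background = 150L, background_edge_prob = 0.01,
                           seed = 1L) {
  n_special <- n_shared_discordant + n_shared_concordant + 2L * n_private
  if (n_special > n_genes)
    stop("planted gene counts exceed n_genes")
  src_genes <- sprintf("m%04d", seq_len(n_genes))
  tgt_genes <- sprintf("h%04d", seq_len(n_genes))
  map <- data.frame(source = src_genes, target = tgt_genes,
                    stringsAsFactors = FALSE)

  idx <- with_seed(seed, sample(n_genes, n_special))
  take <- function(k) {
    out <- idx[seq_len(k)]
    idx <<- idx[-seq_len(k)]
    out
  }
  disc_i <- take(n_shared_discordant)
  conc_i <- take(n_shared_concordant)
  priv_src_i <- take(n_private)
  priv_tgt_i <- take(n_private)

  half <- ceiling(n_shared_discordant / 2)
  sign_src_disc <- rep(c("down", "up"),
                       c(half, n_shared_discordant - half))
  sign_tgt_disc <- ifelse(sign_src_disc == "down", "up", "down")
  half_c <- ceiling(n_shared_concordant / 2)
  sign_conc <- rep(c("up", "down"), c(half_c, n_shared_concordant - half_c))

  alt_updown <- function(k) rep_len(c("up", "down"), k)
  deg_src <- stats::setNames(
    c(sign_src_disc, sign_conc, alt_updown(n_private)),
    src_genes[c(disc_i, conc_i, priv_src_i)])
  sim_src <- simulate_two_group(
    n_genes = n_genes, frac_deg = 0, effect_size = effect_group,
    noise_sd = noise_group, seed = seed, gene_ids = src_genes,
    deg_genes = deg_src)

  # shared genes respond with the sustained pattern; private ones late-only
  pat_of <- function(s) ifelse(s == "up", "up_up", "down_down")
  late_of <- function(s) ifelse(s == "up", "none_up", "none_down")
  pattern_tgt <- stats::setNames(
    c(pat_of(sign_tgt_disc), pat_of(sign_conc),
      late_of(alt_updown(n_private))),
    tgt_genes[c(disc_i, conc_i, priv_tgt_i)])
  sim_tgt <- simulate_timecourse(
    n_genes = n_genes, pattern_mix = numeric(), effect_size = effect_time,
    noise_sd = noise_time, seed = seed + 1L, gene_ids = tgt_genes,
    pattern_genes = pattern_tgt)

  disc_tgt <- tgt_genes[disc_i]
  hubs <- hub_degrees
  if (length(hubs)) {
    nm <- names(hubs)
    as_index <- suppressWarnings(as.integer(nm))
    resolved <- ifelse(!is.na(as_index), disc_tgt[as_index], nm)
    if (anyNA(resolved) || !all(resolved %in% tgt_genes))
      stop("hub names must be discordant-set indices or target gene ids")
    names(hubs) <- resolved
  }
  sim_net <- simulate_interactome(
    n_background = n_background, degs = disc_tgt, hubs = hubs,
    background_edge_prob = background_edge_prob, seed = seed + 2L)

  gene_sets <- with_seed(seed + 3L, {
    sets <- list(SET_DISCORDANT = disc_tgt)
    for (i in 1:5)
      sets[[sprintf("SET_RANDOM_%d", i)]] <- sample(tgt_genes, 40L)
    sets
  })

  truth <- list(
    shared_discordant = data.frame(
      source_gene = src_genes[disc_i], target_gene = disc_tgt,
      sign_source = sign_src_disc, sign_target = sign_tgt_disc,
      stringsAsFactors = FALSE),
    shared_concordant = data.frame(
      source_gene = src_genes[conc_i], target_gene = tgt_genes[conc_i],
      sign_source = sign_conc, sign_target = sign_conc,
      stringsAsFactors = FALSE),
    hubs = sim_net$truth)
  list(source = sim_src, target = sim_tgt, map = map,
       interactome = sim_net, gene_sets = gene_sets, truth = truth)
}
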