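# Shared simulation fixtures, built once per test run.

# 20 well-separated taxa, 0.5% substitution error, no chimeras: the standard
# recovery scenario for seed clustering.
sim20 <- local({
  ref <- build_reference(20, seed = 7)
  cfg <- sim_config(
    n_samples_per_cell = 1,
    levels = c("reference", "high"), generations = c("G1", "G2"),
    chambers = "DC", reads_per_sample = 500,
    substitution_error_rate = 0.005, chimera_rate = 0, seed = 11
  )
  truth <- simulate_design(ref, cfg)
  reads <- generate_reads(ref, truth, cfg)
  prepared <- prepare_reads(reads, prep_config())
  retained <- prepared[prepared$status == "retained", ]
  pool <- dereplicate(retained)
  features <- cluster_to_features(pool, cluster_config())
  list(ref = ref, cfg = cfg, truth = truth, reads = reads,
       prepared = prepared, retained = retained, pool = pool,
       features = features)
})

# Small noiseless run: 8 taxa, zero error and chimera rates, used for exact
# round-trip and planted-truth checks.
sim0 <- local({
  ref <- build_reference(8, seed = 2)
  cfg <- sim_config(
    n_samples_per_cell = 1,
    levels = c("reference", "high"), generations = c("G1", "G2"),
    chambers = "DC", reads_per_sample = 400,
    substitution_error_rate = 0, chimera_rate = 0, seed = 5
  )
  truth <- simulate_design(ref, cfg)
  reads <- generate_reads(ref, truth, cfg)
  prepared <- prepare_reads(reads, prep_config())
  retained <- prepared[prepared$status == "retained", ]
  pool <- dereplicate(retained)
  features <- cluster_to_features(pool, cluster_config())
  list(ref = ref, cfg = cfg, truth = truth, reads = reads,
       prepared = prepared, retained = retained, pool = pool,
       features = features)
})

# Map retained reads to the feature that absorbed them and to the reference
# sequence best matching that feature's representative.
read_feature_map <- function(sim) {
  amap <- attr(sim$features, "assignment")
  feat <- amap$feature_id[match(toupper(sim$retained$sequence),
                                amap$sequence)]
  best_ref <- vapply(sim$features$sequence, function(s) {
    h <- search_reference(s, sim$ref)
    if (nrow(h) == 0) NA_character_ else h$ref_id[1]
  }, character(1))
  names(best_ref) <- sim$features$feature_id
  tibble::tibble(
    read_id = sim$retained$read_id,
    feature_id = feat,
    mapped_ref = unname(best_ref[feat]),
    true_ref = sim$reads$true_ref_id[match(sim$retained$read_id,
                                           sim$reads$read_id)]
  )
}

# Simulate an NB count table: `effect` multiplies the mean of the first
# `n_hit` features in group B.
nb_sim_table <- function(n_features, n_per_group, dispersion, effect = 1,
                         n_hit = 0, seed = 1) {
  set.seed(seed)
  mu <- stats::rexp(n_features, 1 / 50) + 5
  fold <- rep(1, n_features)
  if (n_hit > 0) fold[seq_len(n_hit)] <- effect
  y <- t(vapply(seq_len(n_features), function(i) {
    c(stats::rnbinom(n_per_group, mu = mu[i], size = 1 / dispersion),
      stats::rnbinom(n_per_group, mu = fold[i] * mu[i],
                     size = 1 / dispersion))
  }, numeric(2 * n_per_group)))
  tbl <- tibble::tibble(feature_id = sprintf("f%04d", seq_len(n_features)))
  dplyr::bind_cols(tbl, tibble::as_tibble(as.data.frame(y)))
}
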