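#' Feature filtering configuration
#'
#' Thresholds for low-count/low-variance feature filtering and for core
#' microbiome membership.
#'
#' @param prevalence_fraction Fraction of samples in which a feature must
#'   meet the count (or abundance) threshold (default 0.20).
#' @param min_count Low-count filter: minimum count a feature must reach in
#'   at least `prevalence_fraction` of samples (default 4).
#' @param variance_quantile Fraction of remaining features with the smallest
#'   inter-quartile range of relative abundance removed by the low-variance
#'   filter (default 0.10).
#' @param core_abundance Relative-abundance threshold for core membership;
#'   default 0.0001 (0.01%), with 0.002 (0.2%) available as a stricter
#'   convention.
#' @return A list of class `subotu_filter_config`.
#' @export
filter_config <- function(prevalence_fraction = 0.20, min_count = 4,
                          variance_quantile = 0.10,
                          core_abundance = 0.0001) {
  stopifnot(prevalence_fraction >= 0, prevalence_fraction <= 1,
            variance_quantile >= 0, variance_quantile <= 1,
            core_abundance >= 0, core_abundance <= 1, min_count >= 0)
  structure(
    list(prevalence_fraction = prevalence_fraction,
         min_count = min_count,
         variance_quantile = variance_quantile,
         core_abundance = core_abundance),
    class = "subotu_filter_config"
  )
}

#' Total sum scaling
#'
#' Divides each sample column by its total so columns sum to 1; idempotent.
#'
#' @param table A feature/taxon table tibble with numeric sample columns.
#' @return The table with counts replaced by relative abundances (the
#'   `total_count` column, if present, is dropped).
#' @export
tss_normalize <- function(table) {
  sp <- ft_split(table)
  tot <- colSums(sp$counts)
  if (any(tot == 0)) {
    stop("all-zero sample column(s): ",
         paste(sp$samples[tot == 0], collapse = ", "), call. = FALSE)
  }
  ft_rebuild(sp$meta, sweep(sp$counts, 2, tot, "/"))
}

#' Filter low-count and low-variance features
#'
#' First removes features lacking a count of at least `min_count` in at least
#' `prevalence_fraction` of samples; then removes the `variance_quantile`
#' fraction of the remaining features with the smallest inter-quartile range
#' of relative abundance.
#'
#' @param table Feature table tibble (raw counts).
#' @param config A [filter_config()].
#' @return A list: `table` (filtered) and `report` (tibble with features in,
#'   removed by each rule, and features out).
#' @export
filter_features <- function(table, config = filter_config()) {
  sp <- ft_split(table)
  n_in <- nrow(sp$counts)
  if (n_in == 0) stop("empty feature table", call. = FALSE)
  n_samples <- ncol(sp$counts)
  needed <- config$prevalence_fraction * n_samples
  hits <- rowSums(sp$counts >= config$min_count)
  keep1 <- hits >= needed
  n_low_count <- sum(!keep1)
  if (!any(keep1)) stop("low-count filter removed all features", call. = FALSE)

  rel <- sweep(sp$counts[keep1, , drop = FALSE], 2, colSums(sp$counts), "/")
  iqr <- apply(rel, 1, stats::IQR)
  n_remove <- floor(config$variance_quantile * nrow(rel))
  keep2 <- rep(TRUE, nrow(rel))
  if (n_remove > 0) {
    keep2[order(iqr)[seq_len(n_remove)]] <- FALSE
  }
  if (!any(keep2)) stop("low-variance filter removed all features",
                        call. = FALSE)
  out <- table[keep1, , drop = FALSE][keep2, , drop = FALSE]
  list(
    table = out,
    report = tibble::tibble(
      features_in = n_in,
      low_count_removed = n_low_count,
      low_variance_removed = n_remove,
      features_out = nrow(out)
    )
  )
}

#' Core microbiome membership
#'
#' Taxa whose relative abundance reaches `core_abundance` in at least
#' `prevalence_fraction` of samples.
#'
#' @param rel_table TSS-normalized table (see [tss_normalize()]).
#' @param config A [filter_config()].
#' @return The subset of `rel_table` rows forming the core, with `prevalence`
#'   (fraction of samples at or above the abundance threshold) added.
#' @export
core_microbiome <- function(rel_table, config = filter_config()) {
  sp <- ft_split(rel_table)
  if (any(abs(colSums(sp$counts) - 1) > 1e-6)) {
    stop("table must be TSS-normalized (columns summing to 1)",
         call. = FALSE)
  }
  n_samples <- ncol(sp$counts)
  hits <- rowSums(sp$counts >= config$core_abundance)
  keep <- hits >= config$prevalence_fraction * n_samples
  out <- rel_table[keep, , drop = FALSE]
  out$prevalence <- unname(hits[keep]) / n_samples
  out
}

#' Chao1 richness estimate
#'
#' Bias-corrected Chao1: `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))`, with `F1`
#' and `F2` the singleton and doubleton counts. The classic form
#' `S_obs + F1^2 / (2 * F2)` is available and falls back to the
#' bias-corrected form when `F2 = 0`.
#'
#' @param counts Non-negative integer vector of feature counts for one
#'   sample.
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return A single numeric richness estimate (0 for an empty sample).
#' @export
#' @examples
#' chao1(c(5, 5, 5))   # 3: no singletons
#' chao1(c(1, 1, 2))   # 3.5
chao1 <- function(counts, bias_corrected = TRUE) {
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  s_obs <- sum(counts > 0)
  if (s_obs == 0) return(0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (!bias_corrected && f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
}

#' Per-sample alpha diversity of a feature table
#'
#' @param table Feature table tibble (raw counts).
#' @param bias_corrected Passed to [chao1()].
#' @return A tibble: `sample_id`, `s_obs`, `chao1`.
#' @export
alpha_diversity <- function(table, bias_corrected = TRUE) {
  sp <- ft_split(table)
  tibble::tibble(
    sample_id = sp$samples,
    s_obs = apply(sp$counts, 2, function(x) sum(x > 0)),
    chao1 = apply(sp$counts, 2, chao1, bias_corrected = bias_corrected)
  )
}

#' Display transforms for heatmaps and barplots
#'
#' `mode = "heatmap"`: log-transform relative abundances (pseudocount of half
#' the smallest nonzero value) then z-score each feature row to mean 0, sd 1;
#' zero-variance rows are set to 0 and flagged in the `flat` column.
#' `mode = "barplot"`: keep taxa with mean relative abundance above
#' `barplot_threshold` and pool the rest into an `"Other"` row, so columns
#' still sum to 1.
#'
#' @param rel_table TSS-normalized table.
#' @param mode `"heatmap"` or `"barplot"`.
#' @param barplot_threshold Mean relative-abundance cutoff for the barplot
#'   mode (default 0.01, i.e. 1%).
#' @return A transformed tibble.
#' @export
display_transforms <- function(rel_table, mode = c("heatmap", "barplot"),
                               barplot_threshold = 0.01) {
  mode <- match.arg(mode)
  sp <- ft_split(rel_table)
  if (mode == "heatmap") {
    pseudo <- min(sp$counts[sp$counts > 0]) / 2
    lg <- log(sp$counts + pseudo)
    mu <- rowMeans(lg)
    sd <- apply(lg, 1, stats::sd)
    flat <- sd == 0
    z <- (lg - mu) / ifelse(sd == 0, 1, sd)
    z[flat, ] <- 0
    out <- ft_rebuild(sp$meta, z)
    out$flat <- flat
    out
  } else {
    keep <- rowMeans(sp$counts) > barplot_threshold
    kept <- sp$counts[keep, , drop = FALSE]
    other <- colSums(sp$counts[!keep, , drop = FALSE])
    labels <- if ("taxon" %in% names(sp$meta)) {
      sp$meta$taxon[keep]
    } else if ("feature_id" %in% names(sp$meta)) {
      sp$meta$feature_id[keep]
    } else {
      rownames(kept)
    }
    mat <- rbind(kept, Other = other)
    tibble::tibble(taxon = c(labels, "Other")) %>%
      dplyr::bind_cols(tibble::as_tibble(as.data.frame(mat)))
  }
}
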