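#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = 1 - 2 * sum(min(x_i, x_j)) / sum(x_i + x_j)` over the sample
#' columns of an abundance table: 0 for identical samples, 1 for samples with
#' no shared taxa.
#'
#' @param table Feature/taxon table tibble with non-negative numeric sample
#'   columns.
#' @return A `dist` object over the samples.
#' @export
bray_curtis <- function(table) {
  sp <- ft_split(table)
  if (any(sp$counts < 0)) stop("abundances must be non-negative",
                               call. = FALSE)
  tot <- colSums(sp$counts)
  if (any(tot == 0)) {
    stop("all-zero sample column(s): ",
         paste(sp$samples[tot == 0], collapse = ", "), call. = FALSE)
  }
  vegan::vegdist(t(sp$counts), method = "bray")
}

#' Principal coordinates analysis
#'
#' Gower double-centering of the squared distances followed by
#' eigendecomposition. Axes with negative eigenvalues (from non-Euclidean
#' dissimilarities such as Bray-Curtis) are dropped with a warning and their
#' count reported; for Euclidean inputs the coordinates reproduce the input
#' distances.
#'
#' @param d A `dist` object (at least 3 samples).
#' @return An object of class `subotu_pcoa`: `points` tibble (`sample_id`,
#'   `Axis1`, ...), `eigenvalues` (positive, descending),
#'   `proportion_explained`, and `n_negative_eigenvalues`.
#' @export
pcoa <- function(d) {
  n <- attr(d, "Size")
  if (is.null(n) || n < 3) stop("need a dist object with >= 3 samples",
                                call. = FALSE)
  # cmdscale warns when fewer than k eigenvalues are positive; we count and
  # report the negative ones ourselves
  cmd <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- cmd$eig
  n_neg <- sum(eig < -1e-10)
  if (n_neg > 0) {
    warning(n_neg, " negative eigenvalue(s) dropped", call. = FALSE)
  }
  pos <- which(eig > 1e-10)
  pts <- cmd$points[, pos, drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_along(pos))
  ids <- attr(d, "Labels") %||% as.character(seq_len(n))
  structure(
    list(
      points = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                tibble::as_tibble(as.data.frame(pts))),
      eigenvalues = eig[pos],
      proportion_explained = eig[pos] / sum(eig[pos]),
      n_negative_eigenvalues = n_neg
    ),
    class = "subotu_pcoa"
  )
}

#' Hierarchical clustering with newick export
#'
#' Agglomerative clustering of a distance matrix with group-average (UPGMA)
#' or Ward linkage (squared-distance ward.D2 convention); UPGMA merge
#' heights are the standard average dissimilarities between merged clusters,
#' giving an ultrametric tree. The dendrogram is also serialized as a newick
#' string whose leaves are the sample ids.
#'
#' @param d A `dist` object (at least 2 samples).
#' @param linkage `"group_average"` (default) or `"ward"`.
#' @return An object of class `subotu_dendro`: the `hclust` object, the
#'   `newick` string, and the linkage used.
#' @export
hcluster <- function(d, linkage = c("group_average", "ward")) {
  linkage <- match.arg(linkage)
  n <- attr(d, "Size")
  if (is.null(n) || n < 2) stop("need a dist object with >= 2 samples",
                                call. = FALSE)
  hc <- stats::hclust(d, method = switch(linkage,
                                         group_average = "average",
                                         ward = "ward.D2"))
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, newick = newick, linkage = linkage),
            class = "subotu_dendro")
}

#' Permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components and tests the pseudo-F statistic by random
#' permutation of the group labels:
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`.
#'
#' @param d A `dist` object.
#' @param groups Group labels, one per sample, at least 2 groups, none empty.
#' @param n_perm Number of permutations (at least 99; default 999).
#' @param seed Integer seed making the permutation stream reproducible.
#' @return An object of class `subotu_permanova` with the pseudo-F,
#'   p-value, degrees of freedom, sums of squares and R2.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  n <- attr(d, "Size")
  groups <- factor(groups)
  if (length(groups) != n) stop("one label per sample required",
                                call. = FALSE)
  if (nlevels(groups) < 2 || any(table(groups) == 0)) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  d2 <- as.matrix(d)^2
  sst <- sum(d2) / (2 * n)
  k <- nlevels(groups)

  ssw_of <- function(lab) {
    e <- stats::model.matrix(~ lab - 1)
    ng <- colSums(e)
    sum(colSums((d2 %*% e) * e) / (2 * ng))
  }
  ssw <- ssw_of(groups)
  ssa <- sst - ssw
  f_obs <- (ssa / (k - 1)) / (ssw / (n - k))

  f_perm <- with_rng(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- groups[sample.int(n)]
      sswp <- ssw_of(lab)
      ((sst - sswp) / (k - 1)) / (sswp / (n - k))
    }, numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  structure(
    list(f = f_obs, p_value = p, df_among = k - 1L, df_within = n - k,
         ss_among = ssa, ss_within = ssw, ss_total = sst,
         r_squared = ssa / sst, n_perm = n_perm, seed = seed),
    class = "subotu_permanova"
  )
}

#' Canonical correspondence analysis of taxa against environment
#'
#' Constrained ordination relating a taxon abundance table to environmental
#' variables: the taxon matrix is chi-square standardized, projected by
#' weighted least squares onto the (log(X+1)-transformed, standardized)
#' environmental variables, and the fitted matrix eigen-analysed. Site,
#' taxon and biplot scores follow the scaling-2 convention. Below-detection
#' (`NA`) environmental values are imputed at half the minimum observed value
#' of the variable and flagged.
#'
#' @param taxa_table Taxon table tibble (taxa in rows, sample columns).
#' @param env Data frame of environmental variables; either with a
#'   `sample_id`/`site` column matching the sample columns of `taxa_table`,
#'   or ordered to match them.
#' @param transform Log(X+1)-transform and standardize the environment
#'   (default `TRUE`).
#' @return An object of class `subotu_cca`: constrained `eigenvalues`,
#'   `total_inertia`, `site_scores`, `taxon_scores`, `biplot_scores`,
#'   `imputed` flags.
#' @export
cca_fit <- function(taxa_table, env, transform = TRUE) {
  sp <- ft_split(taxa_table)
  comm <- t(sp$counts)
  env <- tibble::as_tibble(env)
  id_col <- intersect(c("sample_id", "site"), names(env))[1]
  if (!is.na(id_col)) {
    if (!all(rownames(comm) %in% env[[id_col]])) {
      stop("env is missing samples: ",
           paste(setdiff(rownames(comm), env[[id_col]]), collapse = ", "),
           call. = FALSE)
    }
    env <- env[match(rownames(comm), env[[id_col]]), , drop = FALSE]
    env[[id_col]] <- NULL
  }
  if (!all(vapply(env, is.numeric, logical(1)))) {
    stop("environmental variables must be numeric", call. = FALSE)
  }
  if (nrow(comm) < ncol(env) + 2) {
    stop("need at least n_env + 2 samples", call. = FALSE)
  }
  envm <- as.matrix(env)
  imputed <- is.na(envm)
  if (any(imputed)) {
    for (j in seq_len(ncol(envm))) {
      nas <- is.na(envm[, j])
      if (any(nas)) envm[nas, j] <- min(envm[!nas, j]) / 2
    }
  }
  const <- apply(envm, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    stop("constant environment column(s): ",
         paste(colnames(envm)[const], collapse = ", "), call. = FALSE)
  }
  if (transform) {
    envm <- scale(log(envm + 1))
  }
  kap <- kappa(scale(envm), exact = TRUE)
  if (kap > 1e8) {
    stop("collinear environment columns (condition number ",
         format(kap, digits = 3), ")", call. = FALSE)
  }
  fit <- vegan::cca(X = comm, Y = as.data.frame(envm))
  sc <- vegan::scores(fit, display = c("sites", "species", "bp"),
                      scaling = 2, choices = seq_along(fit$CCA$eig))
  structure(
    list(
      eigenvalues = unname(fit$CCA$eig),
      total_inertia = fit$tot.chi,
      site_scores = dplyr::bind_cols(
        tibble::tibble(sample_id = rownames(sc$sites)),
        tibble::as_tibble(as.data.frame(sc$sites))
      ),
      taxon_scores = dplyr::bind_cols(
        tibble::tibble(taxon = rownames(sc$species)),
        tibble::as_tibble(as.data.frame(sc$species))
      ),
      biplot_scores = dplyr::bind_cols(
        tibble::tibble(variable = rownames(sc$biplot)),
        tibble::as_tibble(as.data.frame(sc$biplot))
      ),
      imputed = imputed,
      vegan_fit = fit
    ),
    class = "subotu_cca"
  )
}
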