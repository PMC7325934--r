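#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample scaling factors relative to a reference sample (the
#' column whose 75th-percentile count fraction is closest to the mean). For
#' each sample, log2 count-fraction ratios (M) against the reference are
#' trimmed (30% on M, 5% on A) and averaged with precision weights; factors
#' are rescaled so their geometric mean is 1. Multiplying library sizes by
#' these factors gives effective library sizes for the negative-binomial
#' model.
#'
#' @param table Feature table tibble with at least 2 numeric sample columns.
#' @param trim_m,trim_a Two-sided trim fractions for M and A values.
#' @return A named numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(table, trim_m = 0.30, trim_a = 0.05) {
  sp <- ft_split(table)
  y <- sp$counts
  if (ncol(y) < 2) stop("need at least 2 samples", call. = FALSE)
  lib <- colSums(y)
  if (any(lib == 0)) {
    stop("all-zero sample column(s): ",
         paste(sp$samples[lib == 0], collapse = ", "), call. = FALSE)
  }
  uq <- apply(sweep(y, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(y)), function(j) {
    if (j == ref) return(1)
    yj <- y[, j]; yr <- y[, ref]
    keep <- yj > 0 & yr > 0
    if (!any(keep)) return(1)
    pj <- yj[keep] / lib[j]; pr <- yr[keep] / lib[ref]
    m <- log2(pj / pr)
    a <- 0.5 * log2(pj * pr)
    w <- 1 / ((lib[j] - yj[keep]) / (lib[j] * yj[keep]) +
                (lib[ref] - yr[keep]) / (lib[ref] * yr[keep]))
    # double trimming as in standard TMM
    lo_m <- stats::quantile(m, trim_m); hi_m <- stats::quantile(m, 1 - trim_m)
    lo_a <- stats::quantile(a, trim_a); hi_a <- stats::quantile(a, 1 - trim_a)
    keep2 <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
    if (!any(keep2)) return(1)
    2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, sp$samples)
}

# Method-of-moments common dispersion on normalized counts: per feature,
# pool within-group mean/variance, phi = (var - mu) / mu^2; the common value
# is the median over informative features.
mom_common_dispersion <- function(q, groups) {
  gl <- split(seq_len(ncol(q)), groups)
  phis <- apply(q, 1, function(x) {
    mus <- vapply(gl, function(j) mean(x[j]), numeric(1))
    # pooled within-group variance
    ss <- sum(vapply(gl, function(j) sum((x[j] - mean(x[j]))^2), numeric(1)))
    df <- ncol(q) - length(gl)
    if (df <= 0) return(NA_real_)
    v <- ss / df
    mu <- mean(mus)
    if (mu <= 0) return(NA_real_)
    (v - mu) / mu^2
  })
  phis <- phis[!is.na(phis)]
  if (length(phis) == 0) return(0)
  max(stats::median(pmax(phis, 0)), 1e-8)
}

# ML estimate of a common log-mean for NB counts y with offsets s (mu = s *
# exp(beta)) at fixed dispersion phi, by Newton iterations on the score.
nb_fit_mean <- function(y, s, phi, iter = 25) {
  mu0 <- sum(y) / sum(s)
  if (mu0 <= 0) return(0)
  beta <- log(mu0)
  for (it in seq_len(iter)) {
    mu <- s * exp(beta)
    w <- mu / (1 + phi * mu)
    score <- sum((y - mu) / (1 + phi * mu))
    info <- sum(w)
    if (info <= 0) break
    step <- score / info
    beta <- beta + sign(step) * min(abs(step), 2)
    if (abs(step) < 1e-10) break
  }
  exp(beta)
}

nb_loglik <- function(y, mu, phi) {
  if (phi < 1e-8) {
    sum(stats::dpois(y, lambda = pmax(mu, 1e-12), log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / phi, mu = pmax(mu, 1e-12), log = TRUE))
  }
}

#' Negative-binomial differential abundance test
#'
#' Multi-group differential abundance via a negative-binomial likelihood
#' ratio test with a common dispersion. Counts are modelled as NB with
#' effective-library-size offsets (TMM-normalized); the common dispersion is
#' estimated by method of moments across features; each feature is tested
#' with a likelihood-ratio test of the group-means model against the
#' intercept-only model, with p-values from a chi-square on
#' `(groups - 1)` degrees of freedom and Benjamini-Hochberg adjustment.
#' Log2 fold changes are reported per non-reference group from group means
#' of normalized counts with a pseudocount of 0.5, relative to the reference
#' (first) group level.
#'
#' @param table Feature table tibble.
#' @param groups Factor (or character) of group labels, one per sample
#'   column, with at least 2 levels; the first level is the reference.
#' @param alpha FDR significance threshold (default 0.05).
#' @param dispersion Optional fixed common dispersion; estimated when `NULL`.
#' @return A tibble of class `subotu_differential`: `feature_id`, one
#'   `log2fc_<level>` column per non-reference level, `statistic`, `df`,
#'   `p_value`, `fdr`, `significant`. The common dispersion is attached as
#'   attribute `"dispersion"`.
#' @export
nb_fit_and_test <- function(table, groups, alpha = 0.05, dispersion = NULL) {
  sp <- ft_split(table)
  y <- sp$counts
  groups <- factor(groups)
  if (length(groups) != ncol(y)) {
    stop("one group label per sample column is required", call. = FALSE)
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  f <- tmm_factors(table)
  eff <- colSums(y) * f
  s <- eff / exp(mean(log(eff)))   # offsets scaled to geometric mean 1
  q <- sweep(y, 2, s, "/")         # normalized counts on a common scale
  phi <- dispersion %||% mom_common_dispersion(q, groups)

  lev <- levels(groups)
  gl <- split(seq_len(ncol(y)), groups)
  res <- purrr::map_dfr(seq_len(nrow(y)), function(i) {
    yi <- y[i, ]
    if (all(yi == 0)) {
      lfc <- stats::setNames(rep(0, length(lev) - 1), lev[-1])
      return(tibble::tibble(!!!as.list(lfc), statistic = 0,
                            p_value = 1))
    }
    mu0 <- nb_fit_mean(yi, s, phi)
    ll0 <- nb_loglik(yi, s * mu0, phi)
    ll1 <- sum(vapply(gl, function(j) {
      m <- nb_fit_mean(yi[j], s[j], phi)
      nb_loglik(yi[j], s[j] * m, phi)
    }, numeric(1)))
    stat <- max(0, 2 * (ll1 - ll0))
    gm <- vapply(gl, function(j) mean(q[i, j]), numeric(1))
    lfc <- log2((gm[-1] + 0.5) / (gm[1] + 0.5))
    tibble::tibble(!!!as.list(stats::setNames(lfc, lev[-1])),
                   statistic = stat,
                   p_value = stats::pchisq(stat, df = length(lev) - 1,
                                           lower.tail = FALSE))
  })
  names(res)[seq_len(length(lev) - 1)] <- paste0("log2fc_", lev[-1])
  out <- dplyr::bind_cols(
    tibble::tibble(feature_id = rownames(y) %||%
                     as.character(seq_len(nrow(y)))),
    res
  )
  out$df <- length(lev) - 1L
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < alpha
  attr(out, "dispersion") <- phi
  class(out) <- c("subotu_differential", class(out))
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; input order is
#' preserved.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values (same length and order).
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
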