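#' Convert mercury concentration units
#'
#' ng/g dry weight is equivalent to ppb, so ppm = ng/g divided by 1000.
#'
#' @param value Non-negative numeric vector.
#' @param from,to `"ng/g"` or `"ppm"`.
#' @return Converted values.
#' @export
#' @examples
#' convert_units(1688.31, "ng/g", "ppm")  # 1.68831
convert_units <- function(value, from = "ng/g", to = "ppm") {
  units <- c("ng/g", "ppm")
  if (!from %in% units || !to %in% units) {
    stop("units must be 'ng/g' or 'ppm'", call. = FALSE)
  }
  if (any(value < 0)) stop("concentrations must be non-negative",
                           call. = FALSE)
  if (from == to) return(value)
  if (from == "ng/g") value / 1000 else value * 1000
}

#' Pearson correlation between two geochemistry variables
#'
#' Sample Pearson correlation on raw (untransformed) values; rows where
#' either variable is below detection (`NA`) are excluded pairwise.
#'
#' @param table Geochemistry tibble (see [geochem_table()]).
#' @param var_a,var_b Column names.
#' @return A single correlation (NA with a warning if fewer than 3 complete
#'   pairs remain or either variable is constant).
#' @export
#' @examples
#' pearson_pairs(geochem_table(), "thg_ng_g", "mehg_ng_g")
pearson_pairs <- function(table, var_a, var_b) {
  stopifnot(all(c(var_a, var_b) %in% names(table)))
  x <- table[[var_a]]; y <- table[[var_b]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    warning("fewer than 3 complete pairs", call. = FALSE)
    return(NA_real_)
  }
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])
}

#' Methylmercury fraction of total mercury
#'
#' Per-site percentage `100 * MeHg / THg` and the unweighted mean over the
#' chosen sites.
#'
#' @param table Geochemistry tibble.
#' @param sites Optional character vector of site ids to restrict to.
#' @return A list: `per_site` tibble (`site`, `mehg_pct`) and `mean_pct`.
#' @export
#' @examples
#' mehg_fraction(geochem_table(), sites = c("H-02", "S3", "R1"))$mean_pct
mehg_fraction <- function(table, sites = NULL) {
  df <- if (is.null(sites)) table else table[table$site %in% sites, ]
  if (any(is.na(df$thg_ng_g)) || any(df$thg_ng_g <= 0)) {
    stop("THg must be present and positive for all selected sites",
         call. = FALSE)
  }
  per_site <- tibble::tibble(
    site = df$site,
    mehg_pct = 100 * df$mehg_ng_g / df$thg_ng_g
  )
  list(per_site = per_site, mean_pct = mean(per_site$mehg_pct))
}

#' Bin sites by contamination level and cluster the geochemistry
#'
#' Assigns each site a contamination level from its total mercury (defaults:
#' high at or above 1000 ng/g, medium at or above 100 ng/g, low otherwise;
#' sites named in `reference_sites` are flagged `"reference"` from metadata
#' regardless of THg). Cluster analysis then log(X+1)-transforms the
#' measured variables (below-detection values imputed at half the variable
#' minimum), builds a Bray-Curtis dissimilarity matrix and a group-average
#' dendrogram, in two modes: sites as observations (`site_dendro`) and
#' variables as observations (`variable_dendro`).
#'
#' @param table Geochemistry tibble (see [geochem_table()]).
#' @param thresholds Named vector with elements `high` and `medium` (ng/g
#'   THg cutoffs).
#' @param reference_sites Site ids to flag as `"reference"`; `NULL` (default)
#'   bins every site by THg alone.
#' @return A list of class `subotu_geochem_bins`: `bins` tibble (`site`,
#'   `level`, `thg_ng_g`), `site_dendro` and `variable_dendro`
#'   ([hcluster()] objects).
#' @export
bin_and_cluster <- function(table, thresholds = c(high = 1000, medium = 100),
                            reference_sites = NULL) {
  stopifnot(all(c("high", "medium") %in% names(thresholds)))
  if (any(is.na(table$thg_ng_g))) stop("missing THg", call. = FALSE)
  level <- ifelse(table$thg_ng_g >= thresholds["high"], "high",
                  ifelse(table$thg_ng_g >= thresholds["medium"], "medium",
                         "low"))
  if (!is.null(reference_sites)) {
    level[table$site %in% reference_sites] <- "reference"
  }
  bins <- tibble::tibble(site = table$site, level = level,
                         thg_ng_g = table$thg_ng_g)

  num <- as.matrix(table[, vapply(table, is.numeric, logical(1))])
  rownames(num) <- table$site
  for (j in seq_len(ncol(num))) {
    nas <- is.na(num[, j])
    if (any(nas)) num[nas, j] <- min(num[!nas, j]) / 2
  }
  lg <- log(num + 1)
  site_d <- vegan::vegdist(lg, method = "bray")
  var_d <- vegan::vegdist(t(lg), method = "bray")
  structure(
    list(bins = bins,
         site_dendro = hcluster(site_d, "group_average"),
         variable_dendro = hcluster(var_d, "group_average"),
         site_dist = site_d),
    class = "subotu_geochem_bins"
  )
}

#' Mutual nearest neighbours in a distance matrix
#'
#' Helper to check which pair of observations are each other's nearest
#' neighbour (used e.g. to confirm that the two most contaminated sites
#' cluster together).
#'
#' @param d A `dist` object.
#' @return A tibble of mutual nearest-neighbour pairs (`a`, `b`,
#'   `distance`).
#' @export
mutual_nearest <- function(d) {
  m <- as.matrix(d)
  diag(m) <- Inf
  nn <- apply(m, 1, which.min)
  ids <- rownames(m)
  pairs <- purrr::map_dfr(seq_along(nn), function(i) {
    j <- nn[i]
    if (nn[j] == i && i < j) {
      tibble::tibble(a = ids[i], b = ids[j], distance = m[i, j])
    } else {
      NULL
    }
  })
  pairs
}
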