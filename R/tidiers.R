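#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PCoA result
#'
#' @param x A `subotu_pcoa` object.
#' @param ... Unused.
#' @return A tibble of axes: `axis`, `eigenvalue`, `proportion_explained`.
#' @export
tidy.subotu_pcoa <- function(x, ...) {
  tibble::tibble(
    axis = paste0("Axis", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    proportion_explained = x$proportion_explained
  )
}

#' @rdname tidy.subotu_pcoa
#' @export
glance.subotu_pcoa <- function(x, ...) {
  tibble::tibble(
    n_axes = length(x$eigenvalues),
    n_negative_eigenvalues = x$n_negative_eigenvalues,
    prop_first_two = sum(x$proportion_explained[seq_len(
      min(2, length(x$proportion_explained)))])
  )
}

#' Tidy a PERMANOVA result
#'
#' @param x A `subotu_permanova` object.
#' @param ... Unused.
#' @return A tibble with one row per term (among, within, total).
#' @export
tidy.subotu_permanova <- function(x, ...) {
  tibble::tibble(
    term = c("among_groups", "within_groups", "total"),
    df = c(x$df_among, x$df_within, x$df_among + x$df_within),
    sum_of_squares = c(x$ss_among, x$ss_within, x$ss_total),
    statistic = c(x$f, NA, NA),
    p_value = c(x$p_value, NA, NA)
  )
}

#' @rdname tidy.subotu_permanova
#' @export
glance.subotu_permanova <- function(x, ...) {
  tibble::tibble(statistic = x$f, p_value = x$p_value,
                 r_squared = x$r_squared, n_perm = x$n_perm)
}

#' Tidy a CCA result
#'
#' @param x A `subotu_cca` object.
#' @param ... Unused.
#' @return A tibble of constrained axes with eigenvalues and the fraction of
#'   total inertia they explain.
#' @export
tidy.subotu_cca <- function(x, ...) {
  tibble::tibble(
    axis = paste0("CCA", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    proportion_of_inertia = x$eigenvalues / x$total_inertia
  )
}

#' @rdname tidy.subotu_cca
#' @export
glance.subotu_cca <- function(x, ...) {
  tibble::tibble(
    total_inertia = x$total_inertia,
    constrained_inertia = sum(x$eigenvalues),
    constrained_fraction = sum(x$eigenvalues) / x$total_inertia,
    n_axes = length(x$eigenvalues)
  )
}

#' @export
print.subotu_permanova <- function(x, ...) {
  cat("PERMANOVA: pseudo-F =", format(x$f, digits = 4),
      "on", x$df_among, "and", x$df_within, "df; p =",
      format(x$p_value, digits = 4),
      sprintf("(%d permutations)\n", x$n_perm))
  invisible(x)
}

#' @export
print.subotu_pcoa <- function(x, ...) {
  cat("PCoA:", length(x$eigenvalues), "positive axes;",
      x$n_negative_eigenvalues, "negative eigenvalue(s) dropped\n")
  cat("First axes explain:",
      paste0(format(100 * utils::head(x$proportion_explained, 3),
                    digits = 3), "%", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.subotu_cca <- function(x, ...) {
  cat("CCA:", length(x$eigenvalues), "constrained axes; total inertia",
      format(x$total_inertia, digits = 4), "\n")
  invisible(x)
}
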