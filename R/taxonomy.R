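#' Parse and format QIIME-style lineage strings
#'
#' A lineage is a semicolon-separated seven-rank string
#' `k__...;p__...;c__...;o__...;f__...;g__...;s__...`; any rank name may be
#' empty. After normalization no named rank appears below an empty one.
#'
#' @param lineage Character vector of lineage strings.
#' @return `parse_lineage()`: a tibble with seven character columns
#'   (`kingdom` ... `species`), empty strings for unnamed ranks.
#' @export
parse_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";")
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    out <- character(7)
    for (i in seq_len(min(7, length(p)))) {
      out[i] <- sub("^[kpcofgs]__", "", p[i])
    }
    # enforce: everything below the first empty rank is empty
    first_empty <- which(out == "")[1]
    if (!is.na(first_empty) && first_empty < 7) {
      out[first_empty:7] <- ""
    }
    out
  }, character(7)))
  colnames(mat) <- rank_names()
  tibble::as_tibble(mat)
}

#' @rdname parse_lineage
#' @param ranks A character vector (or 7-column data frame row set) of rank
#'   names to re-serialize.
#' @return `format_lineage()`: lineage strings with QIIME prefixes.
#' @export
format_lineage <- function(ranks) {
  if (is.data.frame(ranks)) ranks <- as.matrix(ranks)
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1)
  apply(ranks, 1, function(r) {
    paste0(rank_prefixes(), r, collapse = ";")
  })
}

#' Search a reference database by alignment identity
#'
#' Computes the global alignment identity of a query against every reference
#' sequence (optionally skipping hopeless references with the conservative
#' k-mer prefilter) and returns the hits at or above the identity floor,
#' sorted by decreasing identity and then by `ref_id`.
#'
#' @param query A nonempty DNA string.
#' @param reference Reference tibble (`ref_id`, `lineage`, `sequence`).
#' @param min_identity Identity floor below which hits are dropped (default
#'   0.90).
#' @param config A [cluster_config()] supplying alignment scores and k-mer
#'   size.
#' @param method `"kmer"` or `"exhaustive"`; identical results.
#' @return A tibble of hits: `ref_id`, `lineage`, `identity`.
#' @export
search_reference <- function(query, reference, min_identity = 0.90,
                             config = cluster_config(),
                             method = c("kmer", "exhaustive")) {
  method <- match.arg(method)
  if (!is.character(query) || length(query) != 1 || nchar(query) == 0) {
    stop("query must be a single nonempty string", call. = FALSE)
  }
  if (nrow(reference) == 0) stop("reference is empty", call. = FALSE)
  idx <- if (method == "kmer") {
    k <- config$kmer
    qk <- substring(query, 1:(nchar(query) - k + 1), k:nchar(query))
    kmer_candidates(qk, nchar(query), kmer_sets(reference$sequence, k),
                    nchar(reference$sequence), min_identity, k)
  } else {
    seq_len(nrow(reference))
  }
  if (length(idx) == 0) {
    return(tibble::tibble(ref_id = character(0), lineage = character(0),
                          identity = numeric(0)))
  }
  ids <- identity_to_targets(query, reference$sequence[idx], config)
  keep <- ids >= min_identity
  out <- tibble::tibble(ref_id = reference$ref_id[idx][keep],
                        lineage = reference$lineage[idx][keep],
                        identity = ids[keep])
  dplyr::arrange(out, dplyr::desc(.data$identity), .data$ref_id)
}

# Lowest common named lineage of a set of lineage strings.
lineage_lca <- function(lineages) {
  ranks <- as.matrix(parse_lineage(lineages))
  out <- character(7)
  for (j in seq_len(7)) {
    u <- unique(ranks[, j])
    if (length(u) == 1 && u != "") out[j] <- u else break
  }
  first_empty <- which(out == "")[1]
  if (!is.na(first_empty) && first_empty < 7) out[first_empty:7] <- ""
  out
}

#' Assign a rank-aware lineage from ranked hits
#'
#' Takes the best hit (equal-identity ties collapse to the lowest common
#' named lineage of the tied hits) and walks the ranks top-down, stopping
#' before the first unnamed rank. Assignment depth is additionally gated by
#' identity: genus requires >= 0.97 and species >= 0.99; with no hits at or
#' above the 0.90 floor the feature is unassigned.
#'
#' @param hits Hit tibble from [search_reference()] (already sorted).
#' @param genus_identity,species_identity Identity gates for genus and
#'   species assignment.
#' @return A one-row tibble: `lineage` (possibly truncated), `identity`,
#'   `depth` (a rank name, or `"unassigned"`).
#' @export
assign_lineage <- function(hits, genus_identity = 0.97,
                           species_identity = 0.99) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(lineage = format_lineage(character(7)),
                          identity = NA_real_, depth = "unassigned"))
  }
  best <- hits$identity[1]
  tied <- hits[hits$identity >= best - 1e-12, , drop = FALSE]
  ranks <- if (nrow(tied) > 1) {
    lineage_lca(tied$lineage)
  } else {
    as.character(as.matrix(parse_lineage(tied$lineage))[1, ])
  }
  max_depth <- if (best >= species_identity) 7L
    else if (best >= genus_identity) 6L
    else 5L
  named_depth <- which(ranks == "")[1] - 1L
  if (is.na(named_depth)) named_depth <- 7L
  depth <- min(max_depth, named_depth)
  if (depth < 7) ranks[(depth + 1):7] <- ""
  tibble::tibble(
    lineage = format_lineage(ranks),
    identity = best,
    depth = if (depth == 0) "unassigned" else rank_names()[depth]
  )
}

#' Assign taxonomy to every feature of a feature table
#'
#' Convenience wrapper running [search_reference()] and [assign_lineage()]
#' per feature representative.
#'
#' @param features Feature table from [cluster_to_features()].
#' @param reference Reference tibble.
#' @param min_identity Identity floor (default 0.90).
#' @param config A [cluster_config()].
#' @param method `"kmer"` or `"exhaustive"` search.
#' @inheritParams assign_lineage
#' @return A tibble: `feature_id`, `lineage`, `identity`, `depth`.
#' @export
assign_taxonomy <- function(features, reference, min_identity = 0.90,
                            config = cluster_config(),
                            method = c("kmer", "exhaustive"),
                            genus_identity = 0.97, species_identity = 0.99) {
  method <- match.arg(method)
  res <- purrr::map_dfr(seq_len(nrow(features)), function(i) {
    hits <- search_reference(features$sequence[i], reference, min_identity,
                             config, method)
    assign_lineage(hits, genus_identity, species_identity)
  })
  dplyr::bind_cols(tibble::tibble(feature_id = features$feature_id), res)
}

#' Collapse a feature table at a taxonomic rank
#'
#' Sums counts per named taxon at the requested rank; features whose
#' assignment does not reach that rank are pooled into `"unclassified"`.
#' Column sums are preserved exactly.
#'
#' @param features Feature table with count columns.
#' @param assignments Assignment tibble from [assign_taxonomy()].
#' @param rank One of `"kingdom"` ... `"species"`.
#' @return A tibble: `taxon` plus the sample count columns.
#' @export
collapse_at_rank <- function(features, assignments, rank) {
  if (!rank %in% rank_names()) {
    stop("unknown rank: ", rank, call. = FALSE)
  }
  stopifnot(all(features$feature_id %in% assignments$feature_id))
  sp <- ft_split(features)
  ranks <- parse_lineage(
    assignments$lineage[match(features$feature_id, assignments$feature_id)]
  )
  taxon <- ranks[[rank]]
  taxon[taxon == ""] <- "unclassified"
  agg <- rowsum(sp$counts, group = taxon)
  tibble::tibble(taxon = rownames(agg)) %>%
    dplyr::bind_cols(tibble::as_tibble(as.data.frame(agg))) %>%
    dplyr::arrange(dplyr::desc(rowSums(dplyr::pick(dplyr::where(is.numeric)))))
}

#' Per-sample annotation rate
#'
#' The percentage of reads that belong to features assigned at least at the
#' kingdom rank (i.e. not unassigned), per sample.
#'
#' @param features Feature table with count columns.
#' @param assignments Assignment tibble from [assign_taxonomy()].
#' @return A tibble: `sample_id`, `annotated`, `total`, `rate_pct` (`NA` when
#'   a sample has zero reads).
#' @export
annotation_rate <- function(features, assignments) {
  sp <- ft_split(features)
  assigned <- assignments$depth[match(features$feature_id,
                                      assignments$feature_id)] != "unassigned"
  total <- colSums(sp$counts)
  annotated <- colSums(sp$counts[assigned, , drop = FALSE])
  tibble::tibble(
    sample_id = sp$samples,
    annotated = as.numeric(annotated),
    total = as.numeric(total),
    rate_pct = ifelse(total > 0, 100 * annotated / total, NA_real_)
  )
}
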