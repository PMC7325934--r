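#' Clustering configuration
#'
#' Parameters of the seed-based sub-OTU clustering: the abundance threshold
#' that promotes a dereplicated sequence to a seed, the minimum identity at
#' which a non-seed merges into its nearest seed, and the global alignment
#' scores behind the identity metric.
#'
#' @param min_seed_count Total (or per-sample, see `seed_scope`) count at or
#'   above which a dereplicated sequence is designated a seed.
#' @param min_identity Minimum alignment identity for merging a non-seed into
#'   a seed.
#' @param match,mismatch,gap Alignment scores (gap is the per-column gap
#'   penalty, applied to end gaps too).
#' @param seed_scope `"pooled"` applies `min_seed_count` to the total count
#'   across samples; `"per_sample"` requires the threshold in at least one
#'   sample.
#' @param kmer Word size of the conservative k-mer prefilter used to skip
#'   hopeless alignments; the prefilter never changes results (asserted
#'   against exhaustive assignment in the tests).
#' @return A list of class `subotu_cluster_config`.
#' @export
cluster_config <- function(min_seed_count = 10, min_identity = 0.98,
                           match = 1, mismatch = -1, gap = -2,
                           seed_scope = c("pooled", "per_sample"),
                           kmer = 8) {
  stopifnot(min_identity > 0, min_identity <= 1, min_seed_count >= 1)
  structure(
    list(min_seed_count = as.integer(min_seed_count),
         min_identity = min_identity,
         match = match, mismatch = mismatch, gap = gap,
         seed_scope = match.arg(seed_scope),
         kmer = as.integer(kmer)),
    class = "subotu_cluster_config"
  )
}

#' Dereplicate prepared reads
#'
#' Groups identical (case-normalized) sequences, tallying counts per sample.
#' The pool is sorted by decreasing total count, ties broken lexicographically
#' by sequence, so downstream processing is fully deterministic.
#'
#' @param reads Tibble with columns `sample_id` and `sequence` (e.g. retained
#'   rows of [prepare_reads()]).
#' @return A tibble with `sequence`, one count column per sample, and
#'   `total_count`.
#' @export
dereplicate <- function(reads) {
  stopifnot(all(c("sample_id", "sequence") %in% names(reads)))
  pool <- reads %>%
    dplyr::mutate(sequence = toupper(.data$sequence)) %>%
    dplyr::count(.data$sequence, .data$sample_id) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L)
  counts <- as.matrix(pool[, setdiff(names(pool), "sequence"), drop = FALSE])
  pool$total_count <- as.integer(rowSums(counts))
  pool %>%
    dplyr::arrange(dplyr::desc(.data$total_count), .data$sequence) %>%
    dplyr::relocate("sequence", "total_count")
}

#' Global alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment (end gaps penalized) with the configured
#' scores; identity is the number of matching columns divided by the total
#' number of alignment columns, a symmetric fraction in [0, 1].
#'
#' @param seq_a,seq_b Nonempty DNA strings.
#' @param config A [cluster_config()] supplying the alignment scores.
#' @return A single numeric identity.
#' @export
#' @examples
#' pairwise_identity("ACGTACGTAC", "ACGTACGTAC")  # 1
#' pairwise_identity("ACGTACGTAC", "ACGAACGTAC")  # 0.9
pairwise_identity <- function(seq_a, seq_b, config = cluster_config()) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("sequences must be nonempty", call. = FALSE)
  }
  identity_to_targets(seq_a, seq_b, config)[1]
}

# Align one query against many targets; returns identities.
identity_to_targets <- function(query, targets, config) {
  if (length(targets) == 0) return(numeric(0))
  n <- length(targets)
  aln <- align_global(Biostrings::DNAStringSet(targets),
                      Biostrings::DNAStringSet(rep(query, n)), config)
  identity_of_alignment(aln, nchar(targets), nchar(query))
}

align_global <- function(pattern, subject, config) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = TRUE
  )
  Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject,
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = abs(config$gap)
  )
}

# Identity = matching columns / alignment columns. Every column is either an
# aligned base pair or a gap, so columns = Lp + Ls - (matches + mismatches);
# this avoids materializing the aligned strings.
identity_of_alignment <- function(aln, len_pattern, len_subject) {
  m <- Biostrings::nmatch(aln)
  x <- Biostrings::nmismatch(aln)
  m / (len_pattern + len_subject - m - x)
}

# Elementwise identities for paired query/target vectors in one alignment
# call (much faster than per-query calls for large batches).
batch_identity <- function(queries, targets, config) {
  if (length(queries) == 0) return(numeric(0))
  stopifnot(length(queries) == length(targets))
  aln <- align_global(Biostrings::DNAStringSet(queries),
                      Biostrings::DNAStringSet(targets), config)
  identity_of_alignment(aln, nchar(queries), nchar(targets))
}

# k-mer sets for a character vector of sequences.
kmer_sets <- function(seqs, k) {
  lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1), k:L))
  })
}

# Conservative prefilter: each of the query's Lq - k + 1 k-mer positions can
# be destroyed by at most k edits, and identity >= t allows at most
# e_max = ceil((1 - t) * (Lq + Lt)) edits, so a target passing the threshold
# must contain the k-mers of at least (Lq - k + 1) - k * e_max query
# positions (counted with multiplicity). Never excludes a target that could
# pass the identity threshold.
kmer_candidates <- function(query_kmers, query_len, target_kmers, target_lens,
                            min_identity, k) {
  shared <- vapply(target_kmers, function(tk) {
    sum(query_kmers %in% tk)
  }, numeric(1))
  e_max <- ceiling((1 - min_identity) * (query_len + target_lens))
  bound <- (query_len - k + 1) - k * e_max
  which(shared >= bound)
}

#' Designate seed sequences
#'
#' Returns exactly the dereplicated sequences whose abundance meets the seed
#' threshold, in pool order. Under `seed_scope = "pooled"` (default) the
#' threshold applies to the total count across samples; under `"per_sample"`
#' a sequence qualifies if any single sample reaches the threshold.
#'
#' @param pool Dereplicated tibble from [dereplicate()].
#' @param config A [cluster_config()].
#' @return The seed subset of `pool`.
#' @export
designate_seeds <- function(pool, config = cluster_config()) {
  if (nrow(pool) == 0) return(pool)
  if (config$seed_scope == "pooled") {
    pool[pool$total_count >= config$min_seed_count, , drop = FALSE]
  } else {
    counts <- ft_split(pool)$counts
    keep <- apply(counts, 1, max) >= config$min_seed_count
    pool[keep, , drop = FALSE]
  }
}

#' Cluster a dereplicated pool into sub-OTU features
#'
#' The core step: every non-seed sequence is compared to all seeds with the
#' global alignment identity; if its best identity reaches `min_identity` its
#' counts merge into that seed (ties broken toward the more abundant seed,
#' then lexicographically by seed sequence), otherwise it is retained as an
#' independent feature. Assignment is independent per non-seed (no transitive
#' chaining: an independent non-seed never becomes a merge target). Counts
#' are conserved exactly.
#'
#' @param pool Dereplicated tibble from [dereplicate()].
#' @param config A [cluster_config()].
#' @param seeds Optional seed subset; defaults to [designate_seeds()] on
#'   `pool`.
#' @param method `"kmer"` (default) screens seed candidates with a
#'   conservative k-mer bound before aligning; `"exhaustive"` aligns every
#'   non-seed against every seed. Both give identical tables.
#' @return A feature table tibble: `feature_id`, `sequence` (representative),
#'   `provenance` (`"seed"` or `"independent"`), one count column per sample,
#'   and `total_count`. The attribute `"assignment"` maps every pool sequence
#'   to the feature that absorbed it.
#' @export
cluster_to_features <- function(pool, config = cluster_config(),
                                seeds = NULL,
                                method = c("kmer", "exhaustive")) {
  method <- match.arg(method)
  if (nrow(pool) == 0) {
    return(tibble::tibble(feature_id = character(0), sequence = character(0),
                          provenance = character(0)))
  }
  seeds <- seeds %||% designate_seeds(pool, config)
  if (!all(seeds$sequence %in% pool$sequence)) {
    stop("seeds must be a subset of the pool", call. = FALSE)
  }
  counts <- ft_split(pool)$counts
  sample_names <- colnames(counts)
  is_seed <- pool$sequence %in% seeds$sequence
  seed_idx <- which(is_seed)
  nonseed_idx <- which(!is_seed)

  # assignment[i] = index (into pool) of the seed absorbing non-seed i, or NA
  assignment <- rep(NA_integer_, nrow(pool))
  if (length(seed_idx) > 0 && length(nonseed_idx) > 0) {
    seed_seqs <- pool$sequence[seed_idx]
    seed_lens <- nchar(seed_seqs)
    k <- config$kmer
    seed_kmers <- if (method == "kmer") kmer_sets(seed_seqs, k) else NULL
    # candidate (non-seed, seed) pairs, then one batched alignment call
    cand_list <- lapply(nonseed_idx, function(i) {
      q <- pool$sequence[i]
      if (method == "kmer") {
        qk <- substring(q, 1:(nchar(q) - k + 1), k:nchar(q))
        kmer_candidates(qk, nchar(q), seed_kmers, seed_lens,
                        config$min_identity, k)
      } else {
        seq_along(seed_idx)
      }
    })
    pair_q <- rep(nonseed_idx, lengths(cand_list))
    pair_s <- unlist(cand_list)
    if (length(pair_q) > 0) {
      ids <- batch_identity(pool$sequence[pair_q], seed_seqs[pair_s], config)
      for (grp in split(seq_along(pair_q), pair_q)) {
        i <- pair_q[grp[1]]
        cand <- pair_s[grp]
        ci <- ids[grp]
        best <- max(ci)
        if (best >= config$min_identity) {
          tied <- cand[ci >= best - 1e-12]
          if (length(tied) > 1) {
            ord <- order(-pool$total_count[seed_idx[tied]],
                         pool$sequence[seed_idx[tied]])
            tied <- tied[ord]
          }
          assignment[i] <- seed_idx[tied[1]]
        }
      }
    }
  }

  # merge counts into seeds; independents keep their own rows
  feature_rows <- c(seed_idx, nonseed_idx[is.na(assignment[nonseed_idx])])
  feature_rows <- sort(feature_rows)
  merged <- counts[feature_rows, , drop = FALSE]
  row_of <- match(feature_rows, feature_rows)
  names(row_of) <- feature_rows
  for (i in nonseed_idx) {
    if (!is.na(assignment[i])) {
      tgt <- match(assignment[i], feature_rows)
      merged[tgt, ] <- merged[tgt, ] + counts[i, ]
    }
  }
  out <- tibble::tibble(
    feature_id = sprintf("F%04d", seq_along(feature_rows)),
    sequence = pool$sequence[feature_rows],
    provenance = ifelse(feature_rows %in% seed_idx, "seed", "independent")
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(merged)))
  names(out)[-(1:3)] <- sample_names
  out$total_count <- as.integer(rowSums(merged))
  # per-pool-sequence feature membership, for read-level traceability
  dest <- ifelse(is.na(assignment), seq_len(nrow(pool)), assignment)
  dest_feature <- out$feature_id[match(dest, feature_rows)]
  attr(out, "assignment") <- tibble::tibble(
    sequence = pool$sequence,
    feature_id = dest_feature
  )
  out
}
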