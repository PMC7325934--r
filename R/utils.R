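# Internal helpers shared across modules.

# Evaluate `code` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Every stochastic operation in the package
# goes through this, so a config seed fully determines its output and no
# global RNG state leaks between operations.
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a sub-seed for an operation from a base seed; keeps distinct
# operations on distinct, reproducible streams while staying < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}

rank_names <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

rank_prefixes <- function() {
  c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
}

# Split a feature-table-like tibble into metadata columns and the numeric
# sample-count matrix. Metadata columns are the non-numeric ones (feature_id,
# sequence, provenance, lineage, taxon, ...).
ft_split <- function(tbl) {
  stopifnot(is.data.frame(tbl))
  is_num <- vapply(tbl, is.numeric, logical(1))
  meta_names <- names(tbl)[!is_num]
  # total_count is derived, never a sample column
  sample_names <- setdiff(names(tbl)[is_num], "total_count")
  mat <- as.matrix(tbl[, sample_names, drop = FALSE])
  rn <- if ("feature_id" %in% meta_names) {
    tbl$feature_id
  } else if ("taxon" %in% meta_names) {
    tbl$taxon
  } else if ("sequence" %in% meta_names) {
    tbl$sequence
  } else {
    as.character(seq_len(nrow(tbl)))
  }
  rownames(mat) <- rn
  list(meta = tbl[, meta_names, drop = FALSE], counts = mat,
       samples = sample_names)
}

ft_rebuild <- function(meta, counts) {
  dplyr::bind_cols(tibble::as_tibble(meta),
                   tibble::as_tibble(as.data.frame(counts)))
}

# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8).
iupac_codes <- function() {
  c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
    M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
    V = 7L, H = 11L, D = 13L, B = 14L, N = 15L)
}

# Count IUPAC-aware mismatches between a primer and equal-length read chunks.
# `chunks` is a character vector; positions are incompatible when the bitmasks
# share no base.
iupac_mismatches <- function(primer, chunks) {
  codes <- iupac_codes()
  p <- codes[strsplit(toupper(primer), "")[[1]]]
  n <- length(chunks)
  out <- integer(n)
  if (n == 0L) return(out)
  cm <- matrix(unlist(strsplit(toupper(chunks), "")), nrow = nchar(primer))
  cc <- matrix(codes[cm], nrow = nchar(primer))
  cc[is.na(cc)] <- 0L
  hits <- matrix(bitwAnd(as.vector(cc), p) == 0L, nrow = nchar(primer))
  colSums(hits)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
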