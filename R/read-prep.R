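#' Read preparation configuration
#'
#' Quality rules applied to merged amplicon reads before clustering: primer
#' detection and stripping, ambiguous-base handling, a minimum-length filter,
#' a mean per-base error ceiling from FASTQ qualities, and the abundance-skew
#' ratio used by the chimera detector.
#'
#' @param forward_primer IUPAC string expected at the 5' end, or `NULL` to
#'   skip primer handling entirely (for reads already stripped).
#' @param reverse_primer IUPAC string of the reverse primer; its reverse
#'   complement is stripped from the 3' end when found, but its absence does
#'   not reject a read (merged reads need not span it).
#' @param max_primer_mismatches Mismatches tolerated in IUPAC-aware primer
#'   matching.
#' @param min_length Minimum retained length in bases after trimming.
#' @param per_base_error_threshold Reads whose mean per-base error probability
#'   (from Phred qualities) exceeds this are rejected; reads without
#'   qualities skip the check.
#' @param chimera_abundance_skew How many times more abundant than a query
#'   both candidate parents must be in [detect_chimeras()].
#' @return A list of class `subotu_prep_config`.
#' @export
prep_config <- function(forward_primer = primer_preset("515F"),
                        reverse_primer = primer_preset("926R"),
                        max_primer_mismatches = 2,
                        min_length = 150,
                        per_base_error_threshold = 0.01,
                        chimera_abundance_skew = 2.0) {
  stopifnot(
    min_length > 0,
    per_base_error_threshold > 0, per_base_error_threshold < 1,
    chimera_abundance_skew >= 1
  )
  structure(
    list(forward_primer = forward_primer, reverse_primer = reverse_primer,
         max_primer_mismatches = as.integer(max_primer_mismatches),
         min_length = as.integer(min_length),
         per_base_error_threshold = per_base_error_threshold,
         chimera_abundance_skew = chimera_abundance_skew),
    class = "subotu_prep_config"
  )
}

mean_error_from_quality <- function(quality) {
  vapply(quality, function(q) {
    if (is.na(q) || nchar(q) == 0) return(NA_real_)
    mean(10^(-(utf8ToInt(q) - 33) / 10))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Prepare reads: primer stripping, trimming, and quality filters
#'
#' Applies the read-level rules in order: non-nucleotide characters reject a
#' read as `"alphabet"`; the forward primer must match the 5' end within
#' `max_primer_mismatches` (IUPAC-aware) and is stripped, otherwise the read
#' is rejected as `"primer"`; the reverse-complemented reverse primer is
#' stripped from the 3' end if present; leading/trailing N runs are trimmed
#' and any internal N rejects as `"ambiguous"`; reads whose mean per-base
#' error (from qualities) exceeds the threshold are rejected as `"quality"`;
#' and reads shorter than `min_length` after trimming are rejected as
#' `"length"`.
#'
#' @param reads Tibble with columns `sample_id`, `read_id`, `sequence`, and
#'   optionally `quality`.
#' @param config A [prep_config()].
#' @return The input tibble with `sequence` replaced by its trimmed form and
#'   a `status` column: `"retained"` or the rejection reason.
#' @export
prepare_reads <- function(reads, config = prep_config()) {
  stopifnot(all(c("sample_id", "read_id", "sequence") %in% names(reads)))
  seqs <- toupper(reads$sequence)
  n <- length(seqs)
  status <- rep("retained", n)

  bad_alpha <- grepl("[^ACGTUMRWSYKVHDBN]", seqs)
  status[bad_alpha] <- "alphabet"

  fp <- config$forward_primer
  if (!is.null(fp)) {
    ok <- !bad_alpha
    plen <- nchar(fp)
    long_enough <- nchar(seqs) >= plen & ok
    mm <- rep(Inf, n)
    if (any(long_enough)) {
      mm[long_enough] <- iupac_mismatches(fp, substr(seqs[long_enough], 1, plen))
    }
    reject <- ok & (mm > config$max_primer_mismatches)
    status[reject] <- "primer"
    keep <- ok & !reject
    seqs[keep] <- substr(seqs[keep], plen + 1, nchar(seqs[keep]))
  }

  rp <- config$reverse_primer
  if (!is.null(rp) && !is.null(fp)) {
    rc <- reverse_complement(rp)
    rlen <- nchar(rc)
    cand <- status == "retained" & nchar(seqs) > rlen
    if (any(cand)) {
      tails <- substr(seqs[cand], nchar(seqs[cand]) - rlen + 1, nchar(seqs[cand]))
      mm_r <- iupac_mismatches(rc, tails)
      strip <- which(cand)[mm_r <= config$max_primer_mismatches]
      seqs[strip] <- substr(seqs[strip], 1, nchar(seqs[strip]) - rlen)
    }
  }

  live <- status == "retained"
  seqs[live] <- sub("^N+", "", sub("N+$", "", seqs[live]))
  internal_n <- live & grepl("N", seqs, fixed = TRUE)
  status[internal_n] <- "ambiguous"

  if ("quality" %in% names(reads)) {
    live <- status == "retained"
    err <- mean_error_from_quality(reads$quality)
    bad_q <- live & !is.na(err) & err > config$per_base_error_threshold
    status[bad_q] <- "quality"
  }

  short <- status == "retained" & nchar(seqs) < config$min_length
  status[short] <- "length"

  out <- reads
  out$sequence <- seqs
  out$status <- status
  tibble::as_tibble(out)
}

#' Flag two-parent chimeras in a dereplicated pool
#'
#' A minimal crossover test: a sequence is flagged as chimeric when two
#' candidate parents, each at least `chimera_abundance_skew` times more
#' abundant, admit a single breakpoint such that the left segment matches one
#' parent and the right segment the other at >= 0.99 identity each, while the
#' best whole-sequence identity to any single candidate parent is <= 0.95.
#' Segment comparisons are positional and therefore restricted to candidate
#' parents of the same length as the query (amplicons of a common locus);
#' the most abundant sequence can never be flagged.
#'
#' @param pool Dereplicated tibble from [dereplicate()] (sorted by decreasing
#'   `total_count`).
#' @param config A [prep_config()]; only `chimera_abundance_skew` is used.
#' @return `pool` with a logical `is_chimera` column.
#' @export
detect_chimeras <- function(pool, config = prep_config()) {
  stopifnot(all(c("sequence", "total_count") %in% names(pool)))
  n <- nrow(pool)
  flags <- logical(n)
  if (n < 3) {
    pool$is_chimera <- flags
    return(pool)
  }
  chars <- strsplit(pool$sequence, "")
  lens <- nchar(pool$sequence)
  for (q in seq_len(n)) {
    cand <- which(pool$total_count >= config$chimera_abundance_skew *
                    pool$total_count[q] & lens == lens[q] &
                    seq_len(n) != q)
    if (length(cand) < 2) next
    L <- lens[q]
    qc <- chars[[q]]
    mm <- vapply(cand, function(j) cumsum(qc != chars[[j]]), numeric(L))
    total_mm <- mm[L, ]
    if (min(total_mm) / L < 0.05) next  # close to a real parent, not chimeric
    # per-candidate prefix/suffix identity >= 0.99 at each breakpoint
    b <- seq_len(L - 1)
    left_ok <- mm[b, , drop = FALSE] <= 0.01 * b
    right_ok <- sweep(mm[b, , drop = FALSE], 2, total_mm, "-") * -1
    right_ok <- right_ok <= 0.01 * (L - b)
    if (any(rowSums(left_ok) > 0 & rowSums(right_ok) > 0)) flags[q] <- TRUE
  }
  pool$is_chimera <- flags
  pool
}

#' Summarize read preparation as a per-sample report
#'
#' @param prepared Output of [prepare_reads()] (optionally after marking
#'   chimeric reads with status `"chimera"`).
#' @return A tibble with one row per sample: input count, one column per
#'   rejection reason, `retained`, and `retained_pct` (NA for empty samples).
#'   The categories partition the input count exactly.
#' @export
prep_stats <- function(prepared) {
  reasons <- c("primer", "length", "ambiguous", "quality", "alphabet",
               "chimera")
  out <- prepared %>%
    dplyr::count(.data$sample_id, .data$status) %>%
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  for (r in c(reasons, "retained")) {
    if (!r %in% names(out)) out[[r]] <- 0L
  }
  out %>%
    dplyr::mutate(
      input = rowSums(dplyr::across(dplyr::all_of(c(reasons, "retained")))),
      retained_pct = ifelse(.data$input > 0,
                            100 * .data$retained / .data$input, NA_real_)
    ) %>%
    dplyr::select(dplyr::all_of(c("sample_id", "input", reasons, "retained",
                                  "retained_pct")))
}
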