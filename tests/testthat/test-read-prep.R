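mk_reads <- function(seqs, quality = NULL) {
  out <- tibble::tibble(
    sample_id = "s1",
    read_id = sprintf("r%02d", seq_along(seqs)),
    sequence = seqs
  )
  if (!is.null(quality)) out$quality <- quality
  out
}

test_that("prepare_reads applies the rejection rules in order", {
  fp <- "ACGTACGTAA"
  cfg <- prep_config(forward_primer = fp, reverse_primer = NULL,
                     max_primer_mismatches = 2, min_length = 150)
  insert <- strrep("ACGT", 50)  # 200 bp clean insert
  reads <- mk_reads(c(
    paste0(fp, insert),                        # clean
    paste0("TTTTTTTTTT", insert),              # no primer
    paste0(sub("^AC", "GC", fp), insert),      # 1 mismatch in primer
    paste0(fp, substr(insert, 1, 149)),        # too short after strip
    paste0(fp, "ACGTNNACGT", insert),          # internal N
    paste0(fp, "NNN", insert),                 # leading Ns trimmed, clean
    paste0(fp, gsub("G", "X", insert))         # bad alphabet
  ))
  out <- prepare_reads(reads, cfg)
  expect_equal(out$status,
               c("retained", "primer", "retained", "length", "ambiguous",
                 "retained", "alphabet"))
  expect_equal(out$sequence[1], insert)
  expect_equal(out$sequence[3], insert)  # primer stripped despite mismatch
  expect_equal(out$sequence[6], insert)  # N run trimmed
})

test_that("reverse primer is stripped when present but not required", {
  fp <- "ACGTACGTAA"; rp <- "GGTTCCAACC"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rp)))
  cfg <- prep_config(forward_primer = fp, reverse_primer = rp,
                     min_length = 100)
  insert <- strrep("CAGT", 40)
  out <- prepare_reads(mk_reads(c(paste0(fp, insert, rc),
                                  paste0(fp, insert))), cfg)
  expect_equal(out$status, c("retained", "retained"))
  expect_equal(out$sequence, c(insert, insert))
})

test_that("mean per-base error above threshold rejects a read", {
  fp <- "ACGTACGTAA"
  insert <- strrep("ACGT", 50)
  seqs <- rep(paste0(fp, insert), 2)
  qual <- c(strrep("I", nchar(seqs[1])),   # Q40, error 1e-4
            strrep("#", nchar(seqs[1])))   # Q2, error ~0.63
  out <- prepare_reads(mk_reads(seqs, qual), prep_config(
    forward_primer = fp, reverse_primer = NULL))
  expect_equal(out$status, c("retained", "quality"))
})

test_that("prepare_reads is idempotent in no-primer mode", {
  insert <- strrep("GATC", 60)
  cfg <- prep_config(forward_primer = NULL, reverse_primer = NULL)
  once <- prepare_reads(mk_reads(insert), cfg)
  twice <- prepare_reads(once[, c("sample_id", "read_id", "sequence")], cfg)
  expect_equal(twice$sequence, once$sequence)
  expect_equal(twice$status, once$status)
})

test_that("constructed crossovers are flagged and honest sequences are not", {
  set.seed(8)
  a <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  chim <- paste0(substr(a, 1, 100), substr(b, 101, 200))
  pool <- tibble::tibble(
    sequence = c(a, b, chim),
    s1 = c(50L, 40L, 3L),
    total_count = c(50L, 40L, 3L)
  )
  out <- detect_chimeras(pool, prep_config())
  expect_equal(out$is_chimera, c(FALSE, FALSE, TRUE))

  # a sequence identical to an abundant parent is never flagged
  pool2 <- tibble::tibble(sequence = c(a, b, a), s1 = c(50L, 40L, 2L),
                          total_count = c(50L, 40L, 2L))
  expect_equal(detect_chimeras(pool2, prep_config())$is_chimera,
               rep(FALSE, 3))

  # the most abundant sequence has no more-abundant parents
  pool3 <- tibble::tibble(sequence = c(chim, a, b), s1 = c(90L, 40L, 30L),
                          total_count = c(90L, 40L, 30L))
  expect_false(detect_chimeras(pool3, prep_config())$is_chimera[1])
})

test_that("chimera detector is sensitive and specific on simulator output", {
  ref <- build_reference(12, seed = 3)
  cfg <- sim_config(n_samples_per_cell = 1, chambers = "DC",
                    levels = c("reference", "high"), generations = "G1",
                    reads_per_sample = 1000, substitution_error_rate = 0,
                    chimera_rate = 0.1, seed = 5)
  tr <- simulate_design(ref, cfg)
  rd <- generate_reads(ref, tr, cfg)
  pr <- prepare_reads(rd, prep_config())
  keep <- pr[pr$status == "retained", ]
  pool <- dereplicate(keep)
  fl <- detect_chimeras(pool, prep_config())
  truth <- keep
  truth$chim <- rd$is_chimera[match(keep$read_id, rd$read_id)]
  truth_by_seq <- tapply(truth$chim, toupper(truth$sequence), any)
  is_chim_true <- as.logical(truth_by_seq[fl$sequence])
  sens <- sum(fl$is_chimera & is_chim_true) / sum(is_chim_true)
  fpr <- sum(fl$is_chimera & !is_chim_true) / sum(!is_chim_true)
  expect_gte(sens, 0.80)
  expect_lte(fpr, 0.01)
})

test_that("prep report partitions the input exactly", {
  rep0 <- prep_stats(sim20$prepared)
  expect_true(all(rep0$input ==
    rep0$primer + rep0$length + rep0$ambiguous + rep0$quality +
    rep0$alphabet + rep0$chimera + rep0$retained))
  totals <- table(sim20$prepared$sample_id)
  expect_equal(rep0$input, as.integer(totals[rep0$sample_id]))
  # empty input: zero counts, no percentage
  empty <- prep_stats(tibble::tibble(sample_id = character(0),
                                     status = character(0)))
  expect_equal(nrow(empty), 0)
  # 100 in, 2 rejected -> 98% retained
  df <- tibble::tibble(sample_id = "s", status = c(rep("retained", 98),
                                                   rep("primer", 2)))
  st <- prep_stats(df)
  expect_equal(st$retained, 98)
  expect_equal(st$retained_pct, 98.0)
})
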