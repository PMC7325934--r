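full_lineage <- "k__Bacteria;p__Pro;c__Gam;o__Bur;f__Burk;g__Burkholderia;s__x"
nogenus_lineage <- "k__Bacteria;p__Fir;c__Clo;o__Clos;f__Rumino;g__;s__"

test_that("lineage parsing normalizes trailing empties", {
  r <- parse_lineage("k__A;p__B;c__;o__D;f__;g__;s__")
  expect_equal(r$kingdom, "A")
  expect_equal(r$phylum, "B")
  # named rank below an empty rank is cleared
  expect_equal(r$order, "")
  expect_equal(format_lineage(as.matrix(parse_lineage(full_lineage))),
               full_lineage)
})

test_that("reference search honours the identity floor and ordering", {
  ref <- sim0$ref
  hits <- search_reference(ref$sequence[3], ref)
  expect_equal(hits$ref_id[1], ref$ref_id[3])
  expect_equal(hits$identity[1], 1.0)
  # query at < 0.90 to everything: empty hit list
  set.seed(2)
  junk <- paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
  expect_equal(nrow(search_reference(junk, ref)), 0)
  # k-mer screened scan equals the exhaustive scan
  q <- sim20$features$sequence[5]
  expect_equal(search_reference(q, sim20$ref, method = "kmer"),
               search_reference(q, sim20$ref, method = "exhaustive"))
  expect_error(search_reference("", ref), "nonempty")
})

test_that("identity gates and unnamed ranks bound assignment depth", {
  h <- function(id, lin) tibble::tibble(ref_id = "R1", lineage = lin,
                                        identity = id)
  expect_equal(assign_lineage(h(0.995, full_lineage))$depth, "species")
  a <- assign_lineage(h(0.98, full_lineage))
  expect_equal(a$depth, "genus")
  expect_equal(parse_lineage(a$lineage)$species, "")
  expect_equal(assign_lineage(h(0.95, full_lineage))$depth, "family")
  # unnamed genus stops assignment at family even at species-grade identity
  b <- assign_lineage(h(0.995, nogenus_lineage))
  expect_equal(b$depth, "family")
  # no hits: unassigned
  expect_equal(assign_lineage(h(1, full_lineage)[0, ])$depth, "unassigned")
})

test_that("equal-identity ties resolve to the lowest common named lineage", {
  hits <- tibble::tibble(
    ref_id = c("R1", "R2"),
    lineage = c(full_lineage,
                "k__Bacteria;p__Pro;c__Gam;o__Bur;f__Burk;g__Other;s__y"),
    identity = c(0.995, 0.995)
  )
  a <- assign_lineage(hits)
  expect_equal(a$depth, "family")
  expect_equal(parse_lineage(a$lineage)$family, "Burk")
})

test_that("no assignment violates the gates on simulated features", {
  tax <- assign_taxonomy(sim20$features, sim20$ref)
  ranks7 <- c("kingdom", "phylum", "class", "order", "family", "genus",
              "species")
  depth_idx <- match(tax$depth, ranks7)
  depth_idx[is.na(depth_idx)] <- 0
  expect_true(all(tax$identity[depth_idx >= 6] >= 0.97, na.rm = TRUE))
  expect_true(all(tax$identity[depth_idx == 7] >= 0.99, na.rm = TRUE))
  expect_true(all(is.na(tax$identity) | tax$identity >= 0.90))
  # unnamed-rank truncation: assigned lineage is a prefix of the best hit
  for (i in seq_len(nrow(tax))) {
    if (tax$depth[i] == "unassigned") next
    got <- as.matrix(parse_lineage(tax$lineage[i]))[1, ]
    named <- sum(got != "")
    expect_equal(named, depth_idx[i])
  }
})

test_that("error-free features recover their true genus", {
  tax <- assign_taxonomy(sim0$features, sim0$ref)
  # truth: each noiseless feature is an exact reference amplicon
  true_ref <- sim0$ref$ref_id[match(sim0$features$sequence,
                                    sim0$ref$sequence)]
  true_genus <- parse_lineage(
    sim0$ref$lineage[match(true_ref, sim0$ref$ref_id)])$genus
  got_genus <- parse_lineage(tax$lineage)$genus
  comparable <- true_genus != ""
  expect_gte(mean(got_genus[comparable] == true_genus[comparable]), 0.95)
})

test_that("rank collapse conserves column sums and pools unassigned", {
  ft <- sim20$features
  tax <- assign_taxonomy(ft, sim20$ref)
  gen <- collapse_at_rank(ft, tax, "genus")
  num <- vapply(gen, is.numeric, logical(1))
  before <- colSums(ft[, setdiff(names(ft)[vapply(ft, is.numeric,
                                                  logical(1))],
                                 "total_count")])
  after <- colSums(gen[, names(num)[num]])
  expect_equal(after[names(before)], before)
  expect_error(collapse_at_rank(ft, tax, "tribe"), "unknown rank")
  # features truncated above genus land in "unclassified"
  if (any(tax$depth %in% c("family", "unassigned"))) {
    expect_true("unclassified" %in% gen$taxon)
  }
  # two features of one genus sum their counts
  toy_ft <- tibble::tibble(feature_id = c("F1", "F2"), s1 = c(3L, 4L))
  toy_tax <- tibble::tibble(feature_id = c("F1", "F2"),
                            lineage = rep(full_lineage, 2),
                            identity = c(1, 1), depth = "species")
  toy <- collapse_at_rank(toy_ft, toy_tax, "genus")
  expect_equal(toy$s1[toy$taxon == "Burkholderia"], 7L)
})

test_that("annotation rate counts reads in assigned features", {
  ft <- tibble::tibble(feature_id = c("F1", "F2"), s1 = c(98L, 2L),
                       s2 = c(0L, 5L))
  tax <- tibble::tibble(feature_id = c("F1", "F2"),
                        lineage = c(full_lineage, format_lineage(character(7))),
                        identity = c(1, NA), depth = c("species", "unassigned"))
  ar <- annotation_rate(ft, tax)
  expect_equal(ar$rate_pct[ar$sample_id == "s1"], 98.0)
  expect_equal(ar$rate_pct[ar$sample_id == "s2"], 0.0)
  # planted unassignable taxon: rate equals the non-planted read share
  drop <- "REF001"
  ref_small <- sim0$ref[sim0$ref$ref_id != drop, ]
  tax0 <- assign_taxonomy(sim0$features, ref_small)
  ar0 <- annotation_rate(sim0$features, tax0)
  mapped <- read_feature_map(sim0)
  truth_share <- vapply(ar0$sample_id, function(s) {
    rid <- sim0$retained$read_id[sim0$retained$sample_id == s]
    100 * mean(mapped$true_ref[match(rid, mapped$read_id)] != drop)
  }, numeric(1))
  expect_equal(ar0$rate_pct, unname(truth_share))
})
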