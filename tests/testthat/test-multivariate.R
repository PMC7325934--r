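test_that("Bray-Curtis matches the hand formula and its bounds", {
  tbl <- tibble::tibble(feature_id = c("a", "b"),
                        s1 = c(1, 1), s2 = c(1, 0), s3 = c(1, 1),
                        s4 = c(0, 2))
  d <- as.matrix(bray_curtis(tbl))
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s1", "s2"], 1 / 3)
  expect_equal(d["s2", "s4"], 1)   # disjoint samples
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(abs(d - t(d)) < 1e-12))
  expect_true(all(diag(d) == 0))
  expect_error(bray_curtis(tibble::tibble(f = "a", s1 = 1, s2 = 0)), "s2")
})

test_that("PCoA round-trips Euclidean inputs and reports negatives", {
  set.seed(1)
  xy <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("p", 1:4), NULL))
  d <- dist(xy)
  p <- pcoa(d)
  rec <- dist(as.matrix(p$points[, -1]))
  expect_lt(max(abs(rec - d)), 1e-8)
  expect_equal(p$n_negative_eigenvalues, 0)
  # eigenvalue sum equals the trace of the centered Gower matrix
  dm <- as.matrix(d)^2
  n <- nrow(dm)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% dm %*% J
  expect_equal(sum(p$eigenvalues), sum(diag(G)), tolerance = 1e-8)
  # three equidistant points: two equal positive eigenvalues
  d3 <- as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  p3 <- pcoa(d3)
  expect_equal(p3$eigenvalues[1], p3$eigenvalues[2], tolerance = 1e-10)
  # non-Euclidean input warns and counts dropped axes
  set.seed(2)
  comm <- toy_comm <- matrix(rpois(12 * 15, 3), nrow = 15,
                             dimnames = list(NULL, paste0("s", 1:12)))
  rel <- tss_normalize(dplyr::bind_cols(
    tibble::tibble(feature_id = paste0("f", 1:15)),
    tibble::as_tibble(as.data.frame(comm))))
  expect_warning(pb <- pcoa(bray_curtis(rel)), "negative eigenvalue")
  expect_gt(pb$n_negative_eigenvalues, 0)
  expect_lte(sum(pb$proportion_explained), 1 + 1e-12)
  expect_error(pcoa(dist(xy[1:2, ])), ">= 3")
})

test_that("UPGMA reproduces hand-worked merge heights; ties and leaves behave", {
  dm <- as.dist(matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
                       dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  hc <- hcluster(dm, "group_average")
  expect_equal(hc$hclust$height, c(2, 6))
  tree <- ape::read.tree(text = hc$newick)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
  # two identical samples merge first at height zero
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 5), d = c(9, 1),
             e = c(0, 9))
  hc2 <- hcluster(dist(m), "group_average")
  expect_equal(hc2$hclust$height[1], 0)
  first <- hc2$hclust$merge[1, ]
  expect_setequal(hc2$hclust$labels[-first], c("a", "b"))
  # ultrametric UPGMA tree
  expect_true(ape::is.ultrametric(ape::read.tree(text = hc2$newick)))
  # ward linkage accepted
  expect_s3_class(hcluster(dist(m), "ward"), "subotu_dendro")
  expect_error(hcluster(dist(m[1, , drop = FALSE])), ">= 2")
})

test_that("PERMANOVA matches vegan's statistic and resolves clear separation", {
  set.seed(10)
  m <- rbind(matrix(rnorm(80, 0, 0.1), 8), matrix(rnorm(80, 5, 0.1), 8))
  rownames(m) <- paste0("s", 1:16)
  d <- dist(m)
  g <- rep(c("a", "b"), each = 8)
  pv <- permanova(d, g, n_perm = 999, seed = 3)
  expect_equal(pv$p_value, 0.001)
  a2 <- vegan::adonis2(d ~ grp, data = data.frame(grp = g),
                       permutations = 99)
  expect_equal(pv$f, a2$F[1], tolerance = 1e-10)
  expect_equal(pv$r_squared, a2$R2[1], tolerance = 1e-10)
  # deterministic given seed; permutation lower bound respected
  expect_equal(permanova(d, g, n_perm = 999, seed = 3)$p_value, pv$p_value)
  expect_gte(pv$p_value, 1 / 1000)
  # invariant to sample order
  perm <- sample(16)
  pv2 <- permanova(dist(m[perm, ]), g[perm], n_perm = 999, seed = 3)
  expect_equal(pv2$f, pv$f, tolerance = 1e-10)
  expect_error(permanova(d, rep("a", 16)), "2 non-empty")
})

test_that("PERMANOVA null p-values are calibrated", {
  set.seed(11)
  m <- matrix(rnorm(16 * 5), 16)
  d <- dist(m)
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    permanova(d, sample(rep(c("a", "b"), each = 8)), n_perm = 199,
              seed = s)$p_value
  }, numeric(1))
  frac <- mean(ps <= 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("CCA respects rank bounds, inertia identity, and validation", {
  set.seed(12)
  counts <- matrix(rpois(8 * 12, 30), nrow = 8,
                   dimnames = list(paste0("t", 1:8), paste0("s", 1:12)))
  tbl <- dplyr::bind_cols(tibble::tibble(taxon = rownames(counts)),
                          tibble::as_tibble(as.data.frame(counts)))
  env <- tibble::tibble(sample_id = paste0("s", 1:12),
                        thg = rlnorm(12, 3, 1), tc = rlnorm(12, 1, 0.5))
  cc <- cca_fit(tbl, env)
  expect_lte(length(cc$eigenvalues), 2)
  expect_true(all(cc$eigenvalues >= 0 & cc$eigenvalues <= 1))
  # single environmental variable: exactly one constrained axis
  cc1 <- cca_fit(tbl, env[, c("sample_id", "thg")])
  expect_equal(length(cc1$eigenvalues), 1)
  # constrained eigenvalues bounded by unconstrained CA eigenvalues
  ca <- vegan::cca(t(counts))
  expect_true(all(cc$eigenvalues <=
                    ca$CA$eig[seq_along(cc$eigenvalues)] + 1e-10))
  # total inertia equals chi-square statistic / grand total
  X <- t(counts)
  E <- outer(rowSums(X), colSums(X)) / sum(X)
  expect_equal(cc$total_inertia, sum((X - E)^2 / E) / sum(X),
               tolerance = 1e-8)
  # validation errors
  expect_error(cca_fit(tbl, dplyr::mutate(env, tc = 1)), "tc")
  expect_error(cca_fit(tbl, dplyr::mutate(env, tc2 = tc)), "collinear")
  expect_error(cca_fit(tbl[, 1:4], env), "n_env")
})

test_that("an indicator that determines composition captures the inertia", {
  grp_a <- c(40, 5, 5, 30)
  grp_b <- c(5, 40, 30, 5)
  counts <- cbind(matrix(rep(grp_a, 5), ncol = 5),
                  matrix(rep(grp_b, 5), ncol = 5))
  dimnames(counts) <- list(paste0("t", 1:4), paste0("s", 1:10))
  tbl <- dplyr::bind_cols(tibble::tibble(taxon = rownames(counts)),
                          tibble::as_tibble(as.data.frame(counts)))
  env <- tibble::tibble(sample_id = paste0("s", 1:10),
                        grp = rep(c(0, 1), each = 5))
  cc <- cca_fit(tbl, env, transform = FALSE)
  expect_gte(cc$eigenvalues[1], 0.9 * cc$total_inertia)
})

test_that("tidiers return well-formed summaries", {
  set.seed(13)
  m <- rbind(matrix(rnorm(40, 0, 1), 4), matrix(rnorm(40, 2, 1), 4))
  rownames(m) <- paste0("s", 1:8)
  pv <- permanova(dist(m), rep(c("a", "b"), each = 4), n_perm = 199,
                  seed = 1)
  td <- tidy(pv)
  expect_equal(td$term, c("among_groups", "within_groups", "total"))
  expect_equal(sum(td$sum_of_squares[1:2]), td$sum_of_squares[3])
  expect_equal(glance(pv)$p_value, pv$p_value)
  p <- pcoa(dist(m))
  expect_equal(nrow(tidy(p)), length(p$eigenvalues))
  expect_s3_class(autoplot(p), "ggplot")
})
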