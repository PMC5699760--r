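test_that("pearson_correlation matches hand-computed values", {
  x <- rbind(g1 = c(1.2, 0.3, -0.5, 0.9, 0.1),
             g2 = c(0.8, -0.1, -0.2, 1.1, 0.0))
  colnames(x) <- sprintf("s%d", 1:5)
  r <- pearson_correlation(x)
  hand <- sum((x[1, ] - mean(x[1, ])) * (x[2, ] - mean(x[2, ]))) /
    sqrt(sum((x[1, ] - mean(x[1, ]))^2) * sum((x[2, ] - mean(x[2, ]))^2))
  expect_equal(r["g1", "g2"], hand, tolerance = 1e-12)
  expect_equal(diag(r), c(g1 = 1, g2 = 1))

  dup <- rbind(x, g3 = x[1, ])
  expect_equal(pearson_correlation(dup)["g1", "g3"], 1)
  neg <- rbind(x, g3 = -x[1, ])
  expect_equal(pearson_correlation(neg)["g1", "g3"], -1)

  flat <- rbind(x, g3 = rep(1, 5))
  expect_error(pearson_correlation(flat), "g3")
  expect_error(pearson_correlation(x[, 1:2]), "3 samples")
})

test_that("soft adjacency is |r|^beta with zero diagonal", {
  r <- matrix(c(1, 0.5, -0.5, 0.5, 1, 0, -0.5, 0, 1), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  a6 <- soft_adjacency(r, 6)
  expect_equal(a6["a", "b"], 0.5^6)
  expect_equal(a6["a", "c"], 0.5^6)   # sign dropped
  expect_equal(diag(a6), c(a = 0, b = 0, c = 0))
  a1 <- soft_adjacency(r, 1)
  expect_equal(a1["a", "b"], 0.5)
  expect_error(soft_adjacency(r, 0), "beta")
  expect_error(soft_adjacency(r, -2), "beta")
})

test_that("adjacency decreases in beta strictly for 0 < |r| < 1", {
  r <- seq(0.05, 0.95, by = 0.1)
  vals <- sapply(1:8, function(b) r^b)
  expect_true(all(diff(t(vals)) < 0))
  expect_equal(sapply(1:8, function(b) 0^b), rep(0, 8))
  expect_equal(sapply(1:8, function(b) 1^b), rep(1, 8))
})

test_that("connectivity sums off-diagonal adjacency", {
  ones <- matrix(1, 5, 5); diag(ones) <- 0
  expect_equal(unname(connectivity(ones)), rep(4, 5))
  expect_equal(unname(connectivity(matrix(0, 4, 4))), rep(0, 4))
  toy <- matrix(0, 3, 3)
  toy[1, 2] <- toy[2, 1] <- 0.2
  toy[1, 3] <- toy[3, 1] <- 0.3
  toy[2, 3] <- toy[3, 2] <- 0.4
  expect_equal(unname(connectivity(toy)), c(0.5, 0.6, 0.7))
})

test_that("scale-free fit recovers an exact power law", {
  # three occupied bins at k = 1, 4, 16 with counts 64, 8, 1:
  # p(k) proportional to k^-1.5 exactly, so log-log points are collinear
  k <- rep(c(1, 4, 16), c(64, 8, 1))
  fit <- scale_free_fit(k, n_bins = 10)
  expect_equal(fit$slope, -1.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$signed_index, 1, tolerance = 1e-10)
  expect_equal(fit$bins_used, 3)
})

test_that("scale-free fit of a flat density is zero", {
  k <- rep(1:10, each = 5)   # every bin equally occupied
  fit <- scale_free_fit(k, n_bins = 10)
  expect_equal(fit$slope, 0)
  expect_equal(fit$signed_index, 0)
  expect_error(scale_free_fit(c(0, 0, 1, 1)), "usable bins")
  expect_error(scale_free_fit(c(0, 0)), "positive connectivity")
})

test_that("select_beta applies the smallest-qualifying rule and fallback", {
  set.seed(5)
  x <- matrix(rnorm(30 * 20), 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:20)))
  r <- pearson_correlation(x)
  # a target every candidate meets: the smallest candidate is returned
  low <- select_beta(r, candidates = c(3, 1, 2), target = -1)
  expect_equal(low$beta, 1)
  expect_true(low$reached_target)
  # an unreachable target: argmax returned with a warning
  expect_warning(hi <- select_beta(r, candidates = 1:6, target = 0.999),
                 "no candidate")
  expect_false(hi$reached_target)
  expect_equal(hi$fit$signed_index, max(hi$sweep$signed_index, na.rm = TRUE))
  expect_equal(nrow(hi$sweep), 6)
})

test_that("TOM handles the degenerate extremes", {
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tz <- tom_similarity(z)
  expect_equal(unname(diag(tz)), rep(1, 4))
  expect_equal(sum(tz) - 4, 0)

  full <- matrix(1, 4, 4); diag(full) <- 0
  tf <- tom_similarity(full)
  expect_equal(unname(tf[upper.tri(tf)]), rep(1, 6))

  bad <- full; bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(tom_similarity(bad), "\\[0, 1\\]")
})

test_that("TOM equals the brute-force triple loop on random adjacencies", {
  set.seed(71)
  for (n in c(5, 10, 20)) {
    r <- matrix(runif(n * n, -1, 1), n)
    r <- (r + t(r)) / 2
    diag(r) <- 1
    dimnames(r) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
    adj <- soft_adjacency(r, 6)
    w <- tom_similarity(adj)
    expect_equal(w, naive_tom(adj), tolerance = 1e-12)
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(w, t(w), tolerance = 1e-14)
  }
})

test_that("TOM of a near-zero adjacency stays near the adjacency", {
  set.seed(8)
  n <- 12
  a <- matrix(runif(n * n, 0, 1e-4), n)
  a <- (a + t(a)) / 2; diag(a) <- 0
  dimnames(a) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
  w <- tom_similarity(a)
  off <- upper.tri(a)
  expect_lt(max(abs(w[off] - a[off])), 1e-6)
})

test_that("average linkage agrees with a naive UPGMA reference", {
  set.seed(13)
  for (n in c(6, 10, 15)) {
    d <- matrix(runif(n * n), n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    dimnames(d) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
    tree <- average_linkage(d)
    ref <- naive_upgma(d)
    expect_equal(hclust_merge_sets(tree), ref$merges)
    expect_equal(tree$height, ref$heights, tolerance = 1e-12)
    expect_true(all(diff(tree$height) >= -1e-12))   # monotone heights
  }
})

test_that("average linkage separates two planted blocks", {
  n <- 10
  d <- matrix(0.9, n, n)
  d[1:5, 1:5] <- 0.1
  d[6:10, 6:10] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
  tree <- average_linkage(d)
  expect_equal(max(tree$height), 0.9, tolerance = 1e-12)
  top <- cutree(tree, k = 2)
  expect_equal(unname(top), rep(1:2, each = 5))

  two <- matrix(c(0, 0.4, 0.4, 0), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- average_linkage(two)
  expect_equal(t2$height, 0.4)

  asym <- d; asym[1, 2] <- 0.5
  expect_error(average_linkage(asym), "symmetric")
})

test_that("cut_modules labels clusters by size with grey leftovers", {
  n <- 30
  d <- matrix(0.95, n, n)
  d[1:12, 1:12] <- 0.1     # big block
  d[13:20, 13:20] <- 0.1   # smaller block
  diag(d) <- 0
  dimnames(d) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  tree <- average_linkage(d)

  mods <- cut_modules(tree, height = 0.5, min_size = 5)
  expect_s3_class(mods, "module_assignment")
  expect_equal(unname(unclass(mods)[1:12]), rep("turquoise", 12))
  expect_equal(unname(unclass(mods)[13:20]), rep("blue", 8))
  expect_equal(unname(unclass(mods)[21:30]), rep("grey", 10))

  # min_size filters the smaller block into grey
  big_only <- cut_modules(tree, height = 0.5, min_size = 10)
  expect_equal(sort(unique(unclass(big_only))), c("grey", "turquoise"))

  # cut above the root: everything is one module
  all_in <- cut_modules(tree, height = max(tree$height) + 1, min_size = 5)
  expect_equal(unname(unique(unclass(all_in))), "turquoise")

  # cut below every merge: everything is grey
  none <- cut_modules(tree, height = min(tree$height) / 2, min_size = 2)
  expect_equal(unname(unique(unclass(none))), "grey")
})

test_that("adjusted Rand index matches direct evaluation and mclust", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(1:6, rep(1, 6)), 0)
  # hand-built contingency [[2,1],[1,2]]: ARI = (2 - 2.4)/(6 - 2.4) = -1/9
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 1, 2, 2)
  expect_equal(adjusted_rand_index(a, b), -1 / 9, tolerance = 1e-12)

  skip_if_not_installed("mclust")
  set.seed(19)
  for (i in 1:20) {
    p1 <- sample(1:4, 30, replace = TRUE)
    p2 <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(p1, p2),
                 mclust::adjustedRandIndex(p1, p2), tolerance = 1e-12)
  }
})

test_that("module_recovery aligns genes by name", {
  assign <- structure(c(g1 = "turquoise", g2 = "turquoise", g3 = "grey"),
                      class = "module_assignment")
  truth <- c(g3 = "background", g1 = "M1", g2 = "M1")
  expect_equal(module_recovery(assign, truth), 1)
  expect_error(module_recovery(assign, truth[1:2]), "same genes")
})

test_that("edge export thresholds and orders pairs", {
  m <- matrix(c(1, 0.2, 0.9, 0.2, 1, 0.5, 0.9, 0.5, 1), 3,
              dimnames = list(c("gB", "gA", "gC"), c("gB", "gA", "gC")))
  e <- export_edges(m, 0.4)
  expect_equal(nrow(e), 2)
  expect_true(all(e$gene_a < e$gene_b))
  expect_equal(e$weight[e$gene_a == "gB" & e$gene_b == "gC"], 0.9)
  expect_equal(nrow(export_edges(m, 1.01)), 0)
  expect_equal(nrow(export_edges(m, 0)), 3)
})
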