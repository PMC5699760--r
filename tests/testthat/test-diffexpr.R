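test_that("fold change follows the log10-ratio convention", {
  expect_equal(compute_fold_change(0.5, 0.5),
               data.frame(fold_change = 1, bias = "none",
                          stringsAsFactors = FALSE))
  expect_equal(compute_fold_change(1, 0),
               data.frame(fold_change = 10, bias = "F",
                          stringsAsFactors = FALSE))
  fc <- compute_fold_change(-0.3, 0.07017)
  expect_equal(fc$fold_change, 10^0.37017, tolerance = 1e-12)
  expect_equal(round(fc$fold_change, 2), 2.35)
  expect_equal(fc$bias, "M")
  expect_error(compute_fold_change(NA, 0), "finite")
  expect_error(compute_fold_change(Inf, 0), "finite")
})

test_that("student_t handles identical, separated and degenerate groups", {
  same <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  sep <- student_t(c(1, 2, 3, 4) * 1e-3 + 10, c(1, 2, 3, 4) * 1e-3)
  expect_lt(sep$p_value, 1e-6)

  degen <- student_t(c(1, 1, 1), c(2, 2, 2))
  expect_equal(degen$p_value, 0)
  expect_true(degen$degenerate)

  expect_error(student_t(c(1, NA, 2), c(1, 2, 3)), "finite")
})

test_that("student_t matches the textbook pooled formula and t.test", {
  hand <- pooled_t_formula(c(2.1, 2.9, 3.0), c(1.0, 1.2, 0.9))
  got <- student_t(c(2.1, 2.9, 3.0), c(1.0, 1.2, 0.9))
  expect_equal(got$t_stat, hand$t, tolerance = 1e-12)
  expect_equal(got$p_value, hand$p, tolerance = 1e-12)

  set.seed(301)
  for (i in 1:100) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), mean = 0.5)
    got <- student_t(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("screening filters strictly and ranks by fold change", {
  res <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    p_value = c(0.01, 0.04, 0.06, 0.01, 0.02, 0.01),
    fold_change = c(2.0, 1.5, 3.0, 1.5, 1.5, 1.2),
    stringsAsFactors = FALSE)
  out <- screen_results(res, p_max = 0.05, fc_min = 1.2)
  # g3 fails p (0.06 not < ... strict), g6 fails fc (1.2 not > 1.2);
  # the fc 1.5 tie resolves by ascending p: g4 (0.01), g5 (0.02), g2 (0.04)
  expect_equal(out$gene_id, c("g1", "g4", "g5", "g2"))
  expect_equal(out$rank, 1:4)
  # ties at fc 1.5 broken by p then gene_id
  expect_equal(screen_results(res, fc_min = Inf)$gene_id, character(0))
  expect_equal(nrow(screen_results(res[0, ], 0.05, 1.1)), 0)
  expect_error(screen_results(res, p_max = 0), "p_max")
  expect_error(screen_results(res, fc_min = 0.5), "fc_min")
})

test_that("raising fc_min or lowering p_max never adds genes", {
  set.seed(17)
  ds <- generate_dataset(simulation_config(
    n_genes = 300, n_male = 30, n_female = 30,
    sex_effects = data.frame(gene = 1:50,
                             log10_fc = runif(50, 0.02, 0.3),
                             bias = sample(c("F", "M"), 50, TRUE)),
    seed = 23))
  counts_fc <- sapply(c(1, 1.1, 1.3, 1.5, 2),
                      function(f) nrow(run_screen(ds$expression, ds$samples,
                                                  0.05, f)))
  expect_true(all(diff(counts_fc) <= 0))
  counts_p <- sapply(c(0.1, 0.05, 0.01, 0.001),
                     function(p) nrow(run_screen(ds$expression, ds$samples,
                                                 p, 1.1)))
  expect_true(all(diff(counts_p) <= 0))
})

test_that("swapping sex labels preserves p and fc and flips bias", {
  ds <- generate_dataset(simulation_config(
    n_genes = 100, n_male = 20, n_female = 25,
    sex_effects = data.frame(gene = 1:10, log10_fc = 0.25,
                             bias = rep(c("F", "M"), 5)),
    seed = 31))
  a <- run_screen(ds$expression, ds$samples, 0.05, 1.1)
  swapped <- ds$samples
  swapped$sex <- ifelse(swapped$sex == "M", "F", "M")
  b <- run_screen(ds$expression, swapped, 0.05, 1.1)
  expect_equal(a$gene_id, b$gene_id)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$fold_change, b$fold_change, tolerance = 1e-12)
  expect_equal(b$bias, ifelse(a$bias == "F", "M",
                              ifelse(a$bias == "M", "F", "none")))
})

test_that("run_screen rejects single-sex designs and constant genes", {
  ds <- generate_dataset(simulation_config(n_genes = 10, n_male = 5,
                                           n_female = 5, seed = 3))
  allf <- ds$samples
  allf$sex <- "F"
  expect_error(run_screen(ds$expression, allf), "both sexes")

  x <- ds$expression
  x[1, ] <- 0.7  # constant in both groups
  expect_warning(out <- run_screen(x, ds$samples, 1, 1),
                 "zero variance")
  expect_false("G00001" %in% attr(out, "all_results")$gene_id)
})

test_that("a strong planted effect ranks first", {
  ds <- generate_dataset(simulation_config(
    n_genes = 200, n_male = 100, n_female = 100,
    sex_effects = data.frame(gene = 42, log10_fc = log10(2), bias = "F"),
    noise_sd = 0.05, seed = 77))
  out <- run_screen(ds$expression, ds$samples, 0.05, 1.0)
  expect_equal(out$gene_id[1], "G00042")
  expect_equal(out$bias[1], "F")
  expect_equal(out$fold_change[1], 2, tolerance = 0.05)
})

test_that("chromosome breakdown counts X, Y, autosomes and unknowns", {
  genes <- data.frame(gene_id = c("a", "b", "c", "d"),
                      chromosome = c("X", "X", "Y", "5"),
                      stringsAsFactors = FALSE)
  expect_equal(chromosome_breakdown(c("a", "b", "c", "d"), genes),
               c(X = 2L, Y = 1L, autosome = 1L, unknown = 0L))
  expect_equal(chromosome_breakdown(character(0), genes),
               c(X = 0L, Y = 0L, autosome = 0L, unknown = 0L))
  expect_warning(out <- chromosome_breakdown(c("a", "zz"), genes),
                 "unknown")
  expect_equal(out[["unknown"]], 1L)

  # 80-gene list planted with 7 X and 12 Y genes
  g80 <- data.frame(
    gene_id = sprintf("g%02d", 1:80),
    chromosome = c(rep("X", 7), rep("Y", 12), rep("2", 61)),
    stringsAsFactors = FALSE)
  expect_equal(chromosome_breakdown(g80$gene_id, g80),
               c(X = 7L, Y = 12L, autosome = 61L, unknown = 0L))
})

test_that("probe collapse keeps the most variable probe per gene", {
  x <- rbind(p1 = rep(1, 6),             # constant
             p2 = c(1, 2, 3, 4, 5, 6),   # variable
             p3 = c(0, 1, 0, 1, 0, 1))
  colnames(x) <- sprintf("s%d", 1:6)
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB")
  out <- collapse_probes(x, map)
  expect_equal(rownames(out), c("gA", "gB"))
  expect_equal(unname(out["gA", ]), c(1, 2, 3, 4, 5, 6))

  # identity when one probe per gene
  one <- collapse_probes(x[2:3, ], map[2:3])
  expect_equal(nrow(one), 2)
  expect_equal(unname(one["gB", ]), unname(x["p3", ]))

  # unmapped probes dropped with a warning
  expect_warning(dropped <- collapse_probes(x, map[1:2]), "unmapped")
  expect_equal(rownames(dropped), "gA")

  # variance tie broken by lexicographically smallest probe id
  y <- rbind(pb = c(0, 1), pa = c(1, 0))
  colnames(y) <- c("s1", "s2")
  tied <- collapse_probes(y, c(pb = "g", pa = "g"))
  expect_equal(unname(tied["g", ]), c(1, 0))
})
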