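test_that("the exact conditional test reproduces enumerated binomial tails", {
  # frozen values: brute-force tail enumeration
  expect_equal(poisson_two_sample_test(0, 0, 1, 1, "greater"), 1)
  expect_equal(poisson_two_sample_test(0, 0, 1, 1, "less"), 1)
  expect_equal(poisson_two_sample_test(10, 20, 1, 1, "greater"),
               53009102 / 2^30, tolerance = 1e-12)
  expect_equal(poisson_two_sample_test(5, 5, 1, 1, "greater"),
               0.623046875, tolerance = 1e-12)
  # unequal exposures shift the null proportion
  for (xr in c(0, 3, 17)) for (xa in c(0, 5, 21)) {
    for (w in list(c(1, 1), c(2, 1), c(1, 2), c(3, 7))) {
      p0 <- w[2] / sum(w)
      expect_equal(
        poisson_two_sample_test(xr, xa, w[1], w[2], "greater"),
        binom_tail_oracle(xa, xr + xa, p0, "greater"), tolerance = 1e-12)
      expect_equal(
        poisson_two_sample_test(xr, xa, w[1], w[2], "less"),
        binom_tail_oracle(xa, xr + xa, p0, "less"), tolerance = 1e-12)
    }
  }
  expect_error(poisson_two_sample_test(-1, 2), "non-negative")
  expect_error(poisson_two_sample_test(1.5, 2), "integer")
  expect_error(poisson_two_sample_test(1, 2, s_ref = 0), "> 0")
})

test_that("the exact test is condition-symmetric and tail-monotone", {
  set.seed(3)
  for (i in 1:50) {
    xr <- rpois(1, 20); xa <- rpois(1, 20)
    w <- runif(2, 0.5, 3)
    expect_equal(
      poisson_two_sample_test(xr, xa, w[1], w[2], "greater"),
      poisson_two_sample_test(xa, xr, w[2], w[1], "less"),
      tolerance = 1e-12)
  }
  p_seq <- poisson_two_sample_test(rep(10L, 31), 0:30, 1, 1, "greater")
  expect_true(all(diff(p_seq) <= 1e-15))
})

test_that("BH adjustment matches frozen cases and stays order-preserving", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(10)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))^2
    p[p == 0] <- 1e-9
    expect_equal(bh_fdr(p), p.adjust(p, method = "BH"), tolerance = 1e-14)
  }
  expect_error(bh_fdr(c(0.5, 0)), "in \\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "in \\(0, 1\\]")
})

test_that("DEG calling matches a hand-enumerated toy matrix", {
  cm <- toy_matrix(c(gene1 = 100, gene2 = 100, gene3 = 100),
                   c(gene1 = 200, gene2 = 101, gene3 = 40))
  sf <- compute_scale_factors(cm)
  res <- call_degs(cm, sf)
  expect_equal(res$call, c("up", "unchanged", "down"))
  # fold changes with pseudocount 1 on equal exposures
  expect_equal(res$fc, c(201 / 101, 102 / 101, 41 / 101), tolerance = 1e-12)
  # p-values from the enumeration oracle, BH over the three genes
  p_oracle <- c(binom_tail_oracle(200, 300, 0.5, "greater"),
                binom_tail_oracle(101, 201, 0.5, "greater"),
                binom_tail_oracle(40, 140, 0.5, "less"))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(res$fdr, p.adjust(p_oracle, "BH"), tolerance = 1e-12)
})

test_that("identical condition profiles yield no calls and spike-ins are never tested", {
  cm <- toy_matrix(c(g1 = 50, g2 = 500), c(g1 = 50, g2 = 500))
  res <- call_degs(cm, compute_scale_factors(cm))
  expect_true(all(res$call == "unchanged"))
  expect_false("ERCC-1" %in% res$gene)
  cm3 <- toy_matrix(c(g1 = 1), c(g1 = 2))
  expect_error(call_degs(cm3, compute_scale_factors(cm3),
                         ref_condition = "missing"), "reference")
  expect_error(call_degs(cm3, compute_scale_factors(cm3),
                         condition_of = c(A = "a", B = "b", C = "c")[1:2]),
               NA)
})

test_that("replicates pool by raw-count summation with pooled exposures", {
  m <- rbind(g1 = c(30, 40, 90, 110), E1 = c(1000, 1100, 950, 1050))
  colnames(m) <- c("c1", "c2", "i1", "i2")
  cm <- count_matrix(m, c(g1 = "protein_coding", E1 = "spikein"),
                     c(c1 = "ctrl", c2 = "ctrl", i1 = "ir", i2 = "ir"))
  res <- call_degs(cm, compute_scale_factors(cm))
  expect_equal(res$count_ref, 70)
  expect_equal(res$count_alt, 200)
  p0 <- 2000 / (2100 + 2000)
  expect_equal(res$p_value, binom_tail_oracle(200, 270, p0, "greater"),
               tolerance = 1e-12)
  # per-replicate-pair mode is more conservative than pooling here
  res_pair <- call_degs(cm, compute_scale_factors(cm), pool = FALSE)
  expect_gte(res_pair$p_value, res$p_value)
})

test_that("null simulations keep the realized false discovery proportion near the BH level", {
  fdp <- vapply(1:8, function(s) {
    sim <- simulate_nascent_experiment(nascent_sim_config(
      n_protein_coding = 1500, n_histone = 0, n_rdna = 0,
      baseline_mean_by_class = c(rdna = 5000, histone = 500,
                                 protein_coding = 150, spikein = 100),
      global_shift = c(rdna = 1, histone = 1, protein_coding = 1, spikein = 1),
      frac_upregulated = 0, rng_seed = 100 + s))
    res <- call_degs(sim$counts, compute_scale_factors(sim$counts))
    sum(res$call != "unchanged") / max(1, nrow(res))
  }, numeric(1))
  # with no true positives every call is false; the realized fraction of
  # genes called stays well below the nominal level
  expect_lte(mean(fdp), 0.05)
})

test_that("z-scores standardize rows and zero out degenerate ones", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(7, 7, 7, 7), c = c(0, 0, 10, 10))
  colnames(m) <- paste0("s", 1:4)
  z <- zscore_matrix(m)
  expect_equal(unname(z$z["a", ]),
               c(-1.161895, -0.387298, 0.387298, 1.161895), tolerance = 1e-6)
  expect_equal(unname(z$z["b", ]), rep(0, 4))
  live <- z$z[z$sd > 0, ]
  expect_equal(unname(rowMeans(live)), rep(0, nrow(live)), tolerance = 1e-12)
  expect_equal(unname(apply(live, 1, sd)), rep(1, nrow(live)),
               tolerance = 1e-12)
})

test_that("top-expression slicing clamps, breaks ties lexicographically, and ranks by control RPKM", {
  res <- data.frame(gene = c("gB", "gA", "gC", "gD"),
                    call = c("up", "down", "up", "unchanged"),
                    stringsAsFactors = FALSE)
  summ <- data.frame(feature_id = c("gA", "gB", "gC", "gD"),
                     rpkm = c(5, 5, 9, 100), stringsAsFactors = FALSE)
  top <- rank_and_slice_top(res, summ, 10)
  expect_equal(top$gene, c("gC", "gA", "gB"))  # gD not a DEG; tie gA < gB
  expect_equal(nrow(rank_and_slice_top(res, summ, 2)), 2)
  expect_error(rank_and_slice_top(res, summ, 0), ">= 1")
})

test_that("length comparisons use exact Wilcoxon tails for small groups", {
  res <- data.frame(gene = sprintf("g%d", 1:6),
                    call = c("up", "up", "up", "down", "down", "down"),
                    stringsAsFactors = FALSE)
  ann <- toy_annotation(sprintf("g%d", 1:6),
                        c(100, 200, 300, 1000, 2000, 3000))
  lc <- compare_lengths(res, ann)
  row <- lc$tests[lc$tests$group1 == "activated" &
                    lc$tests$group2 == "repressed", ]
  expect_equal(row$p_value, 0.1)  # 2/C(6,3), both tails
  expect_equal(row$p_value,
               wilcox_exact_oracle(c(100, 200, 300), c(1000, 2000, 3000)))
  expect_equal(row$method, "exact")
  # unchanged group empty: reported not-applicable, no crash
  na_rows <- lc$tests[lc$tests$group1 == "activated" &
                        lc$tests$group2 == "unchanged", ]
  expect_true(is.na(na_rows$p_value))
  # identical length distributions are not distinguishable
  ann_same <- toy_annotation(sprintf("g%d", 1:6), rep(500, 6))
  lc2 <- compare_lengths(res, ann_same)
  expect_equal(lc2$tests$p_value[lc2$tests$group1 == "activated" &
                                   lc2$tests$group2 == "repressed"], 1)
})
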