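test_that("per-gene statistics reduce to the pooled two-sample t", {
  em <- rand_em(20, 10, seed = 1)
  test <- em_samples(em)[1:5]
  ctrl <- em_samples(em)[6:10]
  st <- per_gene_stats(em, test, ctrl,
                       rotation_config(100, variance_shrinkage = "none"))
  lx <- log2(em$values + 1)
  for (g in em_genes(em)) {
    a <- lx[g, test]; b <- lx[g, ctrl]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    t_ref <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
    row <- st[st$gene == g, ]
    expect_equal(row$t, t_ref, tolerance = 1e-10)
    expect_equal(row$lfc, mean(a) - mean(b), tolerance = 1e-12)
  }
  # identical groups: all statistics zero
  em0 <- em
  em0$values[, ctrl] <- em0$values[, test]
  st0 <- per_gene_stats(em0, test, ctrl, rotation_config(100))
  expect_lt(max(abs(st0$t)), 1e-8)
  expect_lt(max(abs(st0$lfc)), 1e-12)
  expect_error(per_gene_stats(em, test[1], ctrl, rotation_config(100)),
               ">= 2 samples")
})

test_that("a strongly shifted gene dominates the statistics", {
  v <- matrix(rep(c(1, 2, 1, 2, 1, 2, 1, 2), each = 10), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:8)))
  withr::with_seed(2, v <- v + matrix(rnorm(80, 0, 0.01), 10))
  v["g01", 1:4] <- v["g01", 1:4] + 5          # large shift, tiny variance
  em <- make_em(v, scale = "log2")
  st <- per_gene_stats(em, paste0("s", 1:4), paste0("s", 5:8),
                       rotation_config(100, variance_shrinkage = "none"))
  expect_equal(st$gene[which.max(abs(st$t))], "g01")
})

test_that("rotation p-values are seeded, floored above zero, and exchange under relabeling", {
  em <- rand_em(30, 12, seed = 3)
  test <- em_samples(em)[1:6]
  ctrl <- em_samples(em)[7:12]
  set <- em_genes(em)[1:10]
  r1 <- rotation_test(em, test, ctrl, set, rotation_config(499, seed = 7))
  r2 <- rotation_test(em, test, ctrl, set, rotation_config(499, seed = 7))
  expect_identical(r1[c("p_up", "p_down", "p_two_sided")],
                   r2[c("p_up", "p_down", "p_two_sided")])
  expect_gt(r1$p_up, 0)
  expect_gt(r1$p_down, 0)
  expect_lte(r1$p_two_sided, 1)
  # label exchange: p_up and p_down swap exactly, concordance unchanged
  swapped <- rotation_test(em, ctrl, test, set, rotation_config(499, seed = 7))
  expect_identical(swapped$p_up, r1$p_down)
  expect_identical(swapped$p_down, r1$p_up)
  expect_identical(swapped$frac_concordant, r1$frac_concordant)
  expect_error(rotation_test(em, test, ctrl, set[1], rotation_config(99)),
               ">= 2 set genes")
})

test_that("a coordinated 3-SD shift is detected with high power", {
  withr::with_seed(4, {
    v <- matrix(2^rnorm(50 * 20, 6, 1), nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
  })
  em <- make_em(v)
  test <- sprintf("s%02d", 1:10)
  ctrl <- sprintf("s%02d", 11:20)
  set <- sprintf("g%02d", 1:20)
  lx <- log2(v + 1)
  shifted <- em
  sds <- apply(lx[set, ], 1, sd)
  shifted$values[set, test] <- 2^(lx[set, test] + 3 * sds) - 1
  r <- rotation_test(shifted, test, ctrl, set, rotation_config(9999, seed = 5))
  expect_lte(r$p_up, 0.001)
  expect_equal(r$direction, "up")
  expect_gte(r$frac_concordant, 0.8)
})

test_that("the rotation null is calibrated at small simulation scale", {
  # null data: rejection rate of p_up <= 0.1 over 200 simulations should sit
  # inside the exact binomial 99.9% interval
  n_sims <- 200
  alpha <- 0.1
  rejections <- 0
  for (i in seq_len(n_sims)) {
    withr::with_seed(1000 + i, {
      v <- matrix(rnorm(15 * 12), nrow = 15,
                  dimnames = list(sprintf("g%02d", 1:15),
                                  sprintf("s%02d", 1:12)))
    })
    em <- make_em(v, scale = "log2")
    r <- rotation_test(em, sprintf("s%02d", 1:6), sprintf("s%02d", 7:12),
                       sprintf("g%02d", 1:8), rotation_config(99, seed = i))
    if (r$p_up <= alpha) rejections <- rejections + 1
  }
  ci <- qbinom(c(0.0005, 0.9995), n_sims, alpha)
  expect_gte(rejections, ci[1])
  expect_lte(rejections, ci[2])
})

test_that("BH adjustment validates input and matches the step-up computation", {
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  # hand-computed step-up: sort, scale by m/rank, cumulative min from the top
  p <- c(0.003, 0.04, 0.9, 0.012)
  ps <- sort(p)
  adj_sorted <- rev(cummin(rev(ps * 4 / seq_len(4))))
  expect_equal(sort(bh_fdr(p)), adj_sorted)
  expect_equal(bh_fdr(p)[order(p)], adj_sorted)
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("the significance rule applies both thresholds inclusively", {
  expect_true(significance_call(0.005, 0.85))
  expect_false(significance_call(0.005, 0.70))   # strong FDR, weak concordance
  expect_false(significance_call(0.05, 0.95))
  expect_true(significance_call(0.01, 0.80))     # exact boundary, inclusive
  expect_false(significance_call(0.0100001, 0.80))
  expect_false(significance_call(0.01, 0.7999))
  expect_equal(significance_call(c(0.005, 0.02), c(0.9, 0.9)), c(TRUE, FALSE))
})

test_that("set_test_all adjusts within the family and flags the influx pattern", {
  pf <- generate_profiles(250, 5, 10,
                          cell_type_names = c("immune", "kera", "fibro",
                                              "endo", "mel"),
                          seed = 6)
  d <- mixture_design(10, setNames(rep(5, 5), pf$cell_types),
                      noise_sigma = 0.15, seed = 7)
  pair <- generate_condition_pair(pf, d, "immune", 10, 30, 30, seed = 8)
  comb <- expression_matrix(cbind(pair$cases$values, pair$controls$values),
                            scale = "linear")
  res <- set_test_all(comb, pf$marker_map, em_samples(pair$cases),
                      em_samples(pair$controls),
                      cfg = rotation_config(999, seed = 9))
  expect_equal(res$fdr, bh_fdr(res$p_two_sided))
  imm <- res[res$signature == "immune", ]
  expect_true(imm$significant)
  expect_equal(imm$direction, "up")
  down <- res[res$signature != "immune", ]
  expect_gte(sum(down$significant & down$direction == "down"), 3)
})

test_that("rotation p-values agree with limma's roast on the same contrast", {
  skip_if_not_installed("limma")
  withr::with_seed(10, {
    v <- matrix(rnorm(60 * 16, 7, 1), nrow = 60,
                dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:16)))
    v[1:15, 1:8] <- v[1:15, 1:8] + 1.2     # coordinated up-shift
  })
  em <- make_em(v, scale = "log2")
  test <- sprintf("s%02d", 1:8)
  ctrl <- sprintf("s%02d", 9:16)
  set <- sprintf("g%02d", 1:15)
  ours <- rotation_test(em, test, ctrl, set, rotation_config(9999, seed = 11))
  design <- cbind(Intercept = 1, Test = as.numeric(colnames(v) %in% test))
  lr <- limma::roast(v, index = match(set, rownames(v)), design = design,
                     contrast = 2, nrot = 9999, set.statistic = "mean")
  # both see the planted shift as clearly significant in the same direction
  expect_lte(ours$p_up, 0.001)
  expect_lte(lr$p.value["Up", "P.Value"], 0.001)
  # and agree on a null set from the same data
  null_set <- sprintf("g%02d", 31:45)
  ours0 <- rotation_test(em, test, ctrl, null_set,
                         rotation_config(9999, seed = 12))
  lr0 <- limma::roast(v, index = match(null_set, rownames(v)),
                      design = design, contrast = 2, nrot = 9999,
                      set.statistic = "mean")
  expect_gt(ours0$p_two_sided, 0.05)
  expect_gt(lr0$p.value["UpOrDown", "P.Value"], 0.05)
})
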