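test_that("identical cluster sets match themselves with Jaccard 1", {
  cs <- toy_clusterset(list(paste0("a", 1:8), paste0("b", 1:6), paste0("c", 1:5)))
  universe <- sprintf("u%03d", 1:200)
  universe <- c(universe, unlist(cs$clusters))
  m <- match_clusters(cs, cs, universe, min_size = 5)
  expect_equal(nrow(m), 3)
  expect_true(all(m$jaccard == 1))
  expect_true(all(m$cluster_a == m$cluster_b))
})

test_that("disjoint cluster contents yield no matches", {
  cs_a <- toy_clusterset(list(paste0("a", 1:8), paste0("b", 1:6)))
  cs_b <- toy_clusterset(list(paste0("x", 1:8), paste0("y", 1:6)))
  universe <- c(unlist(cs_a$clusters), unlist(cs_b$clusters),
                sprintf("u%03d", 1:100))
  expect_equal(nrow(match_clusters(cs_a, cs_b, universe)), 0)
  expect_error(match_clusters(cs_a, cs_b, character()), "empty universe")
})

test_that("overlap p-values equal the exact hypergeometric tail sum", {
  universe <- sprintf("g%04d", 1:1000)
  shared <- universe[1:15]
  ca <- c(shared, universe[101:105])              # 20 genes
  cb <- c(shared, universe[201:215])              # 30 genes
  cs_a <- toy_clusterset(list(ca))
  cs_b <- toy_clusterset(list(cb))
  m <- match_clusters(cs_a, cs_b, universe, min_jaccard = 0, max_fdr = 1)
  # brute-force sum over k = 15..20 of C(30,k) C(970,20-k) / C(1000,20)
  brute <- sum(sapply(15:20, function(k) {
    choose(30, k) * choose(970, 20 - k) / choose(1000, 20)
  }))
  expect_equal(m$p_value, brute, tolerance = 1e-12)
  expect_equal(m$n_common, 15)
})

test_that("catalog derivation is plain set algebra with provenance", {
  cs_a <- toy_clusterset(list(c("a", "b", "c"), paste0("x", 1:5)))
  cs_b <- toy_clusterset(list(c("b", "c", "d"), paste0("y", 1:5)))
  universe <- c(letters, paste0("x", 1:5), paste0("y", 1:5))
  matches <- data.frame(cluster_a = 2L, cluster_b = 2L)  # size-ordered ids
  cat <- derive_catalog(matches, cs_a, cs_b, names = "sig")
  expect_identical(cat$signatures$sig, c("b", "c"))
  expect_identical(cat$a_specific$sig, "a")
  expect_identical(cat$b_specific$sig, "d")
  # |cluster_A| = n_common + n_A_specific, exactly
  expect_equal(length(cs_a$clusters[[2]]),
               length(cat$signatures$sig) + length(cat$a_specific$sig))
})

test_that("hair-follicle-like counts are reproduced from clusters of 138 and 72", {
  shared <- sprintf("s%03d", 1:62)
  ca <- c(shared, sprintf("a%03d", 1:76))   # 138 genes
  cb <- c(shared, sprintf("b%03d", 1:10))   # 72 genes
  cs_a <- toy_clusterset(list(ca))
  cs_b <- toy_clusterset(list(cb))
  universe <- c(ca, cb, sprintf("u%04d", 1:2000))
  m <- match_clusters(cs_a, cs_b, universe)
  cat <- derive_catalog(m, cs_a, cs_b, names = "hair_follicle")
  ot <- overlap_table(cat)
  row <- ot$rows[ot$rows$signature == "hair_follicle", ]
  expect_equal(row$n_a_specific, 76)
  expect_equal(row$n_b_specific, 10)
  expect_equal(row$n_common, 62)
  expect_equal(row$pct_common_vs_a, 45)
  expect_equal(row$pct_common_vs_b, 86)
})

test_that("dataset-specific clusters can be kept unilaterally but not if matched", {
  cs_a <- toy_clusterset(list(paste0("a", 1:8), paste0("k", 1:5)))
  cs_b <- toy_clusterset(list(paste0("a", 1:8)))
  universe <- c(unlist(cs_a$clusters), sprintf("u%03d", 1:100))
  m <- match_clusters(cs_a, cs_b, universe)
  expect_equal(nrow(m), 1)
  cat <- derive_catalog(m, cs_a, cs_b, keep_dataset_specific = list(
    list(dataset = "A", cluster = 2L, name = "a_only")
  ))
  expect_identical(cat$dataset_specific$a_only, sort(paste0("k", 1:5)))
  expect_identical(unname(cat$dataset_of["a_only"]), "A")
  expect_error(
    derive_catalog(m, cs_a, cs_b, keep_dataset_specific = list(
      list(dataset = "A", cluster = m$cluster_a[1])
    )),
    "matched"
  )
  # no matches, one keep-listed cluster -> exactly one dataset-specific signature
  none <- m[0, ]
  cat0 <- derive_catalog(none, cs_a, cs_b, keep_dataset_specific = list(
    list(dataset = "B", cluster = 1L)
  ))
  expect_length(cat0$signatures, 0)
  expect_length(cat0$dataset_specific, 1)
})

test_that("overlap percentages round half away from zero and summarize correctly", {
  mk <- function(nc, na, nb, nm) {
    genes <- sprintf("%s_c%03d", nm, seq_len(nc))
    list(sig = genes, a = sprintf("%s_a%03d", nm, seq_len(na)),
         b = if (nb > 0) sprintf("%s_b%03d", nm, seq_len(nb)) else character())
  }
  seb <- mk(105, 17, 229, "seb")     # 86% / 31%
  endo <- mk(40, 150, 18, "endo")    # 21% / 69%
  mel <- mk(7, 1, 10, "mel")         # 87.5 -> 88% / 41%
  cat <- signature_catalog(
    list(seb = seb$sig, endo = endo$sig, mel = mel$sig),
    a_specific = list(seb = seb$a, endo = endo$a, mel = mel$a),
    b_specific = list(seb = seb$b, endo = endo$b, mel = mel$b)
  )
  ot <- overlap_table(cat)
  expect_equal(ot$rows$pct_common_vs_a, c(86, 21, 88))
  expect_equal(ot$rows$pct_common_vs_b, c(31, 69, 41))
  expect_equal(ot$summary$mean_pct_vs_a, mean(c(86, 21, 88)))
  expect_equal(ot$summary$sd_pct_vs_a, sd(c(86, 21, 88)))
  expect_equal(ot$summary$n_shared, 3)
  expect_error(signature_catalog(list(s = c("a", "b")),
                                 a_specific = list(s = "a")), "disjoint")
})

test_that("derived catalogs recover ground-truth markers on two-platform cohorts", {
  study <- two_platform_study(n_genes = 400, n_types = 4, markers = 12,
                              n_samples = 120, seed = 41)
  both <- intersect_genes(filter_expressed(study$a$matrix),
                          filter_expressed(study$b$matrix))
  cs_a <- mcl_cluster(correlation_graph(both$a, 0.7))
  cs_b <- mcl_cluster(correlation_graph(both$b, 0.7))
  m <- match_clusters(cs_a, cs_b, em_genes(both$a))
  cat <- derive_catalog(m, cs_a, cs_b)
  universe <- em_genes(both$a)
  hits <- 0
  for (ct in names(study$profiles$marker_map)) {
    truth <- intersect(study$profiles$marker_map[[ct]], universe)
    best <- which.max(vapply(cat$signatures,
                             function(s) length(intersect(s, truth)), 0L))
    sig <- cat$signatures[[best]]
    recovery <- length(intersect(sig, truth)) / length(truth)
    intruders <- length(setdiff(sig, truth)) / length(sig)
    expect_gte(recovery, 0.9)
    expect_lte(intruders, 0.05)
    hits <- hits + 1
  }
  expect_equal(hits, 4)
})

test_that("signature splitting finds planted subprograms only when cases are present", {
  # parent signature = markers of a structural type plus markers of a
  # disease-linked type that is absent from controls; in controls the two
  # blocks cannot decouple, with cases they must
  pf <- generate_profiles(200, 4, 15,
                          cell_type_names = c("kera", "disease", "immune", "other"),
                          seed = 51)
  ctrl_conc <- c(kera = 5, disease = 0, immune = 5, other = 5)
  case_conc <- c(kera = 5, disease = 5, immune = 5, other = 5)
  ctrl <- generate_cohort(pf, mixture_design(60, ctrl_conc, noise_sigma = 0.15,
                                             seed = 52))
  cases <- generate_cohort(pf, mixture_design(60, case_conc, noise_sigma = 0.15,
                                              seed = 53))
  colnames(cases$matrix$values) <- sub("^seq-like", "case", colnames(cases$matrix$values))
  comb <- expression_matrix(cbind(ctrl$matrix$values, cases$matrix$values),
                            scale = "linear")
  sig <- c(pf$marker_map$kera, pf$marker_map$disease)
  ctrl_ids <- em_samples(ctrl$matrix)
  case_ids <- setdiff(em_samples(comb), ctrl_ids)

  only_ctrl <- split_signature(sig, comb, sample_subset = ctrl_ids,
                               r_threshold = 0.7, test_samples = case_ids,
                               control_samples = ctrl_ids)
  expect_false(only_ctrl$split)

  full <- split_signature(sig, comb, r_threshold = 0.7,
                          test_samples = case_ids, control_samples = ctrl_ids)
  expect_true(full$split)
  # ground-truth block membership is the oracle
  expect_gte(length(intersect(full$up_set, pf$marker_map$disease)) /
               length(full$up_set), 0.9)
  expect_gte(length(intersect(full$down_set, pf$marker_map$kera)) /
               length(full$down_set), 0.9)
  # subgroup ratio is higher and more variable across cases
  expect_gt(mean(full$ratio[case_ids]), mean(full$ratio[ctrl_ids]))
  expect_gt(sd(full$ratio[case_ids]), sd(full$ratio[ctrl_ids]))
  expect_error(split_signature(sig, comb, r_threshold = 0.7,
                               test_samples = case_ids,
                               control_samples = c(ctrl_ids, case_ids[1])),
               "disjoint")
})

test_that("catalogs round-trip through GMT export", {
  cat <- signature_catalog(
    list(s1 = c("a", "b"), s2 = c("c", "d", "e")),
    a_specific = list(s1 = "x", s2 = character()),
    b_specific = list(s1 = character(), s2 = "y"),
    dataset_specific = list(only_a = c("p", "q")),
    dataset_of = c(only_a = "A")
  )
  path <- withr::local_tempfile(fileext = ".gmt")
  write_catalog(cat, path)
  back <- read_gmt(path)
  expect_identical(back$s1, c("a", "b"))
  expect_identical(back$only_a, c("p", "q"))
  expect_match(attr(back, "descriptions")[["s1"]], "a_specific=1")
})
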