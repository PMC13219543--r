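test_that("CPM normalization scales columns to a million", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  expect_equal(unname(normalize_counts(m)[, 1]), c(250000, 250000, 500000))
  set.seed(41)
  m2 <- matrix(rpois(30, 50), 10, 3,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  cpm <- normalize_counts(m2)
  expect_equal(unname(colSums(cpm)), rep(1e6, 3), tolerance = 1e-6)
  expect_equal(normalize_counts(cpm), cpm)                 # idempotent
  m3 <- m2; m3[, 2] <- m3[, 2] * 7
  expect_equal(normalize_counts(m3), cpm)                  # scale invariant
  m2[, 1] <- 0
  expect_error(normalize_counts(m2), "all-zero")
})

test_that("translational efficiency is the double ratio of cell means", {
  # identical case/control ratios: te_log2 exactly 0
  e0 <- tiny_experiment(case_poly = c(100, 40), case_mono = c(50, 20),
                        ctrl_poly = c(100, 40), ctrl_mono = c(50, 20))
  te0 <- compute_te(e0)
  expect_equal(te0$te_log2, c(0, 0))
  expect_equal(te0$te_fc, c(1, 1))
  # case poly/mono mean CPM 200/100 vs control 100/100 -> te_log2 ~ 1
  # (two genes so CPM is determined; gene 2 is the complement)
  e1 <- tiny_experiment(case_poly = c(200, 800), case_mono = c(100, 900),
                        ctrl_poly = c(100, 900), ctrl_mono = c(100, 900))
  cpm <- normalize_counts(e1)
  expect_equal(unname(cpm["g01", "case_polysome_r1"]), 2e5)
  te1 <- compute_te(e1)
  expect_equal(te1$te_log2[1], 1, tolerance = 2e-3)  # pseudocount negligible
  expect_equal(te1$te_fc[1], 2, tolerance = 5e-3)
})

test_that("an all-zero gene gets a missing TE, not zero", {
  e <- tiny_experiment(case_poly = c(100, 0), case_mono = c(50, 0),
                       ctrl_poly = c(80, 0), ctrl_mono = c(60, 0))
  te <- compute_te(e)
  expect_true(is.na(te$te_log2[2]))
  expect_false(is.na(te$te_log2[1]))
})

test_that("swapping case and control labels negates te_log2 exactly", {
  g <- gen_polysome_counts(count_spec(n_genes = 200, seed = 9))
  e <- g$experiment
  te <- compute_te(e)
  swapped <- e$samples
  swapped$genotype <- ifelse(swapped$genotype == "case", "control", "case")
  te_sw <- compute_te(polysome_experiment(e$counts, swapped))
  expect_identical(te_sw$te_log2, -te$te_log2)
})

test_that("rescaling any raw library leaves te_log2 unchanged", {
  g <- gen_polysome_counts(count_spec(n_genes = 150, seed = 10))
  e <- g$experiment
  te <- compute_te(e)
  counts2 <- e$counts
  counts2[, 3] <- counts2[, 3] * 4.5
  counts2[, 8] <- counts2[, 8] * 0.21
  te2 <- compute_te(polysome_experiment(counts2, e$samples))
  expect_equal(te2$te_log2, te$te_log2, tolerance = 1e-10)
})

test_that("the ratio matrix pairs replicates and drops unpaired ones", {
  g <- gen_polysome_counts(count_spec(n_genes = 50, reps = 3, seed = 11))
  rm_ <- ratio_matrix(g$experiment)
  expect_equal(dim(rm_$X), c(6, 50))
  expect_equal(rm_$genotype, rep(c("case", "control"), each = 3))
  # drop one polysome library: its replicate becomes unpaired
  e <- g$experiment
  keep <- e$samples$sample_id != "mut_poly_r3"
  e2 <- polysome_experiment(e$counts[, keep], e$samples[keep, ])
  expect_warning(rm2 <- ratio_matrix(e2), "unpaired")
  expect_equal(nrow(rm2$X), 5)
})

test_that("saTE selection needs both the TE fold change and the VIP", {
  te <- data.frame(gene_id = c("a", "b", "c", "d"),
                   te_log2 = c(-0.5, -0.2, 0.4, NA))
  te$te_fc <- 2^abs(te$te_log2)
  vip <- c(a = 1.3, b = 2.0, c = 0.4, d = 1.5)
  res <- select_sate(te, vip)
  expect_equal(res$selected, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$direction, c("low", "low", "high", NA))
  # te_fc ~ 1.149 < 1.25 for b regardless of its large VIP
  expect_false(res$selected[res$gene_id == "b"])
  expect_error(select_sate(te, c(vip, zz = 1)), "absent from the TE table")
})

test_that("polysome/monosome totals give the bulk translation ratio", {
  e <- tiny_experiment(case_poly = c(2e6, 1e6), case_mono = c(1e6, 5e5),
                       ctrl_poly = c(1e6, 5e5), ctrl_mono = c(1e6, 5e5))
  r <- polysome_monosome_ratio(e)
  expect_equal(r$ratio[r$genotype == "case"], 2)
  expect_equal(r$ratio[r$genotype == "control"], 1)
  expect_equal(r$mean, r$ratio)  # identical replicates
  expect_equal(r$sem, c(0, 0))
  expect_equal(r$n, c(2, 2))
  # gene order cannot matter
  e2 <- polysome_experiment(e$counts[2:1, ], e$samples)
  expect_equal(polysome_monosome_ratio(e2), r)
})

test_that("fit_te_plsda separates planted genotype effects", {
  g <- gen_polysome_counts(count_spec(n_genes = 300, planted_fraction = 0.3,
                                      effect_te_log2 = 2, dispersion = 0.01,
                                      seed = 12))
  for (src in c("ratio", "monosome", "polysome")) {
    m <- fit_te_plsda(g$experiment, source = src)
    expect_s3_class(m, "plsda_model")
    expect_equal(attr(m, "source"), src)
  }
  m <- fit_te_plsda(g$experiment, source = "ratio")
  expect_gt(m$var_explained_y[1], 0.9)
  # planted genes dominate the VIP ranking
  vip <- vip_scores(m)
  top <- names(sort(vip, decreasing = TRUE))[1:50]
  truth <- g$truth$gene_id[g$truth$planted]
  expect_gt(mean(top %in% truth), 0.9)
})
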