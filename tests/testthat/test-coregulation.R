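make_t <- function(ids, lfc = 0, padj = 1)
  data.frame(gene_id = ids, log2fc = lfc, padj = padj)
make_p <- function(ids, lfc = 0, pval = 1)
  data.frame(gene_id = ids, log2fc = lfc, pval = pval)

test_that("merging keeps the gene_id intersection and reports the rest", {
  m <- suppressMessages(merge_coreg_tables(make_t(c("g1", "g2", "g3")),
                                           make_p(c("g2", "g3", "g4"))))
  expect_setequal(m$gene_id, c("g2", "g3"))
  expect_equal(attr(m, "unmatched"), c(transcripts = 1L, proteins = 1L))
  expect_warning(suppressMessages(
    merge_coreg_tables(make_t("g1"), make_p("g9"))), "no gene_id shared")
  expect_error(suppressMessages(
    merge_coreg_tables(make_t(c("g1", "g1")), make_p("g1"))), "duplicate.*g1")
  # self-join: one record per gene
  tt <- make_t(c("a", "b"), lfc = c(1, -1))
  self <- suppressMessages(
    merge_coreg_tables(tt, make_p(c("a", "b"), lfc = c(1, -1))))
  expect_equal(nrow(self), 2)
})

records <- function(t, p, pv = 0.01)
  data.frame(gene_id = sprintf("g%d", seq_along(t)), t_log2fc = t,
             t_padj = 0.01, p_log2fc = p, p_pval = pv)

test_that("quadrant classification follows the sign and cutoff rules", {
  r <- records(t = c(1, 1, 1, -1, -1, 0, 1, 1),
               p = c(1, -1, 0.3, 1, -1, 1, 1, 1),
               pv = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.2, NA))
  q <- suppressWarnings(classify_quadrants(r))
  expect_equal(q$assignments$quadrant,
               c("Q1", "Q4", "excluded",  # 2^0.3 ~ 1.23 < 1.5
                 "Q2", "Q3",
                 "excluded",              # t_log2fc == 0: sign undefined
                 "excluded",              # protein p over cutoff
                 "excluded"))             # missing protein p
  expect_warning(classify_quadrants(r), "lack a protein p-value")
  # relaxed preset admits the |FC| > 1.2 protein
  q2 <- suppressWarnings(classify_quadrants(r, preset = "relaxed"))
  expect_equal(q2$assignments$quadrant[3], "Q1")
  expect_equal(q2$fc_cutoff, 1.2)
  # strict transcript mode filters on the transcript side too
  r3 <- records(t = c(1, 0.3), p = c(1, 1))
  q3 <- classify_quadrants(r3, strict_transcripts = TRUE)
  expect_equal(q3$assignments$quadrant, c("Q1", "excluded"))
  expect_error(classify_quadrants(r, fc_cutoff = 1), "fc_cutoff")
})

test_that("assignments partition the genes and behave monotonically", {
  set.seed(31)
  r <- records(t = rnorm(500), p = rnorm(500), pv = runif(500))
  q <- classify_quadrants(r)
  tab <- table(q$assignments$quadrant)
  expect_equal(sum(tab), 500)                      # a partition
  expect_equal(sum(q$counts) + q$n_excluded, 500)
  expect_true(all(q$assignments$quadrant %in%
                    c("Q1", "Q2", "Q3", "Q4", "excluded")))
  if (q$n_assigned > 0)
    expect_equal(sum(q$percentages), 100, tolerance = 0.01)
  # raising fc_cutoff / lowering p_cutoff never rescues an excluded gene
  excl <- q$assignments$gene_id[q$assignments$quadrant == "excluded"]
  for (par in list(list(fc = 2.0, p = 0.05), list(fc = 1.5, p = 0.01))) {
    q2 <- classify_quadrants(r, fc_cutoff = par$fc, p_cutoff = par$p)
    excl2 <- q2$assignments$gene_id[q2$assignments$quadrant == "excluded"]
    expect_true(all(excl %in% excl2))
  }
})

test_that("negating both fold changes swaps Q1<->Q3 and Q2<->Q4 exactly", {
  set.seed(32)
  r <- records(t = rnorm(400), p = rnorm(400, sd = 1.5), pv = runif(400))
  q <- classify_quadrants(r)$assignments$quadrant
  r2 <- r
  r2$t_log2fc <- -r$t_log2fc
  r2$p_log2fc <- -r$p_log2fc
  q2 <- classify_quadrants(r2)$assignments$quadrant
  swap <- c(Q1 = "Q3", Q2 = "Q4", Q3 = "Q1", Q4 = "Q2", excluded = "excluded")
  expect_identical(q2, unname(swap[q]))
})

test_that("quadrant summary normalizes over assigned genes and subsets", {
  r <- records(t = rep(1, 10), p = rep(1, 10))
  q <- classify_quadrants(r)
  s <- quadrant_summary(q)
  expect_equal(s$summary$percentage[s$summary$quadrant == "Q1"], 100)
  # planted 40/10/10/40 table recovered exactly
  g <- gen_coreg_table(omics_spec(n_genes = 1000, fc_sd = 0, seed = 5))
  rec <- suppressMessages(merge_coreg_tables(g$transcripts, g$proteins))
  qq <- classify_quadrants(rec)
  ss <- quadrant_summary(qq, subset = g$truth$gene_id[g$truth$label %in% c("Q1", "Q4")])
  expect_equal(ss$summary$percentage, c(40, 10, 10, 40))
  expect_equal(sum(ss$subset_summary$percentage), 100)
  expect_equal(ss$subset_summary$percentage[c(1, 4)], c(50, 50))
  # all-excluded input errors
  r0 <- records(t = 1, p = 0.1)
  expect_error(quadrant_summary(classify_quadrants(r0)), "excluded")
})

test_that("hypergeometric p matches closed form and brute-force enumeration", {
  res <- hypergeom_enrichment(paste0("g", 1:4),
                              list(t1 = paste0("g", 1:5)),
                              paste0("g", 1:10))
  expect_equal(res$pval, 5 / 210)  # C(5,4) C(5,0) / C(10,4)
  # term == universe: overlap certain
  res2 <- hypergeom_enrichment(paste0("g", 1:3),
                               list(all = paste0("g", 1:8)),
                               paste0("g", 1:8))
  expect_equal(res2$pval, 1)
  # exhaustive-draw oracle over all small configurations
  for (N in c(5, 8, 12)) {
    univ <- paste0("g", seq_len(N))
    for (K in c(2, ceiling(N / 2), N - 1)) {
      for (n in c(2, ceiling(N / 3))) {
        sel <- utils::tail(univ, n)  # deterministic draw
        res <- hypergeom_enrichment(sel, list(t = univ[seq_len(K)]), univ)
        x <- res$overlap
        expect_equal(res$pval, enumerate_hypergeom_p(N, K, n, x),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("enrichment applies BH across terms and validates inputs", {
  set.seed(33)
  univ <- paste0("g", 1:50)
  ann <- list(a = univ[1:10], b = univ[5:30], c = univ[40:50], d = univ[1:2])
  res <- hypergeom_enrichment(univ[1:12], ann, univ)
  expect_true(all(res$padj >= res$pval))
  expect_equal(res$padj, p.adjust(res$pval, "BH"))
  expect_true(!is.unsorted(res$pval))
  expect_true(all(res$overlap <= pmin(res$selected_size, res$term_size)))
  expect_error(hypergeom_enrichment(character(), ann, univ), "empty selection")
  expect_error(hypergeom_enrichment("g1", ann, character()), "empty universe")
  expect_error(hypergeom_enrichment("zz", ann, univ), "outside the universe")
})
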