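test_that("cpm normalization scales each sample to one million", {
  lib <- make_library(n_genes = 1, sgrnas_per_gene = 2, n_controls = 0)
  samples <- make_samples(cell_lines = "A", days = c(1, 21))
  m <- matrix(c(1L, 3L, 2L, 2L), nrow = 2,
              dimnames = list(lib$sgrna_id, samples$sample_id))
  norm <- normalize_cpm(screen_counts(m, samples))
  expect_equal(unname(norm$cpm[, 1]), c(250000, 750000))
  sc <- make_counts(make_library(5, 3, 2), make_samples())
  norm <- normalize_cpm(sc)
  expect_equal(unname(colSums(norm$cpm)), rep(1e6, ncol(sc$counts)),
               tolerance = 1e-9)

  z <- m
  z[, 2] <- 0L
  expect_error(normalize_cpm(screen_counts(z, samples)),
               samples$sample_id[2], fixed = TRUE)
  expect_error(normalize_cpm(screen_counts(m, samples), pseudocount = -1),
               "pseudocount")
})

test_that("sgrna_lfc is zero at the reference day and matches hand ratios", {
  lib <- make_library(n_genes = 1, sgrnas_per_gene = 2, n_controls = 0)
  samples <- make_samples(cell_lines = "A", days = c(1, 21))
  # equal totals (1000) so cpm ratios equal count ratios exactly
  m <- matrix(c(64L, 936L, 2L, 998L), nrow = 2,
              dimnames = list(lib$sgrna_id, samples$sample_id))
  lf <- sgrna_lfc(normalize_cpm(screen_counts(m, samples), pseudocount = 0))
  ref <- lf[lf$day == 1, ]
  expect_true(all(ref$lfc == 0))
  # 2/64 = 1/32 -> -5 log2 units, the 32-fold depletion scale
  expect_equal(lf$lfc[lf$day == 21 & lf$sgrna_id == lib$sgrna_id[1]], -5)

  # unchanged abundance -> lfc 0
  m2 <- matrix(c(50L, 950L, 50L, 950L), nrow = 2,
               dimnames = dimnames(m))
  lf2 <- sgrna_lfc(normalize_cpm(screen_counts(m2, samples)))
  expect_equal(lf2$lfc[lf2$day == 21], c(0, 0), tolerance = 1e-12)

  # guide absent at both days: pseudocount forces lfc 0
  m3 <- matrix(c(0L, 1000L, 0L, 1000L), nrow = 2, dimnames = dimnames(m))
  lf3 <- sgrna_lfc(normalize_cpm(screen_counts(m3, samples),
                                 pseudocount = 0.5))
  expect_equal(lf3$lfc[lf3$day == 21 & lf3$sgrna_id == lib$sgrna_id[1]], 0)
  expect_true(all(is.finite(lf3$lfc)))
})

test_that("replicates are averaged on the cpm scale before the ratio", {
  lib <- make_library(n_genes = 1, sgrnas_per_gene = 1, n_controls = 1)
  samples <- make_samples(cell_lines = "A", days = c(1, 21), replicates = 2)
  # day-21 replicates 100 and 300 cpm-equivalents -> mean 200 vs ref 100
  m <- matrix(c(100L, 900L, 100L, 900L, 100L, 900L, 300L, 700L), nrow = 2,
              dimnames = list(lib$sgrna_id, samples$sample_id))
  lf <- sgrna_lfc(normalize_cpm(screen_counts(m, samples), pseudocount = 0))
  expect_equal(lf$lfc[lf$day == 21 & lf$sgrna_id == lib$sgrna_id[1]],
               log2(200 / 100))
})

test_that("gene_score is the mean sgRNA lfc, excludes controls, is linear", {
  lib <- make_library(n_genes = 2, sgrnas_per_gene = 3, n_controls = 2)
  targeting <- lib$sgrna_id[!lib$is_control]
  lf <- make_lfc(lib$sgrna_id, "B", 21,
                 c(-1, -2, -3, 0, 0, 0, 5, 5))
  cs <- gene_score(lf, lib)
  expect_equal(nrow(cs), 2L)            # controls excluded
  expect_equal(cs$cs[cs$gene_id == "gene01"], -2)
  expect_equal(cs$cs[cs$gene_id == "gene02"], 0)
  expect_equal(cs$n_sgrna, c(3L, 3L))

  for (k in c(-2, 0.5, 3)) {
    lfk <- lf
    lfk$lfc <- lf$lfc * k
    expect_equal(gene_score(lfk, lib)$cs, cs$cs * k)
  }

  # uniformly depleted gene scores negative (other gene absent -> warning)
  dep <- make_lfc(targeting[1:3], "B", 21, c(-4, -5, -6))
  expect_warning(dep_cs <- gene_score(dep, lib), "dropped")
  expect_lt(dep_cs$cs, 0)
})

test_that("one-sample t p-values match the numeric oracle to 1e-9", {
  lib <- make_library(n_genes = 1, sgrnas_per_gene = 8, n_controls = 0)
  ids <- lib$sgrna_id
  # a small worked example checked against the oracle
  lf <- make_lfc(ids[1:3], "B", 21, c(-1.0, 0.5, -0.2))
  got <- gene_test(lf, lib)$pvalue
  expect_equal(got, t_pvalue_oracle(c(-1.0, 0.5, -0.2)), tolerance = 1e-9)

  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    x <- round(rnorm(n, sd = 2), 3)
    if (sd(x) < 1e-8) next
    lf <- make_lfc(ids[seq_len(n)], "B", 21, x)
    expect_equal(gene_test(lf, lib)$pvalue, t_pvalue_oracle(x),
                 tolerance = 1e-9)
  }
})

test_that("degenerate t cases follow the deterministic rules", {
  lib <- make_library(n_genes = 1, sgrnas_per_gene = 3, n_controls = 0)
  ids <- lib$sgrna_id
  expect_equal(gene_test(make_lfc(ids, "B", 21, c(-2, -2, -2)), lib)$pvalue, 0)
  expect_equal(gene_test(make_lfc(ids, "B", 21, c(0, 0, 0)), lib)$pvalue, 1)
  expect_warning(
    p1 <- gene_test(make_lfc(ids[1], "B", 21, -3), lib)$pvalue,
    "single sgRNA")
  expect_equal(p1, 1)
})

test_that("KS test compares gene guides to the control distribution", {
  lib <- make_library(n_genes = 2, sgrnas_per_gene = 4, n_controls = 20)
  set.seed(7)
  ctrl_lfc <- rnorm(20, 0, 0.1)
  lf <- make_lfc(lib$sgrna_id, "B", 21,
                 c(rep(-5, 4), rnorm(4, 0, 0.1), ctrl_lfc))
  ks <- gene_test(lf, lib, method = "ks")
  expect_lt(ks$pvalue[ks$gene_id == "gene01"], 0.01)
  expect_gt(ks$pvalue[ks$gene_id == "gene02"], 0.1)
  no_ctrl <- make_library(n_genes = 2, sgrnas_per_gene = 4, n_controls = 0)
  expect_error(gene_test(make_lfc(no_ctrl$sgrna_id, "B", 21,
                                  rnorm(8)), no_ctrl, method = "ks"),
               "control")
})

test_that("BH adjustment is available behind a flag", {
  lib <- make_library(n_genes = 3, sgrnas_per_gene = 3, n_controls = 0)
  set.seed(3)
  lf <- make_lfc(lib$sgrna_id, "B", 21, rnorm(9))
  out <- gene_test(lf, lib, adjust = "BH")
  expect_true("padj" %in% names(out))
  expect_equal(out$padj, p.adjust(out$pvalue, "BH"))
  expect_false("padj" %in% names(gene_test(lf, lib)))
})

test_that("ecdf curves are monotone, reach 1, and shift with translation", {
  lf <- make_lfc(paste0("s", 1:3), "A", 21, c(-1, 0, 1))
  ec <- ecdf_curve(lf, "A", 21)
  expect_equal(ec$value, c(-1, 0, 1))
  expect_equal(ec$fraction, c(1 / 3, 2 / 3, 1))

  # reference day: all-zero values collapse to a single step at 0
  ref <- make_lfc(paste0("s", 1:5), "A", 1, rep(0, 5))
  ec0 <- ecdf_curve(ref, "A", 1)
  expect_equal(ec0$value, 0)
  expect_equal(ec0$fraction, 1)

  set.seed(11)
  for (i in 1:20) {
    v <- round(rnorm(sample(2:30, 1)), 2)
    lf <- make_lfc(paste0("s", seq_along(v)), "A", 4, v)
    ec <- ecdf_curve(lf, "A", 4)
    expect_true(all(diff(ec$fraction) > 0))
    expect_equal(ec$fraction[length(ec$fraction)], 1)
    shifted <- lf
    shifted$lfc <- lf$lfc - 0.7
    ec2 <- ecdf_curve(shifted, "A", 4)
    expect_equal(ec2$value, ec$value - 0.7)
    expect_equal(ec2$fraction, ec$fraction)
  }

  expect_error(ecdf_curve(lf, "Z", 4), "no lfc values")
})
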