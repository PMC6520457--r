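test_that("simulated libraries have the configured geometry", {
  cfg <- sim_config(n_genes = 50, sgrnas_per_gene = 3, n_controls = 4,
                    seed = 2)
  lib <- simulate_library(cfg)
  expect_equal(nrow(lib), 50 * 3 + 4)
  expect_equal(sum(lib$is_control), 4L)
  per_gene <- table(lib$gene_id[!lib$is_control])
  expect_true(all(per_gene == 3))
  expect_false(anyDuplicated(lib$spacer) > 0)
  expect_true(all(nchar(lib$spacer) == 20))
  expect_true(all(grepl("^[ACGT]+$", lib$spacer)))
  # determinism by seed
  expect_identical(lib, simulate_library(cfg))
  cfg2 <- sim_config(n_genes = 50, sgrnas_per_gene = 3, n_controls = 4,
                     seed = 3)
  expect_false(identical(simulate_library(cfg2)$spacer, lib$spacer))
})

test_that("planted fitness follows the archetype sign grid", {
  cfg <- sim_config(n_genes = 900, coverage = 10, seed = 4,
                    class_fractions = rep(1 / 9, 9))
  lib <- simulate_library(cfg)
  truth <- assign_fitness(lib, cfg)
  g <- truth$genes
  expect_equal(sort(unique(g$true_group)), 1:9)
  # group 8 archetype: neutral in A, depleted in B
  g8 <- g[g$true_group == 8, ]
  expect_true(all(g8$f_a == 0))
  expect_true(all(g8$f_b == -cfg$effect_size))
  # group 2: neutral in A, enriched in B at the enrichment scale
  g2 <- g[g$true_group == 2, ]
  expect_true(all(g2$f_a == 0))
  expect_true(all(g2$f_b == cfg$effect_size * cfg$enrichment_scale))
  # group 5: doubly neutral
  g5 <- g[g$true_group == 5, ]
  expect_true(all(g5$f_a == 0 & g5$f_b == 0))
  # signs of (f_a, f_b) recover the declared group for every gene
  sa <- sign(g$f_a); sb <- sign(g$f_b)
  implied <- (2L - sb) * 3L + (sa + 2L) - 3L
  expect_equal(implied, g$true_group)
  # efficiencies in [0, 1], controls neutral
  expect_true(all(truth$sgrnas$efficiency >= 0 &
                    truth$sgrnas$efficiency <= 1))
  ctrl <- truth$sgrnas$gene_id == "non-targeting"
  expect_true(all(truth$sgrnas$efficiency[ctrl] == 1))

  all5 <- sim_config(n_genes = 30, class_fractions = c(0, 0, 0, 0, 1, 0,
                                                       0, 0, 0), seed = 1)
  t5 <- assign_fitness(simulate_library(all5), all5)
  expect_true(all(t5$genes$f_a == 0 & t5$genes$f_b == 0))

  expect_error(sim_config(class_fractions = rep(0.1, 9)), "sum to 1")
  expect_error(sim_config(class_fractions = rep(0.2, 5)), "9")
})

test_that("simulated counts conserve the multinomial total and the seed", {
  cfg <- sim_config(n_genes = 100, coverage = 50, seed = 8)
  scr <- simulate_screen(cfg)
  n <- nrow(scr$library)
  expect_true(all(colSums(scr$counts$counts) == round(cfg$coverage * n)))
  expect_identical(scr$counts$counts, simulate_screen(cfg)$counts$counts)
  cfg2 <- sim_config(n_genes = 100, coverage = 50, seed = 9)
  expect_false(identical(simulate_screen(cfg2)$counts$counts,
                         scr$counts$counts))

  # Dirichlet-multinomial sampling keeps the conservation law and
  # inflates variance relative to the multinomial
  cfgd <- sim_config(n_genes = 100, coverage = 50, seed = 8,
                     dispersion = 0.01)
  scrd <- simulate_screen(cfgd)
  expect_true(all(colSums(scrd$counts$counts) == round(cfg$coverage * n)))
  d1 <- scrd$counts$counts[, "A_d1_r1"]
  m1 <- scr$counts$counts[, "A_d1_r1"]
  expect_gt(var(as.numeric(d1)), var(as.numeric(m1)))
})

test_that("all-neutral screens have near-zero expected lfc everywhere", {
  cfg <- sim_config(n_genes = 400, coverage = 500,
                    class_fractions = c(0, 0, 0, 0, 1, 0, 0, 0, 0),
                    seed = 12)
  scr <- simulate_screen(cfg)
  lf <- sgrna_lfc(normalize_cpm(scr$counts))
  later <- lf[lf$day != 1, ]
  expect_lt(abs(mean(later$lfc)), 0.02)
  expect_lt(max(abs(tapply(later$lfc, later$day, mean))), 0.03)
})

test_that("planted 32-fold depletion is recovered in expectation", {
  # sparse group-8 class so relative-abundance renormalization is negligible;
  # high coverage shrinks counting noise
  cfg <- sim_config(n_genes = 1000, coverage = 2000,
                    class_fractions = c(0, 0, 0, 0, 0.98, 0, 0, 0.02, 0),
                    seed = 3)
  scr <- simulate_screen(cfg)
  lf <- sgrna_lfc(normalize_cpm(scr$counts))
  g8 <- scr$truth$genes$gene_id[scr$truth$genes$true_group == 8]
  sg8 <- scr$library$sgrna_id[scr$library$gene_id %in% g8]
  realized <- mean(lf$lfc[lf$cell_line == "B" & lf$day == 21 &
                            lf$sgrna_id %in% sg8])
  mean_eff <- with(cfg$efficiency_dist, shape1 / (shape1 + shape2))
  expect_equal(realized, -5 * mean_eff, tolerance = 0.05)
  # and the A cell line stays put
  realized_a <- mean(lf$lfc[lf$cell_line == "A" & lf$day == 21 &
                              lf$sgrna_id %in% sg8])
  expect_lt(abs(realized_a), 0.1)
})

test_that("simulated reads invert exactly through count_spacers", {
  cfg <- sim_config(n_genes = 15, n_controls = 3, coverage = 8, seed = 5)
  scr <- simulate_screen(cfg)
  sample_id <- "B_d21_r1"
  fq <- tempfile(fileext = ".fastq")
  simulate_reads(scr, sample_id, fq)
  res <- count_spacers(fq, scr$library, sample_id = sample_id)
  expect_identical(res$counts, scr$counts$counts[, sample_id])
  expect_equal(res$unassigned, 0L)
  expect_equal(res$ambiguous, 0L)

  # corrupting one read's spacer makes it unassigned on recount
  reads <- simulate_reads(scr, sample_id)
  corrupted <- sub("^(.{26})[ACGT]{20}", "\\1NNNNNNNNNNNNNNNNNNNN",
                   reads[1])
  res2 <- count_spacers(c(corrupted, reads[-1]), scr$library)
  expect_equal(res2$unassigned, 1L)
  expect_equal(sum(res2$counts), sum(scr$counts$counts[, sample_id]) - 1L)

  # zero-count sample gives an empty FASTQ
  zero <- scr
  zero$counts$counts[, sample_id] <- 0L
  fq0 <- tempfile(fileext = ".fastq")
  simulate_reads(zero, sample_id, fq0)
  expect_equal(file.size(fq0), 0)
  expect_error(simulate_reads(scr, "nope", fq), "not present")
})

test_that("recovery evaluation tallies the confusion matrix correctly", {
  cfg <- sim_config(n_genes = 90, coverage = 20, seed = 10,
                    class_fractions = rep(1 / 9, 9))
  lib <- simulate_library(cfg)
  truth <- assign_fitness(lib, cfg)
  rows <- data.frame(gene_id = truth$genes$gene_id,
                     group = truth$genes$true_group)

  perfect <- evaluate_recovery(rows, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(sum(diag(perfect$confusion)), 90)
  expect_equal(unname(rowSums(perfect$confusion)),
               unname(tabulate(truth$genes$true_group, 9)))

  all5 <- rows
  all5$group <- 5L
  ev <- evaluate_recovery(all5, truth)
  expect_equal(unname(ev$recall[5]), 1)
  expect_true(all(ev$recall[-5][rowSums(ev$confusion)[-5] > 0] == 0))
  # confusion row sums are conserved whatever the calls
  expect_equal(rowSums(ev$confusion), rowSums(perfect$confusion))

  other <- rows
  other$gene_id <- paste0("z", other$gene_id)
  expect_error(evaluate_recovery(other, truth), "universe")
})
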