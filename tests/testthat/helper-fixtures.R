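# shared fixtures: tiny libraries, count matrices and TSV writers used
# across the suite; everything is built in code at test time

make_library <- function(n_genes = 2, sgrnas_per_gene = 2, n_controls = 1,
                         spacer_width = 20) {
  set.seed(42)
  n <- n_genes * sgrnas_per_gene + n_controls
  spacers <- replicate(n, paste(sample(c("A", "C", "G", "T"), spacer_width,
                                       replace = TRUE), collapse = ""))
  while (anyDuplicated(spacers)) {
    spacers[duplicated(spacers)] <- replicate(
      sum(duplicated(spacers)),
      paste(sample(c("A", "C", "G", "T"), spacer_width, replace = TRUE),
            collapse = ""))
  }
  genes <- sprintf("gene%02d", seq_len(n_genes))
  sgrna_library(data.frame(
    sgrna_id = c(paste0(rep(genes, each = sgrnas_per_gene), "_sg",
                        rep(seq_len(sgrnas_per_gene), n_genes)),
                 sprintf("ctrl_%02d", seq_len(n_controls))),
    gene_id = c(rep(genes, each = sgrnas_per_gene),
                rep("non-targeting", n_controls)),
    spacer = spacers,
    stringsAsFactors = FALSE))
}

make_samples <- function(cell_lines = c("A", "B"), days = c(1, 21),
                         replicates = 1) {
  g <- expand.grid(replicate = seq_len(replicates), day = days,
                   cell_line = cell_lines, stringsAsFactors = FALSE)
  g$sample_id <- paste0(g$cell_line, "_d", g$day, "_r", g$replicate)
  g[, c("sample_id", "cell_line", "day", "replicate")]
}

make_counts <- function(library = make_library(), samples = make_samples(),
                        seed = 1, lambda = 100) {
  set.seed(seed)
  m <- matrix(rpois(nrow(library) * nrow(samples), lambda),
              nrow = nrow(library),
              dimnames = list(library$sgrna_id, samples$sample_id))
  screen_counts(m, samples)
}

write_library_tsv <- function(lib, path = tempfile(fileext = ".tsv")) {
  write.table(lib[c("sgrna_id", "gene_id", "spacer")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  path
}

# a minimal lfc table built directly (bypassing counts) for scoring tests
make_lfc <- function(sgrna_id, cell_line, day, lfc) {
  res <- data.frame(sgrna_id = sgrna_id, cell_line = cell_line, day = day,
                    lfc = lfc, stringsAsFactors = FALSE)
  class(res) <- c("lfc_table", "data.frame")
  res
}

# independent numeric oracle for the one-sample two-sided t-test:
# t density written out from its gamma-function form and integrated
# numerically; never calls pt()
t_pvalue_oracle <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- sd(x)
  tstat <- m / (s / sqrt(n))
  df <- n - 1
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  tail <- integrate(dens, abs(tstat), Inf, rel.tol = 1e-12,
                    abs.tol = 1e-14)$value
  2 * tail
}

# brute-force truth table for the nine-group rule, written independently
# of classify_gene(): nested conditionals transcribing the group legend
classify_oracle <- function(cs_b, p_b, cs_a, p_a, alpha = 0.05) {
  sig_up <- function(cs, p) p < alpha && cs > 0
  sig_dn <- function(cs, p) p < alpha && cs < 0
  if (sig_up(cs_b, p_b)) {
    if (sig_dn(cs_a, p_a)) 1L else if (sig_up(cs_a, p_a)) 3L else 2L
  } else if (sig_dn(cs_b, p_b)) {
    if (sig_dn(cs_a, p_a)) 7L else if (sig_up(cs_a, p_a)) 9L else 8L
  } else {
    if (sig_dn(cs_a, p_a)) 4L else if (sig_up(cs_a, p_a)) 6L else 5L
  }
}
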