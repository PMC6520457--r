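#' Nine-group sign-by-significance classification of one gene
#'
#' Each cell line is reduced to one of three states from its CRISPR score
#' and p-value: significantly enriched (`cs > 0` and `p < alpha`),
#' significantly depleted (`cs < 0` and `p < alpha`), or no significant
#' change otherwise. A score of exactly 0 carries no direction and is
#' always "no change", whatever its p-value, and the boundary `p == alpha`
#' is not significant. The 3 x 3 state pairs over cell lines B
#' (transformed role) and A (primary role) map to groups 1-9:
#'
#' | B \\ A       | sig down | ns | sig up |
#' |-------------|----------|----|--------|
#' | **sig up**  | 1        | 2  | 3      |
#' | **ns**      | 4        | 5  | 6      |
#' | **sig down**| 7        | 8  | 9      |
#'
#' Group 8 — depleted only in the transformed line — collects candidate
#' context-specific vulnerabilities; group 5 is the doubly-neutral bulk.
#'
#' @param cs_b,p_b CRISPR score and p-value in cell line B (vectorized).
#' @param cs_a,p_a CRISPR score and p-value in cell line A.
#' @param alpha Significance level (default 0.05).
#' @return Integer vector of group labels in 1..9.
#' @export
classify_gene <- function(cs_b, p_b, cs_a, p_a, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  n <- max(length(cs_b), length(p_b), length(cs_a), length(p_a))
  cs_b <- rep_len(cs_b, n); p_b <- rep_len(p_b, n)
  cs_a <- rep_len(cs_a, n); p_a <- rep_len(p_a, n)
  if (anyNA(cs_b) || anyNA(p_b) || anyNA(cs_a) || anyNA(p_a)) {
    stop("missing score or p-value in classification input")
  }
  if (any(c(p_a, p_b) < 0 | c(p_a, p_b) > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  state <- function(cs, p) {
    # 1 = sig down, 2 = ns, 3 = sig up
    ifelse(p < alpha & cs > 0, 3L, ifelse(p < alpha & cs < 0, 1L, 2L))
  }
  sb <- state(cs_b, p_b)
  sa <- state(cs_a, p_a)
  # rows: B state (sig up, ns, sig down); cols: A state (sig down, ns, sig up)
  map <- matrix(1:9, nrow = 3L, byrow = TRUE)
  brow <- c(3L, 2L, 1L)[sb]   # B sig up -> row 1, ns -> 2, sig down -> 3
  map[cbind(brow, sa)]
}

#' Classify every shared gene of a paired screen
#'
#' Applies [classify_gene()] to the genes shared by the two score tables at
#' one day (default: the latest day present in both), yielding one row per
#' gene and a full partition into the nine groups.
#'
#' @param scores_a,scores_b `gene_score_table`s with `pvalue` columns (from
#'   [gene_test()]) for cell line A (primary role) and B (transformed
#'   role). Each table must contain a single cell line; subset first if
#'   needed.
#' @param day Day at which to classify (default: latest day shared by both
#'   tables).
#' @param alpha Significance level (default 0.05).
#' @return A data frame of class `gene_class_table` with columns `gene_id`,
#'   `cs_a`, `p_a`, `cs_b`, `p_b`, `group`; `day` and `alpha` are kept as
#'   attributes. Use [group_sizes()] for the nine group counts.
#' @export
classify_screen <- function(scores_a, scores_b, day = NULL, alpha = 0.05) {
  for (nm in c("a", "b")) {
    sc <- if (nm == "a") scores_a else scores_b
    if (!all(c("gene_id", "cell_line", "day", "cs", "pvalue") %in% names(sc))) {
      stop("scores_", nm, " must have columns gene_id, cell_line, day, cs, ",
           "pvalue (run gene_test() first)")
    }
    if (length(unique(sc$cell_line)) != 1L) {
      stop("scores_", nm, " must contain exactly one cell line; subset first")
    }
  }
  if (is.null(day)) {
    shared_days <- intersect(scores_a$day, scores_b$day)
    if (length(shared_days) == 0L) stop("no day shared by the two score tables")
    day <- max(shared_days)
  }
  a <- scores_a[scores_a$day == day, , drop = FALSE]
  b <- scores_b[scores_b$day == day, , drop = FALSE]
  genes <- intersect(a$gene_id, b$gene_id)
  if (length(genes) == 0L) {
    stop("no genes shared by the two score tables at day ", day)
  }
  a <- a[match(genes, a$gene_id), , drop = FALSE]
  b <- b[match(genes, b$gene_id), , drop = FALSE]
  res <- data.frame(gene_id = genes, cs_a = a$cs, p_a = a$pvalue,
                    cs_b = b$cs, p_b = b$pvalue,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$group <- classify_gene(res$cs_b, res$p_b, res$cs_a, res$p_a,
                             alpha = alpha)
  attr(res, "day") <- day
  attr(res, "alpha") <- alpha
  class(res) <- c("gene_class_table", "data.frame")
  res
}

#' Group sizes of a classification
#'
#' @param rows A `gene_class_table` from [classify_screen()].
#' @return Named integer vector of length 9 (names `"1"`..`"9"`) summing to
#'   the number of classified genes.
#' @export
group_sizes <- function(rows) {
  stopifnot("group" %in% names(rows))
  structure(tabulate(rows$group, nbins = 9L), names = as.character(1:9))
}

#' Call strictly essential genes
#'
#' Flags genes whose terminal CRISPR score in the transformed line (B)
#' falls at or below a log2 threshold, by default -5, i.e. at least 32-fold
#' depletion of the gene's sgRNAs relative to day 1. By default the call is
#' restricted to group 8 (depleted only in the transformed line, the
#' candidate context-specific vulnerabilities); with
#' `restrict_to_group8 = FALSE` any significantly depleted gene in B
#' (groups 7, 8, 9) is eligible.
#'
#' @param rows A `gene_class_table` from [classify_screen()].
#' @param log2_threshold Log2 CRISPR-score cutoff, must be negative
#'   (default -5, a 32-fold decrease).
#' @param restrict_to_group8 Restrict calls to group 8 (default `TRUE`).
#' @return A data frame of class `essential_call_table` with columns
#'   `gene_id`, `group`, `log2_ratio` (the terminal B score) and `called`.
#' @export
call_strict_essential <- function(rows, log2_threshold = -5,
                                  restrict_to_group8 = TRUE) {
  stopifnot(inherits(rows, "data.frame"),
            all(c("gene_id", "group", "cs_b") %in% names(rows)))
  if (!is.numeric(log2_threshold) || length(log2_threshold) != 1L ||
      log2_threshold >= 0) {
    stop("log2_threshold must be a single negative number ",
         "(a log2 fold change, e.g. -5 for 32-fold depletion)")
  }
  eligible <- if (restrict_to_group8) rows$group == 8L
              else rows$group %in% c(7L, 8L, 9L)
  res <- data.frame(gene_id = rows$gene_id, group = rows$group,
                    log2_ratio = rows$cs_b,
                    called = eligible & rows$cs_b <= log2_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "log2_threshold") <- log2_threshold
  attr(res, "fold_change") <- 2^abs(log2_threshold)
  class(res) <- c("essential_call_table", "data.frame")
  res
}

#' Correlate gene essentiality between two screens
#'
#' Pearson correlation (and its square) of CRISPR scores over the genes
#' shared by two score tables at one day, complete cases only.
#'
#' @param scores_x,scores_y `gene_score_table`s, one cell line each.
#' @param day Day at which to compare (default: latest shared day).
#' @return A list of class `screen_correlation` with elements
#'   `n_shared_genes`, `pearson_r`, `r_squared`.
#' @export
correlate_screens <- function(scores_x, scores_y, day = NULL) {
  for (sc in list(scores_x, scores_y)) {
    if (!all(c("gene_id", "day", "cs") %in% names(sc))) {
      stop("score tables must have columns gene_id, day, cs")
    }
  }
  if (is.null(day)) {
    shared_days <- intersect(scores_x$day, scores_y$day)
    if (length(shared_days) == 0L) stop("no day shared by the two score tables")
    day <- max(shared_days)
  }
  x <- scores_x[scores_x$day == day, , drop = FALSE]
  y <- scores_y[scores_y$day == day, , drop = FALSE]
  genes <- intersect(x$gene_id, y$gene_id)
  vx <- x$cs[match(genes, x$gene_id)]
  vy <- y$cs[match(genes, y$gene_id)]
  ok <- is.finite(vx) & is.finite(vy)
  vx <- vx[ok]; vy <- vy[ok]
  if (length(vx) < 3L) {
    stop("need at least 3 shared genes with finite scores; have ", length(vx))
  }
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0) {
    stop("zero variance in one of the score vectors")
  }
  r <- cor(vx, vy, method = "pearson")
  structure(list(n_shared_genes = length(vx), pearson_r = r,
                 r_squared = r^2),
            class = "screen_correlation")
}

#' @export
print.screen_correlation <- function(x, ...) {
  cat("screen correlation over ", x$n_shared_genes, " genes: r = ",
      format(x$pearson_r, digits = 3), ", R^2 = ",
      format(x$r_squared, digits = 3), "\n", sep = "")
  invisible(x)
}
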