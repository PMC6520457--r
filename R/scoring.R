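#' Normalize a count matrix to reads per million
#'
#' Scales each sample to a library size of one million so that samples
#' sequenced to different depths are comparable. The pseudocount is stored
#' for downstream log-ratio computation; it is not added here.
#'
#' @param x A `screen_counts` object.
#' @param pseudocount Small positive number added inside the log ratio by
#'   [sgrna_lfc()] to keep fold changes finite when a guide drops to zero
#'   (default 0.5).
#' @return A list of class `cpm_matrix` with elements `cpm` (numeric matrix,
#'   each column summing to 1e6), `samples` and `pseudocount`.
#' @export
normalize_cpm <- function(x, pseudocount = 0.5) {
  stopifnot(inherits(x, "screen_counts"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount < 0) {
    stop("pseudocount must be a single non-negative number")
  }
  totals <- colSums(x$counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(x$counts)[totals == 0], collapse = ", "))
  }
  cpm <- sweep(x$counts, 2L, totals, "/") * 1e6
  structure(list(cpm = cpm, samples = x$samples, pseudocount = pseudocount),
            class = "cpm_matrix")
}

#' Per-sgRNA log2 fold changes against the reference day
#'
#' For each cell line, computes
#' `lfc = log2((cpm_t + pseudocount) / (cpm_ref + pseudocount))` for every
#' sgRNA and day, where the reference is that cell line's designated
#' reference day (default: its smallest day, the screen's day 1).
#' Replicates of a (cell line, day) are averaged on the cpm scale before
#' the ratio is formed. The reference day itself is included with lfc
#' identically zero.
#'
#' @param norm A `cpm_matrix` from [normalize_cpm()].
#' @return A data frame of class `lfc_table` with columns `sgrna_id`,
#'   `cell_line`, `day`, `lfc`, and the pseudocount as an attribute.
#' @export
sgrna_lfc <- function(norm) {
  stopifnot(inherits(norm, "cpm_matrix"))
  samples <- norm$samples
  ps <- norm$pseudocount
  out <- list()
  for (cl in unique(samples$cell_line)) {
    ref_day <- reference_day(samples, cl)
    cl_samples <- samples[samples$cell_line == cl, , drop = FALSE]
    days <- sort(unique(cl_samples$day))
    if (!ref_day %in% days) {
      stop("cell line '", cl, "' has no sample at its reference day ",
           ref_day)
    }
    day_mean <- function(d) {
      ids <- cl_samples$sample_id[cl_samples$day == d]
      rowMeans(norm$cpm[, ids, drop = FALSE])
    }
    ref <- day_mean(ref_day)
    for (d in days) {
      lfc <- if (d == ref_day) {
        rep(0, nrow(norm$cpm))
      } else {
        log2((day_mean(d) + ps) / (ref + ps))
      }
      out[[length(out) + 1L]] <- data.frame(
        sgrna_id = rownames(norm$cpm), cell_line = cl, day = d, lfc = lfc,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  if (any(!is.finite(res$lfc))) {
    # only reachable with pseudocount 0 and a zero reference cpm
    res$lfc[is.nan(res$lfc)] <- 0   # 0/0: unobserved at both days
  }
  attr(res, "pseudocount") <- ps
  class(res) <- c("lfc_table", "data.frame")
  res
}

#' Per-gene CRISPR scores
#'
#' The CRISPR score of a gene at a given (cell line, day) is the arithmetic
#' mean of the log2 fold changes of its sgRNAs: negative scores mark
#' depleted (essential or pro-proliferative) genes, positive scores mark
#' enriched (growth-suppressive) genes. Non-targeting controls are
#' excluded.
#'
#' @param lfcs An `lfc_table` from [sgrna_lfc()].
#' @param library The `sgrna_library` the screen was counted against.
#' @return A data frame of class `gene_score_table` with columns `gene_id`,
#'   `cell_line`, `day`, `cs` and `n_sgrna`.
#' @export
gene_score <- function(lfcs, library) {
  stopifnot(is.data.frame(lfcs), is.data.frame(library))
  gene <- library$gene_id[match(lfcs$sgrna_id, library$sgrna_id)]
  ctrl <- library$is_control[match(lfcs$sgrna_id, library$sgrna_id)]
  if (anyNA(gene)) {
    stop("sgRNA(s) in lfc table absent from library: ",
         paste(utils::head(unique(lfcs$sgrna_id[is.na(gene)]), 5L),
               collapse = ", "))
  }
  keep <- !ctrl
  dropped <- setdiff(unique(library$gene_id[!library$is_control]),
                     unique(gene[keep]))
  if (length(dropped) > 0L) {
    warning("gene(s) with no sgRNAs in the lfc table were dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  }
  lf <- lfcs[keep, , drop = FALSE]
  gene <- gene[keep]
  key <- paste(gene, lf$cell_line, lf$day, sep = "\r")
  s1 <- rowsum(lf$lfc, key, reorder = TRUE)
  n <- rowsum(rep(1L, nrow(lf)), key, reorder = TRUE)
  parts <- do.call(rbind, strsplit(rownames(s1), "\r", fixed = TRUE))
  res <- data.frame(gene_id = parts[, 1L], cell_line = parts[, 2L],
                    day = as.numeric(parts[, 3L]),
                    cs = as.numeric(s1) / as.numeric(n),
                    n_sgrna = as.integer(n),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$cell_line, res$day, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("gene_score_table", "data.frame")
  res
}

#' Per-gene significance tests on sgRNA log2 fold changes
#'
#' Attaches a two-sided p-value to every (gene, cell line, day) CRISPR
#' score:
#'
#' * `method = "t"` (default): one-sample two-tailed t-test of the gene's
#'   sgRNA log2 fold changes against 0, with `n_sgrna - 1` degrees of
#'   freedom. Degenerate cases are resolved deterministically and
#'   monotonically with the evidence: zero variance with a nonzero mean
#'   gives p = 0, zero variance with zero mean gives p = 1, and a single
#'   sgRNA gives p = 1 with a warning.
#' * `method = "ks"`: two-sided two-sample Kolmogorov-Smirnov test of the
#'   gene's sgRNA log2 fold changes against the pooled non-targeting
#'   control distribution at the same (cell line, day).
#'
#' No multiple-testing correction is applied by default;
#' `adjust = "BH"` adds a Benjamini-Hochberg adjusted column `padj`
#' computed within each (cell line, day).
#'
#' @inheritParams gene_score
#' @param method `"t"` or `"ks"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `gene_score_table` (see [gene_score()]) with an additional
#'   `pvalue` column (and `padj` when `adjust = "BH"`).
#' @export
gene_test <- function(lfcs, library, method = c("t", "ks"),
                      adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  scores <- gene_score(lfcs, library)
  gene <- library$gene_id[match(lfcs$sgrna_id, library$sgrna_id)]
  ctrl <- library$is_control[match(lfcs$sgrna_id, library$sgrna_id)]

  if (method == "t") {
    keep <- !ctrl
    lf <- lfcs[keep, , drop = FALSE]
    key <- paste(gene[keep], lf$cell_line, lf$day, sep = "\r")
    s1 <- rowsum(lf$lfc, key, reorder = TRUE)
    s2 <- rowsum(lf$lfc^2, key, reorder = TRUE)
    n <- as.numeric(rowsum(rep(1L, nrow(lf)), key, reorder = TRUE))
    m <- as.numeric(s1) / n
    ss <- pmax(as.numeric(s2) - n * m^2, 0)
    sd <- sqrt(ss / pmax(n - 1, 1))
    p <- rep(NA_real_, length(n))
    single <- n == 1
    if (any(single)) {
      warning(sum(single), " gene/timepoint(s) with a single sgRNA: ",
              "p-value set to 1")
      p[single] <- 1
    }
    degen <- !single & sd < 1e-12
    p[degen & abs(m) > 1e-12] <- 0
    p[degen & abs(m) <= 1e-12] <- 1
    ok <- !single & !degen
    tstat <- m[ok] / (sd[ok] / sqrt(n[ok]))
    p[ok] <- 2 * pt(-abs(tstat), df = n[ok] - 1)
    pkey <- rownames(s1)
  } else {
    if (!any(ctrl)) stop("method 'ks' requires non-targeting control sgRNAs")
    keep <- !ctrl
    lf <- lfcs[keep, , drop = FALSE]
    gn <- gene[keep]
    ctrl_lf <- lfcs[ctrl, , drop = FALSE]
    key <- paste(gn, lf$cell_line, lf$day, sep = "\r")
    groups <- split(lf$lfc, key)
    ckey <- paste(ctrl_lf$cell_line, ctrl_lf$day, sep = "\r")
    ctrl_groups <- split(ctrl_lf$lfc, ckey)
    pkey <- names(groups)
    cond <- sub("^[^\r]*\r", "", pkey)
    p <- vapply(seq_along(groups), function(i) {
      ref <- ctrl_groups[[cond[i]]]
      if (is.null(ref)) stop("no control lfc values for condition ", cond[i])
      suppressWarnings(ks.test(groups[[i]], ref,
                               alternative = "two.sided")$p.value)
    }, numeric(1))
  }

  skey <- paste(scores$gene_id, scores$cell_line, scores$day, sep = "\r")
  scores$pvalue <- p[match(skey, pkey)]
  if (adjust == "BH") {
    cond <- paste(scores$cell_line, scores$day, sep = "\r")
    scores$padj <- ave(scores$pvalue, cond,
                       FUN = function(z) p.adjust(z, method = "BH"))
  }
  attr(scores, "method") <- method
  scores
}

#' Empirical cumulative distribution of sgRNA log2 fold changes
#'
#' The cumulative sgRNA-frequency curve of one (cell line, day): a global
#' leftward shift of later days relative to the reference indicates
#' progressive depletion of a subset of guides.
#'
#' @inheritParams gene_score
#' @param cell_line,day Condition to summarize.
#' @return A data frame of class `ecdf_curve` with columns `value` (sorted
#'   distinct lfc values) and `fraction` (cumulative fraction of sgRNAs at
#'   or below each value, non-decreasing and ending at 1).
#' @export
ecdf_curve <- function(lfcs, cell_line, day) {
  sel <- lfcs$cell_line == cell_line & lfcs$day == day
  v <- lfcs$lfc[sel]
  if (length(v) == 0L) {
    stop("no lfc values for cell line '", cell_line, "', day ", day)
  }
  v <- sort(v)
  n <- length(v)
  last <- !duplicated(v, fromLast = TRUE)
  res <- data.frame(value = v[last], fraction = which(last) / n,
                    row.names = NULL)
  class(res) <- c("ecdf_curve", "data.frame")
  res
}

#' Write a tidy table to a tab-separated file
#'
#' Helper shared by the pipeline for lfc, score, classification and ECDF
#' tables: UTF-8, tab-separated, header row, no quoting.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
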