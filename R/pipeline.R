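#' Configuration of an end-to-end pipeline run
#'
#' Validates all parameters before any stage runs. Counts can be supplied
#' either as a precomputed count matrix plus metadata, or as per-sample
#' FASTQ files to be quantified with [count_spacers()].
#'
#' @param library_path Path to the sgRNA library TSV.
#' @param counts_path,metadata_path Paths to a precomputed counts TSV and
#'   its sample metadata TSV (either these or `fastq_paths`).
#' @param fastq_paths Named character vector of FASTQ paths, names =
#'   sample ids matching `metadata_path` (requires `metadata_path`).
#' @param out_dir Output directory (created if absent).
#' @param cell_line_a,cell_line_b Cell lines taking the primary (A) and
#'   transformed (B) roles of the classification; by default the two cell
#'   lines in the metadata, in sorted order.
#' @param pseudocount Pseudocount for [normalize_cpm()] (default 0.5).
#' @param method Per-gene test, `"t"` or `"ks"` (see [gene_test()]).
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @param terminal_day Day at which to classify (default: latest shared
#'   day).
#' @param essential_threshold Log2 cutoff for [call_strict_essential()]
#'   (default -5).
#' @param restrict_to_group8 Restrict strict-essential calls to group 8
#'   (default `TRUE`).
#' @param control_label Reserved control `gene_id`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(library_path,
                       counts_path = NULL, metadata_path = NULL,
                       fastq_paths = NULL,
                       out_dir = ".",
                       cell_line_a = NULL, cell_line_b = NULL,
                       pseudocount = 0.5,
                       method = c("t", "ks"),
                       alpha = 0.05,
                       terminal_day = NULL,
                       essential_threshold = -5,
                       restrict_to_group8 = TRUE,
                       control_label = "non-targeting") {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    stop("pseudocount must be non-negative")
  }
  if (!is.numeric(essential_threshold) || essential_threshold >= 0) {
    stop("essential_threshold must be a negative log2 fold change")
  }
  if (is.null(counts_path) == is.null(fastq_paths)) {
    stop("supply exactly one of counts_path or fastq_paths")
  }
  if (is.null(metadata_path)) stop("metadata_path is required")
  paths <- c(library_path, counts_path, metadata_path, fastq_paths)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(list(library_path = library_path, counts_path = counts_path,
                 metadata_path = metadata_path, fastq_paths = fastq_paths,
                 out_dir = out_dir,
                 cell_line_a = cell_line_a, cell_line_b = cell_line_b,
                 pseudocount = pseudocount, method = method, alpha = alpha,
                 terminal_day = terminal_day,
                 essential_threshold = essential_threshold,
                 restrict_to_group8 = restrict_to_group8,
                 control_label = control_label),
            class = "run_config")
}

#' Run the full count -> score -> classify -> call -> report pipeline
#'
#' Executes the stages in fixed order, writes every intermediate table to
#' `out_dir` as TSV, and returns (and writes) a machine-readable report.
#' A failure in any stage aborts with the stage name and cause. Rerunning
#' with identical inputs and configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages (default `FALSE`).
#' @return A list of class `run_report`; also written to
#'   `out_dir/report.json` (see [write_report()]).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[pairedscreen] ", ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    say(name, " (", format(proc.time()[["elapsed"]] - t0, digits = 3), "s)")
    res
  }
  outputs <- character(0)
  emit <- function(x, file) {
    path <- file.path(config$out_dir, file)
    write_tsv(x, path)
    outputs <<- c(outputs, file)
    path
  }

  library <- stage("read_library",
                   read_library(config$library_path,
                                control_label = config$control_label))
  counts <- stage("counts", {
    if (!is.null(config$counts_path)) {
      read_counts(config$counts_path, config$metadata_path, library = library)
    } else {
      samples <- read.delim(config$metadata_path, sep = "\t", quote = "")
      mat <- sapply(names(config$fastq_paths), function(s) {
        count_spacers(config$fastq_paths[[s]], library, sample_id = s)$counts
      })
      sc <- screen_counts(mat, samples)
      write_counts(sc, file.path(config$out_dir, "counts.tsv"),
                   file.path(config$out_dir, "metadata.tsv"))
      outputs <<- c(outputs, "counts.tsv", "metadata.tsv")
      sc
    }
  })

  cls <- sort(unique(counts$samples$cell_line))
  cell_a <- if (is.null(config$cell_line_a)) cls[1L] else config$cell_line_a
  cell_b <- if (is.null(config$cell_line_b)) cls[2L] else config$cell_line_b
  if (!all(c(cell_a, cell_b) %in% cls)) {
    stop("cell lines '", cell_a, "'/'", cell_b, "' not found in metadata")
  }

  norm <- stage("normalize_cpm", normalize_cpm(counts, config$pseudocount))
  lfcs <- stage("sgrna_lfc", sgrna_lfc(norm))
  emit(lfcs, "sgrna_lfc.tsv")
  scores <- stage("gene_test",
                  gene_test(lfcs, library, method = config$method))
  emit(scores, "gene_scores.tsv")

  rows <- stage("classify", classify_screen(
    scores_a = scores[scores$cell_line == cell_a, , drop = FALSE],
    scores_b = scores[scores$cell_line == cell_b, , drop = FALSE],
    day = config$terminal_day, alpha = config$alpha))
  emit(rows, "classification.tsv")
  sizes <- group_sizes(rows)
  emit(data.frame(group = names(sizes), n_genes = as.integer(sizes)),
       "group_sizes.tsv")

  calls <- stage("call_strict_essential", call_strict_essential(
    rows, log2_threshold = config$essential_threshold,
    restrict_to_group8 = config$restrict_to_group8))
  emit(calls, "essential_calls.tsv")

  ecdf_files <- stage("ecdf", {
    files <- character(0)
    for (cl in c(cell_a, cell_b)) {
      for (d in sort(unique(counts$samples$day[
        counts$samples$cell_line == cl]))) {
        f <- paste0("ecdf_", cl, "_day", d, ".tsv")
        emit(ecdf_curve(lfcs, cl, d), f)
        files <- c(files, f)
      }
    }
    files
  })

  report <- structure(list(
    version = as.character(packageVersion("pairedscreen")),
    config = list(
      library_path = config$library_path,
      counts_path = config$counts_path,
      metadata_path = config$metadata_path,
      cell_line_a = cell_a, cell_line_b = cell_b,
      pseudocount = config$pseudocount, method = config$method,
      alpha = config$alpha,
      terminal_day = attr(rows, "day"),
      essential_threshold = config$essential_threshold,
      restrict_to_group8 = config$restrict_to_group8),
    stages = list(
      n_sgrna = nrow(library),
      n_control_sgrna = sum(library$is_control),
      n_samples = ncol(counts$counts),
      n_lfc_rows = nrow(lfcs),
      n_score_rows = nrow(scores),
      n_classified_genes = nrow(rows)),
    group_sizes = as.list(sizes),
    essential_genes = calls$gene_id[calls$called],
    ecdf_files = ecdf_files,
    outputs = outputs), class = "run_report")
  write_report(report, file.path(config$out_dir, "report.json"))
  say("done: ", nrow(rows), " genes classified, ",
      sum(calls$called), " strict essential calls")
  report
}

#' Write / read a pipeline report
#'
#' The report is serialized as JSON with a stable schema; [read_report()]
#' validates the schema (version present, nine-entry group-size table) and
#' errors on violations. Writing then reading restores an equal report.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param path JSON file path.
#' @return `write_report()`: `path`, invisibly. `read_report()`: the
#'   `run_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  report <- jsonlite::read_json(path, simplifyVector = FALSE)
  required <- c("version", "config", "stages", "group_sizes",
                "essential_genes", "ecdf_files", "outputs")
  missing <- setdiff(required, names(report))
  if (length(missing) > 0L) {
    stop("report at ", path, " is missing field(s): ",
         paste(missing, collapse = ", "))
  }
  if (!identical(sort(names(report$group_sizes)), as.character(1:9))) {
    stop("report group_sizes must have exactly the nine groups 1..9")
  }
  report$group_sizes <- lapply(report$group_sizes, as.integer)
  report$essential_genes <- as.character(unlist(report$essential_genes))
  report$ecdf_files <- as.character(unlist(report$ecdf_files))
  report$outputs <- as.character(unlist(report$outputs))
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("pairedscreen run report (v", x$version, ")\n", sep = "")
  cat("  genes classified: ", x$stages$n_classified_genes, "\n", sep = "")
  cat("  group sizes: ",
      paste(names(x$group_sizes), unlist(x$group_sizes), sep = "=",
            collapse = " "), "\n", sep = "")
  cat("  strict essential genes: ", length(x$essential_genes), "\n", sep = "")
  invisible(x)
}
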