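#' Construct a screen count matrix with sample metadata
#'
#' @param counts Non-negative integer matrix, rows = sgRNAs (rownames are
#'   `sgrna_id`), columns = samples (colnames are `sample_id`).
#' @param samples Data frame with columns `sample_id`, `cell_line`, `day`,
#'   `replicate` and optionally a logical `reference` column designating the
#'   reference sample(s) of each cell line. Without a `reference` column the
#'   smallest day of each cell line is the reference (the screen's day 1).
#' @param unassigned,ambiguous Optional named per-sample counts of reads
#'   that matched no spacer / more than one sgRNA.
#' @return A list of class `screen_counts` with elements `counts`,
#'   `samples`, `unassigned`, `ambiguous`.
#' @export
screen_counts <- function(counts, samples, unassigned = NULL,
                          ambiguous = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sgrna_id rownames and sample_id colnames")
  }
  bad <- !is.finite(counts) | counts < 0 | counts != round(counts)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop("count for sgRNA '", rownames(counts)[i[1L]], "' in sample '",
         colnames(counts)[i[2L]], "' is not a non-negative integer")
  }
  storage.mode(counts) <- "integer"
  samples <- validate_samples(samples)
  missing_meta <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_meta) > 0L) {
    stop("sample(s) in counts absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  missing_counts <- setdiff(samples$sample_id, colnames(counts))
  if (length(missing_counts) > 0L) {
    stop("sample(s) in metadata absent from counts: ",
         paste(missing_counts, collapse = ", "))
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples,
                 unassigned = unassigned, ambiguous = ambiguous),
            class = "screen_counts")
}

validate_samples <- function(samples) {
  required <- c("sample_id", "cell_line", "day", "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0L) {
    stop("sample metadata is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$cell_line <- as.character(samples$cell_line)
  samples$day <- as.numeric(samples$day)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id in metadata")
  }
  if (any(!is.finite(samples$day) | samples$day < 0)) {
    stop("day must be a non-negative number")
  }
  if (any(!is.finite(samples$replicate) | samples$replicate < 1L)) {
    stop("replicate must be a positive integer")
  }
  key <- paste(samples$cell_line, samples$day, samples$replicate)
  if (anyDuplicated(key)) {
    stop("duplicated (cell_line, day, replicate) in metadata: ",
         key[duplicated(key)][1L])
  }
  if ("reference" %in% names(samples)) {
    samples$reference <- as.logical(samples$reference)
    for (cl in unique(samples$cell_line)) {
      ref_days <- unique(samples$day[samples$cell_line == cl &
                                       samples$reference %in% TRUE])
      if (length(ref_days) > 1L) {
        stop("cell line '", cl, "' has reference samples at more than one ",
             "day (", paste(ref_days, collapse = ", "), ")")
      }
    }
  }
  samples
}

#' Reference day of a cell line
#'
#' The day each later time point is compared against: the day flagged in the
#' metadata's `reference` column if present, otherwise the smallest day
#' observed for that cell line.
#'
#' @param samples Sample metadata data frame (see [screen_counts()]).
#' @param cell_line Cell line identifier.
#' @return The reference day, a numeric scalar.
#' @export
reference_day <- function(samples, cell_line) {
  rows <- samples[samples$cell_line == cell_line, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no samples for cell line '", cell_line, "'")
  if ("reference" %in% names(rows) && any(rows$reference %in% TRUE)) {
    return(unique(rows$day[rows$reference %in% TRUE]))
  }
  min(rows$day)
}

#' Read / write a count matrix and its sample metadata
#'
#' The counts file is tab-separated with first column `sgrna_id` and one
#' column per sample; the metadata file maps `sample_id` to `cell_line`,
#' `day` and `replicate` (optional logical `reference` column). Files are
#' UTF-8, header row required, no quoting. `read_counts(write_counts(x))`
#' is the identity.
#'
#' @param counts_path Path to the counts table.
#' @param metadata_path Path to the sample metadata table.
#' @param library Optional `sgrna_library`; if given, every `sgrna_id` in
#'   the counts file must be present in it.
#' @return A `screen_counts` object.
#' @export
read_counts <- function(counts_path, metadata_path, library = NULL) {
  tab <- read.delim(counts_path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE)
  if (names(tab)[1L] != "sgrna_id") {
    stop("first column of ", counts_path, " must be 'sgrna_id'")
  }
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(counts) <- as.character(tab$sgrna_id)
  samples <- read.delim(metadata_path, header = TRUE, sep = "\t",
                        quote = "", check.names = FALSE)
  if (!is.null(library)) {
    unknown <- setdiff(rownames(counts), library$sgrna_id)
    if (length(unknown) > 0L) {
      stop("sgRNA(s) in counts absent from library: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
  }
  screen_counts(counts, samples)
}

#' @rdname read_counts
#' @param x A `screen_counts` object.
#' @export
write_counts <- function(x, counts_path, metadata_path) {
  stopifnot(inherits(x, "screen_counts"))
  tab <- data.frame(sgrna_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}

#' @export
print.screen_counts <- function(x, ...) {
  cat("screen_counts: ", nrow(x$counts), " sgRNAs x ", ncol(x$counts),
      " samples (", length(unique(x$samples$cell_line)), " cell line(s), days ",
      paste(sort(unique(x$samples$day)), collapse = "/"), ")\n", sep = "")
  invisible(x)
}
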