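#' Read and validate an sgRNA library table
#'
#' Reads a tab-separated library file with header columns `sgrna_id`,
#' `gene_id` and `spacer`. Records whose `gene_id` equals `control_label`
#' are flagged as non-targeting controls.
#'
#' @param path Path to a tab-separated file with columns `sgrna_id`,
#'   `gene_id`, `spacer`.
#' @param control_label Reserved `gene_id` marking non-targeting control
#'   sgRNAs (default `"non-targeting"`).
#' @param spacer_length If not `NULL`, every spacer must have exactly this
#'   length.
#' @return A data frame of class `sgrna_library` with columns `sgrna_id`,
#'   `gene_id`, `spacer` and `is_control`, validated by
#'   [validate_library()]. The control label is kept in the
#'   `control_label` attribute.
#' @seealso [count_spacers()], [simulate_library()]
#' @export
read_library <- function(path, control_label = "non-targeting",
                         spacer_length = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE)
  required <- c("sgrna_id", "gene_id", "spacer")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("library file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  sgrna_library(tab[required], control_label = control_label,
                spacer_length = spacer_length)
}

#' Construct an sgRNA library object
#'
#' @param records Data frame with columns `sgrna_id`, `gene_id`, `spacer`.
#' @inheritParams read_library
#' @return A validated `sgrna_library` data frame (see [read_library()]).
#' @export
sgrna_library <- function(records, control_label = "non-targeting",
                          spacer_length = NULL) {
  lib <- data.frame(sgrna_id = as.character(records$sgrna_id),
                    gene_id = as.character(records$gene_id),
                    spacer = as.character(records$spacer),
                    stringsAsFactors = FALSE)
  lib$is_control <- lib$gene_id == control_label
  attr(lib, "control_label") <- control_label
  class(lib) <- c("sgrna_library", "data.frame")
  validate_library(lib, spacer_length = spacer_length)
}

#' Validate an sgRNA library
#'
#' Checks sgRNA id uniqueness, spacer alphabet (uppercase ACGT only,
#' non-empty) and, optionally, spacer length. Validation is pure: the input
#' is returned unchanged on success.
#'
#' @param library An `sgrna_library` data frame.
#' @param spacer_length Optional required spacer length.
#' @return `library`, invisibly unchanged, on success; otherwise an error
#'   naming the first offending record.
#' @export
validate_library <- function(library, spacer_length = NULL) {
  stopifnot(is.data.frame(library))
  dup <- duplicated(library$sgrna_id)
  if (any(dup)) {
    stop("duplicated sgrna_id in library: ",
         paste(unique(library$sgrna_id[dup]), collapse = ", "))
  }
  bad <- !grepl("^[ACGT]+$", library$spacer)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("spacer for sgRNA '", library$sgrna_id[i], "' (line ", i + 1L,
         ") is not a non-empty uppercase ACGT string: '",
         library$spacer[i], "'")
  }
  if (!is.null(spacer_length)) {
    off <- nchar(library$spacer) != spacer_length
    if (any(off)) {
      i <- which(off)[1L]
      stop("spacer for sgRNA '", library$sgrna_id[i], "' has length ",
           nchar(library$spacer[i]), ", expected ", spacer_length)
    }
  }
  if (nrow(library) > 0L && all(library$is_control)) {
    warning("library contains only non-targeting control sgRNAs")
  }
  library
}

#' Control label of a library
#' @param library An `sgrna_library`.
#' @return The reserved control `gene_id`, a character scalar.
#' @export
control_label <- function(library) {
  lab <- attr(library, "control_label")
  if (is.null(lab)) "non-targeting" else lab
}

#' Write an sgRNA library to a tab-separated file
#'
#' @param library An `sgrna_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  write.table(library[c("sgrna_id", "gene_id", "spacer")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
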