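#' Count sgRNA spacers in sequencing reads
#'
#' Assigns each read to the unique library spacer that occurs as an exact
#' substring of the read (forward orientation only, no mismatches). Reads
#' matching no spacer are tallied as unassigned; reads matching spacers of
#' two or more distinct sgRNAs are tallied as ambiguous and discarded, so
#' counts stay integral and reproducible. Assigned + unassigned + ambiguous
#' always equals the number of reads.
#'
#' Spacers duplicated across sgRNA records are permitted in the library, but
#' any read containing such a spacer necessarily hits more than one sgRNA
#' and is therefore counted as ambiguous.
#'
#' @param reads Either a path to a FASTQ file (4-line records; qualities are
#'   ignored) or a character vector of read sequences.
#' @param library A validated `sgrna_library` (see [read_library()]).
#' @param sample_id Sample identifier stored with the result.
#' @return A list of class `spacer_counts` with elements `counts` (named
#'   integer vector over every `sgrna_id` in the library), `unassigned`,
#'   `ambiguous`, `n_reads` and `sample_id`.
#' @export
count_spacers <- function(reads, library, sample_id = "sample") {
  validate_library(library)
  if (nrow(library) == 0L) stop("cannot count spacers against an empty library")
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  reads <- as.character(reads)
  counts <- structure(integer(nrow(library)), names = library$sgrna_id)
  if (length(reads) == 0L) {
    return(structure(list(counts = counts, unassigned = 0L, ambiguous = 0L,
                          n_reads = 0L, sample_id = sample_id),
                     class = "spacer_counts"))
  }

  subject <- Biostrings::DNAStringSet(reads)
  # one PDict per spacer width; hits accumulated per read as sgRNA row indices
  hits <- vector("list", length(reads))
  widths <- nchar(library$spacer)
  for (w in unique(widths)) {
    rows <- which(widths == w)
    spc <- library$spacer[rows]
    uspc <- unique(spc)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(uspc))
    per_read <- Biostrings::vwhichPDict(pd, subject)
    spc_to_rows <- split(rows, match(spc, uspc))
    for (i in seq_along(per_read)) {
      if (length(per_read[[i]]) > 0L) {
        hit_rows <- unlist(spc_to_rows[as.character(per_read[[i]])],
                           use.names = FALSE)
        hits[[i]] <- c(hits[[i]], hit_rows)
      }
    }
  }

  n_hits <- lengths(hits)
  unassigned <- sum(n_hits == 0L)
  assigned_rows <- unlist(hits[n_hits == 1L], use.names = FALSE)
  ambiguous <- sum(n_hits >= 2L)
  if (length(assigned_rows) > 0L) {
    tab <- tabulate(assigned_rows, nbins = nrow(library))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, unassigned = as.integer(unassigned),
                 ambiguous = as.integer(ambiguous),
                 n_reads = length(reads), sample_id = sample_id),
            class = "spacer_counts")
}

#' @export
print.spacer_counts <- function(x, ...) {
  cat("spacer counts for sample '", x$sample_id, "': ", x$n_reads,
      " reads; assigned ", sum(x$counts), ", unassigned ", x$unassigned,
      ", ambiguous ", x$ambiguous, "\n", sep = "")
  invisible(x)
}
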