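#' Counted collection of unique small-RNA sequences
#'
#' A `read_library` holds the collapsed form of a small-RNA library: each
#' distinct sequence appears once, together with its abundance count. All
#' sequences are stored in DNA alphabet (U converted to T, uppercase);
#' user-facing bias statistics report the first position under the RNA
#' label "U".
#'
#' @param sequences character vector of reads (need not be unique; identical
#'   sequences are collapsed with summed counts). Must be non-empty strings
#'   over `{A,C,G,T}` after normalization.
#' @param counts integer vector of positive per-record counts, recycled to
#'   `length(sequences)`. Default 1 per record.
#' @param name library label used in collapsed-FASTA headers and reports.
#'
#' @return An object of class `read_library`: a list with elements
#'   `name`, `records` (data.frame with columns `sequence`, `count`) and
#'   `total_count`.
#' @examples
#' lib <- read_library(c("TGACA", "TGACA", "AACGT"), name = "demo")
#' lib$total_count  # 3
#' @export
read_library <- function(sequences, counts = 1L, name = "library") {
  stopifnot(is.character(sequences))
  counts <- rep_len(as.numeric(counts), length(sequences))
  if (any(counts <= 0) || any(counts != floor(counts))) {
    stop("counts must be positive integers")
  }
  sequences <- normalize_sequence(sequences)
  bad <- !grepl("^[ACGT]+$", sequences)
  if (any(bad)) {
    stop("sequences must be non-empty strings over {A,C,G,T,U}: ",
         paste(utils::head(sequences[bad], 3), collapse = ", "))
  }
  if (length(sequences) == 0L) {
    records <- data.frame(sequence = character(), count = numeric(),
                          stringsAsFactors = FALSE)
  } else {
    agg <- tapply(counts, sequences, sum)
    records <- data.frame(sequence = names(agg), count = as.numeric(agg),
                          stringsAsFactors = FALSE, row.names = NULL)
    records <- records[order(records$sequence), , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(
    list(name = name, records = records, total_count = sum(records$count)),
    class = "read_library"
  )
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("read_library '%s': %d unique sequences, %s reads\n",
              x$name, nrow(x$records), format(x$total_count)))
  invisible(x)
}

#' Normalize nucleotide strings to the internal DNA alphabet
#'
#' Uppercases and converts U to T. Performs no validation.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @keywords internal
normalize_sequence <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Reverse-complement of DNA strings
#'
#' @param x character vector over `{A,C,G,T}`.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
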