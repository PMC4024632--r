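# FASTA/FASTQ ingestion with collapsing of identical sequences.
# Count suffixes on FASTA headers ("..._xN" preferred, bare "..._N"
# accepted) mark pre-collapsed reads.

parse_count_suffix <- function(headers) {
  n <- rep(1, length(headers))
  mx <- regmatches(headers, regexpr("x([0-9]+)$", headers))
  has_x <- grepl("x[0-9]+$", headers)
  n[has_x] <- as.numeric(sub("^x", "", mx))
  plain <- !has_x & grepl("_[0-9]+$", headers)
  if (any(plain)) {
    n[plain] <- as.numeric(sub("^.*_([0-9]+)$", "\\1", headers[plain]))
  }
  n[n < 1] <- 1
  n
}

# Shared normalization/filtering contract for both readers. Records with N
# are dropped (warning); records with other foreign characters are rejected
# (warning) and the run continues.
collapse_records <- function(seqs, headers, counts, name) {
  seqs <- normalize_sequence(seqs)
  keep <- rep(TRUE, length(seqs))
  has_n <- grepl("N", seqs, fixed = TRUE)
  valid_no_n <- grepl("^[ACGTN]+$", seqs)
  foreign <- !valid_no_n
  if (any(foreign)) {
    warning(sprintf(
      "%d record(s) rejected (characters outside {A,C,G,T,U,N}): e.g. %s",
      sum(foreign), paste(utils::head(headers[foreign], 3), collapse = ", ")),
      call. = FALSE)
    keep[foreign] <- FALSE
  }
  drop_n <- has_n & !foreign
  if (any(drop_n)) {
    warning(sprintf("%d record(s) containing N dropped: e.g. %s",
                    sum(drop_n),
                    paste(utils::head(headers[drop_n], 3), collapse = ", ")),
            call. = FALSE)
    keep[drop_n] <- FALSE
  }
  read_library(seqs[keep], counts[keep], name = name)
}

#' Read a small-RNA library from FASTA
#'
#' Reads (optionally gzip-compressed) FASTA, collapses identical sequences
#' with summed counts and normalizes to the DNA alphabet (U to T,
#' uppercase). Header suffixes of the form `_xN` or `_N` (N an integer) are
#' interpreted as pre-collapsed counts; otherwise each record counts 1.
#' Records containing `N` are dropped with a warning; records with other
#' foreign characters are rejected with a warning and the run continues.
#'
#' @param path path to a FASTA file.
#' @param name library label; defaults to the file name without extension.
#' @return a [read_library].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1_x15", "ugaca"), fa)
#' read_fasta(fa)$records  # TGACA with count 15
#' @export
read_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*(\\.gz)?$", "", basename(path))
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) return(read_library(character(), name = name))
  headers <- sub("\\s.*$", "", names(set))
  collapse_records(as.character(set), headers, parse_count_suffix(headers),
                   name)
}

#' Read a small-RNA library from FASTQ
#'
#' Reads (optionally gzip-compressed) 4-line-record FASTQ; qualities are
#' ignored. Collapsing and normalization follow the same contract as
#' [read_fasta]; FASTQ headers carry no count suffix so each record
#' counts 1.
#'
#' @inheritParams read_fasta
#' @return a [read_library].
#' @export
read_fastq <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*(\\.gz)?$", "", basename(path))
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) return(read_library(character(), name = name))
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ in ", path, ": ", length(lines),
         " lines is not a multiple of 4", call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 4L)
  headers <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  if (any(!startsWith(headers, "@")) || any(!startsWith(plus, "+"))) {
    bad <- which(!startsWith(headers, "@") | !startsWith(plus, "+"))[1]
    stop("malformed FASTQ in ", path, ": record ", bad,
         " (line ", (bad - 1L) * 4L + 1L, ") lacks @/+ markers",
         call. = FALSE)
  }
  mism <- nchar(seqs) != nchar(quals)
  if (any(mism)) {
    bad <- which(mism)[1]
    stop("malformed FASTQ in ", path, ": record ", bad,
         " (line ", (bad - 1L) * 4L + 2L,
         ") sequence/quality length mismatch", call. = FALSE)
  }
  collapse_records(seqs, sub("^@", "", sub("\\s.*$", "", headers)),
                   rep(1, length(seqs)), name)
}

#' Write a collapsed library as FASTA
#'
#' Emits one record per unique sequence with headers
#' `<libname>_<i>_x<count>`, so that `read_fasta()` on the output
#' reproduces the library exactly.
#'
#' @param library a [read_library].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_collapsed <- function(library, path) {
  stopifnot(inherits(library, "read_library"))
  rec <- library$records
  lines <- character(0)
  if (nrow(rec) > 0L) {
    headers <- sprintf(">%s_%d_x%d", library$name, seq_len(nrow(rec)),
                       as.integer(rec$count))
    lines <- as.vector(rbind(headers, rec$sequence))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Read a transposon consensus set from FASTA
#'
#' @param path path to a FASTA file of consensus sequences.
#' @return a named character vector (DNA alphabet, uppercase); an object
#'   usable wherever a consensus set is expected.
#' @export
read_consensus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  nm <- sub("\\s.*$", "", names(set))
  seqs <- normalize_sequence(as.character(set))
  consensus_set(seqs, nm)
}

#' Construct a consensus set from sequences and names
#'
#' @param sequences character vector of consensus sequences.
#' @param names unique labels, one per sequence.
#' @return named character vector of class `consensus_set`.
#' @export
consensus_set <- function(sequences, names) {
  sequences <- normalize_sequence(sequences)
  if (length(sequences) != length(names)) stop("names/sequences mismatch")
  if (anyDuplicated(names)) {
    stop("duplicate consensus names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (any(nchar(sequences) == 0L)) stop("empty consensus sequence")
  structure(stats::setNames(sequences, names), class = "consensus_set")
}

#' Write a consensus set as FASTA
#'
#' @param consensus a [consensus_set] or named character vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_consensus <- function(consensus, path) {
  lines <- as.vector(rbind(paste0(">", names(consensus)),
                           as.character(consensus)))
  writeLines(lines, path)
  invisible(path)
}
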