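# Read-length distributions, positional nucleotide biases (1U / 10A) and
# per-transposon strand bias. Statistics are abundance-weighted by default;
# `weighted = FALSE` computes them over unique sequences instead (the
# convention used for published percentages is not standardised, so both
# are exposed).

#' Count-weighted read-length histogram
#'
#' @param library a [read_library].
#' @return object of class `length_histogram`: list with `counts` (named
#'   numeric, names are lengths in nt) and `modal_length` (ties break
#'   toward the smaller length).
#' @export
length_histogram <- function(library) {
  stopifnot(inherits(library, "read_library"))
  rec <- library$records
  if (nrow(rec) == 0L) stop("empty library: no length histogram")
  agg <- tapply(rec$count, nchar(rec$sequence), sum)
  lens <- as.integer(names(agg))
  o <- order(lens)
  counts <- stats::setNames(as.numeric(agg)[o], lens[o])
  modal <- lens[o][which.max(counts)]  # which.max takes the first maximum
  structure(list(counts = counts, modal_length = modal),
            class = "length_histogram")
}

#' Nucleotide fractions at one read position
#'
#' Fractions of A, C, G and U (internally T) at a 1-based position,
#' computed over reads long enough to have that position. Weighted by
#' abundance counts by default.
#'
#' @param library a [read_library].
#' @param position 1-based position.
#' @param weighted if `FALSE`, every unique sequence counts once.
#' @return object of class `positional_bias`: list with `position`,
#'   `fractions` (named numeric over A, C, G, U summing to 1) and
#'   `n_eligible` (weighted count of eligible reads).
#' @export
positional_base_fraction <- function(library, position, weighted = TRUE) {
  stopifnot(inherits(library, "read_library"), position >= 1)
  rec <- library$records
  elig <- nchar(rec$sequence) >= position
  if (!any(elig)) stop("no read long enough for position ", position)
  w <- if (weighted) rec$count[elig] else rep(1, sum(elig))
  base <- substr(rec$sequence[elig], position, position)
  tot <- sum(w)
  frac <- vapply(c(A = "A", C = "C", G = "G", U = "T"),
                 function(b) sum(w[base == b]) / tot, numeric(1))
  structure(list(position = as.integer(position), fractions = frac,
                 n_eligible = tot),
            class = "positional_bias")
}

#' Fraction of reads with 5' U (1U-bias)
#'
#' @inheritParams positional_base_fraction
#' @return numeric fraction in `[0, 1]`.
#' @export
u1_bias <- function(library, weighted = TRUE) {
  positional_base_fraction(library, 1L, weighted)$fractions[["U"]]
}

#' Fraction of reads with A at position 10 (10A-bias)
#'
#' Reads shorter than 10 nt are excluded from the eligible set.
#'
#' @inheritParams positional_base_fraction
#' @return numeric fraction in `[0, 1]`.
#' @export
a10_bias <- function(library, weighted = TRUE) {
  positional_base_fraction(library, 10L, weighted)$fractions[["A"]]
}

#' Per-transposon strand bias of mapped reads
#'
#' Sums hit weights per transposon and strand and scores each transposon
#' by the signed sense fraction `2 f - 1` in `[-1, +1]` (+1 all sense,
#' -1 all antisense). Transposons with zero mapped weight are reported
#' with `NA` fraction and score.
#'
#' @param mapped a [map_library] result.
#' @param consensus optional [consensus_set]; when given, every consensus
#'   appears as a row even with zero weight.
#' @return data.frame with columns `transposon`, `sense_weight`,
#'   `antisense_weight`, `sense_fraction`, `score`.
#' @export
strand_bias_table <- function(mapped, consensus = NULL) {
  stopifnot(inherits(mapped, "mapped_library"))
  h <- mapped$hits
  tps <- if (is.null(consensus)) unique(h$transposon) else names(consensus)
  sw <- aw <- stats::setNames(rep(0, length(tps)), tps)
  if (nrow(h) > 0L) {
    s <- tapply(h$weight[h$strand == "sense"],
                h$transposon[h$strand == "sense"], sum)
    a <- tapply(h$weight[h$strand == "antisense"],
                h$transposon[h$strand == "antisense"], sum)
    sw[names(s)] <- s
    aw[names(a)] <- a
  }
  tot <- sw + aw
  frac <- ifelse(tot > 0, sw / tot, NA_real_)
  data.frame(transposon = tps, sense_weight = as.numeric(sw),
             antisense_weight = as.numeric(aw),
             sense_fraction = as.numeric(frac),
             score = as.numeric(2 * frac - 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a length histogram as TSV
#' @param hist a [length_histogram] result.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_length_tsv <- function(hist, path) {
  utils::write.table(
    data.frame(length = as.integer(names(hist$counts)),
               count = as.numeric(hist$counts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write positional biases as TSV (one row per position)
#' @param biases list of [positional_base_fraction] results.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_bias_tsv <- function(biases, path) {
  rows <- lapply(biases, function(b)
    data.frame(position = b$position, A = b$fractions[["A"]],
               C = b$fractions[["C"]], G = b$fractions[["G"]],
               U = b$fractions[["U"]], n = b$n_eligible))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a strand-bias table as TSV
#' @param tab a [strand_bias_table] result.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_strand_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
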