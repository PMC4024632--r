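# Exact-match placement of reads on transposon consensus sequences.
#
# Coordinates are 0-based half-open throughout: a hit covers
# [start, end) on the consensus as written in the input FASTA ("sense").
# The 5' nucleotide sits at `start` for sense hits and at `end - 1` for
# antisense hits. Multimapping sequences are weighted fractionally so that
# total mapped weight is count-conserving.

#' Build an exact-match k-mer seed index over a consensus set
#'
#' Every k-mer of every consensus (sense strand) is recorded with its
#' position; queries verify full-length matches extending from a seed at
#' the read's first k-mer. Antisense matches are found by querying the
#' reverse complement of the read.
#'
#' @param consensus a [consensus_set] (or named character vector of
#'   sequences).
#' @param k seed length in nt; must not exceed the shortest read that will
#'   be mapped (reads shorter than `k` fall back to a direct scan).
#' @return an object of class `consensus_index`.
#' @examples
#' idx <- build_index(consensus_set("AAAATTTTGGGG", "tp1"), k = 4)
#' idx$n_seeds  # 9
#' @export
build_index <- function(consensus, k = 12L) {
  if (length(consensus) == 0L) stop("empty consensus set")
  if (anyDuplicated(names(consensus))) stop("duplicate consensus names")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  seqs <- normalize_sequence(as.character(consensus))
  names(seqs) <- names(consensus)
  lens <- nchar(seqs)
  short <- lens < k
  if (any(short)) {
    warning("consensus shorter than k contributes no seeds: ",
            paste(names(seqs)[short], collapse = ", "), call. = FALSE)
  }
  all_km <- character(0)
  all_idx <- integer(0)
  all_pos <- integer(0)
  for (i in seq_along(seqs)) {
    L <- lens[i]
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    all_km <- c(all_km, substring(seqs[i], starts, starts + k - 1L))
    all_idx <- c(all_idx, rep.int(i, length(starts)))
    all_pos <- c(all_pos, starts)
  }
  seeds <- new.env(parent = emptyenv(), hash = TRUE,
                   size = max(29L, length(all_km)))
  if (length(all_km)) {
    grp <- split(seq_along(all_km), all_km)
    list2env(lapply(grp, function(g)
      cbind(idx = all_idx[g], pos = all_pos[g])), envir = seeds)
  }
  structure(list(sequences = seqs, k = k, seeds = seeds,
                 n_seeds = length(all_km)),
            class = "consensus_index")
}

#' @export
print.consensus_index <- function(x, ...) {
  cat(sprintf("consensus_index: %d sequence(s), k = %d, %d seed positions\n",
              length(x$sequences), x$k, x$n_seeds))
  invisible(x)
}

# Vectorized one-strand exact lookup of many queries via the seed table.
# Returns (query_id, idx, pos) with 1-based match positions; queries
# shorter than k fall back to a direct fixed-string scan.
seed_lookup_many <- function(index, queries) {
  qlen <- nchar(queries)
  out_q <- integer(0); out_i <- integer(0); out_p <- integer(0)
  long <- which(qlen >= index$k)
  if (length(long)) {
    km <- substr(queries[long], 1L, index$k)
    cand <- mget(km, envir = index$seeds, ifnotfound = list(NULL))
    nc <- vapply(cand, NROW, integer(1))
    if (any(nc > 0L)) {
      qid <- rep.int(long, nc)
      mat <- do.call(rbind, cand[nc > 0L])
      full <- substring(index$sequences[mat[, "idx"]], mat[, "pos"],
                        mat[, "pos"] + qlen[qid] - 1L)
      ok <- full == queries[qid]
      out_q <- qid[ok]; out_i <- mat[ok, "idx"]; out_p <- mat[ok, "pos"]
    }
  }
  for (q in which(qlen < index$k)) {      # rare: reads shorter than k
    n <- qlen[q]
    for (i in seq_along(index$sequences)) {
      L <- nchar(index$sequences[i])
      if (L < n) next
      starts <- seq_len(L - n + 1L)     # all-substring scan: overlapping
      found <- starts[substring(index$sequences[i], starts,
                                starts + n - 1L) == queries[q]]
      if (length(found)) {
        out_q <- c(out_q, rep.int(q, length(found)))
        out_i <- c(out_i, rep.int(i, length(found)))
        out_p <- c(out_p, found)
      }
    }
  }
  list(query = out_q, idx = out_i, pos = out_p)
}

# Map many normalized sequences at once; returns one data.frame of hits
# keyed by `seq_id` (position in `sequences`), deterministically ordered
# by (seq_id, transposon, start, strand).
map_many <- function(index, sequences) {
  qlen <- nchar(sequences)
  sn <- seed_lookup_many(index, sequences)
  an <- seed_lookup_many(index, reverse_complement(sequences))
  seq_id <- c(sn$query, an$query)
  if (length(seq_id) == 0L) {
    return(data.frame(seq_id = integer(), transposon = character(),
                      start = integer(), end = integer(),
                      strand = character(), five_prime = integer(),
                      stringsAsFactors = FALSE))
  }
  idx <- c(sn$idx, an$idx)
  start <- c(sn$pos, an$pos) - 1L
  strand <- rep(c("sense", "antisense"),
                c(length(sn$query), length(an$query)))
  end <- start + qlen[seq_id]
  out <- data.frame(
    seq_id = seq_id, transposon = names(index$sequences)[idx],
    start = start, end = end, strand = strand,
    five_prime = ifelse(strand == "sense", start, end - 1L),
    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("seq_id", "transposon", "start",
                               "strand")]), , drop = FALSE]
  out <- out[order(out$seq_id, out$transposon, out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map one sequence to all exact occurrences on both strands
#'
#' @param index a [build_index] result.
#' @param sequence a normalized read (uppercase DNA).
#' @return data.frame with columns `sequence`, `transposon`, `start`,
#'   `end` (0-based half-open), `strand` (`"sense"`/`"antisense"`) and
#'   `five_prime`; zero rows when the read does not occur. Rows are ordered
#'   by (transposon, start, strand).
#' @export
map_sequence <- function(index, sequence) {
  stopifnot(inherits(index, "consensus_index"), length(sequence) == 1L)
  sequence <- normalize_sequence(sequence)
  out <- map_many(index, sequence)
  out$sequence <- rep.int(sequence, nrow(out))
  out[c("sequence", "transposon", "start", "end", "strand", "five_prime")]
}

#' Map a collapsed library onto a consensus index
#'
#' Each unique sequence is mapped once; every hit of a sequence receives
#' weight `count / n_hits`, so the summed weight of all hits of a sequence
#' equals its library count and total mapped weight plus `unmapped_count`
#' equals the library's `total_count`.
#'
#' @param index a [build_index] result.
#' @param library a [read_library].
#' @return an object of class `mapped_library`: list with `name`, `hits`
#'   (data.frame with hit columns plus `weight`) and `unmapped_count`.
#' @export
map_library <- function(index, library) {
  stopifnot(inherits(library, "read_library"))
  rec <- library$records
  h <- map_many(index, rec$sequence)
  n_hits <- tabulate(h$seq_id, nbins = nrow(rec))
  unmapped <- sum(rec$count[n_hits == 0L])
  hits <- data.frame(
    sequence = rec$sequence[h$seq_id], transposon = h$transposon,
    start = h$start, end = h$end, strand = h$strand,
    five_prime = h$five_prime,
    weight = rec$count[h$seq_id] / n_hits[h$seq_id],
    stringsAsFactors = FALSE)
  structure(list(name = library$name, hits = hits,
                 unmapped_count = unmapped),
            class = "mapped_library")
}

#' @export
print.mapped_library <- function(x, ...) {
  cat(sprintf(
    "mapped_library '%s': %d hits (weight %.1f), unmapped count %s\n",
    x$name, nrow(x$hits), sum(x$hits$weight), format(x$unmapped_count)))
  invisible(x)
}

#' Write mapped hits as BED6
#'
#' `chrom` is the transposon name, coordinates are the 0-based half-open
#' hit interval, `name` the read sequence, `score` the hit weight times
#' 1000 rounded, and `strand` `+`/`-` for sense/antisense.
#'
#' @param mapped a [map_library] result.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_bed <- function(mapped, path) {
  h <- mapped$hits
  bed <- data.frame(chrom = h$transposon, chromStart = h$start,
                    chromEnd = h$end, name = h$sequence,
                    score = round(h$weight * 1000),
                    strand = ifelse(h$strand == "sense", "+", "-"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write mapped hits as TSV including the 5' coordinate column
#'
#' @inheritParams write_bed
#' @return invisibly, the path.
#' @export
write_hits_tsv <- function(mapped, path) {
  utils::write.table(mapped$hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
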