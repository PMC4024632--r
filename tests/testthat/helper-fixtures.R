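# Shared fixtures: all generated in code, nothing on disk.

write_tmp <- function(lines, ext = ".fa") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# n random reads of the given lengths, chopped from one random string
random_reads <- function(n, lengths = 27L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lengths <- rep_len(lengths, n)
  pool <- paste(sample(c("A", "C", "G", "T"), sum(lengths),
                       replace = TRUE), collapse = "")
  ends <- cumsum(lengths)
  substring(pool, ends - lengths + 1L, ends)
}

# minimal mapped_library from explicit hit rows (for histogram/strand tests)
mk_mapped <- function(transposon, five_prime, strand, weight = 1,
                      read_len = 26L, name = "stub") {
  n <- length(five_prime)
  strand <- rep_len(strand, n)
  weight <- rep_len(weight, n)
  start <- ifelse(strand == "sense", five_prime, five_prime - read_len + 1L)
  hits <- data.frame(
    sequence = strrep("A", read_len), transposon = rep_len(transposon, n),
    start = start, end = start + read_len, strand = strand,
    five_prime = five_prime, weight = weight, stringsAsFactors = FALSE)
  structure(list(name = name, hits = hits, unmapped_count = 0),
            class = "mapped_library")
}

# naive all-substring scan of both strands: the mapping oracle
brute_force_map <- function(consensus, read) {
  rows <- list()
  rc <- pirnakit::reverse_complement(read)
  n <- nchar(read)
  for (i in seq_along(consensus)) {
    s <- as.character(consensus[[i]])
    L <- nchar(s)
    if (L < n) next
    starts <- seq_len(L - n + 1L)
    subs <- substring(s, starts, starts + n - 1L)
    for (st in starts[subs == read]) {
      rows[[length(rows) + 1L]] <- data.frame(
        transposon = names(consensus)[i], start = st - 1L,
        end = st - 1L + n, strand = "sense", five_prime = st - 1L,
        stringsAsFactors = FALSE)
    }
    for (st in starts[subs == rc]) {
      rows[[length(rows) + 1L]] <- data.frame(
        transposon = names(consensus)[i], start = st - 1L,
        end = st - 1L + n, strand = "antisense", five_prime = st - 2L + n,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(transposon = character(), start = integer(),
                      end = integer(), strand = character(),
                      five_prime = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$transposon, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
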