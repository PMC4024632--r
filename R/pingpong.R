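# The Ping-pong signature: distribution of 5'-5' overlap distances
# between opposite-strand read populations on a shared consensus, and a
# z-score for the 10-nt peak.
#
# Overlap convention: for a sense hit with 5' coordinate p and an
# antisense hit with 5' coordinate q on the same transposon, the overlap
# is d = q - p + 1, so 5' ends 9 nt apart give d = 10 (the classic
# secondary-biogenesis geometry) and coinciding 5' ends give d = 1.
# Pairs outside [dmin, dmax] — including 3'-side configurations with
# d < 1 — are ignored.

#' 5'-5' overlap histogram between two mapped libraries
#'
#' Every pair of hits on the same transposon with opposite strands (one
#' hit from each library, in either role) contributes the product of its
#' hit weights to the bin of its overlap distance. The histogram is
#' symmetric in its two arguments.
#'
#' @param mapped_a,mapped_b [map_library] results over the same consensus
#'   set.
#' @param dmin,dmax overlap range in nt (default 1-30, covering piRNA
#'   lengths).
#' @return object of class `overlap_histogram`: list with `dmin`, `dmax`,
#'   `counts` (named numeric over `dmin:dmax`) and `total_pairs` (summed
#'   pair weight in range).
#' @export
overlap_histogram <- function(mapped_a, mapped_b, dmin = 1L, dmax = 30L) {
  stopifnot(inherits(mapped_a, "mapped_library"),
            inherits(mapped_b, "mapped_library"), dmin <= dmax, dmin >= 1)
  ds <- dmin:dmax
  counts <- stats::setNames(rep(0, length(ds)), ds)
  if (nrow(mapped_a$hits) == 0L || nrow(mapped_b$hits) == 0L) {
    warning("empty mapped library: empty overlap histogram", call. = FALSE)
    return(structure(list(dmin = as.integer(dmin), dmax = as.integer(dmax),
                          counts = counts, total_pairs = 0),
                     class = "overlap_histogram"))
  }
  # aggregate weight by (transposon, strand, five_prime)
  agg <- function(h, strand) {
    sel <- h$strand == strand
    if (!any(sel)) return(NULL)
    key <- paste(h$transposon[sel], h$five_prime[sel], sep = "\r")
    w <- tapply(h$weight[sel], key, sum)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    data.frame(transposon = vapply(parts, `[`, "", 1L),
               five_prime = as.integer(vapply(parts, `[`, "", 2L)),
               weight = as.numeric(w), stringsAsFactors = FALSE)
  }
  cross <- function(sense, anti) {
    if (is.null(sense) || is.null(anti)) return()
    for (tp in intersect(unique(sense$transposon),
                         unique(anti$transposon))) {
      s <- sense[sense$transposon == tp, ]
      a <- anti[anti$transposon == tp, ]
      d <- outer(a$five_prime, s$five_prime, `-`) + 1L
      w <- outer(a$weight, s$weight)
      keep <- d >= dmin & d <= dmax
      if (any(keep)) {
        add <- tapply(w[keep], d[keep], sum)
        counts[names(add)] <<- counts[names(add)] + as.numeric(add)
      }
    }
  }
  cross(agg(mapped_a$hits, "sense"), agg(mapped_b$hits, "antisense"))
  cross(agg(mapped_b$hits, "sense"), agg(mapped_a$hits, "antisense"))
  structure(list(dmin = as.integer(dmin), dmax = as.integer(dmax),
                 counts = counts, total_pairs = sum(counts)),
            class = "overlap_histogram")
}

#' @export
print.overlap_histogram <- function(x, ...) {
  cat(sprintf("overlap_histogram [%d, %d] nt, total pair weight %.1f\n",
              x$dmin, x$dmax, x$total_pairs))
  if (x$total_pairs > 0) {
    peak <- names(x$counts)[which.max(x$counts)]
    cat(sprintf("  peak at d = %s (%.1f%% of weight)\n", peak,
                100 * max(x$counts) / x$total_pairs))
  }
  invisible(x)
}

#' z-score of the Ping-pong peak
#'
#' Compares the count in the target bin (default 10 nt) to the mean and
#' sample (n-1) standard deviation of all other bins in the histogram
#' range. When the background standard deviation is zero the score is
#' undefined and `z` is `NA` (never infinite).
#'
#' @param histogram an [overlap_histogram].
#' @param target_bin overlap distance of interest in nt.
#' @return object of class `pingpong_score`: list with `target_bin`, `z`,
#'   `background_mean`, `background_sd`.
#' @export
pingpong_zscore <- function(histogram, target_bin = 10L) {
  stopifnot(inherits(histogram, "overlap_histogram"))
  if (target_bin < histogram$dmin || target_bin > histogram$dmax) {
    stop("target_bin ", target_bin, " outside histogram range")
  }
  bg <- histogram$counts[names(histogram$counts) != as.character(target_bin)]
  if (length(bg) < 2L) {
    stop("need at least 2 background bins for a z-score")
  }
  m <- mean(bg)
  s <- stats::sd(bg)
  dev <- histogram$counts[[as.character(target_bin)]] - m
  # a perfectly flat histogram scores 0; a spike over a constant
  # background is undefined (never infinite)
  z <- if (s > 0) dev / s else if (dev == 0) 0 else NA_real_
  structure(list(target_bin = as.integer(target_bin), z = z,
                 background_mean = m, background_sd = s),
            class = "pingpong_score")
}

#' @export
print.pingpong_score <- function(x, ...) {
  cat(sprintf(
    "pingpong_score: bin %d nt, z = %s (background %.3f +/- %.3f)\n",
    x$target_bin, ifelse(is.na(x$z), "undefined", sprintf("%.2f", x$z)),
    x$background_mean, x$background_sd))
  invisible(x)
}

#' Write an overlap histogram as TSV
#'
#' Columns: distance, weighted_count and fraction of total pair weight.
#'
#' @param histogram an [overlap_histogram].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_overlap_tsv <- function(histogram, path) {
  frac <- if (histogram$total_pairs > 0)
    histogram$counts / histogram$total_pairs else histogram$counts * 0
  utils::write.table(
    data.frame(distance = as.integer(names(histogram$counts)),
               weighted_count = as.numeric(histogram$counts),
               fraction = as.numeric(frac)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a Ping-pong score as TSV
#' @param score a [pingpong_zscore] result.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_score_tsv <- function(score, path) {
  utils::write.table(
    data.frame(target_bin = score$target_bin, z = score$z,
               background_mean = score$background_mean,
               background_sd = score$background_sd),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
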