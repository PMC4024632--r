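# Generative model of piRNA biogenesis on a transposon consensus.
#
# Primary reads are cut from the antisense strand with a tunable 5'-U
# preference: p_1U is the marginal probability that a read starts with U
# (the quantity reported as "1U bias"). It is realised as a mixture —
# with weight m the 5' coordinate is drawn uniformly from antisense
# positions whose first nucleotide is U (consensus base A at that
# coordinate), otherwise uniformly from all valid positions — where m is
# solved per read length so the mixture's marginal U frequency equals
# p_1U; when p_1U is below the background U frequency the mixture
# saturates at the unconditional draw. Secondary reads are slicer
# products on the sense
# strand whose 5' coordinate sits exactly `overlap` nt into a sampled
# primary partner (5'-5' overlap = overlap, default 10 nt), so a U at a
# partner's position 1 forces an A at the secondary's position 10 by
# base-pair complementarity. Lengths follow a discrete triangular law on
# 24-32 nt; 3' ends are drawn independently of the partner.
#
# All randomness flows through R's RNG; pass `seed` for reproducibility.

#' Discrete triangular read-length distribution
#'
#' Probability weights rise linearly from `min` to `mode` and fall
#' linearly to `max`, emulating the unimodal 24-32 nt length profile of
#' piRNA libraries (primary populations peak near 28 nt, secondary near
#' 27 nt).
#'
#' @param min,max inclusive length range in nt.
#' @param mode modal length in nt.
#' @return object of class `length_law`: list with `lengths` and `prob`.
#' @export
length_law <- function(min = 24L, max = 32L, mode = 28L) {
  stopifnot(min >= 1, min <= mode, mode <= max)
  lens <- min:max
  up <- (lens - (min - 1)) / (mode - (min - 1))
  down <- ((max + 1) - lens) / ((max + 1) - mode)
  w <- pmin(up, down)
  structure(list(lengths = lens, prob = w / sum(w)), class = "length_law")
}

draw_lengths <- function(law, n) {
  sample(law$lengths, n, replace = TRUE, prob = law$prob)
}

#' Random transposon consensus sequence
#'
#' i.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`.
#'
#' @param length consensus length in nt (at least 50).
#' @param gc_content GC fraction in `[0, 1]`.
#' @param seed optional integer seed.
#' @param name consensus label.
#' @return a single-entry [consensus_set].
#' @export
random_consensus <- function(length, gc_content = 0.5, seed = NULL,
                             name = "consensus_1") {
  stopifnot(length >= 50)
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc_content) / 2, gc_content / 2,
                           gc_content / 2, (1 - gc_content) / 2))
  consensus_set(paste(bases, collapse = ""), name)
}

empty_truth <- function() {
  data.frame(read_id = character(), sequence = character(),
             transposon = character(), five_prime = integer(),
             strand = character(), origin = character(),
             partner_id = character(), stringsAsFactors = FALSE)
}

#' Simulate a primary piRNA library
#'
#' Primary reads lie on the antisense strand of the consensus (the
#' orientation of primary, Siwi-type piRNA populations). Read lengths are
#' drawn from `law`; each read's 5' coordinate is drawn from a mixture of
#' a U-conditioned draw (uniform over antisense positions carrying a 5'
#' U, i.e. consensus base A) and an unconditional draw (uniform over all
#' positions admitting the drawn length), with the mixture weight solved
#' per length so that the expected 1U fraction of the library equals
#' `p_1U`. When `p_1U` is below the consensus's background U frequency
#' the mixture saturates at the unconditional draw and the realised bias
#' equals that background (about 0.25 on a balanced consensus at
#' `p_1U = 0`).
#'
#' @param consensus a single-entry [consensus_set] (or the first entry of
#'   a larger one is used, with a warning).
#' @param n_reads number of reads to simulate.
#' @param p_1U target marginal probability of a 5' U (default 0.8, the
#'   1U bias characteristic of primary-piRNA-binding Piwi proteins).
#' @param law a [length_law] (default mode 28 nt).
#' @param seed optional integer seed.
#' @return list with `library` (a collapsed [read_library]) and `truth`
#'   (data.frame: `read_id`, `sequence`, `transposon`, `five_prime`
#'   (0-based consensus coordinate of the 5' nucleotide), `strand`,
#'   `origin = "primary"`, `partner_id = NA`).
#' @export
simulate_primary <- function(consensus, n_reads, p_1U = 0.8,
                             law = length_law(mode = 28L), seed = NULL) {
  stopifnot(n_reads >= 1, p_1U >= 0, p_1U <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (length(consensus) > 1L) {
    warning("using first consensus entry only", call. = FALSE)
  }
  cons <- as.character(consensus[[1L]])
  tp <- names(consensus)[1L]
  L <- nchar(cons)
  if (L < max(law$lengths)) stop("consensus shorter than the longest read")
  cons_bases <- strsplit(cons, "")[[1L]]
  # 0-based antisense 5' coordinates whose read starts with U
  u_starts <- which(cons_bases == "A") - 1L
  lens <- draw_lengths(law, n_reads)
  unif <- stats::runif(n_reads)
  q <- integer(n_reads)
  for (l in unique(lens)) {
    sel <- lens == l
    # antisense 5' at q covers [q - l + 1, q]; need q >= l - 1
    pool_all <- (l - 1L):(L - 1L)
    pool_u <- u_starts[u_starts >= l - 1L]
    bg <- length(pool_u) / length(pool_all)
    # mixture weight giving marginal P(U1) = p_1U; saturates at the
    # unconditional draw when p_1U <= background
    m <- if (bg >= 1) 0 else min(1, max(0, (p_1U - bg) / (1 - bg)))
    use_u <- sel & unif < m
    nu <- sum(use_u)
    na <- sum(sel) - nu
    if (nu > 0L) {
      if (length(pool_u) == 0L) {
        stop("no U-start position admits a read of length ", l)
      }
      q[use_u] <- pool_u[sample.int(length(pool_u), nu, replace = TRUE)]
    }
    if (na > 0L) {
      q[sel & !use_u] <- pool_all[sample.int(length(pool_all), na,
                                             replace = TRUE)]
    }
  }
  start <- q - lens + 1L
  windows <- substring(cons, start + 1L, q + 1L)
  seqs <- reverse_complement(windows)
  ids <- sprintf("p%06d", seq_len(n_reads))
  truth <- data.frame(read_id = ids, sequence = seqs, transposon = tp,
                      five_prime = q, strand = "antisense",
                      origin = "primary", partner_id = NA_character_,
                      stringsAsFactors = FALSE)
  list(library = read_library(seqs, name = "primary"), truth = truth)
}

#' Simulate a secondary (Ping-pong) piRNA library
#'
#' Each secondary read samples a primary partner (abundance-weighted,
#' i.e. uniformly over the primary truth records) and is placed on the
#' opposite (sense) strand with its 5' coordinate `p = q - (overlap - 1)`
#' where `q` is the partner's 5' coordinate, giving a 5'-5' overlap of
#' exactly `overlap` nt. Lengths are drawn independently from `law`;
#' draws whose read would run off the consensus are resampled.
#'
#' @param primary_truth the `truth` data.frame from [simulate_primary].
#' @param consensus the same consensus the primaries were simulated on.
#' @param n_reads number of secondary reads.
#' @param overlap 5'-5' overlap in nt (default 10, the slicer geometry of
#'   the Ping-pong cycle).
#' @param law a [length_law] (default mode 27 nt).
#' @param seed optional integer seed.
#' @return list with `library` (collapsed [read_library], name
#'   "secondary") and `truth` (`origin = "secondary"`, `partner_id`
#'   linking each read to its primary partner).
#' @export
simulate_secondary <- function(primary_truth, consensus, n_reads,
                               overlap = 10L, law = length_law(mode = 27L),
                               seed = NULL) {
  stopifnot(n_reads >= 1, overlap >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(primary_truth) == 0L) stop("no primary records")
  cons <- as.character(consensus[[1L]])
  tp <- names(consensus)[1L]
  L <- nchar(cons)
  max_p <- max(primary_truth$five_prime) - (overlap - 1L)
  if (max_p < 0L) {
    stop("overlap geometry impossible: no primary 5' end at coordinate >= ",
         overlap - 1L)
  }
  partner <- integer(n_reads)
  p <- integer(n_reads)
  lens <- integer(n_reads)
  todo <- seq_len(n_reads)
  tries <- 0L
  while (length(todo) > 0L) {
    tries <- tries + 1L
    if (tries > 1000L) stop("overlap geometry impossible for all primaries")
    partner[todo] <- sample.int(nrow(primary_truth), length(todo),
                                replace = TRUE)
    lens[todo] <- draw_lengths(law, length(todo))
    p[todo] <- primary_truth$five_prime[partner[todo]] - (overlap - 1L)
    ok <- p[todo] >= 0L & (p[todo] + lens[todo]) <= L
    todo <- todo[!ok]
  }
  seqs <- substring(cons, p + 1L, p + lens)
  ids <- sprintf("s%06d", seq_len(n_reads))
  truth <- data.frame(read_id = ids, sequence = seqs, transposon = tp,
                      five_prime = p, strand = "sense",
                      origin = "secondary",
                      partner_id = primary_truth$read_id[partner],
                      stringsAsFactors = FALSE)
  list(library = read_library(seqs, name = "secondary"), truth = truth)
}

#' Simulate a mixture ("chimera-like") library
#'
#' Reads are drawn from parent libraries at the given proportions
#' (abundance-weighted within each parent), except that with probability
#' `novel_fraction` a read is instead a novel random sequence absent from
#' any parent by construction with overwhelming probability.
#'
#' @param libraries list of parent [read_library] objects.
#' @param proportions numeric vector summing to 1, one entry per parent:
#'   the relative contribution of each parent among non-novel reads.
#' @param n_reads number of reads in the mixture.
#' @param novel_fraction probability that a read is novel, in `[0, 1]`.
#' @param seed optional integer seed.
#' @param law [length_law] for novel read lengths (default mode 27 nt).
#' @return list with `library` (collapsed [read_library], name "mixture")
#'   and `truth` (data.frame: `read_id`, `sequence`, `origin` — a parent
#'   library name or "novel").
#' @export
simulate_mixture <- function(libraries, proportions, n_reads,
                             novel_fraction = 0, seed = NULL,
                             law = length_law(mode = 27L)) {
  stopifnot(length(libraries) == length(proportions), n_reads >= 1)
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (novel_fraction < 0 || novel_fraction > 1) {
    stop("novel_fraction must be in [0,1]")
  }
  if (!is.null(seed)) set.seed(seed)
  parent_names <- vapply(libraries, function(l) l$name, "")
  is_novel <- stats::runif(n_reads) < novel_fraction
  which_parent <- rep(NA_integer_, n_reads)
  n_parent <- sum(!is_novel)
  if (n_parent > 0L) {
    which_parent[!is_novel] <- sample.int(length(libraries), n_parent,
                                          replace = TRUE,
                                          prob = proportions)
  }
  seqs <- character(n_reads)
  for (i in seq_along(libraries)) {
    sel <- !is_novel & which_parent == i
    if (!any(sel)) next
    rec <- libraries[[i]]$records
    seqs[sel] <- rec$sequence[sample.int(nrow(rec), sum(sel),
                                         replace = TRUE,
                                         prob = rec$count)]
  }
  if (any(is_novel)) {
    nl <- draw_lengths(law, sum(is_novel))
    seqs[is_novel] <- vapply(nl, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
            collapse = ""), "")
  }
  origin <- ifelse(is_novel, "novel", parent_names[which_parent])
  truth <- data.frame(read_id = sprintf("m%06d", seq_len(n_reads)),
                      sequence = seqs, origin = origin,
                      stringsAsFactors = FALSE)
  list(library = read_library(seqs, name = "mixture"), truth = truth)
}

#' Write a simulation truth table as TSV
#'
#' @param truth a truth data.frame from one of the simulators.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
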