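# Cross-library sequence sharing and fold-enrichment classification:
# the rule used to attribute reads bound by a hybrid Piwi protein to one
# of its two parent proteins. Comparison is on reads-per-million by
# default so libraries of different sequencing depth are commensurate;
# raw-count mode is retained behind `normalization = "raw"`.

#' Reads-per-million normalization
#'
#' @param library a [read_library] with `total_count > 0`.
#' @return named numeric vector: `rpm(s) = count(s) * 1e6 / total_count`.
#' @export
normalize_rpm <- function(library) {
  stopifnot(inherits(library, "read_library"))
  if (library$total_count <= 0) stop("empty library: cannot normalize")
  stats::setNames(library$records$count * 1e6 / library$total_count,
                  library$records$sequence)
}

#' Classify sequences by fold enrichment between two libraries
#'
#' Over the union of sequences in A and B, each sequence with normalized
#' abundances `a` and `b` is classed `A_only` when `a >= fold * b`,
#' `B_only` when `b >= fold * a`, and `shared_AB` otherwise. A sequence
#' absent from one library has abundance 0 there, so any presence in the
#' other library yields that side's exclusive class. Ties at exactly
#' `fold`-times are assigned to the enriched side.
#'
#' @param lib_a,lib_b [read_library] objects.
#' @param fold enrichment threshold, `> 1` (default 5).
#' @param normalization `"rpm"` (default) or `"raw"` counts.
#' @return object of class `enrichment_classification`: list with `table`
#'   (data.frame: `sequence`, `abundance_a`, `abundance_b`, `class`),
#'   `fold_threshold`, `normalization` and the two library names.
#' @export
classify_sequences <- function(lib_a, lib_b, fold = 5,
                               normalization = c("rpm", "raw")) {
  stopifnot(inherits(lib_a, "read_library"),
            inherits(lib_b, "read_library"), fold > 1)
  normalization <- match.arg(normalization)
  av <- if (normalization == "rpm") normalize_rpm(lib_a) else
    stats::setNames(lib_a$records$count, lib_a$records$sequence)
  bv <- if (normalization == "rpm") normalize_rpm(lib_b) else
    stats::setNames(lib_b$records$count, lib_b$records$sequence)
  seqs <- sort(union(names(av), names(bv)))
  a <- ifelse(seqs %in% names(av), av[seqs], 0)
  b <- ifelse(seqs %in% names(bv), bv[seqs], 0)
  cls <- ifelse(a >= fold * b, "A_only",
                ifelse(b >= fold * a, "B_only", "shared_AB"))
  structure(list(
    table = data.frame(sequence = seqs, abundance_a = as.numeric(a),
                       abundance_b = as.numeric(b), class = cls,
                       stringsAsFactors = FALSE, row.names = NULL),
    fold_threshold = fold, normalization = normalization,
    name_a = lib_a$name, name_b = lib_b$name),
    class = "enrichment_classification")
}

#' Partition a third library's reads against two parent libraries
#'
#' Each sequence of the query (chimera-bound) library is looked up in the
#' union of the two parents by exact full-sequence identity. Sequences
#' found in a parent are "in parents" and carry their
#' [classify_sequences] class (A_only / B_only / shared_AB); the rest are
#' "only in chimera". All fractions are weighted by the query library's
#' counts.
#'
#' @param chimera the query [read_library].
#' @param lib_a,lib_b parent [read_library] objects.
#' @inheritParams classify_sequences
#' @return object of class `chimera_partition`: list with
#'   `fraction_in_parents`, `fraction_only_in_chimera`, `breakdown`
#'   (named numeric: fractions of total chimera weight in A_only, B_only,
#'   shared_AB), `per_sequence` (data.frame) and `fold_threshold`.
#' @export
partition_chimera <- function(chimera, lib_a, lib_b, fold = 5,
                              normalization = c("rpm", "raw")) {
  stopifnot(inherits(chimera, "read_library"))
  cls <- classify_sequences(lib_a, lib_b, fold, normalization)
  lut <- stats::setNames(cls$table$class, cls$table$sequence)
  rec <- chimera$records
  found <- rec$sequence %in% names(lut)
  assigned <- ifelse(found, lut[rec$sequence], "only_in_chimera")
  tot <- sum(rec$count)
  frac_of <- function(label) sum(rec$count[assigned == label]) / tot
  breakdown <- c(A_only = frac_of("A_only"), B_only = frac_of("B_only"),
                 shared_AB = frac_of("shared_AB"))
  av <- normalize_rpm(lib_a)
  bv <- normalize_rpm(lib_b)
  per_seq <- data.frame(
    sequence = rec$sequence, count_chimera = rec$count,
    rpm_a = as.numeric(ifelse(rec$sequence %in% names(av),
                              av[rec$sequence], 0)),
    rpm_b = as.numeric(ifelse(rec$sequence %in% names(bv),
                              bv[rec$sequence], 0)),
    class = as.character(assigned),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    fraction_in_parents = sum(rec$count[found]) / tot,
    fraction_only_in_chimera = sum(rec$count[!found]) / tot,
    breakdown = breakdown, per_sequence = per_seq,
    fold_threshold = fold),
    class = "chimera_partition")
}

#' @export
print.chimera_partition <- function(x, ...) {
  cat(sprintf(
    "chimera_partition: %.1f%% in parents (A_only %.1f%%, B_only %.1f%%, shared %.1f%%), %.1f%% only in chimera\n",
    100 * x$fraction_in_parents, 100 * x$breakdown[["A_only"]],
    100 * x$breakdown[["B_only"]], 100 * x$breakdown[["shared_AB"]],
    100 * x$fraction_only_in_chimera))
  invisible(x)
}

#' Write a chimera partition as TSVs
#'
#' Writes the per-sequence table to `<prefix>.sequences.tsv` and the
#' summary fractions to `<prefix>.summary.tsv`.
#'
#' @param partition a [partition_chimera] result.
#' @param prefix output path prefix.
#' @return invisibly, the two paths.
#' @export
write_partition_tsv <- function(partition, prefix) {
  p1 <- paste0(prefix, ".sequences.tsv")
  p2 <- paste0(prefix, ".summary.tsv")
  utils::write.table(partition$per_sequence, p1, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- data.frame(
    metric = c("fraction_in_parents", "fraction_only_in_chimera",
               "fraction_A_only", "fraction_B_only", "fraction_shared_AB",
               "fold_threshold"),
    value = c(partition$fraction_in_parents,
              partition$fraction_only_in_chimera,
              partition$breakdown[["A_only"]],
              partition$breakdown[["B_only"]],
              partition$breakdown[["shared_AB"]],
              partition$fold_threshold))
  utils::write.table(summ, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
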