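# File-level pipeline stages. Each cmd_* function reads standard formats,
# runs one analysis stage and writes machine-readable TSV/BED/YAML under
# an output prefix; cmd_report collects the stage outputs into one
# summary without recomputing anything. Log messages go to standard
# error via message().

#' Run the simulator and write all artifacts
#'
#' Writes `consensus.fa`, collapsed FASTA per library (`primary.fa`,
#' `secondary.fa`, `mixture.fa`), a combined truth TSV and a YAML echo of
#' the configuration into `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving all randomness.
#' @param consensus_length,gc_content consensus parameters.
#' @param n_primary,n_secondary,n_mixture library sizes.
#' @param p_1U primary 5'-U preference.
#' @param overlap secondary 5'-5' overlap in nt.
#' @param mixture_proportions parent proportions (primary, secondary) for
#'   the mixture library.
#' @param novel_fraction novel-read fraction of the mixture.
#' @return invisibly, a list of the generated objects.
#' @export
cmd_simulate <- function(out_dir, seed = 1L, consensus_length = 5000L,
                         gc_content = 0.5, n_primary = 2000L,
                         n_secondary = 2000L, n_mixture = 2000L,
                         p_1U = 0.8, overlap = 10L,
                         mixture_proportions = c(0.3, 0.7),
                         novel_fraction = 0.37) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  cons <- random_consensus(consensus_length, gc_content, seed = seed)
  prim <- simulate_primary(cons, n_primary, p_1U = p_1U, seed = seed + 1L)
  seco <- simulate_secondary(prim$truth, cons, n_secondary,
                             overlap = overlap, seed = seed + 2L)
  mix <- simulate_mixture(list(prim$library, seco$library),
                          mixture_proportions, n_mixture,
                          novel_fraction = novel_fraction,
                          seed = seed + 3L)
  write_consensus(cons, file.path(out_dir, "consensus.fa"))
  write_collapsed(prim$library, file.path(out_dir, "primary.fa"))
  write_collapsed(seco$library, file.path(out_dir, "secondary.fa"))
  write_collapsed(mix$library, file.path(out_dir, "mixture.fa"))
  truth <- rbind(prim$truth, seco$truth)
  write_truth_tsv(truth, file.path(out_dir, "truth.tsv"))
  write_truth_tsv(mix$truth, file.path(out_dir, "truth_mixture.tsv"))
  cfg <- list(seed = seed, consensus_length = consensus_length,
              gc_content = gc_content, n_primary = n_primary,
              n_secondary = n_secondary, n_mixture = n_mixture,
              p_1U = p_1U, overlap = overlap,
              mixture_proportions = as.numeric(mixture_proportions),
              novel_fraction = novel_fraction)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  message("simulated libraries written to ", out_dir)
  invisible(list(consensus = cons, primary = prim, secondary = seco,
                 mixture = mix, config = cfg))
}

read_any_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(gzfile(path), n = 1L)
  if (length(first) && startsWith(first, "@")) read_fastq(path)
  else read_fasta(path)
}

#' Map a read library onto consensus sequences
#'
#' Writes `<out_prefix>.bed` (BED6), `<out_prefix>.hits.tsv` (with the 5'
#' coordinate column) and `<out_prefix>.unmapped.tsv`.
#'
#' @param reads_path FASTA/FASTQ of reads (may be pre-collapsed).
#' @param consensus_path FASTA of consensus sequences.
#' @param out_prefix output path prefix.
#' @param k seed length for the index.
#' @return invisibly, the [map_library] result.
#' @export
cmd_map <- function(reads_path, consensus_path, out_prefix, k = 12L) {
  lib <- read_any_library(reads_path)
  if (lib$total_count == 0) stop("no reads in ", reads_path)
  idx <- build_index(read_consensus(consensus_path), k = k)
  mapped <- map_library(idx, lib)
  write_bed(mapped, paste0(out_prefix, ".bed"))
  write_hits_tsv(mapped, paste0(out_prefix, ".hits.tsv"))
  utils::write.table(
    data.frame(library = lib$name, unmapped_count = mapped$unmapped_count,
               total_count = lib$total_count),
    paste0(out_prefix, ".unmapped.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d hits, unmapped count %s", lib$name,
                  nrow(mapped$hits), format(mapped$unmapped_count)))
  invisible(mapped)
}

# rebuild a mapped_library from a cmd_map hits TSV
read_hits_tsv <- function(path, name = "mapped") {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(name = name, hits = h, unmapped_count = NA_real_),
            class = "mapped_library")
}

#' Library statistics: length histogram, positional biases, strand bias
#'
#' Writes `<out_prefix>.lengths.tsv` and `<out_prefix>.bias.tsv` (U1 and
#' A10 rows) always, plus `<out_prefix>.strand.tsv` when a consensus is
#' supplied (the library is then mapped first).
#'
#' @param reads_path FASTA/FASTQ of reads.
#' @param out_prefix output path prefix.
#' @param consensus_path optional consensus FASTA for strand bias.
#' @param weighted abundance-weighted statistics (default) or
#'   unique-sequence mode.
#' @return invisibly, a list of the computed statistics.
#' @export
cmd_stats <- function(reads_path, out_prefix, consensus_path = NULL,
                      weighted = TRUE) {
  lib <- read_any_library(reads_path)
  if (lib$total_count == 0) stop("no reads in ", reads_path)
  lh <- length_histogram(lib)
  write_length_tsv(lh, paste0(out_prefix, ".lengths.tsv"))
  biases <- list(positional_base_fraction(lib, 1L, weighted),
                 positional_base_fraction(lib, 10L, weighted))
  write_bias_tsv(biases, paste0(out_prefix, ".bias.tsv"))
  out <- list(lengths = lh, biases = biases)
  if (!is.null(consensus_path)) {
    cons <- read_consensus(consensus_path)
    mapped <- map_library(build_index(cons), lib)
    out$strand <- strand_bias_table(mapped, cons)
    write_strand_tsv(out$strand, paste0(out_prefix, ".strand.tsv"))
  }
  message(sprintf("%s: modal length %d nt, U1 %.3f, A10 %.3f", lib$name,
                  lh$modal_length, biases[[1]]$fractions[["U"]],
                  biases[[2]]$fractions[["A"]]))
  invisible(out)
}

#' Ping-pong analysis of two libraries on a shared consensus
#'
#' Maps both libraries, computes the 5'-5' overlap histogram and the
#' target-bin z-score; writes `<out_prefix>.overlap.tsv` and
#' `<out_prefix>.score.tsv`.
#'
#' @param reads_a,reads_b FASTA/FASTQ paths of the two libraries.
#' @param consensus_path consensus FASTA.
#' @param out_prefix output path prefix.
#' @param dmin,dmax overlap range in nt.
#' @param target_bin z-score bin (default 10 nt).
#' @return invisibly, list with `histogram` and `score`.
#' @export
cmd_pingpong <- function(reads_a, reads_b, consensus_path, out_prefix,
                         dmin = 1L, dmax = 30L, target_bin = 10L) {
  cons <- read_consensus(consensus_path)
  idx <- build_index(cons)
  ma <- map_library(idx, read_any_library(reads_a))
  mb <- map_library(idx, read_any_library(reads_b))
  hist <- overlap_histogram(ma, mb, dmin = dmin, dmax = dmax)
  score <- pingpong_zscore(hist, target_bin = target_bin)
  write_overlap_tsv(hist, paste0(out_prefix, ".overlap.tsv"))
  write_score_tsv(score, paste0(out_prefix, ".score.tsv"))
  message(sprintf("ping-pong bin %d nt: z = %.2f", target_bin, score$z))
  invisible(list(histogram = hist, score = score))
}

#' Classify a query library's reads against two parent libraries
#'
#' Writes `<out_prefix>.sequences.tsv` and `<out_prefix>.summary.tsv`.
#'
#' @param chimera_path,reads_a,reads_b FASTA/FASTQ paths (query, parent A,
#'   parent B).
#' @param out_prefix output path prefix.
#' @param fold enrichment threshold (default 5).
#' @return invisibly, the [partition_chimera] result.
#' @export
cmd_classify <- function(chimera_path, reads_a, reads_b, out_prefix,
                         fold = 5) {
  part <- partition_chimera(read_any_library(chimera_path),
                            read_any_library(reads_a),
                            read_any_library(reads_b), fold = fold)
  write_partition_tsv(part, out_prefix)
  message(sprintf("%.1f%% of query reads found in parents",
                  100 * part$fraction_in_parents))
  invisible(part)
}

#' Collect stage outputs into one summary
#'
#' Reads the TSVs previously written by the other stages under `dir`
#' (matching the given prefixes) and writes `report.yaml` summarising
#' modal length, U1/A10 biases, ping-pong z and classification fractions
#' without recomputing them.
#'
#' @param dir directory holding stage outputs.
#' @param stats_prefixes character vector of `cmd_stats` prefixes
#'   (relative to `dir`).
#' @param pingpong_prefix optional `cmd_pingpong` prefix.
#' @param classify_prefix optional `cmd_classify` prefix.
#' @return invisibly, the report list.
#' @export
cmd_report <- function(dir, stats_prefixes = character(),
                       pingpong_prefix = NULL, classify_prefix = NULL) {
  report <- list()
  for (pf in stats_prefixes) {
    lt <- utils::read.delim(file.path(dir, paste0(pf, ".lengths.tsv")))
    bt <- utils::read.delim(file.path(dir, paste0(pf, ".bias.tsv")))
    report$libraries[[pf]] <- list(
      modal_length = lt$length[which.max(lt$count)],
      u1_bias = bt$U[bt$position == 1],
      a10_bias = bt$A[bt$position == 10])
  }
  if (!is.null(pingpong_prefix)) {
    st <- utils::read.delim(file.path(dir, paste0(pingpong_prefix,
                                                  ".score.tsv")))
    ot <- utils::read.delim(file.path(dir, paste0(pingpong_prefix,
                                                  ".overlap.tsv")))
    report$pingpong <- list(
      target_bin = st$target_bin, z = st$z,
      modal_distance = ot$distance[which.max(ot$weighted_count)],
      fraction_at_target =
        ot$fraction[ot$distance == st$target_bin])
  }
  if (!is.null(classify_prefix)) {
    su <- utils::read.delim(file.path(dir, paste0(classify_prefix,
                                                  ".summary.tsv")))
    report$classification <- as.list(stats::setNames(su$value, su$metric))
  }
  yaml::write_yaml(report, file.path(dir, "report.yaml"))
  invisible(report)
}
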