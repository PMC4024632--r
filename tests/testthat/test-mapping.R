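test_that("index construction reports seeds and validates input", {
  idx <- build_index(consensus_set("AAAATTTTGGGG", "tp1"), k = 4)
  expect_equal(idx$n_seeds, 9)  # 12 - 4 + 1

  expect_error(build_index(consensus_set(character(), character())),
               "empty")
  cs <- consensus_set(c("ACGTACGTACGT", "ACGT"), c("a", "b"))
  names(cs)[2] <- "a"
  expect_error(build_index(cs, k = 4), "duplicate")
  expect_warning(
    build_index(consensus_set(c("ACGTACGTACGT", "ACG"), c("a", "b")),
                k = 4),
    "no seeds")
})

test_that("map_sequence agrees with the brute-force scan on worked cases", {
  cs <- consensus_set("AAAATTTTGGGG", "tp1")
  idx <- build_index(cs, k = 4)

  h <- map_sequence(idx, "ATTT")
  expect_identical(h[-1], brute_force_map(cs, "ATTT"))
  sense <- h[h$strand == "sense", ]
  expect_equal(sense$start, 3)
  expect_equal(sense$end, 7)
  expect_equal(sense$five_prime, 3)

  h2 <- map_sequence(idx, "AAAT")  # reverse complement of ATTT
  expect_identical(h2[-1], brute_force_map(cs, "AAAT"))
  anti <- h2[h2$strand == "antisense", ]
  expect_equal(anti$start, 3)
  expect_equal(anti$end, 7)
  expect_equal(anti$five_prime, 6)

  expect_equal(nrow(map_sequence(idx, "GGGGG")), 0)
})

test_that("map_sequence equals the brute-force oracle on random cases", {
  set.seed(11)
  for (case in 1:60) {
    L <- sample(40:200, 1)
    cs <- consensus_set(paste(sample(c("A", "C", "G", "T"), L,
                                     replace = TRUE), collapse = ""),
                        "tp")
    n <- sample(4:35, 1)
    # half the reads are planted so matches are common
    read <- if (case %% 2 == 0) {
      st <- sample(L - n + 1, 1)
      w <- substr(cs[[1]], st, st + n - 1)
      if (runif(1) < 0.5) reverse_complement(w) else w
    } else {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
            collapse = "")
    }
    idx <- build_index(cs, k = 12)
    expect_identical(map_sequence(idx, read)[-1],
                     brute_force_map(cs, read))
  }
})

test_that("mapping a read and its reverse complement mirror each other", {
  set.seed(13)
  cons <- random_consensus(500, 0.5, name = "tp")
  idx <- build_index(cons)
  for (i in 1:20) {
    st <- sample(470, 1)
    read <- substr(cons[[1]], st, st + 25)
    a <- map_sequence(idx, read)
    b <- map_sequence(idx, reverse_complement(read))
    expect_equal(nrow(a), nrow(b))
    key <- function(h) h[order(h$start), c("transposon", "start", "end")]
    expect_equal(key(a), key(b))
    ord_a <- order(a$start)
    ord_b <- order(b$start)
    expect_true(all(a$strand[ord_a] != b$strand[ord_b]))
    expect_equal(a$five_prime[ord_a] + b$five_prime[ord_b],
                 a$start[ord_a] + a$end[ord_a] - 1L)
  }
})

test_that("multimapper weights split counts and conserve totals", {
  cs <- consensus_set("ACGTACGTACGTTTTTTTTT", "tp")  # ACGTACGT at 0 and 4
  idx <- build_index(cs, k = 4)
  lib <- read_library("ACGTACGT", 6)
  m <- map_library(idx, lib)
  expect_equal(sum(m$hits$weight), 6)
  expect_true(all(m$hits$weight == 6 / nrow(m$hits)))

  lib2 <- read_library("CCCCCCCCCC", 5)
  m2 <- map_library(idx, lib2)
  expect_equal(nrow(m2$hits), 0)
  expect_equal(m2$unmapped_count, 5)

  # conservation on a simulated library
  cons <- random_consensus(2000, 0.5, seed = 3, name = "tp")
  sim <- simulate_primary(cons, 300, p_1U = 0.8, seed = 4)
  m3 <- map_library(build_index(cons), sim$library)
  expect_equal(sum(m3$hits$weight) + m3$unmapped_count,
               sim$library$total_count)
})

test_that("BED6 and hits TSV outputs carry the declared columns", {
  cons <- random_consensus(300, 0.5, seed = 5, name = "tp")
  sim <- simulate_primary(cons, 20, seed = 6)
  m <- map_library(build_index(cons), sim$library)
  bed <- tempfile(fileext = ".bed")
  tsv <- tempfile(fileext = ".tsv")
  write_bed(m, bed)
  write_hits_tsv(m, tsv)
  b <- read.delim(bed, header = FALSE)
  expect_equal(ncol(b), 6)
  expect_true(all(b$V6 %in% c("+", "-")))
  h <- read.delim(tsv)
  expect_true(all(c("five_prime", "weight", "strand") %in% names(h)))
  expect_equal(h$end - h$start, nchar(h$sequence))
})
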