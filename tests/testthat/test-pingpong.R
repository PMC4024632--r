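test_that("overlap distances follow the 5'-5' convention", {
  a <- mk_mapped("tp", 100, "sense")
  b <- mk_mapped("tp", 109, "antisense")
  h <- overlap_histogram(a, b)
  expect_equal(h$counts[["10"]], 1)
  expect_equal(h$total_pairs, 1)

  # coinciding 5' ends give d = 1
  h1 <- overlap_histogram(mk_mapped("tp", 100, "antisense"),
                          mk_mapped("tp", 100, "sense"))
  expect_equal(h1$counts[["1"]], 1)

  # 3'-side configurations (d < 1) are ignored
  h0 <- overlap_histogram(mk_mapped("tp", 100, "sense"),
                          mk_mapped("tp", 90, "antisense"))
  expect_equal(h0$total_pairs, 0)

  # pairs on different transposons never combine
  hx <- overlap_histogram(mk_mapped("tp1", 100, "sense"),
                          mk_mapped("tp2", 109, "antisense"))
  expect_equal(hx$total_pairs, 0)
})

test_that("the histogram is exactly symmetric in its arguments", {
  set.seed(41)
  a <- mk_mapped("tp", sample(50:500, 40),
                 sample(c("sense", "antisense"), 40, replace = TRUE),
                 weight = runif(40, 0.2, 3))
  b <- mk_mapped("tp", sample(50:500, 40),
                 sample(c("sense", "antisense"), 40, replace = TRUE),
                 weight = runif(40, 0.2, 3))
  expect_identical(overlap_histogram(a, b)$counts,
                   overlap_histogram(b, a)$counts)
})

test_that("pair weights multiply and empty inputs warn", {
  a <- mk_mapped("tp", 100, "sense", weight = 2)
  b <- mk_mapped("tp", 109, "antisense", weight = 3)
  expect_equal(overlap_histogram(a, b)$counts[["10"]], 6)

  empty <- structure(list(name = "e",
                          hits = a$hits[0, ], unmapped_count = 0),
                     class = "mapped_library")
  expect_warning(h <- overlap_histogram(a, empty), "empty")
  expect_equal(h$total_pairs, 0)
})

test_that("shifting antisense 5' ends by +k shifts the histogram by +k", {
  set.seed(42)
  a <- mk_mapped("tp", sample(100:400, 25), "sense")
  b <- mk_mapped("tp", sample(100:420, 25), "antisense")
  h <- overlap_histogram(a, b, dmin = 1, dmax = 60)
  b2 <- b
  b2$hits$five_prime <- b$hits$five_prime + 5L
  h2 <- overlap_histogram(a, b2, dmin = 1, dmax = 60)
  inner <- as.character(6:60)
  expect_equal(unname(h2$counts[inner]),
               unname(h$counts[as.character(1:55)]))
})

test_that("the peak z-score matches hand arithmetic and handles degeneracy", {
  flat <- structure(list(dmin = 1L, dmax = 10L,
                         counts = setNames(rep(2, 10), 1:10),
                         total_pairs = 20),
                    class = "overlap_histogram")
  expect_equal(pingpong_zscore(flat, 5)$z, 0)

  h <- structure(list(dmin = 1L, dmax = 3L,
                      counts = c("1" = 1, "2" = 4, "3" = 3),
                      total_pairs = 8),
                 class = "overlap_histogram")
  s <- pingpong_zscore(h, 2)
  expect_equal(s$background_mean, 2)
  expect_equal(s$background_sd, sqrt(2))
  expect_equal(s$z, 2 / sqrt(2), tolerance = 1e-12)

  spike <- structure(list(dmin = 1L, dmax = 10L,
                          counts = setNames(c(rep(0, 9), 100),
                                            c(1:9, 10)),
                          total_pairs = 100),
                     class = "overlap_histogram")
  sp <- pingpong_zscore(spike, 10)
  expect_true(is.na(sp$z))
  expect_equal(sp$background_sd, 0)

  expect_error(pingpong_zscore(flat, 99), "outside")
})

test_that("pure ping-pong simulations put all weight at the overlap bin in a sparse regime", {
  cons <- random_consensus(200000, 0.5, seed = 43, name = "tp")
  prim <- simulate_primary(cons, 20, p_1U = 0.8, seed = 44)
  seco <- simulate_secondary(prim$truth, cons, 20, overlap = 10, seed = 45)
  idx <- build_index(cons)
  h <- overlap_histogram(map_library(idx, prim$library),
                         map_library(idx, seco$library))
  expect_equal(names(h$counts)[which.max(h$counts)], "10")
  expect_gte(h$counts[["10"]] / h$total_pairs, 0.99)
})
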