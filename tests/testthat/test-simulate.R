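test_that("random consensus sequences are reproducible with the target composition", {
  a <- random_consensus(1000, 0.5, seed = 61)
  b <- random_consensus(1000, 0.5, seed = 61)
  expect_identical(as.character(a), as.character(b))

  gc1 <- random_consensus(500, 1.0, seed = 62)
  expect_true(grepl("^[GC]+$", gc1[[1]]))

  big <- random_consensus(100000, 0.4, seed = 63)
  bases <- table(strsplit(big[[1]], "")[[1]])
  expect_lt(abs(bases[["G"]] / 100000 - 0.2),
            3 * sqrt(0.2 * 0.8 / 100000))
  expect_lt(abs(bases[["A"]] / 100000 - 0.3),
            3 * sqrt(0.3 * 0.7 / 100000))

  expect_error(random_consensus(1000, 1.5), "gc_content")
  expect_error(random_consensus(10, 0.5), ">= 50")
})

test_that("primary simulation honours the 5'-U preference at its extremes", {
  cons <- random_consensus(5000, 0.5, seed = 64, name = "tp")
  forced <- simulate_primary(cons, 500, p_1U = 1, seed = 65)
  expect_equal(u1_bias(forced$library), 1.0)
  expect_true(all(substr(forced$truth$sequence, 1, 1) == "T"))

  null <- simulate_primary(cons, 5000, p_1U = 0, seed = 66)
  u1 <- u1_bias(null$library)
  expect_lt(abs(u1 - 0.25), 3 * sqrt(0.25 * 0.75 / 5000) + 0.02)
})

test_that("primary truth records are antisense and map back to their coordinates", {
  cons <- random_consensus(3000, 0.5, seed = 67, name = "tp")
  sim <- simulate_primary(cons, 100, p_1U = 0.8, seed = 68)
  expect_true(all(sim$truth$strand == "antisense"))
  expect_equal(sum(sim$library$records$count), 100)

  idx <- build_index(cons)
  for (i in sample(100, 15)) {
    hits <- map_sequence(idx, sim$truth$sequence[i])
    found <- any(hits$strand == "antisense" &
                   hits$five_prime == sim$truth$five_prime[i])
    expect_true(found)
  }
})

test_that("secondary reads sit on the sense strand with the exact slicer overlap", {
  cons <- random_consensus(4000, 0.5, seed = 69, name = "tp")
  prim <- simulate_primary(cons, 500, p_1U = 0.8, seed = 70)
  seco <- simulate_secondary(prim$truth, cons, 500, overlap = 10,
                             seed = 71)
  expect_true(all(seco$truth$strand == "sense"))
  q <- prim$truth$five_prime[match(seco$truth$partner_id,
                                   prim$truth$read_id)]
  expect_true(all(q - seco$truth$five_prime + 1 == 10))

  # complementarity at the overlap edge: U1 partner forces A10 product
  partner_first <- substr(prim$truth$sequence[
    match(seco$truth$partner_id, prim$truth$read_id)], 1, 1)
  pos10 <- substr(seco$truth$sequence, 10, 10)
  expect_true(all(pos10[partner_first == "T"] == "A"))

  # non-default overlap geometry
  seco7 <- simulate_secondary(prim$truth, cons, 200, overlap = 7,
                              seed = 72)
  q7 <- prim$truth$five_prime[match(seco7$truth$partner_id,
                                    prim$truth$read_id)]
  expect_true(all(q7 - seco7$truth$five_prime + 1 == 7))
})

test_that("emergent 10A bias of secondaries matches the primaries' 1U bias", {
  cons <- random_consensus(5000, 0.5, seed = 73, name = "tp")
  prim <- simulate_primary(cons, 5000, p_1U = 0.8, seed = 74)
  seco <- simulate_secondary(prim$truth, cons, 5000, seed = 75)
  u1 <- u1_bias(prim$library)
  a10 <- a10_bias(seco$library)
  expect_lt(abs(a10 - u1), 3 * sqrt(u1 * (1 - u1) / 5000))
})

test_that("strand bias of simulated libraries points the expected way", {
  cons <- random_consensus(3000, 0.5, seed = 76, name = "tp")
  prim <- simulate_primary(cons, 400, p_1U = 0.8, seed = 77)
  seco <- simulate_secondary(prim$truth, cons, 400, seed = 78)
  idx <- build_index(cons)
  expect_gt(strand_bias_table(map_library(idx, seco$library))$score, 0.95)
  expect_lt(strand_bias_table(map_library(idx, prim$library))$score,
            -0.95)
})

test_that("mixtures resample parents at the stated proportions with seeded determinism", {
  cons <- random_consensus(2000, 0.5, seed = 79, name = "tp")
  prim <- simulate_primary(cons, 300, p_1U = 0.8, seed = 80)
  seco <- simulate_secondary(prim$truth, cons, 300, seed = 81)

  pure <- simulate_mixture(list(prim$library, seco$library), c(1, 0),
                           500, novel_fraction = 0, seed = 82)
  expect_true(all(pure$library$records$sequence %in%
                    prim$library$records$sequence))
  expect_true(all(pure$truth$origin == "primary"))

  m1 <- simulate_mixture(list(prim$library, seco$library), c(0.3, 0.7),
                         500, novel_fraction = 0.37, seed = 83)
  m2 <- simulate_mixture(list(prim$library, seco$library), c(0.3, 0.7),
                         500, novel_fraction = 0.37, seed = 83)
  expect_identical(m1$library$records, m2$library$records)
  expect_identical(m1$truth, m2$truth)

  expect_error(simulate_mixture(list(prim$library), c(0.5), 10), "sum to 1")
  expect_error(simulate_mixture(list(prim$library), 1, 10,
                                novel_fraction = 2), "novel_fraction")
})

test_that("the triangular length law has the declared support and mode", {
  law <- length_law(24, 32, 27)
  expect_equal(law$lengths, 24:32)
  expect_equal(sum(law$prob), 1)
  expect_equal(law$lengths[which.max(law$prob)], 27)
  expect_error(length_law(24, 32, 40))
})
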