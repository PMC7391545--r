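test_that("one-generation transitions from each pure cross type match the brood algebra", {
  cases <- list(
    list(start = c(1, 0, 0, 0), want = c(0.5, 0.5, 0, 0)),
    list(start = c(0, 1, 0, 0), want = c(0, 0.5, 0.25, 0.25)),
    list(start = c(0, 0, 1, 0), want = c(0, 1, 0, 0)),
    list(start = c(0, 0, 0, 1), want = c(0, 0, 0, 1)))
  for (cs in cases) {
    d <- cross_type_distribution(cs$start[1], cs$start[2], cs$start[3], cs$start[4])
    stepped <- step_cross_types(d)
    expect_identical(unname(stepped$freq), cs$want)
    expect_identical(stepped$generation, 1L)
  }
})

test_that("invalid distributions are rejected", {
  expect_error(cross_type_distribution(0.5, 0.5, 0.5, -0.5), "non-negative")
  expect_error(cross_type_distribution(0.5, 0.2, 0.1, 0.1), "sum to 1")
  expect_error(cross_type_distribution(1 / 3, 1 / 3, 1 / 3, 0, mode = "exact"),
               "n / 2\\^k")
  expect_silent(cross_type_distribution(1 / 3, 1 / 3, 1 / 3, 0,
                                        mode = "floating"))
})

test_that("inbreeding summary is f = C + D and p = D", {
  d2 <- cross_type_distribution(0.25, 0.5, 0.125, 0.125, generation = 2)
  pt <- inbreeding_from_distribution(d2)
  expect_identical(pt$f, 0.25)
  expect_identical(pt$p_fully_inbred, 0.125)
  expect_identical(pt$generation, 2L)
  pure_A <- inbreeding_from_distribution(cross_type_distribution(1, 0, 0, 0))
  expect_identical(pure_A$f, 0)
  pure_D <- inbreeding_from_distribution(cross_type_distribution(0, 0, 0, 1))
  expect_identical(pure_D$f, 1)
  expect_identical(pure_D$p_fully_inbred, 1)
})

test_that("15 generations from A0=1 reproduce the exact dyadic endpoint values", {
  tr <- inbreeding_trajectory(15)
  last <- tr[tr$generation == 15, ]
  expect_identical(last$f, 0.951263427734375)
  expect_identical(last$p_fully_inbred, 0.93621826171875)
  expect_identical(round(100 * last$f, 1), 95.1)
  expect_identical(round(100 * last$p_fully_inbred, 1), 93.6)
  expect_identical(tr$f[tr$generation == 1], 0)  # F1 daughters never IBD
})

test_that("exact iteration agrees with the matrix-power oracle and conserves mass", {
  G <- 40L
  tr <- inbreeding_trajectory(G)
  oracle <- chain_oracle(G)
  freqs <- as.matrix(tr[, c("freq_A", "freq_B", "freq_C", "freq_D")])
  expect_true(max(abs(freqs - oracle)) < 1e-12)
  expect_identical(unname(rowSums(freqs)), rep(1, G + 1L))  # exact conservation
  expect_identical(tr$freq_A, 2^-(0:G))  # A_t = A_0 / 2^t exactly
})

test_that("trajectory invariants hold: monotone D always, monotone f from gen 1, absorption", {
  starts <- list(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0.25, 0.25, 0.25, 0.25),
                 c(0.5, 0, 0.5, 0), c(0.125, 0.375, 0.25, 0.25))
  for (s in starts) {
    tr <- inbreeding_trajectory(50, cross_type_distribution(s[1], s[2], s[3], s[4]))
    expect_true(all(diff(tr$p_fully_inbred) >= 0))
    expect_true(all(diff(tr$f[tr$generation >= 1]) >= 0))
    expect_true(tr$f[nrow(tr)] > 1 - 1e-4)        # f -> 1
    expect_true(tr$freq_D[nrow(tr)] > 1 - 1e-4)   # chain absorbs in D
  }
})

test_that("direct recurrence equals the chain's f sequence under the one-index shift", {
  G <- 35L
  tr <- inbreeding_trajectory(G)
  rec <- direct_f_recurrence(G + 1L)
  # recurrence index t+1 <-> chain generation t; f_1 = f_2 = 0 match gens 0, 1
  expect_identical(unname(rec), tr$f[tr$generation >= 2])
  expect_identical(rec[["f_3"]], 0.25)
  expect_identical(rec[["f_16"]], 0.951263427734375)
  # f = 1 is a fixed point of the recurrence
  expect_identical(1 / 4 + 1 / 4 * 1 + 1 / 2 * 1, 1)
  expect_error(direct_f_recurrence(2), ">= 3")
})

test_that("generations_to_threshold scans the exact trajectory", {
  expect_identical(generations_to_threshold(0.95, "f"), 15L)
  expect_identical(generations_to_threshold(0.9, "p_fully_inbred"), 13L)
  expect_identical(generations_to_threshold(0, "f"), 0L)
  expect_identical(generations_to_threshold(0, "p_fully_inbred"), 0L)
  expect_error(generations_to_threshold(1, "f"), "unreachable")
  # from an already inbred start any threshold below 1 is met at once
  d <- cross_type_distribution(0, 0, 0, 1)
  expect_identical(generations_to_threshold(0.99, "f", d), 0L)
})
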