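test_that("matched pairs over four populations yields the eight printed combinations", {
  d <- crossing_design("matched-pairs-4", c("A", "B", "C", "D"))
  combos <- enumerate_combinations(d)
  expect_length(combos, 8L)
  expect_setequal(as.character(combos),
                  c("ABCD", "ABDC", "BACD", "BADC",
                    "CDAB", "CDBA", "DCAB", "DCBA"))
  rep <- mito_representation(combos)
  expect_identical(rep$counts, c(A = 2L, B = 2L, C = 2L, D = 2L))
  expect_true(rep$balanced)
})

test_that("round robin over three populations yields six balanced combinations", {
  d <- crossing_design("round-robin-3", c("E", "F", "G"))
  combos <- enumerate_combinations(d)
  expect_length(combos, 6L)
  # each combination is a permutation of the founder labels
  expect_true(all(vapply(strsplit(combos, ""), function(x)
    setequal(x, c("E", "F", "G")) && !anyDuplicated(x), logical(1))))
  rep <- mito_representation(combos)
  expect_identical(rep$counts, c(E = 2L, F = 2L, G = 2L))
  expect_true(rep$balanced)
})

test_that("unsupported designs and label sets are rejected", {
  expect_error(crossing_design("matched-pairs-4", c("A", "B", "C")), "exactly 4")
  expect_error(crossing_design("round-robin-3", LETTERS[1:4]), "exactly 3")
  expect_error(crossing_design("matched-pairs-4", c("A", "A", "B", "C")),
               "unique")
  expect_error(crossing_design("matched-pairs-4", c("AB", "C", "D", "E")),
               "single characters")
  expect_error(mito_representation(character(0)), "non-empty")
})

test_that("schedules satisfy the haplodiploid provenance constraints", {
  for (kind in c("matched-pairs-4", "round-robin-3")) {
    pops <- if (kind == "matched-pairs-4") LETTERS[1:4] else c("E", "F", "G")
    sched <- build_schedule(crossing_design(kind, pops))
    expect_true(isTRUE(validate_schedule(sched)))
    # the hybrid block carries 8 (matched pairs) or 6 (round robin) cross types
    n_hybrid <- if (kind == "matched-pairs-4") 8L else 6L
    hybrid_rows <- sum(nchar(sched[[3]]$crosses$mother) > 1)
    expect_identical(hybrid_rows, n_hybrid)
    # terminal block pools every combination
    expect_setequal(sched[[length(sched)]]$pool,
                    as.character(enumerate_combinations(crossing_design(kind, pops))))
  }
})

test_that("removing the virgin-isolation step breaks male provenance", {
  sched <- build_schedule(crossing_design("matched-pairs-4", LETTERS[1:4]))
  sched[[2]]$isolate_virgin <- character(0)
  bad <- validate_schedule(sched)
  expect_false(isTRUE(bad))
  expect_true(any(grepl("no virgin", attr(bad, "violations"))))
})

test_that("founding census applies the minimum and as-available rules", {
  combos8 <- c("ABCD", "ABDC", "BACD", "BADC", "CDAB", "CDBA", "DCAB", "DCBA")
  avail <- stats::setNames(c(80, 72, 90, 75, 88, 74, 101, 72), combos8)
  cens <- founding_census(avail, "minimum")
  expect_true(all(cens$per_combination == 72))
  expect_identical(cens$total, 576)
  cens6 <- founding_census(stats::setNames(rep(51, 6), letters[1:6]), "minimum")
  expect_identical(cens6$total, 306)
  males <- founding_census(stats::setNames(c(40, 35, 30, 32, 28, 32), letters[1:6]),
                           "as-available")
  expect_identical(males$total, 197)
  expect_identical(males$per_combination[["a"]], 40)
  expect_error(founding_census(numeric(0)), "non-empty")
  expect_error(founding_census(c(a = -1, b = 2)), "non-negative")
})
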