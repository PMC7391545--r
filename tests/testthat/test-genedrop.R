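test_that("founding schemes produce the expected ploidy and alleles", {
  p <- found_line()
  expect_identical(p$female$genotype[[1]], c("x", "y"))
  expect_identical(p$male$genotype[[1]], "z")
  expect_true(is.na(p$male$father_id))
  inbred <- found_line(list(female = c("x", "x"), male = "x"))
  expect_identical(as.character(classify_cross_type(
    inbred$female$genotype[[1]][1], inbred$female$genotype[[1]][2],
    inbred$male$genotype[[1]])), "D")
  expect_error(found_line(list(female = c("x", "y"), male = c("x", "y"))),
               "1 allele")
  expect_error(new_individual("m", "male", list("x"), father_id = "dad"),
               "unfertilized")
})

test_that("offspring transmission follows haplodiploid rules", {
  p <- found_line()
  set.seed(11)
  daughters <- replicate(400, paste(
    produce_offspring(p$female, p$male, "female")$genotype[[1]], collapse = ""))
  expect_true(all(daughters %in% c("xz", "yz")))
  expect_gt(mean(daughters == "xz"), 0.4)  # ~1/2 each
  expect_lt(mean(daughters == "xz"), 0.6)
  sons <- replicate(400, produce_offspring(p$female, sex = "male")$genotype[[1]])
  expect_true(all(sons %in% c("x", "y")))
  # homozygous mother: son allele deterministic
  hom <- found_line(list(female = c("x", "x"), male = "x"))
  expect_identical(produce_offspring(hom$female, sex = "male")$genotype[[1]], "x")
  # fertilization contract
  expect_error(produce_offspring(p$female, sex = "female"), "father")
  expect_error(produce_offspring(p$female, p$male, "male"), "unfertilized")
})

test_that("advance_line is absorbing from a fully inbred pair and samples sib pairs uniformly", {
  hom <- found_line(list(female = c("x", "x"), male = "x"))
  nxt <- advance_line(hom)
  expect_identical(nxt$female$genotype[[1]], c("x", "x"))
  expect_identical(nxt$male$genotype[[1]], "x")
  set.seed(7)
  p <- found_line()
  combos <- replicate(800, {
    nx <- advance_line(p)
    paste(paste(nx$female$genotype[[1]], collapse = ""), nx$male$genotype[[1]])
  })
  tab <- table(combos) / length(combos)
  expect_setequal(names(tab), c("xz x", "xz y", "yz x", "yz y"))
  expect_true(all(abs(tab - 0.25) < 3 * sqrt(0.25 * 0.75 / 800)))
})

test_that("pedigrees conserve founder alleles and respect arrhenotoky", {
  ped <- simulate_pedigree(10, n_loci = 2, seed = 3)
  alleles <- unlist(strsplit(unlist(ped[, c("locus_1", "locus_2")]), "/"))
  expect_true(all(alleles %in% c("x", "y", "z")))
  expect_true(all(is.na(ped$father_id[ped$sex == "male"])))
  expect_true(all(!is.na(ped$father_id[ped$sex == "female" & ped$generation > 0])))
  # females diploid, males haploid in the written encoding
  expect_true(all(grepl("/", ped$locus_1[ped$sex == "female"])))
  expect_true(all(!grepl("/", ped$locus_1[ped$sex == "male"])))
})

test_that("Monte-Carlo estimates start at zero inbreeding and are reproducible", {
  mc <- estimate_inbreeding_mc(5000, generations = 2, seed = 42)
  expect_identical(mc$f_hat[mc$generation == 0], 0)
  expect_identical(mc$f_hat[mc$generation == 1], 0)  # F1 daughters are xz or yz
  mc2 <- estimate_inbreeding_mc(5000, generations = 2, seed = 42)
  expect_identical(mc$f_hat, mc2$f_hat)
})

test_that("per-line streams are stable when more lines are added", {
  small <- estimate_inbreeding_mc(300, generations = 6, seed = 9)
  big <- estimate_inbreeding_mc(600, generations = 6, seed = 9)
  # enlarging the panel under the same seed leaves the first lines untouched
  expect_identical(attr(small, "final_type"), attr(big, "final_type")[1:300])
})

test_that("MC cross-type frequencies track the analytic chain within 3 SE", {
  n <- 20000
  mc <- estimate_inbreeding_mc(n, generations = 10, seed = 5)
  oracle <- chain_oracle(10)
  for (g in 1:10) {
    est <- unlist(mc[mc$generation == g, c("freq_A", "freq_B", "freq_C", "freq_D")])
    expect_true(all(mapply(within_3se, est, oracle[g + 1, ], n)),
                label = sprintf("cross-type frequencies at generation %d", g))
  }
})

test_that("homozygosity is exchangeable across independent loci", {
  mc <- estimate_inbreeding_mc(20000, generations = 15, n_loci = 3, seed = 13)
  per_locus <- attr(mc, "per_locus_f")
  truth <- 0.951263427734375
  expect_true(all(vapply(per_locus, within_3se, logical(1),
                         truth = truth, n = 20000)))
  gw <- attr(mc, "genomewide_fully_inbred")
  expect_lte(gw, min(per_locus))  # genome-wide fixation is rarer than per-locus
})
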