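test_that("founder-origin configurations carry truncated-binomial weights", {
  trio <- make_trio()
  cfg <- enumerate_founder_configs(trio, 0.01)
  expect_equal(nrow(cfg), 3L)
  z <- 0.9999
  expect_equal(cfg$weight, c(0.9801, 0.0099, 0.0099) / z, tolerance = 1e-12)
  expect_equal(sum(cfg$weight), 1)

  single <- make_singletons(1)
  cfg1 <- enumerate_founder_configs(single, 0.5)
  expect_equal(cfg1$weight, c(0.5, 0.5))

  for (seed in 1:5) {
    ped <- random_small_ped(8, seed)
    expect_equal(sum(enumerate_founder_configs(ped, 0.07)$weight), 1)
  }
})

test_that("trio carrier priors match hand enumeration", {
  trio <- make_trio()
  expect_equal(config_prior(trio, c(F1 = 1, M1 = 0, C1 = 1), 0.01),
               0.0099 * 0.5 / 0.9999, tolerance = 1e-12)
  expect_equal(config_prior(trio, c(F1 = 0, M1 = 0, C1 = 0), 0.01),
               0.9801 / 0.9999, tolerance = 1e-12)
  # no de novo events: carrier child of two non-carrier parents is impossible
  expect_equal(config_prior(trio, c(F1 = 0, M1 = 0, C1 = 1), 0.01), 0)
  # all 8 vectors sum to 1
  tot <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    tot <- tot + config_prior(trio, c(F1 = a, M1 = b, C1 = cc), 0.01)
  }
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("brute-force oracle reproduces trio values and normalises", {
  trio <- make_trio()
  expect_equal(brute_force_prior(trio, c(F1 = 1, M1 = 0, C1 = 1), 0.01),
               0.0099 * 0.5 / 0.9999, tolerance = 1e-12)
  empty <- stats::setNames(integer(0), character(0))
  expect_equal(brute_force_prior(trio, empty, 0.01), 1, tolerance = 1e-12)
  big <- simulate_pedigree_set(n_families = 1, generations = 4,
                               mean_offspring = 3, seed = 3)
  if (nrow(big) > 20) {
    expect_error(brute_force_prior(big, c(), 0.01), "20 members")
  }
})

test_that("exact priors agree with the enumeration oracle on random pedigrees", {
  # a reduced sweep; the full 200-pedigree sweep runs in the acceptance suite
  for (seed in 1:40) {
    n <- 3L + (seed %% 10L)
    ped <- random_small_ped(n, seed)
    y <- random_assignment(ped, min(4L, n), seed + 1000L)
    a1 <- c(0.01, 0.05, 0.2)[1L + seed %% 3L]
    expect_equal(config_prior(ped, y, a1), brute_force_prior(ped, y, a1),
                 tolerance = 1e-12)
  }
})

test_that("transmission to a child of one carrier parent is exactly 1/2", {
  trio <- make_trio()
  pd <- config_prior(trio, c(F1 = 1, M1 = 0, C1 = 1), 0.3)
  pn <- config_prior(trio, c(F1 = 1, M1 = 0, C1 = 0), 0.3)
  expect_equal(pd / (pd + pn), 0.5, tolerance = 1e-12)
})

test_that("family prior tables normalise, match fresh evaluation, ignore mu/sigma", {
  ped <- random_small_ped(9, 77, max_typed = 3L)
  tab <- family_prior_tables(ped, 0.02)
  t1 <- tab[[1]]
  expect_equal(length(t1$prob), 8L)
  expect_equal(sum(t1$prob), 1, tolerance = 1e-10)
  withr::with_seed(8, {
    for (r in 1:20) {
      bits <- sample(0:1, 3, replace = TRUE)
      y <- stats::setNames(bits, t1$typed_ids)
      mask <- sum(bits * 2^(0:2))
      expect_equal(t1$prob[mask + 1], config_prior(ped, y, 0.02),
                   tolerance = 1e-14)
    }
  })
  # tables depend only on structure and alpha: recomputation is bit-identical
  expect_identical(family_prior_tables(ped, 0.02)[[1]]$prob, t1$prob)
})

test_that("a prior table dumps to TSV with bits and probabilities", {
  ped <- make_trio()
  tab <- family_prior_tables(ped, 0.01)
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- write_prior_table(tab, "T1", path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), c("F1", "M1", "C1", "prior"))
  expect_equal(nrow(back), 8L)
  expect_equal(sum(back$prior), 1, tolerance = 1e-10)
  expect_error(write_prior_table(tab, "nope", "x.tsv"), "no prior table")
})

test_that("the typed-table budget is enforced", {
  ped <- make_trio()
  expect_error(family_prior_tables(ped, 0.01, max_typed = 2L), "budget")
})

test_that("founder carrier marginal approaches alpha1 for rare variants", {
  ped <- random_small_ped(10, 5)
  a1 <- 1e-4
  founders <- ped$individual_id[ped$founder]
  f1 <- founders[1]
  p <- config_prior(ped, stats::setNames(1L, f1), a1)
  nf <- length(founders)
  z <- (1 - a1)^nf + nf * a1 * (1 - a1)^(nf - 1)
  expect_equal(p, a1 * (1 - a1)^(nf - 1) / z, tolerance = 1e-12)
  expect_lt(abs(p - a1) / a1, 1e-3)
})

test_that("consanguineous pedigrees are rejected", {
  # child of two sibs
  ped <- new_ped_tbl(data.frame(
    family_id = "T",
    individual_id = c("F", "M", "S1", "S2", "K"),
    father_id = c(NA, NA, "F", "F", "S1"),
    mother_id = c(NA, NA, "M", "M", "S2"),
    sex = c(1, 2, 1, 2, 1)
  ))
  expect_error(config_prior(ped, c(K = 1), 0.01), "blood relatives")
})
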