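test_that("pedigree simulation is reproducible and structurally valid", {
  p1 <- simulate_pedigree_set(n_families = 25, generations = 3, seed = 17)
  p2 <- simulate_pedigree_set(n_families = 25, generations = 3, seed = 17)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_equal(length(unique(p1$family_id)), 25L)
  # validation ran inside the constructor; founders >= 2 per family
  founders_per <- tapply(p1$founder, p1$family_id, sum)
  expect_true(all(founders_per >= 2))
  # cohort scale emulates the study design: ~210 typed members
  expect_gt(sum(p1$typed), 150)
  expect_lt(sum(p1$typed), 280)
})

test_that("variant transmission honours Mendelian rates", {
  # 10,000 offspring of carrier x non-carrier matings via many trios
  n <- 10000L
  ped <- new_ped_tbl(data.frame(
    family_id = rep(sprintf("F%05d", 1:n), each = 3),
    individual_id = paste0(rep(sprintf("F%05d", 1:n), each = 3), c("_d", "_m", "_c")),
    father_id = rep(c(NA, NA, "d"), n),
    mother_id = rep(c(NA, NA, "m"), n),
    sex = rep(c(1, 2, 2), n)
  ) |> transform(
    father_id = ifelse(is.na(father_id), NA, paste0(family_id, "_d")),
    mother_id = ifelse(is.na(mother_id), NA, paste0(family_id, "_m"))
  ))
  # alpha close to 1/2 makes carrier-founder trios common; condition on
  # exactly one carrier parent and count carrier children
  carr <- drop_variant(ped, 0.45, seed = 19)
  cw <- matrix(carr$carrier, ncol = 3, byrow = TRUE)
  one_parent <- cw[, 1] + cw[, 2] == 1
  expect_gt(sum(one_parent), 2000)
  frac <- mean(cw[one_parent, 3])
  se <- sqrt(0.25 / sum(one_parent))
  expect_lt(abs(frac - 0.5), 3 * se)
  # children of two non-carrier parents are never carriers
  expect_true(all(cw[cw[, 1] + cw[, 2] == 0, 3] == 0))
})

test_that("founder carrier frequency matches the truncated-binomial marginal", {
  n <- 20000L
  ped <- new_ped_tbl(data.frame(
    family_id = rep(sprintf("G%05d", 1:(n / 2)), each = 2),
    individual_id = sprintf("G%05d_%d", rep(1:(n / 2), each = 2), rep(1:2, n / 2)),
    father_id = NA, mother_id = NA, sex = rep(c(1, 2), n / 2)
  ))
  a1 <- 0.05
  carr <- drop_variant(ped, a1, seed = 23)
  z <- (1 - a1)^2 + 2 * a1 * (1 - a1)
  expected <- a1 * (1 - a1) / z
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(carr$carrier) - expected), 3 * se)
})

test_that("site simulation respects regime and degenerates correctly", {
  ped <- simulate_pedigree_set(n_families = 5, seed = 29)
  carr <- drop_variant(ped, 0.2, seed = 30, min_typed_carriers = 2)
  s <- simulate_site(ped, carr, "mendelian", sigma0 = 1e-12, sigma1 = 1e-12,
                     seed = 31)
  expect_true(all(abs(s$m[s$group == 0] - (-3)) < 1e-6))
  expect_true(all(abs(s$m[s$group == 1] - 0) < 1e-6))
  expect_equal(s$individual_id, attr(ped, "typed_order"))
  g <- simulate_site(ped, NULL, "gaussian", seed = 32)
  expect_true(all(g$group == 0))
  expect_error(simulate_site(ped, NULL, "mendelian"), "carrier assignment")
})

test_that("ascertainment keeps only multiplex families and is recorded", {
  ped <- simulate_pedigree_set(n_families = 10, seed = 37)
  carr <- drop_variant(ped, 0.01, seed = 38)
  ph <- simulate_phenotypes(ped, carr, min_affected = 2, seed = 39)
  counts <- ph |>
    dplyr::filter(sex == "female") |>
    dplyr::group_by(family_id) |>
    dplyr::summarise(n_aff = sum(affected))
  expect_true(all(counts$n_aff >= 2))
  asc <- attr(ph, "ascertainment")
  expect_equal(asc$policy, "resample")
  expect_equal(sort(asc$retained), sort(unique(ph$family_id)))
  expect_true(all(ph$age > 0))
})

test_that("a strong carrier hazard shifts onset ages earlier", {
  ped <- simulate_pedigree_set(n_families = 15, seed = 41)
  earlier <- 0
  for (r in 1:10) {
    carr <- drop_variant(ped, 0.25, seed = 500 + r, min_typed_carriers = 5)
    ph <- simulate_phenotypes(ped, carr, hr = 5, min_affected = 0,
                              seed = 600 + r)
    dat <- dplyr::inner_join(ph, carr, by = c("family_id", "individual_id")) |>
      dplyr::filter(sex == "female", affected)
    med <- tapply(dat$age, dat$carrier, median)
    if (length(med) == 2 && med["1"] < med["0"]) earlier <- earlier + 1
  }
  expect_gte(earlier, 8)
})

test_that("simulated cohorts round-trip through the file readers cleanly", {
  co <- simulate_cohort(n_families = 5, n_mendelian = 2, n_mixture = 2,
                        n_gaussian = 2, seed = 43)
  dir <- withr::local_tempdir()
  write_pedigrees(co$ped, file.path(dir, "ped.tsv"))
  write_methylation(co$mat, file.path(dir, "m.tsv"))
  readr::write_tsv(co$annotation, file.path(dir, "ann.tsv"))
  expect_no_warning({
    ped2 <- read_pedigrees(file.path(dir, "ped.tsv"))
    mat2 <- read_methylation(file.path(dir, "m.tsv"), values = "m")
    ann2 <- read_annotation(file.path(dir, "ann.tsv"))
  })
  expect_equal(ped2$individual_id, co$ped$individual_id)
  expect_equal(mat2$probe_id, co$mat$probe_id)
  expect_equal(ann2$probe_id, co$annotation$probe_id)
  # identical seed, identical files
  co2 <- simulate_cohort(n_families = 5, n_mendelian = 2, n_mixture = 2,
                         n_gaussian = 2, seed = 43)
  expect_identical(as.data.frame(co$mat), as.data.frame(co2$mat))
  expect_identical(co$phenotypes$age, co2$phenotypes$age)
})

test_that("mixture and mendelian sites share marginal distributions", {
  # pooled two-sample tests should NOT distinguish the regimes: the
  # difference is the family structure, not the marginal
  ped <- simulate_pedigree_set(n_families = 25, seed = 47)
  apart <- 0
  for (r in 1:10) {
    carr <- drop_variant(ped, 0.01, seed = 700 + r)
    sm <- simulate_site(ped, carr, "mendelian", seed = 800 + r)
    sx <- simulate_site(ped, NULL, "mixture", seed = 900 + r)
    p <- suppressWarnings(stats::ks.test(sm$m, sx$m)$p.value)
    if (p < 0.05) apart <- apart + 1
  }
  expect_lte(apart, 1)
})
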