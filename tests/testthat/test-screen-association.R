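make_screen_cohort <- function(seed = 101, n_mendelian = 3, n_mixture = 2,
                               n_gaussian = 2) {
  simulate_cohort(n_families = 6, n_mendelian = n_mendelian,
                  n_mixture = n_mixture, n_gaussian = n_gaussian, seed = seed)
}

test_that("the screen ranks by delta-l with lexicographic tie-break", {
  co <- make_screen_cohort()
  scr <- suppressWarnings(screen_sites(co$mat, co$ped, k = 2))
  expect_s3_class(scr, "screen_result")
  expect_true(all(diff(scr$delta_l) <= 1e-12))
  expect_equal(sum(scr$selected), 2L)
  expect_equal(scr$rank, seq_len(nrow(scr)))
  # ties: fabricate by duplicating a probe's values under two ids
  mat2 <- co$mat[c(1, 1, 2), ]
  mat2$probe_id <- c("cg_b", "cg_a", "cg_c")
  scr2 <- suppressWarnings(screen_sites(mat2, co$ped, k = 3))
  tied <- scr2$probe_id[abs(scr2$delta_l - scr2$delta_l[match("cg_a", scr2$probe_id)]) < 1e-12]
  expect_equal(sort(tied[1:2]), c("cg_a", "cg_b"))
  expect_equal(match("cg_a", scr2$probe_id) + 1L, match("cg_b", scr2$probe_id))
})

test_that("k larger than the probe count returns everything with a warning", {
  co <- make_screen_cohort(seed = 102)
  expect_warning(scr <- screen_sites(co$mat, co$ped, k = 999), "exceeds")
  expect_true(all(scr$selected))
})

test_that("probes with too few distinct values are skipped with a reason", {
  co <- make_screen_cohort(seed = 103)
  mat <- co$mat
  mat[1, -1] <- as.list(rep(0, ncol(mat) - 1))
  scr <- suppressWarnings(screen_sites(mat, co$ped, k = 2))
  sk <- attr(scr, "skipped")
  expect_equal(sk$probe_id, mat$probe_id[1])
  expect_match(sk$reason, "distinct")
  expect_false(mat$probe_id[1] %in% scr$probe_id)
})

test_that("Bonferroni thresholds divide the family-wise level", {
  expect_identical(bonferroni_alpha(0.05, 1000), 5e-5)
  expect_identical(bonferroni_alpha(0.05, 1), 0.05)
  expect_identical(bonferroni_alpha(0.01, 20), 5e-4)
  expect_error(bonferroni_alpha(0.05, 0), "positive")
})

fake_survival_data <- function(n = 120, seed = 7, beta = 0) {
  withr::with_seed(seed, {
    q1 <- runif(n)
    age <- 80 * (rexp(n) / exp(beta * q1))^(1 / 3) + 20
    cens <- runif(n, 40, 90)
    tibble::tibble(
      carriers = list(tibble::tibble(individual_id = sprintf("I%03d", 1:n), q1 = q1)),
      phen = list(tibble::tibble(individual_id = sprintf("I%03d", 1:n),
                                 affected = age < cens,
                                 age = pmin(age, cens),
                                 sex = "female"))
    )
  })
}

test_that("a constant covariate yields LRT 0 and p 1; no events errors", {
  d <- fake_survival_data()
  carr <- d$carriers[[1]]; phen <- d$phen[[1]]
  carr$q1 <- 0.5
  res <- cox_lrt(carr, phen)
  expect_equal(res$lrt_statistic, 0)
  expect_equal(res$p_value, 1)
  phen$affected <- FALSE
  expect_error(cox_lrt(d$carriers[[1]], phen), "no events")
})

test_that("the Cox LRT statistic is invariant to affine covariate rescaling", {
  d <- fake_survival_data(seed = 8, beta = 1)
  carr <- d$carriers[[1]]; phen <- d$phen[[1]]
  r1 <- cox_lrt(carr, phen)
  carr2 <- dplyr::mutate(carr, q1 = 10 * q1 - 3)
  r2 <- cox_lrt(carr2, phen)
  expect_lt(abs(r1$lrt_statistic - r2$lrt_statistic), 1e-8)
})

test_that("the LRT matches survival's own likelihood components", {
  d <- fake_survival_data(seed = 9, beta = 1.5)
  carr <- d$carriers[[1]]; phen <- d$phen[[1]]
  res <- cox_lrt(carr, phen)
  dat <- dplyr::inner_join(carr, phen, by = "individual_id")
  fit <- survival::coxph(survival::Surv(age, affected) ~ q1, data = dat)
  expect_equal(res$lrt_statistic, 2 * diff(fit$loglik), tolerance = 1e-10)
  expect_equal(res$p_value,
               pchisq(2 * diff(fit$loglik), 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$significant, res$p_value < 5e-5)
})

test_that("males are excluded from the default risk set but kept optionally", {
  d <- fake_survival_data(seed = 10, beta = 1)
  carr <- d$carriers[[1]]; phen <- d$phen[[1]]
  phen$sex[1:40] <- "male"
  res_f <- cox_lrt(carr, phen)
  expect_equal(res_f$n, 80L)
  res_all <- cox_lrt(carr, phen, females_only = FALSE)
  expect_equal(res_all$n, 120L)
})

test_that("the Cox LRT has high power in an event-rich strong-effect regime", {
  # large families and high baseline risk give several events per family;
  # with hazard ratio 5 the carrier covariate should be detected far below
  # the screen-wide Bonferroni threshold
  ped <- simulate_pedigree_set(n_families = 25, generations = 3,
                               mean_offspring = 4, max_offspring = 6,
                               typed_fraction = 0.9,
                               max_typed_per_family = 16, seed = 2100)
  ps <- numeric(15)
  for (r in seq_along(ps)) {
    carr <- drop_variant(ped, 0.1, seed = 2200 + r, min_typed_carriers = 10)
    phen <- simulate_phenotypes(ped, carr, shape = 3, scale = 75, hr = 5,
                                censor_range = c(50, 80), min_affected = 2,
                                seed = 2300 + r)
    q <- dplyr::transmute(carr, individual_id, q1 = as.numeric(carrier))
    ps[r] <- suppressWarnings(cox_lrt(q, phen)$p_value)
  }
  expect_lt(median(ps), 5e-5)
})

test_that("the SNP trend test rejects single-class input and detects a trend", {
  withr::with_seed(12, {
    dl <- rexp(4000, 1 / 5)
    expect_error(snp_trend_test(data.frame(delta_l = dl, near_snp = TRUE)),
                 "single class")
    ns <- runif(4000) < plogis(-3 + 0.4 * dl)
    tr <- suppressWarnings(snp_trend_test(data.frame(delta_l = dl, near_snp = ns)))
    expect_lt(tr$p_value, 1e-6)
    expect_equal(nrow(tr$binned), 10L)
    expect_true(all(tr$binned$lo <= tr$binned$prop_near_snp))
    expect_true(all(tr$binned$hi >= tr$binned$prop_near_snp))
    gl <- glance(tr)
    expect_equal(gl$df, 3L)
  })
})

test_that("screen plus association flags the causal site end to end", {
  co <- simulate_cohort(n_families = 12, n_mendelian = 2, n_mixture = 3,
                        n_gaussian = 3, hr = 8, min_typed_carriers = 4,
                        seed = 131)
  scr <- suppressWarnings(screen_sites(co$mat, co$ped, k = 3))
  res <- suppressWarnings(
    associate_screen(scr, co$mat, co$ped, co$phenotypes,
                     family_wise_alpha = 0.05))
  expect_equal(nrow(res), 3L)
  expect_true(all(res$lrt_statistic >= 0))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
})
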