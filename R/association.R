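#' Bonferroni-corrected per-test significance threshold
#'
#' @param family_wise_alpha Family-wise error rate (e.g. 0.05).
#' @param m Number of tests (e.g. the 1000 screened probes).
#' @return `family_wise_alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 1000) # 5e-5
#' @export
bonferroni_alpha <- function(family_wise_alpha, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop_ms("m must be a positive integer")
  }
  if (!(family_wise_alpha > 0 && family_wise_alpha < 1)) {
    stop_ms("family_wise_alpha must be in (0, 1)")
  }
  family_wise_alpha / m
}

#' Cox proportional-hazards likelihood-ratio test of carrier probability
#'
#' Tests association between disease and the posterior carrier
#' probability at one site, with age as the time scale (age at diagnosis
#' for affected, age at censoring otherwise). The p-value comes from the
#' likelihood-ratio test against the null model — not the Wald test —
#' because under multiple-case ascertainment the hazard-ratio estimate
#' is biased while the LRT p-value remains valid under the null. The
#' log hazard ratio is returned but flagged ascertainment-biased.
#'
#' @param carriers Tibble from [carrier_posteriors()] (`individual_id`,
#'   `q1`, optionally `probe_id`, `family_id`).
#' @param phenotypes Tibble from [read_phenotypes()] (`individual_id`,
#'   `affected`, `age`, `sex`).
#' @param females_only Restrict the risk set to females (default `TRUE`,
#'   the convention for a breast-cancer phenotype; males remain in the
#'   pedigree for transmission regardless).
#' @param ties Tie handling for the partial likelihood: `"efron"`
#'   (default) or `"breslow"`.
#' @param stratify_by_family Stratify the baseline hazard by family.
#'   Default `FALSE` (pooled partial likelihood).
#' @param alpha Per-test significance threshold used to set the
#'   `significant` flag. Default `5e-5` (0.05/1000).
#' @return A one-row tibble: `probe_id`, `lrt_statistic`, `p_value`,
#'   `n`, `n_events`, `log_hr_biased`, `significant`.
#' @export
cox_lrt <- function(carriers, phenotypes, females_only = TRUE,
                    ties = c("efron", "breslow"),
                    stratify_by_family = FALSE, alpha = 5e-5) {
  ties <- match.arg(ties)
  probe <- if ("probe_id" %in% names(carriers)) carriers$probe_id[1] else NA_character_
  dat <- dplyr::inner_join(
    dplyr::select(carriers, dplyr::any_of(c("individual_id", "family_id", "q1"))),
    phenotypes, by = "individual_id"
  )
  if (females_only) dat <- dplyr::filter(dat, .data$sex == "female")
  dat <- dplyr::filter(dat, !is.na(.data$q1))
  if (!nrow(dat)) stop_ms("empty risk set")
  n_events <- sum(dat$affected)
  if (n_events < 1L) stop_ms("no events in the risk set")

  out <- function(stat, p, loghr) tibble::tibble(
    probe_id = probe, lrt_statistic = stat, p_value = p,
    n = nrow(dat), n_events = n_events,
    log_hr_biased = loghr, significant = p < alpha
  )
  if (stats::var(dat$q1) < .Machine$double.eps) {
    return(out(0, 1, NA_real_))
  }
  fml <- if (stratify_by_family) {
    survival::Surv(age, affected) ~ q1 + survival::strata(family_id)
  } else {
    survival::Surv(age, affected) ~ q1
  }
  fit <- survival::coxph(fml, data = dat, ties = ties)
  stat <- max(0, 2 * (fit$loglik[2] - fit$loglik[1]))
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  out(stat, p, unname(stats::coef(fit)[1]))
}

#' Logistic trend of SNP proximity in delta-l
#'
#' Validation of the delta-l statistic: probes measured near a known SNP
#' tend to show Mendelian-like inheritance as an artefact of probe
#' hybridisation, so the proportion of near-SNP probes should increase
#' with delta-l if the statistic captures heritable patterns. Fits a
#' logistic regression of the near-SNP indicator on an orthogonal
#' polynomial in delta-l and tests it against the intercept-only model
#' by likelihood ratio; also returns binned proportions with exact
#' binomial 95 percent confidence intervals for plotting.
#'
#' @param data Data frame with columns `delta_l` (numeric) and
#'   `near_snp` (logical).
#' @param degree Polynomial degree. Default 3.
#' @param bins Number of equal-count delta-l bins for the summary.
#'   Default 10.
#' @return An object of class `snp_trend`: list with `fit` (the glm),
#'   `lrt_statistic`, `df`, `p_value`, and `binned` (tibble of bin
#'   midpoints, proportions, CIs).
#' @export
snp_trend_test <- function(data, degree = 3L, bins = 10L) {
  if (!all(c("delta_l", "near_snp") %in% names(data))) {
    stop_ms("data needs columns delta_l and near_snp")
  }
  y <- as.logical(data$near_snp)
  dl <- as.numeric(data$delta_l)
  if (length(unique(y)) < 2L) stop_ms("near_snp has a single class; trend test undefined")
  if (length(unique(dl)) < 2L) stop_ms("need at least 2 distinct delta_l values")
  degree <- min(degree, length(unique(dl)) - 1L)
  df_ <- data.frame(y = y, dl = dl)
  fit <- stats::glm(y ~ poly(dl, degree), family = stats::binomial(), data = df_)
  null <- stats::glm(y ~ 1, family = stats::binomial(), data = df_)
  stat <- max(0, 2 * (stats::logLik(fit) - stats::logLik(null)))
  p <- stats::pchisq(stat, df = degree, lower.tail = FALSE)

  brk <- unique(stats::quantile(dl, probs = seq(0, 1, length.out = bins + 1L)))
  grp <- cut(dl, breaks = brk, include.lowest = TRUE)
  binned <- purrr::map_dfr(levels(grp), function(b) {
    sel <- grp == b
    k <- sum(y[sel]); n <- sum(sel)
    ci <- stats::binom.test(k, n)$conf.int
    tibble::tibble(bin = b, delta_l_mid = stats::median(dl[sel]), n = n,
                   prop_near_snp = k / n, lo = ci[1], hi = ci[2])
  })
  structure(list(fit = fit, lrt_statistic = as.numeric(stat), df = degree,
                 p_value = as.numeric(p), binned = binned),
            class = "snp_trend")
}

#' @export
print.snp_trend <- function(x, ...) {
  cat(sprintf("<snp_trend> degree-%d logistic trend, LRT = %.3f, p = %.3g\n",
              x$df, x$lrt_statistic, x$p_value))
  invisible(x)
}

#' @rdname snp_trend_test
#' @param x A `snp_trend` object.
#' @param ... Unused.
#' @return `glance.snp_trend()`: one-row tibble with the LRT statistic,
#'   degrees of freedom and p-value.
#' @export
glance.snp_trend <- function(x, ...) {
  tibble::tibble(lrt_statistic = x$lrt_statistic, df = x$df,
                 p_value = x$p_value, nobs = length(x$fit$y))
}
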