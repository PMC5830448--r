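# Per-probe model fits: Gaussian, two-component Gaussian mixture with
# fixed weights, and the Mendelian model in which group membership is the
# carrier status of a rare autosomal variant segregating in the pedigrees.
# Mixing weights (alpha0, alpha1) are fixed, not estimated.

theta_vec <- function(alpha1, mu0, mu1, sigma0, sigma1) {
  c(alpha0 = 1 - alpha1, alpha1 = alpha1,
    mu0 = mu0, mu1 = mu1, sigma0 = sigma0, sigma1 = sigma1)
}

new_ms_fit <- function(model, theta, loglik, iterations, converged,
                       orientation, trace, n, q1 = NULL) {
  structure(
    list(model = model, theta = theta, loglik = loglik,
         iterations = iterations, converged = converged,
         orientation = orientation, loglik_trace = trace, n = n, q1 = q1),
    class = "ms_fit"
  )
}

#' @export
print.ms_fit <- function(x, ...) {
  cat(sprintf("<ms_fit:%s> n = %d, loglik = %.4f, iterations = %d%s\n",
              x$model, x$n, x$loglik, x$iterations,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  print(round(x$theta, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a model fit into a parameter tibble
#'
#' @param x An `ms_fit` from [fit_gaussian()], [fit_mixture()] or
#'   [fit_mendelian()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.ms_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' One-row summary of a model fit
#'
#' @inheritParams tidy.ms_fit
#' @return A one-row tibble: `model`, `logLik`, `iterations`,
#'   `converged`, `orientation`, `nobs`.
#' @export
glance.ms_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$loglik,
                 iterations = x$iterations, converged = x$converged,
                 orientation = x$orientation %||% NA_character_, nobs = x$n)
}

#' Fit the single-Gaussian null model
#'
#' Maximum likelihood: mean = sample mean, sd = \eqn{\sqrt{\sum (x -
#' \bar x)^2 / n}} (the MLE, not the n-1 estimator), floored at
#' `sigma_min`.
#'
#' @param x Numeric vector of M-values (n >= 2).
#' @param sigma_min Variance floor on the sd scale. Default `1e-3`.
#' @return An `ms_fit` with `model = "gauss"`.
#' @export
fit_gaussian <- function(x, sigma_min = 1e-3) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop_ms("fit_gaussian needs n >= 2")
  mu <- mean(x)
  sig <- sqrt(sum((x - mu)^2) / n)
  if (sig < sigma_min) {
    warning("all values (near-)identical; variance floor applied", call. = FALSE)
    sig <- sigma_min
  }
  ll <- sum(stats::dnorm(x, mu, sig, log = TRUE))
  theta <- c(alpha0 = NA_real_, alpha1 = NA_real_,
             mu0 = mu, mu1 = mu, sigma0 = sig, sigma1 = sig)
  new_ms_fit("gauss", theta, ll, 0L, TRUE, NA_character_, ll, n)
}

# deterministic 2-means split: centers start at min/max of x
init_thetas <- function(x, alpha1, sigma_min) {
  km <- suppressWarnings(stats::kmeans(x, centers = matrix(c(min(x), max(x)))))
  lo <- which.min(km$centers); hi <- which.max(km$centers)
  msd <- function(v) max(sqrt(mean((v - mean(v))^2)), sigma_min)
  m_lo <- km$centers[lo]; m_hi <- km$centers[hi]
  s_lo <- if (sum(km$cluster == lo) > 1) msd(x[km$cluster == lo]) else sigma_min
  s_hi <- if (sum(km$cluster == hi) > 1) msd(x[km$cluster == hi]) else sigma_min
  list(
    upper = theta_vec(alpha1, mu0 = m_lo, mu1 = m_hi, sigma0 = s_lo, sigma1 = s_hi),
    lower = theta_vec(alpha1, mu0 = m_hi, mu1 = m_lo, sigma0 = s_hi, sigma1 = s_lo)
  )
}

em_control <- function(tol = 1e-8, max_iter = 500L, sigma_min = 1e-3) {
  list(tol = tol, max_iter = max_iter, sigma_min = sigma_min)
}

# one EM run for the independent mixture with fixed weights
em_mixture_run <- function(x, theta, ctrl) {
  n <- length(x)
  a0 <- theta[["alpha0"]]; a1 <- theta[["alpha1"]]
  mu0 <- theta[["mu0"]]; mu1 <- theta[["mu1"]]
  s0 <- theta[["sigma0"]]; s1 <- theta[["sigma1"]]
  trace <- numeric(0)
  ll_old <- -Inf; conv <- FALSE; it <- 0L; collapsed <- FALSE
  repeat {
    l0 <- log(a0) + stats::dnorm(x, mu0, s0, log = TRUE)
    l1 <- log(a1) + stats::dnorm(x, mu1, s1, log = TRUE)
    m <- pmax(l0, l1)
    ll <- sum(m + log(exp(l0 - m) + exp(l1 - m)))
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < ctrl$tol * (abs(ll_old) + ctrl$tol)) {
      conv <- TRUE
      break
    }
    if (it >= ctrl$max_iter) break
    it <- it + 1L
    r1 <- 1 / (1 + exp(l0 - l1))
    r0 <- 1 - r1
    upd <- function(r, mu_old, s_old) {
      sr <- sum(r)
      if (sr <= 1e-12) {
        collapsed <<- TRUE
        return(c(mu_old, max(s_old, ctrl$sigma_min)))
      }
      w <- r / sr
      mu <- sum(w * x)
      c(mu, max(sqrt(sum(w * (x - mu)^2)), ctrl$sigma_min))
    }
    p0 <- upd(r0, mu0, s0); p1 <- upd(r1, mu1, s1)
    mu0 <- p0[1]; s0 <- p0[2]; mu1 <- p1[1]; s1 <- p1[2]
    ll_old <- ll
  }
  l0 <- log(a0) + stats::dnorm(x, mu0, s0, log = TRUE)
  l1 <- log(a1) + stats::dnorm(x, mu1, s1, log = TRUE)
  q1 <- 1 / (1 + exp(l0 - l1))
  list(theta = theta_vec(a1, mu0, mu1, s0, s1), loglik = trace[length(trace)],
       iterations = it, converged = conv, trace = trace, q1 = q1,
       collapsed = collapsed)
}

orientation_of <- function(theta) {
  if (theta[["mu1"]] >= theta[["mu0"]]) "upper" else "lower"
}

# pick between the two orientation runs: higher loglik, ties -> upper
pick_orientation <- function(runs) {
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  if (abs(lls[1] - lls[2]) <= 1e-9) {
    ors <- vapply(runs, function(r) orientation_of(r$theta), character(1))
    best <- if ("upper" %in% ors) which(ors == "upper")[1] else 1L
  } else best <- which.max(lls)
  runs[[best]]
}

#' Fit the independent two-component Gaussian mixture by EM
#'
#' Mixing weights are fixed at `(1 - alpha1, alpha1)` and never updated;
#' only the component means and standard deviations are estimated. Two
#' EM runs are performed — rare component initialised at the upper and
#' at the lower mode of a deterministic 2-means split — and the
#' higher-likelihood fit is returned (ties keep the upper orientation).
#'
#' @param x Numeric vector of M-values (n >= 4).
#' @param alpha1 Fixed weight of the rare component. Default 0.01.
#' @param theta_init Optional named theta vector
#'   (`alpha0,alpha1,mu0,mu1,sigma0,sigma1`) to seed a single run.
#' @param control List from [em_control()]: `tol` (relative log-likelihood
#'   change, default 1e-8), `max_iter` (500), `sigma_min` (1e-3).
#' @return An `ms_fit` with `model = "mixture"`; `q1` holds the final
#'   per-observation responsibilities of the rare component.
#' @export
fit_mixture <- function(x, alpha1 = 0.01, theta_init = NULL,
                        control = em_control()) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop_ms("fit_mixture needs n >= 4, got %d", length(x))
  runs <- if (is.null(theta_init)) {
    inits <- init_thetas(x, alpha1, control$sigma_min)
    list(em_mixture_run(x, inits$upper, control),
         em_mixture_run(x, inits$lower, control))
  } else {
    list(em_mixture_run(x, theta_init, control))
  }
  best <- if (length(runs) == 2L) pick_orientation(runs) else runs[[1]]
  if (isTRUE(best$collapsed)) collapse_warning("mixture")
  new_ms_fit("mixture", best$theta, best$loglik, best$iterations,
             best$converged, orientation_of(best$theta), best$trace,
             length(x), best$q1)
}

# align a site's M-values with a stacked prior-table design
align_site <- function(site, typed_order) {
  if (is.data.frame(site)) {
    if (!all(c("individual_id", "m") %in% names(site))) {
      stop_ms("site data frame needs columns individual_id and m")
    }
    x <- stats::setNames(site$m, site$individual_id)
  } else {
    x <- site
    if (is.null(names(x))) {
      if (length(x) != length(typed_order)) {
        stop_ms("unnamed site vector must match the typed order length")
      }
      names(x) <- typed_order
    }
  }
  missing <- setdiff(typed_order, names(x))
  if (length(missing)) {
    stop_ms("site lacks M-values for typed member(s): %s",
            paste(utils::head(missing, 5L), collapse = ", "))
  }
  as.numeric(x[typed_order])
}

# one EM run for the Mendelian model on a stacked design
em_mendel_run <- function(x, stack, theta, ctrl) {
  a0 <- theta[["alpha0"]]; a1 <- theta[["alpha1"]]
  mu0 <- theta[["mu0"]]; mu1 <- theta[["mu1"]]
  s0 <- theta[["sigma0"]]; s1 <- theta[["sigma1"]]
  B <- stack$B; fi <- stack$fam_index; lp <- stack$logprior
  nf <- stack$n_fam
  trace <- numeric(0)
  ll_old <- -Inf; conv <- FALSE; it <- 0L; collapsed <- FALSE
  estep <- function() {
    ll0 <- stats::dnorm(x, mu0, s0, log = TRUE)
    ll1 <- stats::dnorm(x, mu1, s1, log = TRUE)
    sum0 <- as.numeric(rowsum(ll0, stack$fam_of_col, reorder = TRUE))
    rowll <- as.numeric(B %*% (ll1 - ll0)) + sum0[fi] + lp
    logz <- stack_logsumexp(rowll, stack)
    post <- exp(rowll - logz[fi])
    q1 <- as.numeric(Matrix::crossprod(B, post))
    list(loglik = sum(logz), q1 = q1)
  }
  repeat {
    e <- estep()
    trace <- c(trace, e$loglik)
    if (is.finite(ll_old) &&
        abs(e$loglik - ll_old) < ctrl$tol * (abs(ll_old) + ctrl$tol)) {
      conv <- TRUE
      break
    }
    if (it >= ctrl$max_iter) break
    it <- it + 1L
    q1 <- pmin(pmax(e$q1, 0), 1)
    q0 <- 1 - q1
    upd <- function(q, mu_old, sd_old) {
      sq <- sum(q)
      if (sq <= 1e-12) {
        collapsed <<- TRUE
        return(c(mu_old, max(sd_old, ctrl$sigma_min)))
      }
      w <- q / sq
      mu <- sum(w * x)
      c(mu, max(sqrt(sum(w * (x - mu)^2)), ctrl$sigma_min))
    }
    p0 <- upd(q0, mu0, s0); p1 <- upd(q1, mu1, s1)
    mu0 <- p0[1]; s0 <- p0[2]; mu1 <- p1[1]; s1 <- p1[2]
    ll_old <- e$loglik
  }
  e <- estep()
  list(theta = theta_vec(a1, mu0, mu1, s0, s1), loglik = e$loglik,
       iterations = it, converged = conv, trace = trace, q1 = e$q1,
       collapsed = collapsed)
}

collapse_warning <- function(model) {
  warning(warningCondition(
    sprintf("%s fit: one component lost all posterior mass; its parameters were frozen at the variance floor", model),
    class = "mendelscreen_collapse"
  ))
}

#' Fit the Mendelian model by generalized EM
#'
#' Identical to the fixed-weight Gaussian mixture except that the latent
#' group memberships are the carrier statuses of a rare autosomal
#' variant segregating in the pedigrees, so they are dependent within
#' families. The E-step computes, family by family, the posterior over
#' all carrier vectors of the family's typed members — Gaussian
#' "penetrance" times the cached segregation prior, renormalised — and
#' the per-individual carrier probabilities; the M-step is the standard
#' weighted Gaussian update. Both carrier orientations are tried (seeded
#' by the corresponding mixture fits unless `theta_init` is given) and
#' the higher-likelihood fit returned.
#'
#' @param site M-values for the typed members: a data frame with columns
#'   `individual_id` and `m`, or a (named) numeric vector aligned to the
#'   typed order.
#' @param ped A `ped_tbl` with typed members attached.
#' @param tables Optional precomputed [family_prior_tables()]; computed
#'   from `ped` and `alpha1` when `NULL`.
#' @param alpha1 Fixed carrier frequency. Default 0.01.
#' @param theta_init Optional named theta vector to seed a single run.
#' @param control See [em_control()].
#' @return An `ms_fit` with `model = "mendelian"`; `q1` holds posterior
#'   carrier probabilities of the typed members (typed order).
#' @export
fit_mendelian <- function(site, ped, tables = NULL, alpha1 = 0.01,
                          theta_init = NULL, control = em_control()) {
  typed_order <- attr(ped, "typed_order") %||% ped$individual_id[ped$typed]
  if (!length(typed_order)) stop_ms("no typed members; attach_typed_members() first")
  if (is.null(tables)) tables <- family_prior_tables(ped, alpha1)
  if (!is.null(attr(tables, "alpha1")) && abs(attr(tables, "alpha1") - alpha1) > 1e-12) {
    stop_ms("prior tables were built with alpha1 = %g, not %g",
            attr(tables, "alpha1"), alpha1)
  }
  stack <- if (inherits(tables, "prior_stack")) tables else {
    stack_prior_tables(tables, typed_order)
  }
  x <- align_site(site, typed_order)
  if (length(x) < 4L) stop_ms("fit_mendelian needs >= 4 typed values")
  runs <- if (is.null(theta_init)) {
    inits <- init_thetas(x, alpha1, control$sigma_min)
    seeds <- lapply(inits, function(th) em_mixture_run(x, th, control)$theta)
    lapply(seeds, function(th) em_mendel_run(x, stack, th, control))
  } else {
    list(em_mendel_run(x, stack, theta_init, control))
  }
  best <- if (length(runs) == 2L) pick_orientation(runs) else runs[[1]]
  if (isTRUE(best$collapsed)) collapse_warning("mendelian")
  new_ms_fit("mendelian", best$theta, best$loglik, best$iterations,
             best$converged, orientation_of(best$theta), best$trace,
             length(x), stats::setNames(best$q1, typed_order))
}

#' Delta-l: how Mendelian is a site, over and above how bimodal
#'
#' Fits the independent mixture and the Mendelian model to one site's
#' M-values and returns \eqn{\Delta l = l_{Mendel} - l_{mix}} together
#' with the component parameters. Both models have the same number of
#' free parameters, so \eqn{\Delta l} also orders them exactly as AIC or
#' BIC would, with the Mendelian model preferred whenever
#' \eqn{\Delta l > 0}.
#'
#' @inheritParams fit_mendelian
#' @param probe_id Probe label carried into the output.
#' @return A one-row tibble: `probe_id`, `l_gauss`, `l_mix`, `l_mendel`,
#'   `delta_l`, `mu0`, `mu1`, `sigma0`, `sigma1`, `orientation`,
#'   `iterations`, `converged`. The two fits are attached as attribute
#'   `fits`.
#' @export
delta_l <- function(site, ped, tables = NULL, alpha1 = 0.01,
                    control = em_control(), probe_id = NA_character_) {
  typed_order <- attr(ped, "typed_order") %||% ped$individual_id[ped$typed]
  x <- align_site(site, typed_order)
  fit_g <- fit_gaussian(x, control$sigma_min)
  fit_x <- fit_mixture(x, alpha1 = alpha1, control = control)
  fit_m <- fit_mendelian(x, ped, tables = tables, alpha1 = alpha1,
                         control = control)
  # both likelihoods live on the same parameter space, so each fit's
  # optimum seeds one more EM run of the other model; this guards the
  # comparison against one model stopping in a worse local maximum
  repol <- em_mixture_run(x, fit_m$theta, control)
  if (repol$loglik > fit_x$loglik + 1e-10) {
    fit_x <- new_ms_fit("mixture", repol$theta, repol$loglik, repol$iterations,
                        repol$converged, orientation_of(repol$theta),
                        repol$trace, length(x), repol$q1)
  }
  out <- tibble::tibble(
    probe_id = probe_id,
    l_gauss = fit_g$loglik, l_mix = fit_x$loglik, l_mendel = fit_m$loglik,
    delta_l = fit_m$loglik - fit_x$loglik,
    mu0 = fit_m$theta[["mu0"]], mu1 = fit_m$theta[["mu1"]],
    sigma0 = fit_m$theta[["sigma0"]], sigma1 = fit_m$theta[["sigma1"]],
    orientation = fit_m$orientation,
    iterations = fit_m$iterations,
    converged = fit_x$converged && fit_m$converged
  )
  attr(out, "fits") <- list(gauss = fit_g, mixture = fit_x, mendelian = fit_m)
  out
}
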