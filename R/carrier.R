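#' Posterior carrier probabilities for family members
#'
#' Computes, at the plug-in Mendelian MLE, each individual's posterior
#' probability of carrying the hypothetical variant given the family's
#' observed M-values and the pedigree structure. Only pedigree structure
#' and M-values are used — never phenotype data. For typed members this
#' is the E-step quantity (sum of the family posterior over carrier
#' vectors in which the member is a carrier); for untyped members
#' (`scope = "all_members"`, the default) the configuration sum is
#' extended to include that member, marginalising all other untyped
#' members exactly.
#'
#' @param site M-values for the typed members (data frame with
#'   `individual_id`, `m`, or named/aligned numeric vector).
#' @param ped A `ped_tbl` with typed members attached.
#' @param theta Named theta vector, normally `fit$theta` from a converged
#'   [fit_mendelian()]; alternatively pass the `ms_fit` itself.
#' @param scope `"all_members"` (default) or `"typed_only"`.
#' @param alpha1 Carrier frequency used for the segregation priors.
#'   Defaults to `theta[["alpha1"]]`.
#' @param tables Optional precomputed [family_prior_tables()]; speeds up
#'   `scope = "typed_only"` across repeated calls.
#' @param probe_id Probe label carried into the output.
#' @return A tibble: `probe_id`, `family_id`, `individual_id`, `typed`
#'   (0/1), `q1`. An individual in a family with no typed members gets
#'   the prior marginal (posterior without data).
#' @export
carrier_posteriors <- function(site, ped, theta,
                               scope = c("all_members", "typed_only"),
                               alpha1 = NULL, tables = NULL,
                               probe_id = NA_character_) {
  scope <- match.arg(scope)
  if (inherits(theta, "ms_fit")) theta <- theta$theta
  if (is.null(alpha1)) alpha1 <- theta[["alpha1"]]
  typed_order <- attr(ped, "typed_order") %||% ped$individual_id[ped$typed]
  x <- align_site(site, typed_order)
  names(x) <- typed_order
  mu0 <- theta[["mu0"]]; mu1 <- theta[["mu1"]]
  s0 <- theta[["sigma0"]]; s1 <- theta[["sigma1"]]

  if (scope == "typed_only" && !is.null(tables)) {
    return(posteriors_from_tables(x, ped, tables, mu0, mu1, s0, s1, probe_id))
  }

  sts <- ped_structs(ped)
  rows <- lapply(sts, function(st) {
    k <- length(st$typed)
    xt <- if (k) x[st$typed_ids] else numeric(0)
    ll0 <- if (k) stats::dnorm(xt, mu0, s0, log = TRUE) else numeric(0)
    ll1 <- if (k) stats::dnorm(xt, mu1, s1, log = TRUE) else numeric(0)
    target <- if (scope == "typed_only") st$typed else seq_len(st$n)
    q1 <- vapply(target, function(i) {
      s_idx <- union(st$typed, i)
      v <- prior_vector(st, s_idx, alpha1)
      ks <- length(s_idx)
      msk <- seq_len(2L^ks) - 1L
      bits <- vapply(seq_len(ks), function(b)
        bitwAnd(msk, bitwShiftL(1L, b - 1L)) > 0L, logical(2L^ks))
      if (ks == 1L) bits <- matrix(bits, ncol = 1L)
      typed_cols <- match(st$typed, s_idx)
      ll <- if (k) {
        as.numeric(bits[, typed_cols, drop = FALSE] %*% (ll1 - ll0)) + sum(ll0)
      } else rep(0, 2L^ks)
      lw <- ifelse(v > 0, ll + log(v), -Inf)
      i_col <- match(i, s_idx)
      logz <- logsumexp(lw)
      if (!is.finite(logz)) return(NA_real_)
      exp(logsumexp(lw[bits[, i_col]]) - logz)
    }, numeric(1))
    tibble::tibble(
      probe_id = probe_id,
      family_id = st$family_id,
      individual_id = st$ids[target],
      typed = as.integer(target %in% st$typed),
      q1 = q1
    )
  })
  dplyr::bind_rows(rows)
}

# fast typed-only posteriors through the cached family tables
posteriors_from_tables <- function(x, ped, tables, mu0, mu1, s0, s1, probe_id) {
  typed_order <- names(x)
  stack <- if (inherits(tables, "prior_stack")) tables else {
    stack_prior_tables(tables, typed_order)
  }
  fam_of_col <- stack$fam_of_col
  ll0 <- stats::dnorm(x, mu0, s0, log = TRUE)
  ll1 <- stats::dnorm(x, mu1, s1, log = TRUE)
  sum0 <- as.numeric(rowsum(as.numeric(ll0), fam_of_col, reorder = TRUE))
  rowll <- as.numeric(stack$B %*% (ll1 - ll0)) + sum0[stack$fam_index] + stack$logprior
  logz <- stack_logsumexp(rowll, stack)
  post <- exp(rowll - logz[stack$fam_index])
  q1 <- as.numeric(Matrix::crossprod(stack$B, post))
  tibble::tibble(
    probe_id = probe_id,
    family_id = stack$fam_ids[fam_of_col],
    individual_id = typed_order,
    typed = 1L,
    q1 = q1
  )
}
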