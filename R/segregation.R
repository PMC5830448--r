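#' Founder-origin configurations and their prior weights
#'
#' Under the rare-variant model the only carrier configurations allowed
#' among a family's founders are "no founder carries the variant" or
#' "exactly one founder is a heterozygous carrier". Weights are the
#' binomial terms \eqn{(1-\alpha_1)^F} and \eqn{\alpha_1(1-\alpha_1)^{F-1}}
#' restricted to these configurations and renormalised, so the founder
#' carrier marginal stays close to \eqn{\alpha_1} for rare variants.
#'
#' @param ped A `ped_tbl` containing a single family (or a subset of one).
#' @param alpha1 Population carrier frequency, in (0, 1). Default 0.01.
#' @return A tibble with columns `origin_id` (`NA` for the no-carrier
#'   configuration, otherwise the carrier founder's individual id) and
#'   `weight` (normalised; sums to 1).
#' @export
enumerate_founder_configs <- function(ped, alpha1 = 0.01) {
  if (!(alpha1 > 0 && alpha1 < 1)) stop_ms("alpha1 must be in (0, 1)")
  sts <- ped_structs(ped)
  if (length(sts) != 1L) stop_ms("expected a single family, got %d", length(sts))
  st <- sts[[1]]
  founder_config_weights(st, alpha1)
}

founder_config_weights <- function(st, alpha1) {
  f_ids <- st$ids[st$founders]
  nf <- length(f_ids)
  w <- c((1 - alpha1)^nf, rep(alpha1 * (1 - alpha1)^(nf - 1), nf))
  tibble::tibble(origin_id = c(NA_character_, f_ids), weight = w / sum(w))
}

# Joint prior over carrier statuses of the members indexed by s_idx
# (a subset of 1..n), as a vector of length 2^|s| indexed by bitmask + 1
# (bit b-1 set  <=>  member s_idx[b] is a carrier). Members outside s_idx
# are marginalised exactly. Vectorised downward tree recursion per
# founder-origin configuration: given the origin, carriers form a tree
# rooted at the origin (consanguinity excluded), so
# P(y_s | origin) factorises over parent-child transmissions with
# probability 1/2 each.
prior_vector <- function(st, s_idx, alpha1) {
  check_no_consanguinity(st)
  k <- length(s_idx)
  nmask <- 2L^k
  pos <- integer(st$n); pos[s_idx] <- seq_len(k)
  bit <- function(i) { # logical vector over masks: member i carrier?
    bitwAnd(seq_len(nmask) - 1L, bitwShiftL(1L, pos[i] - 1L)) > 0L
  }
  cfg <- founder_config_weights(st, alpha1)
  out <- numeric(nmask)

  # no-carrier configuration: all constrained members must be 0
  all0 <- rep(TRUE, nmask)
  for (i in s_idx) all0 <- all0 & !bit(i)
  out <- out + cfg$weight[1] * as.numeric(all0)

  rev_topo <- rev(st$topo)
  for (j_row in seq_len(nrow(cfg) - 1L)) {
    j <- st$founders[j_row]
    # descendants of origin j (incl. j)
    in_d <- logical(st$n); in_d[j] <- TRUE
    for (i in st$topo) {
      if (in_d[i]) next
      pa <- c(st$fa[i], st$mo[i])
      pa <- pa[!is.na(pa)]
      if (length(pa) && any(in_d[pa])) in_d[i] <- TRUE
    }
    g1 <- vector("list", st$n)
    g0 <- vector("list", st$n)
    for (i in rev_topo) {
      if (!in_d[i]) next
      c1 <- if (pos[i] > 0L) as.numeric(bit(i)) else rep(1, nmask)
      c0 <- if (pos[i] > 0L) as.numeric(!bit(i)) else rep(1, nmask)
      for (ch in st$children[[i]]) {
        c1 <- c1 * 0.5 * (g1[[ch]] + g0[[ch]])
        c0 <- c0 * g0[[ch]]
      }
      g1[[i]] <- c1
      g0[[i]] <- c0
    }
    res <- g1[[j]]
    for (i in s_idx) if (!in_d[i]) res <- res * !bit(i)
    out <- out + cfg$weight[j_row + 1L] * res
  }
  out
}

#' Exact prior probability of a carrier-status assignment
#'
#' Computes \eqn{P(y_S \mid \alpha_1)} for an assignment of carrier
#' statuses over any subset \eqn{S} of a family's members, summing over
#' founder-origin configurations and Mendelian transmissions (a
#' heterozygous parent transmits the variant to each child independently
#' with probability 1/2) and marginalising members outside \eqn{S}
#' exactly. Consanguineous pedigrees are rejected.
#'
#' @param ped A `ped_tbl` containing a single family.
#' @param assignment Named 0/1 (or logical) vector; names are individual
#'   ids of the subset \eqn{S}, values are carrier statuses.
#' @param alpha1 Carrier frequency. Default 0.01.
#' @return A single probability.
#' @seealso [brute_force_prior()] for the enumeration oracle,
#'   [family_prior_tables()] for cached typed-member tables.
#' @export
config_prior <- function(ped, assignment, alpha1 = 0.01) {
  sts <- ped_structs(ped)
  if (length(sts) != 1L) stop_ms("expected a single family, got %d", length(sts))
  st <- sts[[1]]
  s_idx <- match(names(assignment), st$ids)
  if (anyNA(s_idx)) {
    stop_ms("assignment names not in pedigree: %s",
            paste(names(assignment)[is.na(s_idx)], collapse = ", "))
  }
  if (length(s_idx) == 0L) return(1)
  v <- prior_vector(st, s_idx, alpha1)
  mask <- sum(as.integer(as.logical(assignment)) * 2L^(seq_along(s_idx) - 1L))
  v[mask + 1L]
}

#' Brute-force carrier-prior oracle by full enumeration
#'
#' Independent reference implementation of [config_prior()]: enumerates
#' all \eqn{2^n} complete carrier vectors of the family, scores each as
#' founder-configuration weight times the product of per-child
#' transmission probabilities (a child with \eqn{k} carrier parents is a
#' carrier with probability \eqn{1 - 2^{-k}}), and sums the scores of the
#' vectors matching `assignment` on its subset. Intended for small
#' pedigrees and testing only.
#'
#' @inheritParams config_prior
#' @return A single probability.
#' @export
brute_force_prior <- function(ped, assignment, alpha1 = 0.01) {
  sts <- ped_structs(ped)
  if (length(sts) != 1L) stop_ms("expected a single family, got %d", length(sts))
  st <- sts[[1]]
  n <- st$n
  if (n > 20L) stop_ms("brute_force_prior supports at most 20 members, got %d", n)
  s_idx <- match(names(assignment), st$ids)
  if (anyNA(s_idx)) stop_ms("assignment names not in pedigree")

  y <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))[, seq_len(n), drop = FALSE]
  cfg <- founder_config_weights(st, alpha1)
  founder_idx <- st$founders

  # founder-configuration weight of each full vector (0 if founders match
  # no allowed configuration)
  fmat <- y[, founder_idx, drop = FALSE]
  n_carrier_founders <- rowSums(fmat)
  w <- numeric(nrow(y))
  w[n_carrier_founders == 0L] <- cfg$weight[1]
  one <- which(n_carrier_founders == 1L)
  if (length(one)) {
    which_f <- apply(fmat[one, , drop = FALSE], 1L, which.max)
    w[one] <- cfg$weight[match(st$ids[founder_idx][which_f], cfg$origin_id)]
  }

  # transmission probability product over non-founders
  p <- w
  for (i in seq_len(n)) {
    if (i %in% founder_idx) next
    kpar <- y[, st$fa[i]] + y[, st$mo[i]]
    p_carrier <- 1 - 0.5^kpar
    p <- p * ifelse(y[, i] == 1L, p_carrier, 1 - p_carrier)
  }
  if (length(s_idx) == 0L) return(sum(p))
  keep <- rep(TRUE, nrow(y))
  tgt <- as.integer(as.logical(assignment))
  for (b in seq_along(s_idx)) keep <- keep & (y[, s_idx[b]] == tgt[b])
  sum(p[keep])
}

#' Precompute per-family carrier-prior tables for typed members
#'
#' The family priors \eqn{P(y^f \mid \theta)} depend only on the pedigree
#' structure and \eqn{\alpha_1}, not on the Gaussian parameters or the
#' M-values, so they are computed once per family — over all
#' \eqn{2^{|typed_f|}} carrier vectors of the family's typed members —
#' and reused across every probe and every EM iteration.
#'
#' @param ped A `ped_tbl` with typed members attached
#'   (see [attach_typed_members()]).
#' @param alpha1 Carrier frequency. Default 0.01.
#' @param max_typed Refuse families whose table would exceed
#'   `2^max_typed` entries. Default 16.
#' @return An object of class `prior_tables`: a list with one element per
#'   family holding the typed-member ids, the carrier-status design
#'   matrix over all vectors, and their prior probabilities.
#' @export
family_prior_tables <- function(ped, alpha1 = 0.01, max_typed = 16L) {
  if (!(alpha1 > 0 && alpha1 < 1)) stop_ms("alpha1 must be in (0, 1)")
  sts <- ped_structs(ped)
  tabs <- lapply(sts, function(st) {
    k <- length(st$typed)
    if (k > max_typed) {
      stop_ms("family %s has %d typed members; table of 2^%d entries exceeds the budget (max_typed = %d). Use per-call config_prior() instead.",
              st$family_id, k, k, max_typed)
    }
    prob <- if (k == 0L) 1 else prior_vector(st, st$typed, alpha1)
    bmat <- if (k == 0L) {
      matrix(FALSE, 1L, 0L)
    } else {
      m <- seq_len(2L^k) - 1L
      vapply(seq_len(k), function(b) bitwAnd(m, bitwShiftL(1L, b - 1L)) > 0L,
             logical(2L^k))
    }
    if (k == 1L) bmat <- matrix(bmat, ncol = 1L)
    list(family_id = st$family_id, typed_ids = st$typed_ids,
         bits = bmat, prob = prob)
  })
  names(tabs) <- vapply(tabs, `[[`, character(1), "family_id")
  structure(tabs, alpha1 = alpha1, class = "prior_tables")
}

#' Dump one family's carrier-prior table as TSV (debugging aid)
#'
#' Writes one row per typed-member carrier vector: the 0/1 status of
#' each typed member and the vector's prior probability.
#'
#' @param tables A [family_prior_tables()] object.
#' @param family_id Which family to dump.
#' @param path Output TSV path.
#' @return The table as a tibble, invisibly.
#' @export
write_prior_table <- function(tables, family_id, path) {
  t <- tables[[family_id]]
  if (is.null(t)) stop_ms("no prior table for family '%s'", family_id)
  out <- tibble::as_tibble(`colnames<-`(1L * t$bits, t$typed_ids))
  out$prior <- t$prob
  readr::write_tsv(out, path)
  invisible(out)
}

#' @export
print.prior_tables <- function(x, ...) {
  k <- vapply(x, function(t) length(t$typed_ids), integer(1))
  cat(sprintf("<prior_tables> %d families, alpha1 = %g, typed members %d-%d\n",
              length(x), attr(x, "alpha1"), min(k), max(k)))
  invisible(x)
}

# Stack all family tables into one sparse design for fast EM:
# one row per (family, carrier vector), columns = global typed order.
stack_prior_tables <- function(tables, typed_order) {
  tabs <- Filter(function(t) length(t$typed_ids) > 0L, tables)
  if (!length(tabs)) stop_ms("no family has typed members")
  rows_per <- vapply(tabs, function(t) nrow(t$bits), integer(1))
  row_off <- c(0L, cumsum(rows_per))
  ii <- integer(0); jj <- integer(0)
  for (f in seq_along(tabs)) {
    t <- tabs[[f]]
    cols <- match(t$typed_ids, typed_order)
    if (anyNA(cols)) stop_ms("typed member of family %s missing from typed order",
                             t$family_id)
    idx <- which(t$bits, arr.ind = TRUE)
    ii <- c(ii, row_off[f] + idx[, 1L])
    jj <- c(jj, cols[idx[, 2L]])
  }
  B <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(sum(rows_per), length(typed_order)))
  fam_cols <- lapply(tabs, function(t) match(t$typed_ids, typed_order))
  fam_of_col <- integer(length(typed_order))
  for (f in seq_along(tabs)) fam_of_col[fam_cols[[f]]] <- f
  structure(list(
    B = B,
    fam_index = rep(seq_along(tabs), rows_per),
    row_start = row_off[-length(row_off)] + 1L,
    row_end = row_off[-1L],
    logprior = log(unlist(lapply(tabs, `[[`, "prob"), use.names = FALSE)),
    n_fam = length(tabs),
    fam_ids = vapply(tabs, `[[`, character(1), "family_id"),
    fam_cols = fam_cols,
    fam_of_col = fam_of_col
  ), class = "prior_stack")
}

# per-family logsumexp over a stacked row vector (rows contiguous per family)
stack_logsumexp <- function(v, stack) {
  nf <- stack$n_fam
  m <- numeric(nf); s <- numeric(nf)
  for (g in seq_len(nf)) {
    seg <- v[stack$row_start[g]:stack$row_end[g]]
    mg <- max(seg)
    m[g] <- mg
    s[g] <- sum(exp(seg - mg))
  }
  m + log(s)
}
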