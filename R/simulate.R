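# Synthetic multiplex-family cohorts with the statistical structure the
# screen assumes: multi-generational pedigrees with marry-in founders, a
# rare variant dropped from at most one carrier founder, carrier-
# conditional bimodal M-values, and ascertained age-at-onset phenotypes.
# Defaults emulate the study design the method targets: 25 families,
# 3 generations, ~210 typed members, carrier frequency 0.01, and
# beta-scale modes around 0.11 vs 0.50 (M-values -3 vs 0).

#' Simulate a set of multi-generational pedigrees
#'
#' Each family starts from a founder couple; offspring in non-terminal
#' generations marry in a new founder and reproduce. Offspring counts
#' are `1 + Poisson(mean_offspring - 1)` capped at `max_offspring`.
#' Members are flagged typed (having methylation data) independently
#' with probability `typed_fraction`.
#'
#' @param n_families Number of families. Default 25.
#' @param generations Number of generations. Default 3.
#' @param mean_offspring Mean offspring per couple. Default 2.5.
#' @param max_offspring Cap on offspring per couple. Default 4.
#' @param typed_fraction Probability a member is typed. Default 0.65.
#' @param max_typed_per_family Cap on typed members per family (blood
#'   samples are rarely available for every member of a large family;
#'   the cap also bounds the `2^k` carrier-vector tables). Default 12.
#' @param seed Integer seed; the pedigree stream is independent of the
#'   variant, methylation and phenotype streams.
#' @return A `ped_tbl` with `typed` set and `typed_order` attached.
#' @export
simulate_pedigree_set <- function(n_families = 25L, generations = 3L,
                                  mean_offspring = 2.5, max_offspring = 4L,
                                  typed_fraction = 0.65,
                                  max_typed_per_family = 12L, seed = 1L) {
  if (n_families < 1L || generations < 1L) stop_ms("need >= 1 family and >= 1 generation")
  rows <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(child_seed(seed, 101L))
    out <- list()
    for (f in seq_len(n_families)) {
      fam <- sprintf("FAM%02d", f)
      nid <- 0L
      new_id <- function() {
        nid <<- nid + 1L
        sprintf("%s_%03d", fam, nid)
      }
      add <- function(id, fa, mo, sex) {
        out[[length(out) + 1L]] <<- tibble::tibble(
          family_id = fam, individual_id = id,
          father_id = fa, mother_id = mo, sex = sex)
      }
      dad <- new_id(); mum <- new_id()
      add(dad, NA, NA, "male"); add(mum, NA, NA, "female")
      couples <- list(c(dad, mum))
      for (g in seq_len(generations - 1L)) {
        nxt <- list()
        for (cp in couples) {
          n_off <- min(1L + stats::rpois(1L, max(mean_offspring - 1, 0)), max_offspring)
          for (o in seq_len(n_off)) {
            kid <- new_id()
            kid_sex <- if (stats::runif(1) < 0.5) "female" else "male"
            add(kid, cp[1], cp[2], kid_sex)
            if (g < generations - 1L) {
              sp <- new_id()
              add(sp, NA, NA, if (kid_sex == "female") "male" else "female")
              nxt[[length(nxt) + 1L]] <-
                if (kid_sex == "male") c(kid, sp) else c(sp, kid)
            }
          }
        }
        couples <- nxt
      }
    }
    df <- dplyr::bind_rows(out)
    df$typed <- stats::runif(nrow(df)) < typed_fraction
    for (fam in unique(df$family_id)) {
      idx <- which(df$family_id == fam & df$typed)
      if (length(idx) > max_typed_per_family) {
        df$typed[sample(idx, length(idx) - max_typed_per_family)] <- FALSE
      }
    }
    df
  })
  ped <- new_ped_tbl(rows)
  attach_typed_members(ped, ped$individual_id[ped$typed])
}

# save/restore the global RNG state so simulator streams stay separable
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

with_stream <- function(seed, offset, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(seed, offset))
  force(code)
}

#' Drop a rare variant through the pedigrees
#'
#' Samples, per family, a founder-origin configuration from the
#' truncated-binomial prior (no carrier founder, or exactly one
#' heterozygous carrier founder) and transmits the variant down the
#' pedigree: each child of a heterozygous parent inherits it
#' independently with probability 1/2.
#'
#' @param ped A `ped_tbl`.
#' @param alpha1 Carrier frequency. Default 0.01.
#' @param seed Integer seed.
#' @param min_typed_carriers Redraw the cohort-wide drop until at least
#'   this many typed members carry the variant (0 = unconditional,
#'   the default). Conditioning makes a site's variant actually
#'   segregate among the sampled individuals — use it to generate
#'   detectable Mendelian sites, not for calibration checks.
#' @param max_retry Retry budget for the conditioned drop.
#' @return Tibble: `family_id`, `individual_id`, `carrier` (0/1).
#' @export
drop_variant <- function(ped, alpha1 = 0.01, seed = 1L,
                         min_typed_carriers = 0L, max_retry = 10000L) {
  sts <- ped_structs(ped)
  typed_ids <- attr(ped, "typed_order") %||% ped$individual_id[ped$typed]
  with_stream(seed, 202L, {
    for (attempt in seq_len(max_retry)) {
      rows <- lapply(sts, function(st) {
        cfg <- founder_config_weights(st, alpha1)
        pick <- sample.int(nrow(cfg), 1L, prob = cfg$weight)
        y <- integer(st$n)
        if (pick > 1L) {
          origin <- match(cfg$origin_id[pick], st$ids)
          y[origin] <- 1L
          for (i in st$topo) {
            if (i == origin || is.na(st$fa[i])) next
            k <- y[st$fa[i]] + y[st$mo[i]]
            if (k > 0L) y[i] <- as.integer(stats::runif(1) < 1 - 0.5^k)
          }
        }
        tibble::tibble(family_id = st$family_id, individual_id = st$ids,
                       carrier = y)
      })
      res <- dplyr::bind_rows(rows)
      n_typed <- sum(res$carrier[res$individual_id %in% typed_ids])
      if (n_typed >= min_typed_carriers) return(res)
    }
    stop_ms("no variant drop with >= %d typed carriers within %d retries",
            min_typed_carriers, max_retry)
  })
}

#' Simulate one methylation site over a cohort
#'
#' Three generative regimes: `"mendelian"` draws each typed member's
#' M-value from the Gaussian component of their true carrier status;
#' `"mixture"` ignores the pedigree and assigns the rare component iid
#' with probability `alpha1`; `"gaussian"` draws everyone from the
#' common component.
#'
#' @param ped A `ped_tbl` with typed members.
#' @param carriers Tibble from [drop_variant()] (used by the mendelian
#'   regime).
#' @param kind `"mendelian"`, `"mixture"` or `"gaussian"`.
#' @param mu0,mu1 Component means, M-value units. Defaults -3 and 0
#'   (beta about 0.11 and 0.50: a hypomethylated common mode and a
#'   hemimethylated carrier mode).
#' @param sigma0,sigma1 Component standard deviations. Default 0.3.
#' @param alpha1 Rare-group frequency for the mixture regime.
#' @param seed Integer seed.
#' @param probe_id Probe label.
#' @return Tibble: `probe_id`, `family_id`, `individual_id`, `group`
#'   (the true component), `m`. Typed members only.
#' @export
simulate_site <- function(ped, carriers = NULL,
                          kind = c("mendelian", "mixture", "gaussian"),
                          mu0 = -3, mu1 = 0, sigma0 = 0.3, sigma1 = 0.3,
                          alpha1 = 0.01, seed = 1L, probe_id = "probe") {
  kind <- match.arg(kind)
  typed_order <- attr(ped, "typed_order") %||% ped$individual_id[ped$typed]
  idx <- match(typed_order, ped$individual_id)
  with_stream(seed, 303L, {
    grp <- switch(kind,
      mendelian = {
        if (is.null(carriers)) stop_ms("mendelian regime needs a carrier assignment")
        carriers$carrier[match(typed_order, carriers$individual_id)]
      },
      mixture = as.integer(stats::runif(length(typed_order)) < alpha1),
      gaussian = integer(length(typed_order))
    )
    m <- stats::rnorm(length(typed_order),
                      mean = ifelse(grp == 1L, mu1, mu0),
                      sd = ifelse(grp == 1L, sigma1, sigma0))
    tibble::tibble(probe_id = probe_id,
                   family_id = ped$family_id[idx],
                   individual_id = typed_order,
                   group = grp, m = m)
  })
}

#' Simulate ascertained disease phenotypes
#'
#' Female ages at onset follow a Weibull proportional-hazards model:
#' baseline cumulative hazard \eqn{(t/scale)^{shape}} multiplied by
#' `hr^carrier`. Every individual has an independent censoring age
#' drawn uniformly on `censor_range`; the recorded age is the minimum
#' of onset and censoring, `affected` marks onset first. Males are
#' censored. Families are ascertained for multiple cases: phenotype
#' draws are rejected and redrawn (`policy = "resample"`, default) or
#' the family is dropped (`"discard"`) until at least `min_affected`
#' affected females remain.
#'
#' @param ped A `ped_tbl`.
#' @param carriers Tibble from [drop_variant()].
#' @param shape,scale Weibull baseline hazard parameters (years).
#'   Defaults 3 and 110 give roughly a 20 percent female risk by age 70.
#' @param hr Carrier hazard ratio. Default 1 (null).
#' @param censor_range Uniform censoring-age range. Default c(50, 80).
#' @param min_affected Ascertainment: minimum affected females per
#'   retained family. Default 2.
#' @param policy `"resample"` or `"discard"`.
#' @param max_retry Retry budget per family. Default 1000.
#' @param seed Integer seed.
#' @return Tibble: `family_id`, `individual_id`, `affected`, `age`,
#'   `sex`, with attribute `ascertainment` recording the policy, retry
#'   counts and retained families.
#' @export
simulate_phenotypes <- function(ped, carriers, shape = 3, scale = 110,
                                hr = 1, censor_range = c(50, 80),
                                min_affected = 2L,
                                policy = c("resample", "discard"),
                                max_retry = 1000L, seed = 1L) {
  policy <- match.arg(policy)
  if (hr <= 0) stop_ms("hazard ratio must be positive")
  y <- carriers$carrier[match(ped$individual_id, carriers$individual_id)]
  with_stream(seed, 404L, {
    fams <- split(seq_len(nrow(ped)), ped$family_id)
    out <- list(); retries <- integer(0); kept <- character(0)
    for (fname in names(fams)) {
      rowsf <- fams[[fname]]
      fem <- ped$sex[rowsf] == "female"
      ok <- FALSE
      for (try in seq_len(max_retry)) {
        cens <- stats::runif(length(rowsf), censor_range[1], censor_range[2])
        rate <- hr^y[rowsf]
        onset <- scale * (stats::rexp(length(rowsf)) / rate)^(1 / shape)
        onset[!fem] <- Inf
        affected <- onset < cens
        if (sum(affected & fem) >= min_affected) { ok <- TRUE; break }
        if (policy == "discard") break
      }
      retries[fname] <- try
      if (!ok) {
        if (policy == "discard") next
        stop_ms("family %s: ascertainment (>= %d affected females) not met within %d retries",
                fname, min_affected, max_retry)
      }
      kept <- c(kept, fname)
      out[[fname]] <- tibble::tibble(
        family_id = fname,
        individual_id = ped$individual_id[rowsf],
        affected = affected,
        age = pmin(onset, cens),
        sex = ped$sex[rowsf]
      )
    }
    if (!length(out)) stop_ms("no family met the ascertainment criterion")
    res <- dplyr::bind_rows(out)
    attr(res, "ascertainment") <- list(policy = policy,
                                       min_affected = min_affected,
                                       retries = retries, retained = kept)
    res
  })
}

#' Simulate a complete cohort: pedigrees, sites, phenotypes, annotation
#'
#' One call producing everything the pipeline consumes. Site kinds
#' default to 20 Mendelian and 180 non-Mendelian (90 matched-marginal
#' mixture, 90 Gaussian) probes; each Mendelian site gets its own
#' independent variant drop, and the first Mendelian site's carriers
#' drive the (ascertained) phenotypes. A synthetic annotation assigns
#' `snp_distance` values so that SNP-proximity trend tests can run.
#'
#' @param n_families,generations,typed_fraction See
#'   [simulate_pedigree_set()].
#' @param n_mendelian,n_mixture,n_gaussian Site counts. Defaults 20, 90, 90.
#' @param mu0,mu1,sigma0,sigma1,alpha1 Site parameters (see
#'   [simulate_site()]).
#' @param hr Carrier hazard ratio for the causal site. Default 3.
#' @param min_affected Ascertainment threshold. Default 2.
#' @param min_typed_carriers Mendelian sites are drawn conditional on at
#'   least this many typed carriers, so their variant actually
#'   segregates among the sampled individuals. Default 2.
#' @param seed Integer seed.
#' @return A list: `ped`, `mat` (M-value tibble, probes x typed
#'   samples), `phenotypes`, `annotation`, `truth` (site kinds), and
#'   `carriers` (true carrier table of the causal site).
#' @export
simulate_cohort <- function(n_families = 25L, generations = 3L,
                            typed_fraction = 0.65,
                            n_mendelian = 20L, n_mixture = 90L, n_gaussian = 90L,
                            mu0 = -3, mu1 = 0, sigma0 = 0.3, sigma1 = 0.3,
                            alpha1 = 0.01, hr = 3, min_affected = 2L,
                            min_typed_carriers = 2L, seed = 1L) {
  ped <- simulate_pedigree_set(n_families, generations,
                               typed_fraction = typed_fraction, seed = seed)
  typed_order <- attr(ped, "typed_order")
  kinds <- c(rep("mendelian", n_mendelian), rep("mixture", n_mixture),
             rep("gaussian", n_gaussian))
  n_sites <- length(kinds)
  ids <- sprintf("cg%06d", seq_len(n_sites))
  carriers_first <- NULL
  rows <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    carr <- if (kinds[s] == "mendelian") {
      cs <- drop_variant(ped, alpha1, seed = child_seed(seed, 7000L + s),
                         min_typed_carriers = min_typed_carriers)
      if (is.null(carriers_first)) carriers_first <- cs
      cs
    } else NULL
    site <- simulate_site(ped, carr, kinds[s], mu0, mu1, sigma0, sigma1,
                          alpha1, seed = child_seed(seed, 9000L + s),
                          probe_id = ids[s])
    rows[[s]] <- site$m
  }
  mat <- tibble::as_tibble(
    c(list(probe_id = ids),
      stats::setNames(lapply(seq_along(typed_order),
                             function(j) vapply(rows, `[`, numeric(1), j)),
                      typed_order))
  )
  attr(mat, "scale") <- "m"
  if (is.null(carriers_first)) {
    carriers_first <- tibble::tibble(family_id = ped$family_id,
                                     individual_id = ped$individual_id,
                                     carrier = 0L)
  }
  phen <- simulate_phenotypes(ped, carriers_first, hr = hr,
                              min_affected = min_affected,
                              seed = child_seed(seed, 505L))
  annotation <- with_stream(seed, 606L, tibble::tibble(
    probe_id = ids,
    chr = as.character(sample(1:22, n_sites, replace = TRUE)),
    pos = sample.int(2e8, n_sites),
    snp_distance = ifelse(stats::runif(n_sites) < 0.1,
                          sample.int(200L, n_sites, replace = TRUE), NA_integer_)
  ))
  list(ped = ped, mat = mat, phenotypes = phen, annotation = annotation,
       truth = tibble::tibble(probe_id = ids, kind = kinds),
       carriers = carriers_first, seed = seed)
}
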