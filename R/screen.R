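#' Genome-wide delta-l screen
#'
#' Fits the mixture and Mendelian models to every probe of an (already
#' filtered) M-value matrix and ranks probes by
#' \eqn{\Delta l = l_{Mendel} - l_{mix}}, descending, ties broken by
#' probe id. The screen uses only pedigree structure and M-values;
#' phenotypes are not an argument by design. Probes with fewer than
#' `min_distinct` distinct values are skipped with a recorded reason.
#'
#' @param mat Methylation tibble on the M scale (`probe_id` + sample
#'   columns; columns must match the pedigree's typed order).
#' @param ped A `ped_tbl` with typed members attached.
#' @param k Number of top probes to flag as selected. Default 1000.
#' @param alpha1 Fixed carrier frequency. Default 0.01.
#' @param tables Optional precomputed [family_prior_tables()].
#' @param control See [em_control()].
#' @param min_distinct Minimum distinct M-values per probe. Default 4.
#' @return A tibble of class `screen_result`, one row per fitted probe,
#'   ranked: columns of [delta_l()] plus `rank` and `selected`.
#'   Attributes: `k`, `skipped` (tibble of probe_id, reason).
#' @export
screen_sites <- function(mat, ped, k = 1000L, alpha1 = 0.01, tables = NULL,
                         control = em_control(), min_distinct = 4L) {
  typed_order <- attr(ped, "typed_order") %||% ped$individual_id[ped$typed]
  samp <- setdiff(names(mat), "probe_id")
  if (!setequal(samp, typed_order)) {
    stop_ms("matrix samples do not match the pedigree's typed members")
  }
  if (is.null(tables)) tables <- family_prior_tables(ped, alpha1)
  stack <- stack_prior_tables(tables, typed_order)
  vals <- as.matrix(mat[typed_order])

  skipped <- list()
  rows <- vector("list", nrow(mat))
  for (i in seq_len(nrow(mat))) {
    x <- vals[i, ]
    if (length(unique(x)) < min_distinct) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(probe_id = mat$probe_id[i],
                       reason = sprintf("fewer than %d distinct values", min_distinct))
      next
    }
    rows[[i]] <- withCallingHandlers(
      delta_l(stats::setNames(x, typed_order), ped, tables = stack,
              alpha1 = alpha1, control = control, probe_id = mat$probe_id[i]),
      mendelscreen_collapse = function(w) invokeRestart("muffleWarning")
    )
    attr(rows[[i]], "fits") <- NULL
  }
  res <- dplyr::bind_rows(rows)
  if (!nrow(res)) stop_ms("no probe could be fitted")
  res <- dplyr::arrange(res, dplyr::desc(.data$delta_l), .data$probe_id)
  res$rank <- seq_len(nrow(res))
  if (k > nrow(res)) {
    warning(sprintf("k = %d exceeds the %d fitted probes; returning all", k, nrow(res)),
            call. = FALSE)
    k <- nrow(res)
  }
  res$selected <- res$rank <= k
  attr(res, "k") <- k
  attr(res, "alpha1") <- alpha1
  attr(res, "skipped") <- dplyr::bind_rows(skipped)
  class(res) <- c("screen_result", class(tibble::tibble()))
  res
}

#' Associate the selected probes of a screen with disease
#'
#' Convenience wrapper: for each selected probe of a [screen_sites()]
#' result, recompute carrier posteriors at the fitted Mendelian
#' parameters and run the Cox likelihood-ratio test, with the Bonferroni
#' threshold `family_wise_alpha / k`.
#'
#' @param screen A `screen_result`.
#' @param mat The M-value matrix used for the screen.
#' @param ped The `ped_tbl`.
#' @param phenotypes Phenotype tibble (see [read_phenotypes()]).
#' @param family_wise_alpha Family-wise error rate. Default 0.05.
#' @param scope Carrier-posterior scope (see [carrier_posteriors()]).
#' @param ... Passed to [cox_lrt()].
#' @return A tibble, one row per tested probe, ordered as the screen.
#' @export
associate_screen <- function(screen, mat, ped, phenotypes,
                             family_wise_alpha = 0.05,
                             scope = c("all_members", "typed_only"), ...) {
  scope <- match.arg(scope)
  sel <- dplyr::filter(screen, .data$selected)
  alpha <- bonferroni_alpha(family_wise_alpha, nrow(sel))
  typed_order <- attr(ped, "typed_order") %||% ped$individual_id[ped$typed]
  vals <- as.matrix(mat[typed_order])
  rownames(vals) <- mat$probe_id
  purrr::map_dfr(seq_len(nrow(sel)), function(j) {
    pid <- sel$probe_id[j]
    a1 <- attr(screen, "alpha1") %||% 0.01
    theta <- theta_vec(a1, sel$mu0[j], sel$mu1[j], sel$sigma0[j], sel$sigma1[j])
    carr <- carrier_posteriors(stats::setNames(vals[pid, ], typed_order), ped,
                               theta, scope = scope, probe_id = pid)
    cox_lrt(carr, phenotypes, alpha = alpha, ...)
  })
}
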