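#' Run the full screening pipeline from input files
#'
#' Orchestrates filter -> screen -> carrier posteriors -> association
#' and writes all outputs plus a JSON run manifest into `out_dir`.
#' Stage errors abort with a stage-named message.
#'
#' @param config A named list (or path to a YAML/JSON file) with
#'   entries: `pedigree` (PED TSV path), `m_values` (matrix TSV),
#'   `values` (`"m"` or `"beta"`), `annotation` (TSV), `phenotypes`
#'   (TSV; required only for the associate stage), `out_dir`,
#'   `top_k` (default 1000), `alpha_carrier` (default 0.01),
#'   `familywise_alpha` (default 0.05), `snp_bp` (default 10),
#'   `drop_sex` (default TRUE), `stages` (subset of
#'   `c("filter","screen","carriers","associate")`), `seed`.
#' @return A list of the stage results (filter report, screen tibble,
#'   carriers tibble, association tibble), invisibly; files on disk are
#'   the primary output.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("[.]ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop_ms("yaml package required to read YAML configs")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  cfg <- utils::modifyList(list(
    values = "m", top_k = 1000L, alpha_carrier = 0.01,
    familywise_alpha = 0.05, snp_bp = 10L, drop_sex = TRUE,
    stages = c("filter", "screen", "carriers", "associate"), seed = 1L
  ), config)
  stage <- function(name, need, code) {
    miss <- need[vapply(need, function(f) is.null(cfg[[f]]), logical(1))]
    if (length(miss)) {
      stop_ms("stage '%s': missing config entr%s: %s", name,
              if (length(miss) > 1) "ies" else "y", paste(miss, collapse = ", "))
    }
    tryCatch(code, error = function(e) {
      stop_ms("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  if (is.null(cfg$out_dir)) stop_ms("config entry 'out_dir' is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outf <- function(f) file.path(cfg$out_dir, f)
  res <- list()

  ped <- stage("input", "pedigree", read_pedigrees(cfg$pedigree))
  mat <- stage("input", "m_values",
               read_methylation(cfg$m_values, values = cfg$values))
  ped <- attach_typed_members(ped, setdiff(names(mat), "probe_id"))

  if ("filter" %in% cfg$stages) {
    ann <- stage("filter", "annotation", read_annotation(cfg$annotation))
    mat <- stage("filter", character(0),
                 filter_probes(mat, ann, snp_bp = cfg$snp_bp,
                               drop_sex = cfg$drop_sex))
    res$filter_report <- filter_report(mat)
    readr::write_tsv(res$filter_report, outf("filter_report.tsv"))
  }
  scr <- NULL
  if ("screen" %in% cfg$stages) {
    scr <- stage("screen", character(0),
                 screen_sites(mat, ped, k = cfg$top_k,
                              alpha1 = cfg$alpha_carrier))
    res$screen <- scr
    readr::write_tsv(tibble::as_tibble(scr), outf("screen.tsv"))
  }
  carr <- NULL
  if ("carriers" %in% cfg$stages) {
    if (is.null(scr)) stop_ms("stage 'carriers': screen stage must run first")
    sel <- dplyr::filter(scr, .data$selected)
    typed_order <- attr(ped, "typed_order")
    vals <- as.matrix(mat[typed_order]); rownames(vals) <- mat$probe_id
    carr <- stage("carriers", character(0),
      purrr::map_dfr(seq_len(nrow(sel)), function(j) {
        theta <- theta_vec(cfg$alpha_carrier, sel$mu0[j], sel$mu1[j],
                           sel$sigma0[j], sel$sigma1[j])
        carrier_posteriors(stats::setNames(vals[sel$probe_id[j], ], typed_order),
                           ped, theta, probe_id = sel$probe_id[j])
      }))
    res$carriers <- carr
    readr::write_tsv(carr, outf("carriers.tsv"))
  }
  if ("associate" %in% cfg$stages) {
    phen <- stage("associate", "phenotypes", read_phenotypes(cfg$phenotypes))
    if (is.null(carr)) stop_ms("stage 'associate': carriers stage must run first")
    alpha <- bonferroni_alpha(cfg$familywise_alpha, attr(scr, "k"))
    res$association <- stage("associate", character(0),
      carr |>
        dplyr::group_by(.data$probe_id) |>
        dplyr::group_map(~ cox_lrt(dplyr::mutate(.x, probe_id = .y$probe_id),
                                   phen, alpha = alpha)) |>
        dplyr::bind_rows())
    readr::write_tsv(res$association, outf("association.tsv"))
  }
  manifest <- list(
    package = "mendelscreen",
    version = as.character(utils::packageVersion("mendelscreen")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed,
    parameters = cfg[c("values", "top_k", "alpha_carrier", "familywise_alpha",
                       "snp_bp", "drop_sex", "stages")]
  )
  jsonlite::write_json(manifest, outf("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(res)
}
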