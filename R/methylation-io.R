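#' Convert methylation beta-values to M-values and back
#'
#' The M-value is the log2 odds of methylation,
#' \eqn{M = \log_2(\beta / (1 - \beta))}: a bijection from (0, 1) onto the
#' real line, which makes the Gaussian component models appropriate.
#' Beta-values at or beyond the boundaries are clipped to
#' `[eps, 1 - eps]` first.
#'
#' @param beta Numeric vector of methylation proportions.
#' @param eps Boundary clip. Default `1e-6`.
#' @return `beta_to_m()`: M-values; `m_to_beta()`: beta-values.
#' @examples
#' beta_to_m(c(0.5, 0.8)) # 0 and 2
#' m_to_beta(beta_to_m(0.37))
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(!is.finite(beta))) stop_ms("beta values must be finite")
  beta <- pmin(pmax(beta, eps), 1 - eps)
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m Numeric vector of M-values.
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m))) stop_ms("M-values must be finite")
  1 / (1 + 2^(-m))
}

#' Read a methylation matrix
#'
#' Expects a TSV whose first column is `probe_id` and whose remaining
#' columns are samples (header row = sample ids). Values may be
#' beta-values or M-values; beta matrices are converted to M on request.
#' Missing values are not permitted: the complete-data EM weights assume
#' a value for every typed individual.
#'
#' @param path Path to the TSV.
#' @param values `"beta"` or `"m"`: the scale of the stored values.
#' @param convert_to_m Convert a beta matrix to M-values on load.
#'   Default `TRUE`.
#' @return A tibble (`probe_id` + one column per sample) with attribute
#'   `scale` (`"beta"` or `"m"`).
#' @export
read_methylation <- function(path, values = c("m", "beta"), convert_to_m = TRUE) {
  values <- match.arg(values)
  mat <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), .default = readr::col_double()
  ))
  new_meth_tbl(mat, scale = values, convert_to_m = convert_to_m)
}

new_meth_tbl <- function(mat, scale = c("m", "beta"), convert_to_m = FALSE) {
  scale <- match.arg(scale)
  mat <- tibble::as_tibble(mat)
  if (names(mat)[1] != "probe_id") stop_ms("first column must be probe_id")
  vals <- as.matrix(mat[-1])
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop_ms("methylation matrix contains missing or non-finite values; imputation is not supported")
  }
  if (scale == "beta" && (any(vals <= 0) || any(vals >= 1))) {
    vals <- pmin(pmax(vals, 1e-6), 1 - 1e-6)
    mat[-1] <- as.data.frame(vals)
  }
  if (scale == "beta" && convert_to_m) {
    mat[-1] <- as.data.frame(beta_to_m(vals))
    scale <- "m"
  }
  attr(mat, "scale") <- scale
  mat
}

#' Write a methylation matrix to TSV
#'
#' @param mat Methylation tibble (`probe_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(mat, path) {
  readr::write_tsv(mat, path)
  invisible(path)
}

#' Read a probe annotation table
#'
#' TSV with header `probe_id`, `chr`, `pos` (1-based), `snp_distance`
#' (base pairs to the nearest known SNP; empty/NA = no known SNP nearby).
#'
#' @param path Path to the TSV.
#' @return A tibble with those columns.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    chr = readr::col_character(),
    pos = readr::col_integer(),
    snp_distance = readr::col_integer()
  ))
  if (any(ann$pos <= 0, na.rm = TRUE)) stop_ms("positions must be >= 1")
  chr <- sub("^chr", "", ann$chr)
  ok <- chr %in% c(as.character(1:22), "X", "Y")
  if (!all(ok)) {
    stop_ms("unrecognised chromosome(s): %s", paste(unique(ann$chr[!ok]), collapse = ", "))
  }
  ann$chr <- chr
  ann
}

#' Filter probes before screening
#'
#' Applies, in order, the pre-screening exclusions: probes within
#' `snp_bp` base pairs of a known SNP (inclusive: `snp_distance <=
#' snp_bp`), probes on the sex chromosomes, and probes failing detection
#' per `detection_policy`. Detection failure follows the
#' exceeds-threshold convention: a sample fails when its detection
#' p-value is greater than `detection_threshold`.
#'
#' @param mat Methylation tibble (`probe_id` + sample columns).
#' @param annotation Tibble with `probe_id`, `chr`, `snp_distance`
#'   (see [read_annotation()]); must cover every matrix probe.
#' @param snp_bp Exclusion radius around known SNPs in base pairs,
#'   inclusive (default 10: probes with `snp_distance <= 10` are
#'   dropped). `NULL` disables the SNP filter.
#' @param drop_sex Drop chromosomes X and Y. Default `TRUE`.
#' @param detection Optional detection p-value tibble shaped like `mat`.
#' @param detection_threshold Detection p-value threshold. Default 0.05.
#' @param detection_policy How per-sample failures aggregate to a probe:
#'   `"any"` (default; any failing sample drops the probe), `"mean"`
#'   (mean p exceeds threshold), or `"fraction"` (more than
#'   `detection_fraction` of samples fail).
#' @param detection_fraction Fraction for `detection_policy = "fraction"`.
#' @return The filtered tibble, probe order preserved, with attribute
#'   `filter_report` (see [filter_report()]).
#' @export
filter_probes <- function(mat, annotation,
                          snp_bp = 10L, drop_sex = TRUE,
                          detection = NULL, detection_threshold = 0.05,
                          detection_policy = c("any", "mean", "fraction"),
                          detection_fraction = 0.1) {
  detection_policy <- match.arg(detection_policy)
  missing_ann <- setdiff(mat$probe_id, annotation$probe_id)
  if (length(missing_ann)) {
    stop_ms("probe(s) without annotation: %s",
            paste(utils::head(missing_ann, 10L), collapse = ", "))
  }
  ann <- annotation[match(mat$probe_id, annotation$probe_id), ]
  n_input <- nrow(mat)

  drop_snp <- if (!is.null(snp_bp)) {
    !is.na(ann$snp_distance) & ann$snp_distance <= snp_bp
  } else rep(FALSE, n_input)
  drop_xy <- !drop_snp & drop_sex & ann$chr %in% c("X", "Y")

  drop_det <- rep(FALSE, n_input)
  if (!is.null(detection)) {
    det <- detection[match(mat$probe_id, detection$probe_id), ]
    dvals <- as.matrix(det[-1])
    fail <- dvals > detection_threshold
    probe_fail <- switch(detection_policy,
      any = rowSums(fail) > 0L,
      mean = rowMeans(dvals) > detection_threshold,
      fraction = rowMeans(fail) > detection_fraction
    )
    drop_det <- !drop_snp & !drop_xy & probe_fail
  }

  keep <- !(drop_snp | drop_xy | drop_det)
  out <- mat[keep, ]
  attr(out, "scale") <- attr(mat, "scale")
  attr(out, "filter_report") <- tibble::tibble(
    reason = c("input", "snp_proximity", "sex_chromosome", "detection", "retained"),
    n = c(n_input, sum(drop_snp), sum(drop_xy), sum(drop_det), sum(keep))
  )
  out
}

#' Retrieve the filter report attached by [filter_probes()]
#'
#' @param mat A filtered methylation tibble.
#' @return Tibble of removal reasons and counts.
#' @export
filter_report <- function(mat) {
  rep <- attr(mat, "filter_report")
  if (is.null(rep)) stop_ms("no filter report attached; run filter_probes() first")
  rep
}
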