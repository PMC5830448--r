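#' Read multi-generational pedigrees from a PED-style file
#'
#' Parses a headerless, whitespace- or tab-delimited pedigree file with
#' columns `family_id`, `individual_id`, `father_id`, `mother_id`, `sex`
#' (PED/FAM convention: `0` means a missing parent; sex is `1` = male,
#' `2` = female, `0` = unknown). Every row is one individual; parents must
#' be either both given or both missing, every stated parent must itself be
#' a row of the same family, and the parent graph must be acyclic.
#' Individuals with no parents are founders (this includes marry-ins).
#'
#' @param path Path to the pedigree file.
#' @return A tibble of class `ped_tbl` with one row per individual and
#'   columns `family_id`, `individual_id`, `father_id`, `mother_id`
#'   (`NA` when missing), `sex` (`"female"`, `"male"`, `"unknown"`),
#'   `founder` and `typed` (all `FALSE` until [attach_typed_members()] is
#'   called). Row order is input order.
#' @seealso [attach_typed_members()], [write_pedigrees()]
#' @export
read_pedigrees <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("family_id", "individual_id",
                                         "father_id", "mother_id", "sex"))
  new_ped_tbl(tibble::as_tibble(raw))
}

#' Build a validated pedigree table from a data frame
#'
#' @param df Data frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`. Parent codes may use `"0"`/`""` or
#'   `NA` for missing; sex may be coded `1`/`2`/`0` or
#'   `"male"`/`"female"`/`"unknown"`.
#' @return A validated `ped_tbl` tibble (see [read_pedigrees()]).
#' @export
new_ped_tbl <- function(df) {
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  if (!all(need %in% names(df))) {
    stop_ms("pedigree table needs columns: %s", paste(need, collapse = ", "))
  }
  ped <- tibble::as_tibble(df)[need]
  ped <- dplyr::mutate(ped, dplyr::across(dplyr::everything(), as.character))
  miss <- function(v) dplyr::if_else(is.na(v) | v %in% c("0", ""), NA_character_, v)
  ped$father_id <- miss(ped$father_id)
  ped$mother_id <- miss(ped$mother_id)
  sex_map <- c(`1` = "male", `2` = "female", `0` = "unknown",
               male = "male", female = "female", unknown = "unknown")
  if (!all(ped$sex %in% names(sex_map))) {
    stop_ms("unrecognised sex codes: %s",
            paste(unique(ped$sex[!ped$sex %in% names(sex_map)]), collapse = ", "))
  }
  ped$sex <- unname(sex_map[ped$sex])
  if (!"typed" %in% names(df)) ped$typed <- FALSE else ped$typed <- as.logical(df$typed)
  ped$founder <- is.na(ped$father_id) & is.na(ped$mother_id)
  validate_ped(ped)
  class(ped) <- c("ped_tbl", class(tibble::tibble()))
  ped
}

validate_ped <- function(ped) {
  one_parent <- xor(is.na(ped$father_id), is.na(ped$mother_id))
  if (any(one_parent)) {
    stop_ms("individual(s) with exactly one parent given (both or none required): %s",
            paste(ped$individual_id[one_parent], collapse = ", "))
  }
  for (fam in split(ped, ped$family_id)) {
    ids <- fam$individual_id
    if (anyDuplicated(ids)) {
      stop_ms("duplicated individual id(s) in family %s: %s", fam$family_id[1],
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    for (col in c("father_id", "mother_id")) {
      bad <- !is.na(fam[[col]]) & !(fam[[col]] %in% ids)
      if (any(bad)) {
        stop_ms("family %s: %s '%s' of individual '%s' is not a member (row %d)",
                fam$family_id[1], sub("_id", "", col),
                fam[[col]][bad][1], fam$individual_id[bad][1], which(bad)[1])
      }
    }
    check_acyclic(fam)
  }
  invisible(ped)
}

check_acyclic <- function(fam) {
  n <- nrow(fam)
  fa <- match(fam$father_id, fam$individual_id)
  mo <- match(fam$mother_id, fam$individual_id)
  state <- integer(n) # 0 unvisited, 1 in progress, 2 done
  visit <- function(i) {
    if (state[i] == 1L) {
      stop_ms("pedigree cycle detected in family %s at individual '%s'",
              fam$family_id[1], fam$individual_id[i])
    }
    if (state[i] == 2L) return(invisible())
    state[i] <<- 1L
    for (p in c(fa[i], mo[i])) if (!is.na(p)) visit(p)
    state[i] <<- 2L
    invisible()
  }
  for (i in seq_len(n)) visit(i)
  invisible()
}

#' Mark which pedigree members have methylation data
#'
#' Flags the members named in `sample_ids` as typed, in the order of the
#' methylation matrix columns; that order is retained as the
#' `typed_order` attribute and drives the alignment of M-values with
#' individuals everywhere downstream.
#'
#' @param ped A `ped_tbl` from [read_pedigrees()].
#' @param sample_ids Character vector of individual ids with methylation
#'   data, ordered as the methylation matrix columns.
#' @return `ped` with its `typed` column set and attribute `typed_order`.
#' @export
attach_typed_members <- function(ped, sample_ids) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop_ms("duplicated sample ids")
  hit <- match(sample_ids, ped$individual_id)
  if (anyNA(hit)) {
    stop_ms("sample id(s) not found in any pedigree: %s",
            paste(sample_ids[is.na(hit)], collapse = ", "))
  }
  n_fam <- vapply(sample_ids, function(s)
    length(unique(ped$family_id[ped$individual_id == s])), integer(1))
  if (any(n_fam > 1L)) {
    stop_ms("sample id(s) present in more than one family: %s",
            paste(sample_ids[n_fam > 1L], collapse = ", "))
  }
  ped$typed <- ped$individual_id %in% sample_ids
  attr(ped, "typed_order") <- sample_ids
  ped
}

#' Write a pedigree table back to PED-style TSV
#'
#' @param ped A `ped_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigrees <- function(ped, path) {
  sex_code <- c(male = "1", female = "2", unknown = "0")
  out <- data.frame(
    family_id = ped$family_id,
    individual_id = ped$individual_id,
    father_id = dplyr::coalesce(ped$father_id, "0"),
    mother_id = dplyr::coalesce(ped$mother_id, "0"),
    sex = unname(sex_code[ped$sex])
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a phenotype file
#'
#' Expects a TSV with header `individual_id`, `affected` (0/1), `age`
#' (age at diagnosis for affected individuals, age at censoring
#' otherwise, in years), `sex`.
#'
#' @param path Path to the phenotype TSV.
#' @return A tibble with those columns, `affected` logical, `age` numeric.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    affected = readr::col_double(),
    age = readr::col_double(),
    sex = readr::col_character()
  ))
  validate_phenotypes(ph)
}

validate_phenotypes <- function(ph) {
  ph <- tibble::as_tibble(ph)
  ph$affected <- as.logical(ph$affected)
  sex_map <- c(`1` = "male", `2` = "female", `0` = "unknown",
               male = "male", female = "female", unknown = "unknown")
  ph$sex <- unname(sex_map[as.character(ph$sex)])
  if (any(!is.finite(ph$age) | ph$age <= 0)) {
    stop_ms("phenotype ages must be finite and positive")
  }
  ph
}

# --- internal per-family structures -----------------------------------------

# One compact list per family: index-based parent links, topological order,
# children adjacency, typed flags. Used by all segregation computations.
ped_structs <- function(ped) {
  typed_order <- attr(ped, "typed_order") %||% ped$individual_id[ped$typed]
  lapply(split(ped, factor(ped$family_id, unique(ped$family_id))), function(fam) {
    n <- nrow(fam)
    fa <- match(fam$father_id, fam$individual_id)
    mo <- match(fam$mother_id, fam$individual_id)
    founders <- which(is.na(fa) & is.na(mo))
    # topological order: parents before children
    depth <- rep(NA_real_, n)
    get_depth <- function(i) {
      if (!is.na(depth[i])) return(depth[i])
      d <- if (is.na(fa[i])) 0 else 1 + max(get_depth(fa[i]), get_depth(mo[i]))
      depth[i] <<- d
      d
    }
    for (i in seq_len(n)) get_depth(i)
    topo <- order(depth, seq_len(n))
    children <- lapply(seq_len(n), function(i) which(fa == i | mo == i))
    typed <- which(fam$individual_id %in% typed_order)
    typed <- typed[order(match(fam$individual_id[typed], typed_order))]
    list(
      family_id = fam$family_id[1],
      ids = fam$individual_id,
      sex = fam$sex,
      n = n, fa = fa, mo = mo,
      founders = founders,
      children = children,
      topo = topo,
      typed = typed,                       # member indices, typed_order-aligned
      typed_ids = fam$individual_id[typed]
    )
  })
}

# ancestor index set of member i (excluding i)
ancestor_set <- function(st, i) {
  out <- integer(0)
  stack <- c(st$fa[i], st$mo[i])
  stack <- stack[!is.na(stack)]
  while (length(stack)) {
    j <- stack[[1]]; stack <- stack[-1]
    if (!(j %in% out)) {
      out <- c(out, j)
      more <- c(st$fa[j], st$mo[j])
      stack <- c(stack, more[!is.na(more)])
    }
  }
  out
}

# Reject pedigrees where any member's two parents are blood relatives
# (share an ancestor or one descends from the other): under the
# single-founder-origin carrier model such loops could create homozygotes.
check_no_consanguinity <- function(st) {
  for (i in seq_len(st$n)) {
    if (is.na(st$fa[i])) next
    af <- c(st$fa[i], ancestor_set(st, st$fa[i]))
    am <- c(st$mo[i], ancestor_set(st, st$mo[i]))
    if (length(intersect(af, am))) {
      stop_ms("family %s: parents of '%s' are blood relatives; consanguineous pedigrees are not supported",
              st$family_id, st$ids[i])
    }
  }
  invisible(st)
}
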