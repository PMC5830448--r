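# Small pedigree constructors used across the test files.

make_trio <- function(typed = c("F1", "M1", "C1")) {
  ped <- new_ped_tbl(data.frame(
    family_id = "T1",
    individual_id = c("F1", "M1", "C1"),
    father_id = c(NA, NA, "F1"),
    mother_id = c(NA, NA, "M1"),
    sex = c("male", "female", "female")
  ))
  if (length(typed)) ped <- attach_typed_members(ped, typed)
  ped
}

make_singletons <- function(n, prefix = "S") {
  ped <- new_ped_tbl(data.frame(
    family_id = sprintf("%s%03d", prefix, seq_len(n)),
    individual_id = sprintf("%sI%03d", prefix, seq_len(n)),
    father_id = NA, mother_id = NA, sex = "female"
  ))
  attach_typed_members(ped, ped$individual_id)
}

# Random loop-free pedigree of n members built by either adding a child
# to an existing couple or marrying a new founder into the family; typed
# subset of size <= max_typed. Marry-ins are always new founders, so no
# consanguinity can arise.
random_small_ped <- function(n, seed, max_typed = 4L) {
  stopifnot(n >= 2)
  withr::with_seed(seed, {
    ids <- sprintf("P%02d", seq_len(n))
    fa <- rep(NA_character_, n)
    mo <- rep(NA_character_, n)
    sex <- rep(c("male", "female"), length.out = n)
    couples <- list(c(1L, 2L))
    sex[1:2] <- c("male", "female")
    i <- 3L
    while (i <= n) {
      if (stats::runif(1) < 0.6 || i == n) {
        cp <- couples[[sample.int(length(couples), 1L)]]
        fa[i] <- ids[cp[1]]; mo[i] <- ids[cp[2]]
        i <- i + 1L
      } else {
        # new founder marries a random existing member
        partner <- sample.int(i - 1L, 1L)
        sex[i] <- if (sex[partner] == "male") "female" else "male"
        couples[[length(couples) + 1L]] <-
          if (sex[i] == "male") c(i, partner) else c(partner, i)
        i <- i + 1L
      }
    }
    ped <- new_ped_tbl(data.frame(
      family_id = "R1", individual_id = ids,
      father_id = fa, mother_id = mo, sex = sex
    ))
    typed <- sample(ids, min(max_typed, n))
    attach_typed_members(ped, typed)
  })
}

random_assignment <- function(ped, size, seed) {
  withr::with_seed(seed, {
    ids <- sample(ped$individual_id, size)
    stats::setNames(sample(0:1, size, replace = TRUE), ids)
  })
}
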