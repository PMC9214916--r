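#' Curation filter configuration
#'
#' @param long_bond_threshold Bonds longer than this (Angstrom) flag a
#'   molecule as strained (default 1.6).
#' @param large_angle_threshold Four-coordinate carbons with any bond angle
#'   above this (degrees) are flagged as distorted sp3 centres
#'   (default 160).
#' @return A list of thresholds.
#' @export
filter_config <- function(long_bond_threshold = 1.6,
                          large_angle_threshold = 160) {
  list(long_bond_threshold = long_bond_threshold,
       large_angle_threshold = large_angle_threshold)
}

#' Apply the database-cleaning filters
#'
#' Molecules are removed, first matching rule winning as the recorded
#' reason, in this order:
#' 1. `imaginary_freq` — lowest vibrational frequency below zero (a saddle
#'    point, not a minimum); skipped with a warning when the frequency is
#'    missing;
#' 2. `out_of_alphabet` — any atom outside C/H/N/O;
#' 3. `long_bond` — any bond longer than the threshold;
#' 4. `tetravalent_N` — any nitrogen with four bonded neighbours
#'    (zwitterions/charged N);
#' 5. `carbon_octet` — any three-coordinate carbon whose neighbours are all
#'    hydrogens of connectivity 1, oxygens of connectivity 2 or nitrogens
#'    of connectivity 3 (an incomplete carbon octet);
#' 6. `large_angle_C4` — any four-coordinate carbon with a bond angle above
#'    the threshold.
#'
#' Chemistry never raises an exception here; the outcome is a report.
#'
#' @param molecules List of bonded [molecule()] objects.
#' @param config A [filter_config()].
#' @return A `filter_report`: list with `kept` (character ids), `removed`
#'   (tibble id/reason), and `table()`/`print()` support.
#' @export
#' @examples
#' rep <- apply_filters(c(make_filter_probes(), list(perceive_bonds(make_ethanol()))))
#' rep$removed
apply_filters <- function(molecules, config = filter_config()) {
  stopifnot(is.list(molecules))
  reasons <- unname(vapply(molecules, filter_reason, character(1),
                           config = config))
  ids <- unname(vapply(molecules, function(m) m$id, character(1)))
  new_filter_report(
    kept = ids[reasons == ""],
    removed = tibble::tibble(id = ids[reasons != ""],
                             reason = reasons[reasons != ""])
  )
}

filter_reason <- function(m, config) {
  if (!is.na(m$lowest_frequency)) {
    if (m$lowest_frequency < 0) return("imaginary_freq")
  } else {
    warning("molecule ", m$id, ": lowest_frequency missing; ",
            "imaginary-frequency filter skipped", call. = FALSE)
  }
  if (out_of_alphabet(m)) return("out_of_alphabet")
  if (nrow(m$bonds) && any(bond_lengths(m)$length > config$long_bond_threshold)) {
    return("long_bond")
  }
  el <- m$atoms$element
  deg <- atom_degrees(m)
  if (any(el == "N" & deg >= 4L)) return("tetravalent_N")
  adj <- adjacency(m)
  for (c_idx in which(el == "C" & deg == 3L)) {
    nb <- adj[[c_idx]]
    ok_nb <- (el[nb] == "H" & deg[nb] == 1L) |
      (el[nb] == "O" & deg[nb] == 2L) |
      (el[nb] == "N" & deg[nb] == 3L)
    if (all(ok_nb)) return("carbon_octet")
  }
  c4 <- which(el == "C" & deg == 4L)
  if (length(c4)) {
    ang <- enumerate_angle_obs(m, "element")
    central <- vapply(ang$atom_indices, `[[`, 1L, 2L)
    if (any(central %in% c4 & ang$value > config$large_angle_threshold)) {
      return("large_angle_C4")
    }
  }
  ""
}

new_filter_report <- function(kept, removed) {
  structure(list(kept = kept, removed = removed), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> kept %d, removed %d\n",
              length(x$kept), nrow(x$removed)))
  if (nrow(x$removed)) print(table(x$removed$reason))
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(id = x$kept, kept = TRUE, reason = NA_character_),
    tibble::tibble(id = x$removed$id, kept = FALSE, reason = x$removed$reason)
  )
}

#' Keep only the molecules a filter report retained
#' @param molecules List of [molecule()] objects.
#' @param report A `filter_report`.
#' @return The kept subset, in input order.
#' @export
kept_molecules <- function(molecules, report) {
  ids <- vapply(molecules, function(m) m$id, character(1))
  molecules[ids %in% report$kept]
}

#' Remove free-energy duplicates
#'
#' Among molecules with bitwise-equal free energies (up to `tolerance`,
#' default exact), only the one with the lexicographically smallest id is
#' kept; the others are removed with reason `duplicate_free_energy`. Used
#' when training free-energy models, where equal free energies indicate
#' redundant records.
#'
#' @param molecules List of [molecule()] objects, all carrying
#'   `free_energy`.
#' @param tolerance Absolute tolerance for equality; 0 means exact.
#' @return A `filter_report`.
#' @export
dedupe_free_energy <- function(molecules, tolerance = 0) {
  fe <- vapply(molecules, function(m) m$free_energy, numeric(1))
  if (any(is.na(fe))) stop("free_energy missing on some molecules", call. = FALSE)
  ids <- vapply(molecules, function(m) m$id, character(1))
  grp <- if (tolerance == 0) {
    match(fe, fe)
  } else {
    # cluster values closer than tolerance to the first seen representative
    rep_idx <- integer(length(fe))
    for (k in seq_along(fe)) {
      prev <- which(abs(fe[seq_len(k - 1)] - fe[k]) <= tolerance)
      rep_idx[k] <- if (length(prev)) rep_idx[prev[1]] else k
    }
    rep_idx
  }
  keep <- unlist(lapply(split(seq_along(ids), grp), function(ix) {
    ix[order(ids[ix])][1]
  }), use.names = FALSE)
  removed_ix <- setdiff(seq_along(ids), keep)
  new_filter_report(
    kept = ids[sort(keep)],
    removed = tibble::tibble(id = ids[removed_ix],
                             reason = rep("duplicate_free_energy",
                                          length(removed_ix)))
  )
}

#' Stoichiometry-grouped train/test split
#'
#' Molecules are grouped by molecular formula ([stoichiometry_key()]) and
#' split group by group: a group of size one goes to neither set (its
#' energy scale has no counterpart to learn from); a group of size two
#' sends one random molecule to each set; a group of size three or more is
#' split at the test fraction, always leaving at least one molecule on
#' each side (test count = `ceiling(fraction * n)`, capped at `n - 1`).
#' Deterministic given `seed`.
#'
#' @param molecules List of [molecule()] objects.
#' @param test_fraction Test share for groups of size >= 3 (default 0.33).
#' @param seed Integer seed.
#' @return A `split_assignment`: list with character id sets `train`,
#'   `test`, `unassigned` and the seed.
#' @export
split_by_stoichiometry <- function(molecules, test_fraction = 0.33, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  ids <- unname(vapply(molecules, function(m) m$id, character(1)))
  keys <- vapply(molecules, stoichiometry_key, character(1))
  train <- character(); test <- character(); unassigned <- character()
  with_preserved_seed({
    set.seed(as.integer(seed))
    for (key in sort(unique(keys))) {
      grp <- ids[keys == key]
      n <- length(grp)
      if (n == 1L) {
        unassigned <- c(unassigned, grp)
      } else if (n == 2L) {
        pick <- sample(2L, 1L)
        train <- c(train, grp[pick])
        test <- c(test, grp[-pick])
      } else {
        n_test <- min(n - 1L, max(1L, ceiling(test_fraction * n)))
        t_ix <- sample(n, n_test)
        test <- c(test, grp[t_ix])
        train <- c(train, grp[-t_ix])
      }
    }
  })
  structure(
    list(train = train, test = test, unassigned = unassigned,
         seed = as.integer(seed)),
    class = "split_assignment"
  )
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> train %d / test %d / unassigned %d (seed %d)\n",
              length(x$train), length(x$test), length(x$unassigned), x$seed))
  invisible(x)
}

#' @export
tidy.split_assignment <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(id = x$train, set = "train"),
    tibble::tibble(id = x$test, set = "test"),
    tibble::tibble(id = x$unassigned, set = "unassigned")
  )
}

# run code under a local RNG state, restoring the caller's state after
with_preserved_seed <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}
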