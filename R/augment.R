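#' Create one distorted replica of a molecule
#'
#' Every atom is independently translated by exactly `delta` Angstrom
#' along one coordinate axis chosen uniformly from \{+-x, +-y, +-z\}.
#' Bonds and target energies are copied unchanged: replicas sample the
#' neighbourhood of the potential-energy-surface minimum while keeping the
#' minimum's energies as the regression target, which is what lets the
#' trained models accept off-minimum (e.g. force-field) geometries.
#'
#' @param m A [molecule()].
#' @param delta Displacement magnitude, Angstrom (> 0; 0 allowed for
#'   testing and leaves coordinates untouched).
#' @param seed Integer seed; the replica is deterministic given it.
#' @param tag Suffix appended to the id (default built from `delta` and
#'   `seed`).
#' @return The distorted [molecule()].
#' @export
make_distorted_replica <- function(m, delta, seed = 1L,
                                   tag = sprintf("_d%g_s%d", delta, seed)) {
  stopifnot(delta >= 0)
  n <- n_atoms(m)
  with_preserved_seed({
    set.seed(as.integer(seed))
    axis <- sample(3L, n, replace = TRUE)
    sign <- sample(c(-1, 1), n, replace = TRUE)
  })
  xyz <- coords(m)
  xyz[cbind(seq_len(n), axis)] <- xyz[cbind(seq_len(n), axis)] + sign * delta
  m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
  m$id <- paste0(m$id, tag)
  m
}

#' Augment a training set with distorted replicas
#'
#' For every delta in `deltas` and every replicate index, each molecule
#' gains one distorted copy (see [make_distorted_replica()]); the output is
#' the originals followed by all replicas. Replica targets equal the
#' originals' targets. Deterministic under `seed`.
#'
#' @param molecules List of curated [molecule()]s.
#' @param deltas Numeric vector of displacement magnitudes, Angstrom
#'   (default 0.01, the published working value; `c(0.01, 0.05)` is the
#'   published two-replicate compromise).
#' @param replicates_per_delta Replicas per molecule per delta (default 1).
#' @param seed Integer seed.
#' @return List of molecules of length
#'   `length(molecules) * (1 + length(deltas) * replicates_per_delta)`.
#' @export
augment_training_set <- function(molecules, deltas = 0.01,
                                 replicates_per_delta = 1L, seed = 1L) {
  stopifnot(all(deltas > 0), replicates_per_delta >= 1L)
  out <- molecules
  counter <- 0L
  for (delta in deltas) {
    for (r in seq_len(replicates_per_delta)) {
      counter <- counter + 1L
      out <- c(out, lapply(seq_along(molecules), function(k) {
        make_distorted_replica(
          molecules[[k]], delta,
          seed = as.integer((seed * 1000L + counter * 100L + k) %% .Machine$integer.max),
          tag = sprintf("_d%g_r%d", delta, r)
        )
      }))
    }
  }
  out
}

#' Distortion constant of a representation under geometric distortion
#'
#' Quantifies how far feature vectors move when geometries are distorted:
#' the mean over molecules of the L1 distance between the original and
#' distorted feature vectors,
#' `C = (1/N) * sum_j sum_i |X_ij - D_ij|`.
#' Atom-count slots are excluded by default because atom counts are
#' invariant under distortion (including them changes nothing).
#'
#' @param original,distorted Encoded feature tibbles from
#'   [encode_molecules()], matched by `molecule_id` order and of equal
#'   width (the distorted ids may carry replica tags; only order is used).
#' @param include_atom_slots Include the `atom_*` columns (default FALSE).
#' @return A single non-negative number.
#' @export
#' @examples
#' X <- tibble::tibble(molecule_id = c("a", "b"), f1 = c(1, 2), f2 = c(0, 3))
#' D <- tibble::tibble(molecule_id = c("a", "b"), f1 = c(2, 2), f2 = c(0, 1))
#' distortion_constant(X, D) # (1 + 2) / 2 = 1.5
distortion_constant <- function(original, distorted, include_atom_slots = FALSE) {
  ox <- feature_matrix(original)
  dx <- feature_matrix(distorted)
  if (!all(dim(ox) == dim(dx))) {
    stop("original and distorted feature matrices differ in shape", call. = FALSE)
  }
  if (!identical(colnames(ox), colnames(dx))) {
    stop("original and distorted feature columns differ", call. = FALSE)
  }
  keep <- if (include_atom_slots) rep(TRUE, ncol(ox)) else
    !startsWith(colnames(ox), "atom_")
  mean(rowSums(abs(ox[, keep, drop = FALSE] - dx[, keep, drop = FALSE])))
}

# strip the id column of an encoded tibble -> plain numeric matrix
feature_matrix <- function(encoded) {
  df <- as.data.frame(encoded)
  if ("molecule_id" %in% names(df)) {
    rownames(df) <- NULL
    ids <- df$molecule_id
    df$molecule_id <- NULL
    m <- as.matrix(df)
    rownames(m) <- ids
    m
  } else {
    as.matrix(df)
  }
}
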