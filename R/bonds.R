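# single-bond covalent radii, Angstrom
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66)

#' Perceive covalent bonds from 3D geometry
#'
#' Two atoms are bonded when their distance is at most
#' `scale * (r_cov(i) + r_cov(j))`, using single-bond covalent radii
#' H 0.31, C 0.76, N 0.71, O 0.66 Angstrom. The rule is deterministic,
#' idempotent, and invariant under rigid motion; for ordinary organic
#' geometries it reproduces standard connectivity.
#'
#' @param m A [molecule()].
#' @param scale Unitless tolerance on the radius sum (default 1.15).
#' @return The molecule with its bond list replaced by the perceived bonds.
#' @export
#' @examples
#' eth <- perceive_bonds(make_ethanol())
#' nrow(eth$bonds) # 8
perceive_bonds <- function(m, scale = 1.15) {
  stopifnot(scale > 0)
  n <- n_atoms(m)
  radii <- COVALENT_RADII[m$atoms$element]
  radii[is.na(radii)] <- 0.75 # neutral default for out-of-alphabet elements
  xyz <- coords(m)
  if (n >= 2) {
    d <- as.matrix(stats::dist(xyz))
    if (any(d[upper.tri(d)] < 0.3)) {
      stop("degenerate geometry: atoms closer than 0.3 Angstrom in ", m$id,
           call. = FALSE)
    }
    cutoff <- scale * outer(radii, radii, "+")
    hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    m$bonds <- normalize_bonds(
      tibble::tibble(i = hit[, 1], j = hit[, 2]), n
    )
  } else {
    m$bonds <- normalize_bonds(NULL, n)
  }
  m
}

#' Bond lengths of a molecule
#' @param m A [molecule()] with bonds.
#' @return A tibble with columns `i`, `j`, `length` (Angstrom).
#' @export
bond_lengths <- function(m) {
  xyz <- coords(m)
  d <- sqrt(rowSums((xyz[m$bonds$i, , drop = FALSE] -
                       xyz[m$bonds$j, , drop = FALSE])^2))
  tibble::tibble(i = m$bonds$i, j = m$bonds$j, length = d)
}
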