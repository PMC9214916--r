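#' Construct a molecule object
#'
#' A molecule is the package's central container: an ordered atom table with
#' 3D coordinates in Angstrom, an undirected bond list, and optional scalar
#' targets (energies in kcal/mol, lowest vibrational frequency in cm^-1).
#' Elements outside the C/H/N/O alphabet are representable so that curation
#' can reject them; `out_of_alphabet()` flags such molecules.
#'
#' @param id Molecule identifier (single string).
#' @param atoms A data frame with columns `element`, `x`, `y`, `z`
#'   (coordinates in Angstrom).
#' @param bonds A data frame with integer columns `i`, `j` (1-based atom
#'   indices), or `NULL` for no bonds. Stored with `i < j`, deduplicated.
#' @param electronic_energy,free_energy Optional scalar targets, kcal/mol
#'   (free energy at 298.15 K).
#' @param lowest_frequency Optional lowest vibrational frequency, cm^-1.
#' @param provenance Free-text metadata.
#' @return An object of class `molecule`.
#' @export
#' @examples
#' m <- molecule("h2", tibble::tibble(
#'   element = c("H", "H"),
#'   x = c(0, 0.74), y = 0, z = 0
#' ))
#' n_atoms(m)
molecule <- function(id, atoms, bonds = NULL,
                     electronic_energy = NA_real_, free_energy = NA_real_,
                     lowest_frequency = NA_real_, provenance = "") {
  stopifnot(is.character(id), length(id) == 1L)
  atoms <- tibble::as_tibble(atoms)
  req <- c("element", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    stop("`atoms` must have columns element, x, y, z", call. = FALSE)
  }
  atoms <- atoms[req]
  atoms$element <- as.character(atoms$element)
  if (nrow(atoms) < 1L) stop("molecule must have at least one atom", call. = FALSE)
  coords <- as.matrix(atoms[c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("all coordinates must be finite", call. = FALSE)
  bonds <- normalize_bonds(bonds, nrow(atoms))
  structure(
    list(
      id = id, atoms = atoms, bonds = bonds,
      electronic_energy = as.numeric(electronic_energy),
      free_energy = as.numeric(free_energy),
      lowest_frequency = as.numeric(lowest_frequency),
      provenance = provenance
    ),
    class = "molecule"
  )
}

normalize_bonds <- function(bonds, n_atoms) {
  if (is.null(bonds) || (is.data.frame(bonds) && nrow(bonds) == 0L)) {
    return(tibble::tibble(i = integer(), j = integer()))
  }
  bonds <- tibble::as_tibble(bonds)[c("i", "j")]
  i <- as.integer(pmin(bonds$i, bonds$j))
  j <- as.integer(pmax(bonds$i, bonds$j))
  if (any(i == j)) stop("self-bonds are not allowed", call. = FALSE)
  if (any(i < 1L) || any(j > n_atoms)) {
    stop("bond indices out of range", call. = FALSE)
  }
  out <- dplyr::distinct(tibble::tibble(i = i, j = j))
  if (nrow(out) < length(i)) stop("duplicate bonds are not allowed", call. = FALSE)
  dplyr::arrange(out, .data$i, .data$j)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf(
    "<molecule> %s: %d atoms (%s), %d bonds\n",
    x$id, n_atoms(x), stoichiometry_key(x), nrow(x$bonds)
  ))
  if (!is.na(x$electronic_energy)) {
    cat(sprintf("  electronic energy: %.4f kcal/mol\n", x$electronic_energy))
  }
  if (!is.na(x$free_energy)) {
    cat(sprintf("  free energy (298.15 K): %.4f kcal/mol\n", x$free_energy))
  }
  invisible(x)
}

#' @rdname molecule
#' @param m A `molecule`.
#' @export
n_atoms <- function(m) nrow(m$atoms)

#' Coordinates of a molecule as a matrix
#' @param m A `molecule`.
#' @return Numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @export
coords <- function(m) {
  out <- as.matrix(m$atoms[c("x", "y", "z")])
  rownames(out) <- NULL
  out
}

#' Does a molecule contain atoms outside the C/H/N/O alphabet?
#' @param m A `molecule`.
#' @return Logical scalar.
#' @export
out_of_alphabet <- function(m) !all(m$atoms$element %in% c("C", "H", "N", "O"))

#' Per-element atom counts
#' @param m A `molecule`.
#' @return Named integer vector over the elements present.
#' @export
element_counts <- function(m) {
  tab <- table(m$atoms$element)
  stats::setNames(as.integer(tab), names(tab))
}

# Euclidean distance between atoms a and b (1-based indices)
atom_distance <- function(m, a, b) {
  d <- coords(m)[a, ] - coords(m)[b, ]
  sqrt(sum(d * d))
}

# adjacency list: integer vector of neighbours per atom
adjacency <- function(m) {
  adj <- vector("list", n_atoms(m))
  for (k in seq_len(nrow(m$bonds))) {
    i <- m$bonds$i[k]; j <- m$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) if (is.null(v)) integer() else sort(v))
}

# connectivity (degree) per atom
atom_degrees <- function(m) {
  deg <- integer(n_atoms(m))
  if (nrow(m$bonds)) {
    tab <- table(factor(c(m$bonds$i, m$bonds$j), levels = seq_len(n_atoms(m))))
    deg <- as.integer(tab)
  }
  deg
}

#' Apply a rigid (or improper) transformation to a molecule's coordinates
#'
#' Utility used mostly for invariance testing: rotates by `rotation`
#' (3x3 matrix, may include reflection) and then translates.
#'
#' @param m A `molecule`.
#' @param rotation 3x3 matrix.
#' @param translation Length-3 numeric vector, Angstrom.
#' @return A `molecule` with transformed coordinates.
#' @export
transform_molecule <- function(m, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords(m) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
  m
}

#' Permute the atom order of a molecule
#'
#' Bonds are remapped through the permutation, so the molecular graph is
#' unchanged.
#'
#' @param m A `molecule`.
#' @param perm Integer permutation of `seq_len(n_atoms(m))`; atom `perm[k]`
#'   of the input becomes atom `k` of the output.
#' @return A `molecule`.
#' @export
permute_atoms <- function(m, perm) {
  stopifnot(sort(perm) == seq_len(n_atoms(m)))
  inv <- order(perm)
  bonds <- m$bonds
  if (nrow(bonds)) {
    bonds <- tibble::tibble(i = inv[bonds$i], j = inv[bonds$j])
  }
  molecule(m$id, m$atoms[perm, ], bonds,
           electronic_energy = m$electronic_energy,
           free_energy = m$free_energy,
           lowest_frequency = m$lowest_frequency,
           provenance = m$provenance)
}

#' Stoichiometry key of a molecule
#'
#' Canonical molecular-formula key used to group molecules for the
#' train/test split: `"C{a}H{b}N{c}O{d}"` with zero-count elements omitted.
#' Elements outside the alphabet are appended alphabetically so the key is
#' still total.
#'
#' @param m A `molecule`.
#' @return A single string, e.g. `"C2H6O1"` for ethanol.
#' @export
#' @examples
#' stoichiometry_key(make_ethanol())
stoichiometry_key <- function(m) {
  cnt <- element_counts(m)
  order_known <- c("C", "H", "N", "O")
  extra <- sort(setdiff(names(cnt), order_known))
  parts <- character()
  for (el in c(order_known, extra)) {
    if (!is.na(cnt[el]) && cnt[el] > 0) parts <- c(parts, sprintf("%s%d", el, cnt[el]))
  }
  paste(parts, collapse = "")
}

#' Summarise a list of molecules as a tibble
#'
#' @param molecules List of `molecule` objects.
#' @return A tibble with one row per molecule: id, stoichiometry, atom and
#'   bond counts, targets, out-of-alphabet flag.
#' @export
molecules_table <- function(molecules) {
  purrr::map_dfr(molecules, function(m) {
    tibble::tibble(
      id = m$id,
      stoichiometry = stoichiometry_key(m),
      n_atoms = n_atoms(m),
      n_bonds = nrow(m$bonds),
      electronic_energy = m$electronic_energy,
      free_energy = m$free_energy,
      lowest_frequency = m$lowest_frequency,
      out_of_alphabet = out_of_alphabet(m)
    )
  })
}
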