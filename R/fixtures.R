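# ---- idealized geometry builders -------------------------------------------
# All fixture molecules are hand-coded internal coordinates converted to
# Cartesians, so the test surface needs no external structure generator.

# rows: list(element, a, b, c, r, theta, phi) -- classic Z-matrix semantics.
# atom 1 at origin; atom 2 along +x; atom 3 in the xy-plane.
zmat_to_molecule <- function(id, rows) {
  n <- length(rows)
  xyz <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    z <- rows[[k]]
    if (k == 1) next
    if (k == 2) { xyz[2, ] <- c(z$r, 0, 0); next }
    A <- xyz[z$a, ]; B <- xyz[z$b, ]
    theta <- z$theta * pi / 180
    if (k == 3 || is.null(z$c)) {
      # place in the plane spanned by A->B and a fixed out-of-line axis
      ab <- B - A; ab <- ab / sqrt(sum(ab^2))
      ref <- if (abs(ab[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
      perp <- pracma_cross(ab, ref); perp <- perp / sqrt(sum(perp^2))
      inpl <- pracma_cross(perp, ab)
      xyz[k, ] <- A + z$r * (cos(theta) * ab + sin(theta) * inpl)
    } else {
      C <- xyz[z$c, ]
      phi <- z$phi * pi / 180
      bc <- A - B; bcn <- bc / sqrt(sum(bc^2))
      ab <- B - C
      nrm <- pracma_cross(ab, bcn); nrm <- nrm / sqrt(sum(nrm^2))
      m2 <- pracma_cross(nrm, bcn)
      d2 <- c(-z$r * cos(theta), z$r * sin(theta) * cos(phi),
              z$r * sin(theta) * sin(phi))
      xyz[k, ] <- A + d2[1] * bcn + d2[2] * m2 + d2[3] * nrm
    }
  }
  molecule(id, tibble::tibble(
    element = vapply(rows, `[[`, "", "element"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ), provenance = "fixture")
}

za <- function(element, a = NULL, b = NULL, c = NULL, r = NULL,
               theta = NULL, phi = NULL) {
  list(element = element, a = a, b = b, c = c, r = r, theta = theta, phi = phi)
}

TET <- 109.471 # tetrahedral angle, degrees

#' Idealized fixture molecules
#'
#' Hand-built geometries used throughout the tests and the worked
#' examples: staggered ethanol (C-C 1.52, C-O 1.43, O-H 0.96, C-H 1.09
#' Angstrom, tetrahedral angles; 9 atoms and, once perceived, 8 bonds),
#' plus water, ammonia, methane, ethane, methanol, methylamine and
#' formaldehyde. Bonds are not perceived; call [perceive_bonds()].
#'
#' @return A [molecule()].
#' @export
#' @examples
#' eth <- perceive_bonds(make_ethanol())
#' nrow(eth$bonds) # 8
make_ethanol <- function() {
  zmat_to_molecule("ethanol", list(
    za("C"),
    za("C", a = 1, r = 1.52),
    za("O", a = 2, b = 1, r = 1.43, theta = TET),
    za("H", a = 3, b = 2, c = 1, r = 0.96, theta = TET, phi = 180),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = TET, phi = 180),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = TET, phi = 60),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = TET, phi = -60),
    za("H", a = 2, b = 1, c = 5, r = 1.09, theta = TET, phi = 60),
    za("H", a = 2, b = 1, c = 5, r = 1.09, theta = TET, phi = -60)
  ))
}

#' @rdname make_ethanol
#' @export
make_water <- function() {
  zmat_to_molecule("water", list(
    za("O"), za("H", a = 1, r = 0.96),
    za("H", a = 1, b = 2, r = 0.96, theta = 104.5)
  ))
}

#' @rdname make_ethanol
#' @export
make_ammonia <- function() {
  zmat_to_molecule("ammonia", list(
    za("N"), za("H", a = 1, r = 1.01),
    za("H", a = 1, b = 2, r = 1.01, theta = 106.7),
    za("H", a = 1, b = 2, c = 3, r = 1.01, theta = 106.7, phi = 112)
  ))
}

#' @rdname make_ethanol
#' @export
make_methane <- function() {
  zmat_to_molecule("methane", list(
    za("C"), za("H", a = 1, r = 1.09),
    za("H", a = 1, b = 2, r = 1.09, theta = TET),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = TET, phi = 120),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = TET, phi = -120)
  ))
}

#' @rdname make_ethanol
#' @export
make_ethane <- function() {
  zmat_to_molecule("ethane", list(
    za("C"),
    za("C", a = 1, r = 1.54),
    za("H", a = 1, b = 2, r = 1.09, theta = TET),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = TET, phi = 120),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = TET, phi = -120),
    za("H", a = 2, b = 1, c = 3, r = 1.09, theta = TET, phi = 60),
    za("H", a = 2, b = 1, c = 3, r = 1.09, theta = TET, phi = 180),
    za("H", a = 2, b = 1, c = 3, r = 1.09, theta = TET, phi = -60)
  ))
}

#' @rdname make_ethanol
#' @export
make_methanol <- function() {
  zmat_to_molecule("methanol", list(
    za("C"),
    za("O", a = 1, r = 1.43),
    za("H", a = 2, b = 1, r = 0.96, theta = 108.5),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = TET, phi = 180),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = TET, phi = 60),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = TET, phi = -60)
  ))
}

#' @rdname make_ethanol
#' @export
make_methylamine <- function() {
  zmat_to_molecule("methylamine", list(
    za("C"),
    za("N", a = 1, r = 1.47),
    za("H", a = 2, b = 1, r = 1.01, theta = 110, phi = NULL),
    za("H", a = 2, b = 1, c = 3, r = 1.01, theta = 110, phi = 120),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = TET, phi = 180),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = TET, phi = 60),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = TET, phi = -60)
  ))
}

#' @rdname make_ethanol
#' @export
make_formaldehyde <- function() {
  zmat_to_molecule("formaldehyde", list(
    za("C"), za("O", a = 1, r = 1.21),
    za("H", a = 1, b = 2, r = 1.09, theta = 120),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = 120, phi = 180)
  ))
}

#' Idealized hydrogen-bond probe
#'
#' Two hydroxyl groups arranged so one O-H hydrogen sits exactly
#' `hb_distance` Angstrom from the other oxygen along the O-H axis
#' (a diol-like donor/acceptor arrangement reduced to its essentials).
#'
#' @param hb_distance H-to-acceptor distance, Angstrom (default 2.0).
#' @return A [molecule()] (bonds not perceived).
#' @export
make_hbond_probe <- function(hb_distance = 2.0) {
  molecule(sprintf("hbond_probe_%g", hb_distance), tibble::tibble(
    element = c("O", "H", "O", "H"),
    x = c(0, 0.96, 0.96 + hb_distance, 0.96 + hb_distance + 0.96),
    y = c(0, 0, 0, 0), z = c(0, 0, 0, 0)
  ), provenance = "fixture")
}

#' Probe molecules for the six curation filters
#'
#' Six molecules, each violating exactly one cleaning rule: an imaginary
#' frequency; a fluorine atom; a 1.70-Angstrom C-C bond; a four-coordinate
#' nitrogen; a three-coordinate carbon with H1/O2/N3 neighbours only
#' (incomplete octet); and a four-coordinate carbon with a 170-degree bond
#' angle. Bonds are already perceived and all other fields valid, so
#' [apply_filters()] removes each for its own reason and nothing else.
#'
#' @return Named list of six [molecule()]s.
#' @export
make_filter_probes <- function() {
  p1 <- perceive_bonds(make_ethanol())
  p1$id <- "probe_imaginary"; p1$lowest_frequency <- -25.3

  p2 <- molecule("probe_fluorine", tibble::tibble(
    element = c("H", "F"), x = c(0, 0.92), y = 0, z = 0
  ))
  p2 <- perceive_bonds(p2); p2$lowest_frequency <- 50

  p3 <- make_ethane()
  p3$id <- "probe_long_bond"
  # stretch the C-C bond to 1.70 A by translating C2 and its hydrogens
  # (the C-C axis of the ethane fixture is +x)
  moved <- c(2L, 6L, 7L, 8L)
  p3$atoms$x[moved] <- p3$atoms$x[moved] + (1.70 - 1.54)
  p3 <- perceive_bonds(p3); p3$lowest_frequency <- 50

  p4 <- zmat_to_molecule("probe_tetravalent_N", list(
    za("N"), za("H", a = 1, r = 1.03),
    za("H", a = 1, b = 2, r = 1.03, theta = TET),
    za("H", a = 1, b = 2, c = 3, r = 1.03, theta = TET, phi = 120),
    za("H", a = 1, b = 2, c = 3, r = 1.03, theta = TET, phi = -120)
  ))
  p4 <- perceive_bonds(p4); p4$lowest_frequency <- 50

  p5 <- zmat_to_molecule("probe_carbon_octet", list(
    za("C"), za("H", a = 1, r = 1.09),
    za("H", a = 1, b = 2, r = 1.09, theta = 120),
    za("H", a = 1, b = 2, c = 3, r = 1.09, theta = 120, phi = 180)
  ))
  p5 <- perceive_bonds(p5); p5$lowest_frequency <- 50

  p6 <- molecule("probe_large_angle", tibble::tibble(
    element = c("C", "H", "H", "H", "H"),
    x = c(0, 1.09, 1.09 * cos(170 * pi / 180), 0, 0),
    y = c(0, 0, 1.09 * sin(170 * pi / 180), -1.09 * 0.5, -1.09 * 0.5),
    z = c(0, 0, 0, 1.09 * sqrt(3) / 2, -1.09 * sqrt(3) / 2)
  ))
  p6 <- perceive_bonds(p6); p6$lowest_frequency <- 50

  list(probe_imaginary = p1, probe_fluorine = p2, probe_long_bond = p3,
       probe_tetravalent_N = p4, probe_carbon_octet = p5,
       probe_large_angle = p6)
}

#' Generate a synthetic toy dataset with linear-in-features energies
#'
#' Samples idealized CHNO templates (ethane, ethanol, methanol,
#' methylamine, formaldehyde, methane, a hydrogen-bonded diol probe),
#' applies Gaussian coordinate jitter, perceives bonds, and assigns
#' energies that are exactly linear in the encoded feature counts plus
#' Gaussian noise — so regression models have a known ground truth to
#' recover. One ammonia singleton and a two-water pair are always included
#' (for n >= 6) so every stoichiometry-split rule is exercised.
#'
#' @param n Number of molecules (>= 1).
#' @param jitter_sd Per-coordinate Gaussian jitter, Angstrom (default
#'   0.02; 0 gives duplicate geometries per template).
#' @param noise_sd Energy noise standard deviation, kcal/mol (default 1).
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @param config Featurizer configuration used for the generating
#'   dictionary.
#' @return A list of class `toy_dataset`: `molecules` (list), `features`
#'   (encoded tibble), `coefficients` (named numeric, kcal/mol per count),
#'   `dictionary`, `noise_sd`, `seed`.
#' @export
make_toy_dataset <- function(n = 200, jitter_sd = 0.02, noise_sd = 1,
                             seed = 1L, config = featurizer_config()) {
  stopifnot(n >= 1)
  templates <- list(
    ethane = make_ethane, ethanol = make_ethanol, methanol = make_methanol,
    methylamine = make_methylamine, formaldehyde = make_formaldehyde,
    methane = make_methane, hbond = function() make_hbond_probe(2.0)
  )
  mols <- NULL
  coefs <- NULL
  features <- NULL
  dict <- NULL
  with_preserved_seed({
    set.seed(as.integer(seed))
    picks <- character()
    if (n >= 6) {
      picks <- c("ammonia", "water", "water")
      picks <- c(picks, sample(names(templates), n - 3, replace = TRUE))
    } else {
      picks <- sample(names(templates), n, replace = TRUE)
    }
    mols <- lapply(seq_along(picks), function(k) {
      nm <- picks[k]
      m <- if (nm == "ammonia") make_ammonia()
           else if (nm == "water") make_water()
           else templates[[nm]]()
      m$id <- sprintf("mol%04d_%s", k, nm)
      if (jitter_sd > 0) {
        xyz <- coords(m) + matrix(stats::rnorm(3 * n_atoms(m), 0, jitter_sd),
                                  ncol = 3)
        m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
      }
      perceive_bonds(m)
    })
    dict <- build_dictionary(mols, config)
    features <- encode_molecules(mols, dict)
    slots <- feature_names(dict)
    coefs <- stats::setNames(numeric(length(slots)), slots)
    is_atom <- startsWith(slots, "atom_")
    coefs[is_atom] <- stats::runif(sum(is_atom), -3, -1)
    coefs[!is_atom] <- stats::runif(sum(!is_atom), -5, 5)
    y <- as.numeric(feature_matrix(features) %*% coefs) +
      stats::rnorm(length(mols), 0, noise_sd)
    for (k in seq_along(mols)) {
      mols[[k]]$electronic_energy <- y[k]
      mols[[k]]$free_energy <- y[k] - 10
      mols[[k]]$lowest_frequency <- stats::runif(1, 10, 200)
    }
  })
  structure(list(molecules = mols, features = features, coefficients = coefs,
                 dictionary = dict, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "toy_dataset")
}

#' @export
print.toy_dataset <- function(x, ...) {
  cat(sprintf("<toy_dataset> %d molecules, %d features, noise sd %.3g kcal/mol\n",
              length(x$molecules), x$dictionary$n_features, x$noise_sd))
  invisible(x)
}

#' Random count-matrix regression fixture
#'
#' A pure synthetic linear oracle: integer count features (Poisson) with a
#' known coefficient vector and Gaussian noise, mimicking the statistics
#' of count-based molecular feature vectors without the rank limits of a
#' finite template library. Used to verify exact coefficient recovery and
#' interpolation behaviour of the regressors.
#'
#' @param n,p Rows and feature count.
#' @param noise_sd Gaussian noise sd, kcal/mol.
#' @param seed Integer seed.
#' @return List: `X` (tibble with `molecule_id` + `f*` columns), `y`,
#'   `beta` (named, incl. `(Intercept)`), `noise_sd`.
#' @export
make_count_fixture <- function(n = 500, p = 20, noise_sd = 1, seed = 1L) {
  with_preserved_seed({
    set.seed(as.integer(seed))
    X <- matrix(stats::rpois(n * p, lambda = 3), n, p)
    colnames(X) <- sprintf("f%02d", seq_len(p))
    # coefficient magnitudes bounded away from zero so relative recovery
    # error is well defined for every term
    beta <- stats::setNames(
      sample(c(-1, 1), p, replace = TRUE) * stats::runif(p, 20, 60),
      colnames(X)
    )
    intercept <- stats::runif(1, -100, 100)
    y <- intercept + as.numeric(X %*% beta) + stats::rnorm(n, 0, noise_sd)
  })
  list(
    X = dplyr::bind_cols(
      tibble::tibble(molecule_id = sprintf("row%04d", seq_len(n))),
      tibble::as_tibble(X)
    ),
    y = y,
    beta = c("(Intercept)" = intercept, beta),
    noise_sd = noise_sd
  )
}

#' Write the fixture set to disk
#'
#' Writes each toy-dataset molecule as an XYZ file plus a `targets.csv`
#' table (id, electronic_energy, free_energy, lowest_frequency).
#'
#' @param dataset A `toy_dataset` from [make_toy_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in dataset$molecules) {
    write_structure(m, file.path(dir, paste0(m$id, ".xyz")), format = "xyz")
  }
  utils::write.csv(
    molecules_table(dataset$molecules)[
      c("id", "electronic_energy", "free_energy", "lowest_frequency")],
    file.path(dir, "targets.csv"), row.names = FALSE
  )
  invisible(dir)
}
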