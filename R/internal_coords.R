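# canonical element order used for all class labels
ELEMENT_ORDER <- c(C = 1L, H = 2L, N = 3L, O = 4L)

# token for one atom at the requested granularity; sort key encodes
# (element rank, connectivity) so ties between like elements are stable
atom_tokens <- function(m, granularity = c("element", "element+connectivity")) {
  granularity <- match.arg(granularity)
  el <- m$atoms$element
  rank <- ELEMENT_ORDER[el]
  rank[is.na(rank)] <- 9L
  deg <- atom_degrees(m)
  token <- if (granularity == "element") el else paste0(el, deg)
  list(token = token, key = sprintf("%d%03d", rank, deg))
}

obs_tibble <- function(family, class_label, value, idx) {
  tibble::tibble(
    family = family, class_label = class_label, value = value,
    atom_indices = idx
  )
}

#' Enumerate bond-length observations
#'
#' One observation per perceived bond; the class label is the canonically
#' ordered pair of atom tokens (element order C < H < N < O, ties broken by
#' connectivity), so reversing the atom order in the input file never
#' changes a label.
#'
#' @param m A [molecule()] with bonds.
#' @param granularity `"element"` (e.g. `"CH"`) or
#'   `"element+connectivity"` (e.g. `"C4H1"`).
#' @return A tibble with columns `family`, `class_label`, `value`
#'   (Angstrom), `atom_indices` (list of integer vectors).
#' @export
#' @examples
#' eth <- perceive_bonds(make_ethanol())
#' table(enumerate_bond_obs(eth)$class_label)
enumerate_bond_obs <- function(m, granularity = c("element", "element+connectivity")) {
  granularity <- match.arg(granularity)
  tk <- atom_tokens(m, granularity)
  b <- m$bonds
  if (!nrow(b)) return(obs_tibble(character(), character(), numeric(), list()))
  swap <- tk$key[b$i] > tk$key[b$j]
  a1 <- ifelse(swap, b$j, b$i)
  a2 <- ifelse(swap, b$i, b$j)
  obs_tibble(
    "bond",
    paste0(tk$token[a1], tk$token[a2]),
    bond_lengths(m)$length,
    purrr::map2(b$i, b$j, c)
  )
}

#' Enumerate bond-angle observations
#'
#' One observation per connected triple i-j-k with j central; each
#' unordered terminal pair is counted once. The label keeps the central
#' token in the middle and sorts the terminal tokens canonically. The total
#' number of observations is always `sum(d_j * (d_j - 1) / 2)` over atom
#' degrees.
#'
#' @inheritParams enumerate_bond_obs
#' @return A tibble as in [enumerate_bond_obs()], `value` in degrees.
#' @export
enumerate_angle_obs <- function(m, granularity = c("element", "element+connectivity")) {
  granularity <- match.arg(granularity)
  tk <- atom_tokens(m, granularity)
  adj <- adjacency(m)
  xyz <- coords(m)
  lab <- character(); val <- numeric(); idx <- list()
  for (j in seq_len(n_atoms(m))) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    for (p in seq_len(length(nb) - 1)) {
      for (q in (p + 1):length(nb)) {
        i <- nb[p]; k <- nb[q]
        v1 <- xyz[i, ] - xyz[j, ]; v2 <- xyz[k, ] - xyz[j, ]
        n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
        if (n1 < 1e-8 || n2 < 1e-8) {
          stop("degenerate geometry: coincident atoms in angle at atom ", j,
               call. = FALSE)
        }
        cosang <- max(-1, min(1, sum(v1 * v2) / (n1 * n2)))
        ends <- if (tk$key[i] <= tk$key[k]) c(i, k) else c(k, i)
        lab <- c(lab, paste0(tk$token[ends[1]], tk$token[j], tk$token[ends[2]]))
        val <- c(val, acos(cosang) * 180 / pi)
        idx <- c(idx, list(c(ends[1], j, ends[2])))
      }
    }
  }
  obs_tibble(rep("angle", length(val)), lab, val, idx)
}

# signed torsion i-j-k-l in degrees, NA when j-k axis degenerate
torsion_deg <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, ] - xyz[i, ]
  b2 <- xyz[k, ] - xyz[j, ]
  b3 <- xyz[l, ] - xyz[k, ]
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) return(NA_real_)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Enumerate dihedral observations
#'
#' One observation per undirected bonded path i-j-k-l. The value is the
#' absolute torsion in \[0, 180\] degrees, which makes the representation
#' achiral (enantiomeric torsions coincide). The label is the
#' lexicographically smaller of the forward and reversed token sequences.
#' Paths with three collinear consecutive atoms have no defined torsion and
#' are skipped with a warning.
#'
#' @inheritParams enumerate_bond_obs
#' @return A tibble as in [enumerate_bond_obs()], `value` in degrees.
#' @export
enumerate_dihedral_obs <- function(m, granularity = c("element", "element+connectivity")) {
  granularity <- match.arg(granularity)
  tk <- atom_tokens(m, granularity)
  adj <- adjacency(m)
  xyz <- coords(m)
  lab <- character(); val <- numeric(); idx <- list()
  skipped <- 0L
  b <- m$bonds
  for (r in seq_len(nrow(b))) {
    j <- b$i[r]; k <- b$j[r]
    for (i in setdiff(adj[[j]], k)) {
      for (l in setdiff(adj[[k]], j)) {
        if (i == l) next # 3-membered ring wrap-around is not a proper path
        tor <- torsion_deg(xyz, i, j, k, l)
        if (is.na(tor)) { skipped <- skipped + 1L; next }
        fwd <- tk$key[c(i, j, k, l)]
        rev_ <- tk$key[c(l, k, j, i)]
        take_fwd <- paste(fwd, collapse = "") <= paste(rev_, collapse = "")
        seq_idx <- if (take_fwd) c(i, j, k, l) else c(l, k, j, i)
        lab <- c(lab, paste(tk$token[seq_idx], collapse = ""))
        val <- c(val, abs(tor))
        idx <- c(idx, list(seq_idx))
      }
    }
  }
  if (skipped > 0) {
    warning(skipped, " dihedral(s) skipped in ", m$id,
            ": collinear consecutive atoms", call. = FALSE)
  }
  obs_tibble(rep("dihedral", length(val)), lab, val, idx)
}

#' Detect intramolecular hydrogen-bond contacts
#'
#' Every hydrogen covalently bonded to N or O is a donor hydrogen; every N
#' or O atom not covalently bonded to that hydrogen is a candidate
#' acceptor. A contact is recorded when the H-to-acceptor distance lies in
#' `window` (default 1.3 to 2.6 Angstrom, measured hydrogen-to-acceptor).
#' With only C/H/N/O present the four possible classes are OH-O, OH-N,
#' NH-O and NH-N, set by the donor heavy atom and the acceptor element.
#'
#' @param m A [molecule()] with bonds.
#' @param window Length-2 numeric, Angstrom.
#' @return A tibble as in [enumerate_bond_obs()], `value` = H...acceptor
#'   distance in Angstrom.
#' @export
detect_hbond_obs <- function(m, window = c(1.3, 2.6)) {
  adj <- adjacency(m)
  el <- m$atoms$element
  xyz <- coords(m)
  lab <- character(); val <- numeric(); idx <- list()
  donors_h <- which(el == "H" &
                      vapply(adj, function(nb) any(el[nb] %in% c("N", "O")), TRUE))
  acceptors <- which(el %in% c("N", "O"))
  for (h in donors_h) {
    heavy <- adj[[h]][el[adj[[h]]] %in% c("N", "O")][1]
    for (a in setdiff(acceptors, adj[[h]])) {
      d <- sqrt(sum((xyz[h, ] - xyz[a, ])^2))
      if (d >= window[1] && d <= window[2]) {
        lab <- c(lab, paste0(el[heavy], "H-", el[a]))
        val <- c(val, d)
        idx <- c(idx, list(c(heavy, h, a)))
      }
    }
  }
  obs_tibble(rep("hbond", length(val)), lab, val, idx)
}

#' Count NH_x groups
#'
#' For each nitrogen, x is the number of covalently bonded hydrogens;
#' nitrogens with no hydrogen contribute nothing.
#'
#' @param m A [molecule()] with bonds.
#' @return Named integer vector: names are x values (`"1"`, `"2"`, `"3"`),
#'   values are counts of nitrogens carrying that many hydrogens.
#' @export
#' @examples
#' count_nhx(perceive_bonds(make_methylamine())) # c(`2` = 1)
count_nhx <- function(m) {
  adj <- adjacency(m)
  el <- m$atoms$element
  xs <- vapply(which(el == "N"), function(n) sum(el[adj[[n]]] == "H"), 1L)
  xs <- xs[xs >= 1L]
  if (!length(xs)) return(stats::setNames(integer(), character()))
  tab <- table(xs)
  stats::setNames(as.integer(tab), names(tab))
}

#' All internal-coordinate observations of a molecule
#'
#' Convenience wrapper running the four family enumerations at the
#' granularities given in `config` (see [featurizer_config()]).
#'
#' @param m A [molecule()] with bonds.
#' @param config A [featurizer_config()].
#' @return A tibble with one row per observation and a `molecule_id` column.
#' @export
molecule_observations <- function(m, config = featurizer_config()) {
  out <- dplyr::bind_rows(
    enumerate_bond_obs(m, config$granularity$bond),
    enumerate_angle_obs(m, config$granularity$angle),
    enumerate_dihedral_obs(m, config$granularity$dihedral),
    detect_hbond_obs(m, config$hbond_window)
  )
  dplyr::mutate(out, molecule_id = m$id, .before = 1)
}
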