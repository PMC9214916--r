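#' Featurizer configuration
#'
#' Controls the class granularity per family and the KDE bandwidths. The
#' defaults are the best-performing combination: connectivity tokens for
#' angles only, element tokens for bonds and dihedrals, the four fixed
#' hydrogen-bond classes, and bandwidth factor 0.07 throughout (the
#' published value for bonds and angles, mirrored to the other families).
#'
#' @param bond_granularity,angle_granularity,dihedral_granularity
#'   `"element"` or `"element+connectivity"`.
#' @param bandwidth_bond,bandwidth_angle,bandwidth_dihedral,bandwidth_hbond
#'   KDE bandwidth. With `bandwidth_mode = "factor"` (default) the Gaussian
#'   kernel standard deviation is `factor * sd(values)` of the pooled class
#'   sample; with `"absolute"` it is the bandwidth itself, in the class's
#'   units.
#' @param bandwidth_mode `"factor"` or `"absolute"`.
#' @param hbond_window H...acceptor detection window, Angstrom.
#' @param grid_points Number of KDE evaluation grid points (default 2048).
#' @param grid_pad Grid padding in bandwidths beyond the sample range
#'   (default 3).
#' @return A list of settings, class `featurizer_config`.
#' @export
featurizer_config <- function(bond_granularity = "element",
                              angle_granularity = "element+connectivity",
                              dihedral_granularity = "element",
                              bandwidth_bond = 0.07,
                              bandwidth_angle = 0.07,
                              bandwidth_dihedral = 0.07,
                              bandwidth_hbond = 0.07,
                              bandwidth_mode = c("factor", "absolute"),
                              hbond_window = c(1.3, 2.6),
                              grid_points = 2048L,
                              grid_pad = 3) {
  structure(list(
    granularity = list(bond = bond_granularity, angle = angle_granularity,
                       dihedral = dihedral_granularity),
    bandwidth = list(bond = bandwidth_bond, angle = bandwidth_angle,
                     dihedral = bandwidth_dihedral, hbond = bandwidth_hbond),
    bandwidth_mode = match.arg(bandwidth_mode),
    hbond_window = hbond_window,
    grid_points = as.integer(grid_points),
    grid_pad = grid_pad
  ), class = "featurizer_config")
}

#' Fit KDE feature bins for one class of observations
#'
#' A Gaussian KDE is evaluated on a uniform grid spanning the sample range
#' padded by `grid_pad` bandwidths. Every local maximum of the density
#' becomes one feature bin; the interleaving local minima become the
#' assignment boundaries, with the outermost bounds at -Inf/+Inf so no
#' later observation is ever unassignable. A class with a single distinct
#' value (or zero variance) yields one bin covering the whole line.
#'
#' @param values Numeric vector of observed values for one class
#'   (Angstrom or degrees).
#' @param bandwidth Bandwidth factor or absolute bandwidth, per `mode`.
#' @param mode `"factor"` (bandwidth x sample sd) or `"absolute"`.
#' @param grid_points,grid_pad See [featurizer_config()].
#' @return A tibble with one row per bin: `bin`, `maximum`, `lower`,
#'   `upper`.
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(500, 1.33, 0.01), rnorm(500, 1.54, 0.01))
#' fit_feature_bins(x, bandwidth = 0.07)
fit_feature_bins <- function(values, bandwidth = 0.07,
                             mode = c("factor", "absolute"),
                             grid_points = 2048L, grid_pad = 3) {
  mode <- match.arg(mode)
  stopifnot(length(values) >= 1L, bandwidth > 0)
  s <- stats::sd(values)
  # classes whose spread is at floating-point scale are degenerate: one bin
  if (length(values) == 1L || !is.finite(s) ||
      s <= max(abs(values), 1) * 1e-9) {
    return(tibble::tibble(bin = 1L, maximum = stats::median(values),
                          lower = -Inf, upper = Inf))
  }
  h <- if (mode == "factor") bandwidth * s else bandwidth
  d <- stats::density(values, bw = h, kernel = "gaussian",
                      from = min(values) - grid_pad * h,
                      to = max(values) + grid_pad * h,
                      n = grid_points)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  # suppress numerical wiggles of the FFT density in effectively-zero
  # regions: a real peak carries non-negligible mass
  is_max <- is_max & y >= 1e-9 * max(y)
  max_ix <- which(is_max)
  if (!length(max_ix)) max_ix <- which.max(y)
  k <- length(max_ix)
  lower <- rep(-Inf, k); upper <- rep(Inf, k)
  if (k > 1) {
    for (b in seq_len(k - 1)) {
      seg <- max_ix[b]:max_ix[b + 1]
      cut <- d$x[seg[which.min(y[seg])]]
      upper[b] <- cut
      lower[b + 1] <- cut
    }
  }
  tibble::tibble(bin = seq_len(k), maximum = d$x[max_ix],
                 lower = lower, upper = upper)
}

FAMILY_ORDER <- c("bond", "angle", "dihedral", "hbond")

#' Build the feature dictionary from a training set
#'
#' Pools every internal-coordinate observation over the training molecules
#' by family and class, fits KDE bins per class, and assembles the
#' deterministic slot ordering of the representation: the four atom-count
#' slots (C, H, N, O, weighted by 100 at encoding time), then bond, angle,
#' dihedral and hydrogen-bond bins (classes alphabetical within family,
#' bins by ascending maximum within class), then the observed NH_x slots.
#'
#' @param molecules Non-empty list of curated, bonded [molecule()]s.
#' @param config A [featurizer_config()].
#' @return A `feature_dictionary`: list with `bins` (tibble: family,
#'   class_label, bin, maximum, lower, upper, slot), `nhx_slots`,
#'   `config`, `n_features`, and a content `fingerprint`.
#' @export
build_dictionary <- function(molecules, config = featurizer_config()) {
  if (!length(molecules)) stop("empty training set", call. = FALSE)
  obs <- dplyr::bind_rows(lapply(molecules, molecule_observations, config = config))
  bins <- tibble::tibble()
  if (nrow(obs)) {
    bins <- obs |>
      dplyr::group_by(.data$family, .data$class_label) |>
      dplyr::reframe(fit_feature_bins(
        .data$value,
        bandwidth = config$bandwidth[[.data$family[1]]],
        mode = config$bandwidth_mode,
        grid_points = config$grid_points,
        grid_pad = config$grid_pad
      )) |>
      dplyr::mutate(family = factor(.data$family, levels = FAMILY_ORDER)) |>
      dplyr::arrange(.data$family, .data$class_label, .data$maximum) |>
      dplyr::mutate(family = as.character(.data$family))
    bins$slot <- sprintf("%s_%s_%d", bins$family, bins$class_label, bins$bin)
  }
  nhx <- sort(unique(unlist(lapply(molecules, function(m) {
    as.integer(names(count_nhx(m)))
  }))))
  dict <- structure(list(
    atom_slots = c("C", "H", "N", "O"),
    bins = bins,
    nhx_slots = nhx,
    config = config,
    n_features = 4L + nrow(bins) + length(nhx)
  ), class = "feature_dictionary")
  dict$fingerprint <- dictionary_fingerprint(dict)
  dict
}

dictionary_fingerprint <- function(dict) {
  # hash a canonical string rendering, not R objects: raw serialisation is
  # sensitive to ALTREP/attribute internals that change without the content
  # changing
  b <- dict$bins
  payload <- paste(c(
    dict$atom_slots, b$family, b$class_label, sprintf("%d", b$bin),
    sprintf("%.17g", b$maximum), sprintf("%.17g", b$lower),
    sprintf("%.17g", b$upper), sprintf("%d", dict$nhx_slots),
    as.character(jsonlite::toJSON(unclass(dict$config),
                                  auto_unbox = TRUE, digits = NA))
  ), collapse = "")
  rlang::hash(payload)
}

#' @export
print.feature_dictionary <- function(x, ...) {
  cat(sprintf("<feature_dictionary> %d features (%d KDE bins, %d NH_x slots)\n",
              x$n_features, nrow(x$bins), length(x$nhx_slots)))
  if (nrow(x$bins)) {
    print(dplyr::count(x$bins, .data$family, name = "bins"))
  }
  cat("fingerprint:", x$fingerprint, "\n")
  invisible(x)
}

#' Ordered slot names of a dictionary
#' @param dict A `feature_dictionary`.
#' @return Character vector of length `dict$n_features`.
#' @export
feature_names <- function(dict) {
  c(paste0("atom_", dict$atom_slots), dict$bins$slot,
    if (length(dict$nhx_slots)) paste0("nhx_", dict$nhx_slots) else character())
}

# assign values of one class to bins via the (lower, upper] convention
assign_bins <- function(values, class_bins) {
  if (nrow(class_bins) == 1L) return(rep(1L, length(values)))
  cuts <- class_bins$upper[-nrow(class_bins)]
  findInterval(values, cuts, left.open = TRUE) + 1L
}

#' Encode one molecule against a feature dictionary
#'
#' Each observation is assigned to the bin of its class whose
#' `(lower, upper]` interval contains the value; counts accumulate per
#' bin. Atom slots receive 100 x the element count; NH_x slots receive
#' group counts. Observations of classes absent from the dictionary are
#' dropped and reported in the `dropped` attribute — this is deliberate so
#' larger, out-of-training molecules still encode.
#'
#' @param m A bonded [molecule()].
#' @param dict A `feature_dictionary` from [build_dictionary()].
#' @return A one-row tibble: `molecule_id` then one numeric column per
#'   feature slot. Attribute `dropped` is a tibble of out-of-dictionary
#'   observations.
#' @export
#' @examples
#' eth <- perceive_bonds(make_ethanol())
#' dict <- build_dictionary(list(eth))
#' encode_molecule(eth, dict)[, 1:6]
encode_molecule <- function(m, dict) {
  stopifnot(inherits(dict, "feature_dictionary"))
  vec <- stats::setNames(numeric(dict$n_features), feature_names(dict))
  cnt <- element_counts(m)
  for (el in dict$atom_slots) {
    vec[paste0("atom_", el)] <- 100 * ifelse(is.na(cnt[el]), 0L, cnt[el])
  }
  obs <- molecule_observations(m, dict$config)
  dropped <- obs[0, ]
  if (nrow(obs)) {
    key <- paste(obs$family, obs$class_label)
    dict_key <- paste(dict$bins$family, dict$bins$class_label)
    known <- key %in% dict_key
    dropped <- obs[!known, ]
    for (k in unique(key[known])) {
      sel <- which(key == k & known)
      class_bins <- dict$bins[dict_key == k, ]
      bin_ix <- assign_bins(obs$value[sel], class_bins)
      add <- table(factor(class_bins$slot[bin_ix], levels = class_bins$slot))
      vec[names(add)] <- vec[names(add)] + as.numeric(add)
    }
  }
  nhx <- count_nhx(m)
  for (x in names(nhx)) {
    slot <- paste0("nhx_", x)
    if (slot %in% names(vec)) vec[slot] <- nhx[[x]]
    else dropped <- dplyr::bind_rows(
      dropped,
      tibble::tibble(molecule_id = m$id, family = "nhx",
                     class_label = paste0("NH", x), value = NA_real_,
                     atom_indices = list(integer()))
    )
  }
  out <- dplyr::bind_cols(tibble::tibble(molecule_id = m$id),
                          tibble::as_tibble(as.list(vec)))
  attr(out, "dropped") <- dropped
  out
}

#' Encode a set of molecules as a feature matrix
#'
#' @param molecules List of bonded [molecule()]s.
#' @param dict A `feature_dictionary`.
#' @return A tibble: `molecule_id` column plus one column per feature
#'   slot; attribute `dropped` collects out-of-dictionary observations
#'   over the whole set.
#' @export
encode_molecules <- function(molecules, dict) {
  rows <- lapply(molecules, encode_molecule, dict = dict)
  out <- dplyr::bind_rows(rows)
  attr(out, "dropped") <- dplyr::bind_rows(lapply(rows, attr, "dropped"))
  out
}

#' Write / read a feature dictionary as JSON
#'
#' The JSON schema is versioned and lossless: a round-tripped dictionary
#' encodes molecules bit-for-bit identically.
#'
#' @param dict A `feature_dictionary`.
#' @param path Output/input path.
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary`
#'   returns the dictionary.
#' @export
write_dictionary <- function(dict, path) {
  bins_out <- dict$bins[c("family", "class_label", "bin", "maximum",
                          "lower", "upper", "slot")]
  # JSON has no +-Inf and jsonlite trims doubles, so all real-valued
  # columns travel as exact %.17g decimal strings
  bins_out$maximum <- sprintf("%.17g", bins_out$maximum)
  bins_out$lower <- sprintf("%.17g", bins_out$lower)
  bins_out$upper <- sprintf("%.17g", bins_out$upper)
  payload <- list(
    schema = "molkde-dictionary-1",
    atom_slots = dict$atom_slots,
    bins = bins_out,
    nhx_slots = dict$nhx_slots,
    config = unclass(dict$config),
    n_features = dict$n_features,
    fingerprint = dict$fingerprint
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "molkde-dictionary-1")) {
    stop("unrecognised dictionary schema in ", path, call. = FALSE)
  }
  raw <- tibble::as_tibble(p$bins)
  if (!nrow(raw)) {
    bins <- tibble::tibble(family = character(), class_label = character(),
                           bin = integer(), maximum = numeric(),
                           lower = numeric(), upper = numeric(),
                           slot = character())
  } else {
    bins <- tibble::tibble(
      family = as.character(raw$family),
      class_label = as.character(raw$class_label),
      bin = as.integer(raw$bin),
      maximum = as.numeric(raw$maximum),
      lower = as.numeric(raw$lower),
      upper = as.numeric(raw$upper),
      slot = as.character(raw$slot)
    )
  }
  cfg <- p$config
  config <- featurizer_config(
    bond_granularity = cfg$granularity$bond,
    angle_granularity = cfg$granularity$angle,
    dihedral_granularity = cfg$granularity$dihedral,
    bandwidth_bond = cfg$bandwidth$bond,
    bandwidth_angle = cfg$bandwidth$angle,
    bandwidth_dihedral = cfg$bandwidth$dihedral,
    bandwidth_hbond = cfg$bandwidth$hbond,
    bandwidth_mode = cfg$bandwidth_mode,
    hbond_window = as.numeric(cfg$hbond_window),
    grid_points = as.integer(cfg$grid_points),
    grid_pad = as.numeric(cfg$grid_pad)
  )
  dict <- structure(list(
    atom_slots = p$atom_slots,
    bins = bins,
    nhx_slots = as.integer(p$nhx_slots),
    config = config,
    n_features = as.integer(p$n_features)
  ), class = "feature_dictionary")
  dict$fingerprint <- dictionary_fingerprint(dict)
  if (!identical(dict$fingerprint, p$fingerprint)) {
    warning("dictionary fingerprint changed on read; file may have been edited",
            call. = FALSE)
  }
  dict
}

#' Class-level totals of an encoded feature vector
#'
#' Sums the bin columns of an encoded row per (family, class), which is
#' the granularity at which worked examples are usually quoted (e.g. "five
#' CH bonds").
#'
#' @param encoded A row tibble from [encode_molecule()].
#' @param dict The dictionary it was encoded against.
#' @return A tibble: `family`, `class_label`, `count`.
#' @export
class_totals <- function(encoded, dict) {
  if (!nrow(dict$bins)) {
    return(tibble::tibble(family = character(), class_label = character(),
                          count = numeric()))
  }
  vals <- as.numeric(encoded[1, dict$bins$slot])
  tibble::tibble(family = dict$bins$family,
                 class_label = dict$bins$class_label,
                 count = vals) |>
    dplyr::group_by(.data$family, .data$class_label) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}
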