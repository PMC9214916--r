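HARTREE_TO_KCAL <- 627.5094740631

#' Read a molecular structure from XYZ or SDF
#'
#' XYZ files carry no connectivity, so the returned molecule has an empty
#' bond list (use [perceive_bonds()]). For SDF (V2000) the bond block is
#' honoured. Elements outside C/H/N/O are accepted and can be detected with
#' [out_of_alphabet()]; curation decides their fate.
#'
#' @param path File path.
#' @param format `"xyz"` or `"sdf"`; default guessed from the extension.
#' @param id Molecule id; defaults to the file name without extension.
#' @return A [molecule()].
#' @export
read_structure <- function(path, format = c("auto", "xyz", "sdf"), id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sdf", "mol")) "sdf" else "xyz"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  switch(format, xyz = read_xyz(path, id), sdf = read_sdf(path, id))
}

read_xyz <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("malformed XYZ (", path, "): fewer than 3 lines", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ (", path, "): line 1 is not an atom count", call. = FALSE)
  if (length(lines) < n + 2L) {
    stop("malformed XYZ (", path, "): expected ", n, " atom rows", call. = FALSE)
  }
  rows <- lines[3:(n + 2L)]
  parts <- strsplit(trimws(rows), "\\s+")
  bad <- which(vapply(parts, length, 1L) < 4L)
  if (length(bad)) {
    stop("malformed XYZ (", path, "): line ", bad[1] + 2L, " has fewer than 4 fields",
         call. = FALSE)
  }
  el <- vapply(parts, `[[`, "", 1L)
  num <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2:4])), numeric(3))
  if (any(!is.finite(num))) {
    bad <- which(apply(!is.finite(num), 2, any))[1]
    stop("malformed XYZ (", path, "): non-numeric coordinate on line ", bad + 2L,
         call. = FALSE)
  }
  molecule(id, tibble::tibble(element = el, x = num[1, ], y = num[2, ], z = num[3, ]),
           provenance = path)
}

read_sdf <- function(path, id) {
  if (requireNamespace("ChemmineR", quietly = TRUE)) {
    set <- tryCatch(
      suppressWarnings(ChemmineR::read.SDFset(path)),
      error = function(e) stop("malformed SDF (", path, "): ", conditionMessage(e),
                               call. = FALSE)
    )
    sdf <- set[[1]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    atoms <- tibble::tibble(element = el, x = ab[, 1], y = ab[, 2], z = ab[, 3])
    bonds <- if (is.null(bb) || nrow(bb) == 0) NULL else
      tibble::tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]))
    return(molecule(id, atoms, bonds, provenance = path))
  }
  read_sdf_v2000(path, id)
}

# minimal V2000 fallback used only when ChemmineR is unavailable
read_sdf_v2000 <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) stop("malformed SDF (", path, "): too short", call. = FALSE)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) {
    stop("malformed SDF (", path, "): bad counts line (line 4)", call. = FALSE)
  }
  at <- lines[5:(4 + na)]
  atoms <- tibble::tibble(
    element = trimws(substr(at, 32, 34)),
    x = as.numeric(substr(at, 1, 10)),
    y = as.numeric(substr(at, 11, 20)),
    z = as.numeric(substr(at, 21, 30))
  )
  bonds <- NULL
  if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    bonds <- tibble::tibble(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6))
    )
  }
  molecule(id, atoms, bonds, provenance = path)
}

#' Write a molecule to XYZ or SDF
#'
#' Coordinates are printed with enough digits (17 significant) that
#' `read_structure(write_structure(m))` reproduces them exactly.
#'
#' @param m A [molecule()].
#' @param path Output file path.
#' @param format `"xyz"` or `"sdf"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(m, path, format = c("auto", "xyz", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sdf", "mol")) "sdf" else "xyz"
  }
  xyz <- coords(m)
  if (format == "xyz") {
    rows <- sprintf("%-3s %.17g %.17g %.17g", m$atoms$element,
                    xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(c(as.character(n_atoms(m)), m$id, rows), path)
  } else {
    hdr <- c(m$id, "  molkde", "")
    cnt <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   n_atoms(m), nrow(m$bonds))
    at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                  xyz[, 1], xyz[, 2], xyz[, 3], m$atoms$element)
    bl <- if (nrow(m$bonds)) {
      sprintf("%3d%3d  1  0  0  0  0", m$bonds$i, m$bonds$j)
    } else character()
    writeLines(c(hdr, cnt, at, bl, "M  END", "$$$$"), path)
  }
  invisible(path)
}

#' Extract energies and lowest frequency from a quantum-chemistry log
#'
#' Minimal text extraction from the widely used log dialect: the last
#' `SCF Done:` energy, the last `Sum of electronic and thermal Free
#' Energies=` line, and the lowest value over all `Frequencies --` rows.
#' Hartree values are converted to kcal/mol (1 Hartree = 627.5094740631
#' kcal/mol).
#'
#' @param path Path to the log file.
#' @return A one-row tibble with `electronic_energy`, `free_energy`
#'   (kcal/mol) and `lowest_frequency` (cm^-1).
#' @export
extract_qc_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)

  scf <- grep("SCF Done:", lines, value = TRUE)
  if (!length(scf)) stop("electronic_energy not found in ", path, call. = FALSE)
  e_h <- as.numeric(sub(".*=\\s*(-?[0-9.]+([eEdD][+-]?[0-9]+)?)\\s+.*", "\\1",
                        scf[length(scf)]))
  if (is.na(e_h)) stop("electronic_energy not found in ", path, call. = FALSE)

  fe <- grep("Sum of electronic and thermal Free Energies=", lines, value = TRUE)
  if (!length(fe)) stop("free_energy not found in ", path, call. = FALSE)
  g_h <- as.numeric(sub(".*=\\s*(-?[0-9.]+)\\s*$", "\\1", fe[length(fe)]))
  if (is.na(g_h)) stop("free_energy not found in ", path, call. = FALSE)

  fq <- grep("Frequencies --", lines, value = TRUE)
  if (!length(fq)) stop("lowest_frequency not found in ", path, call. = FALSE)
  vals <- unlist(lapply(fq, function(l) {
    as.numeric(strsplit(trimws(sub(".*Frequencies --", "", l)), "\\s+")[[1]])
  }))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("lowest_frequency not found in ", path, call. = FALSE)

  tibble::tibble(
    electronic_energy = e_h * HARTREE_TO_KCAL,
    free_energy = g_h * HARTREE_TO_KCAL,
    lowest_frequency = min(vals)
  )
}

#' Attach targets from a CSV table to molecules
#'
#' The table must have columns `id`, `electronic_energy`, `free_energy`
#' (kcal/mol). CSV values take precedence over anything already stored on
#' the molecules.
#'
#' @param molecules List of [molecule()] objects.
#' @param targets Data frame or path to a CSV file.
#' @return The list of molecules with targets filled in.
#' @export
attach_targets <- function(molecules, targets) {
  if (is.character(targets)) {
    targets <- utils::read.csv(targets, stringsAsFactors = FALSE)
  }
  targets <- tibble::as_tibble(targets)
  lapply(molecules, function(m) {
    row <- targets[targets$id == m$id, ]
    if (nrow(row)) {
      if ("electronic_energy" %in% names(row)) {
        m$electronic_energy <- as.numeric(row$electronic_energy[1])
      }
      if ("free_energy" %in% names(row)) {
        m$free_energy <- as.numeric(row$free_energy[1])
      }
      if ("lowest_frequency" %in% names(row)) {
        m$lowest_frequency <- as.numeric(row$lowest_frequency[1])
      }
    }
    m
  })
}
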