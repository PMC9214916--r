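# shared helpers for the molkde test suite

# random proper rotation matrix (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# brute-force path enumeration oracles, independent of the package's
# token/canonicalisation machinery
brute_angle_count <- function(m) {
  deg <- table(factor(c(m$bonds$i, m$bonds$j), levels = seq_len(n_atoms(m))))
  sum(choose(as.integer(deg), 2))
}

brute_dihedral_count <- function(m) {
  adj <- lapply(seq_len(n_atoms(m)), function(a) {
    sort(c(m$bonds$j[m$bonds$i == a], m$bonds$i[m$bonds$j == a]))
  })
  count <- 0L
  for (r in seq_len(nrow(m$bonds))) {
    j <- m$bonds$i[r]; k <- m$bonds$j[r]
    for (i in setdiff(adj[[j]], k)) {
      for (l in setdiff(adj[[k]], j)) {
        if (i != l) count <- count + 1L
      }
    }
  }
  count
}

# element-level class totals of an encoded ethanol row, with connectivity
# digits stripped so labels aggregate to element composition
element_class_totals <- function(encoded, dict) {
  ct <- class_totals(encoded, dict)
  ct$class_label <- gsub("[0-9]", "", ct$class_label)
  stats::aggregate(count ~ family + class_label, data = as.data.frame(ct), sum)
}

# a minimal quantum-chemistry log with controllable blocks
write_fake_qc_log <- function(path, energy_h = -1.0, free_h = -0.9,
                              freqs = c(-25.3, 10.1, 500.2),
                              include_free = TRUE) {
  lines <- c(
    " SCF Done:  E(RB3LYP) =  -0.5  A.U. after   1 cycles",
    sprintf(" SCF Done:  E(RB3LYP) =  %.10f  A.U. after  10 cycles", energy_h),
    sprintf(" Frequencies -- %s", paste(sprintf("%10.4f", freqs), collapse = " "))
  )
  if (include_free) {
    lines <- c(lines, sprintf(
      " Sum of electronic and thermal Free Energies=       %.6f", free_h))
  }
  writeLines(lines, path)
  path
}

toy_cache <- new.env(parent = emptyenv())

# one moderately sized toy dataset shared across tests (built once)
shared_toy <- function() {
  if (is.null(toy_cache$ds)) toy_cache$ds <- make_toy_dataset(80, seed = 42)
  toy_cache$ds
}
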