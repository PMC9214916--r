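test_that("degenerate classes collapse to a single all-covering bin", {
  b <- fit_feature_bins(rep(1.09, 7), bandwidth = 0.07)
  expect_equal(nrow(b), 1L)
  expect_equal(b$maximum, 1.09)
  expect_equal(b$lower, -Inf)
  expect_equal(b$upper, Inf)
  expect_equal(nrow(fit_feature_bins(1.33)), 1L)
})

test_that("a bimodal sample yields two bins split between the modes", {
  set.seed(1)
  x <- c(rnorm(1000, 1.33, 0.01), rnorm(1000, 1.54, 0.01))
  b <- fit_feature_bins(x, bandwidth = 0.07)
  expect_equal(nrow(b), 2L)
  expect_equal(b$maximum[1], 1.33, tolerance = 0.01)
  expect_equal(b$maximum[2], 1.54, tolerance = 0.01)
  expect_gt(b$upper[1], 1.40)
  expect_lt(b$upper[1], 1.48)
  expect_equal(b$upper[1], b$lower[2])
  # bins tile the line
  expect_equal(b$lower[1], -Inf)
  expect_equal(b$upper[2], Inf)
})

test_that("narrower bandwidths never merge peaks: bin count is monotone", {
  set.seed(2)
  x <- c(rnorm(400, 100, 2), rnorm(400, 109.5, 2), rnorm(400, 120, 2))
  wide <- fit_feature_bins(x, bandwidth = 0.2)
  narrow <- fit_feature_bins(x, bandwidth = 0.1)
  expect_gte(nrow(narrow), nrow(wide))
})

test_that("dictionary covers exactly the classes present in the training set", {
  ds <- shared_toy()
  dict <- ds$dictionary
  obs <- dplyr::bind_rows(lapply(ds$molecules, molecule_observations,
                                 config = dict$config))
  expect_setequal(
    unique(paste(dict$bins$family, dict$bins$class_label)),
    unique(paste(obs$family, obs$class_label))
  )
  expect_equal(dict$n_features, 4L + nrow(dict$bins) + length(dict$nhx_slots))

  # adding the first nitrogen-free-set N molecule grows the class list
  no_n <- Filter(function(m) !any(m$atoms$element == "N"), ds$molecules)
  d0 <- build_dictionary(no_n)
  with_n <- c(no_n, list(perceive_bonds(make_methylamine())))
  d1 <- build_dictionary(with_n)
  expect_gt(nrow(d1$bins), nrow(d0$bins))
  new_classes <- setdiff(d1$bins$class_label, d0$bins$class_label)
  expect_true(any(grepl("N", new_classes)))
})

test_that("dictionary JSON serialisation is deterministic and lossless", {
  ds <- shared_toy()
  mols <- ds$molecules[1:25]
  d1 <- build_dictionary(mols)
  d2 <- build_dictionary(mols)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_dictionary(d1, f1)
  write_dictionary(d2, f2)
  expect_identical(readLines(f1), readLines(f2)) # byte-identical rebuild

  back <- read_dictionary(f1)
  expect_equal(back$fingerprint, d1$fingerprint)
  eth <- perceive_bonds(make_ethanol())
  expect_identical(encode_molecule(eth, back), encode_molecule(eth, d1))
})

test_that("ethanol encodes to the published class totals", {
  eth <- perceive_bonds(make_ethanol())
  ds <- shared_toy()
  enc <- encode_molecule(eth, ds$dictionary)
  ct <- element_class_totals(enc, ds$dictionary)
  get <- function(fam, lab) ct$count[ct$family == fam & ct$class_label == lab]
  expect_equal(get("bond", "CH"), 5)
  expect_equal(get("bond", "HO"), 1)
  expect_equal(get("bond", "CC"), 1)
  expect_equal(get("bond", "CO"), 1)
  # every hydrogen-bond feature is zero
  hb <- ct$count[ct$family == "hbond"]
  expect_true(all(hb == 0))
  # atom slots carry 100-weighted counts: C2 H6 O1, no N
  expect_equal(as.numeric(enc$atom_C), 200)
  expect_equal(as.numeric(enc$atom_H), 600)
  expect_equal(as.numeric(enc$atom_N), 0)
  expect_equal(as.numeric(enc$atom_O), 100)
})

test_that("per-family counts are conserved: column sums equal in-dictionary observations", {
  ds <- shared_toy()
  dict <- ds$dictionary
  for (m in ds$molecules[seq(1, 80, by = 13)]) {
    enc <- encode_molecule(m, dict)
    obs <- molecule_observations(m, dict$config)
    dict_key <- unique(paste(dict$bins$family, dict$bins$class_label))
    in_dict <- paste(obs$family, obs$class_label) %in% dict_key
    for (fam in c("bond", "angle", "dihedral", "hbond")) {
      cols <- dict$bins$slot[dict$bins$family == fam]
      expect_equal(sum(as.numeric(enc[1, cols])),
                   sum(obs$family == fam & in_dict))
    }
  }
})

test_that("bin assignment matches a brute-force nearest-maximum-in-interval oracle", {
  set.seed(3)
  x <- c(rnorm(600, 1.1, 0.02), rnorm(600, 1.35, 0.02), rnorm(600, 1.52, 0.02))
  bins <- fit_feature_bins(x, bandwidth = 0.3)
  expect_gt(nrow(bins), 1L)
  vals <- runif(1000, 0.9, 1.8)
  got <- molkde:::assign_bins(vals, bins)
  oracle <- vapply(vals, function(v) {
    hits <- which(v > bins$lower & v <= bins$upper)
    expect_length(hits, 1L) # intervals tile the line without overlap
    hits
  }, integer(1))
  expect_equal(got, oracle)
  # and the owning interval always contains its own maximum
  expect_true(all(bins$lower < bins$maximum & bins$maximum < bins$upper))
})

test_that("encoding is invariant under rigid motion, reflection and permutation", {
  ds <- shared_toy()
  dict <- ds$dictionary
  eth <- perceive_bonds(make_ethanol())
  ref <- encode_molecule(eth, dict)
  set.seed(11)
  for (k in 1:20) {
    rot <- random_rotation()
    if (k %% 2 == 0) rot <- rot %*% diag(c(-1, 1, 1)) # improper: reflection
    m <- transform_molecule(eth, rot, rnorm(3, 0, 4))
    m <- permute_atoms(m, sample(n_atoms(m)))
    m <- perceive_bonds(m)
    enc <- encode_molecule(m, dict)
    expect_identical(as.numeric(enc[1, -1]), as.numeric(ref[1, -1]))
  }
})

test_that("unknown classes are dropped into the coverage report, not fatal", {
  # a dictionary built only from water knows nothing about C-H chemistry
  w1 <- perceive_bonds(make_water())
  dict <- build_dictionary(list(w1))
  eth <- perceive_bonds(make_ethanol())
  enc <- encode_molecule(eth, dict)
  expect_equal(as.numeric(enc$atom_C), 200) # atom slots always present
  dropped <- attr(enc, "dropped")
  expect_gt(nrow(dropped), 0L)
  expect_true("CH" %in% dropped$class_label)
})
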