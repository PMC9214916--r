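eth <- perceive_bonds(make_ethanol())

test_that("ethanol bond, angle and dihedral classes match the worked example", {
  bonds <- enumerate_bond_obs(eth, "element")
  expect_equal(nrow(bonds), nrow(eth$bonds))
  expect_equal(as.vector(table(bonds$class_label)[c("CC", "CH", "CO", "HO")]),
               c(1L, 5L, 1L, 1L))

  ang <- enumerate_angle_obs(eth, "element")
  # canonical labels: terminal tokens sorted C < H < N < O around the
  # central atom, so OCH prints as HCO and COH keeps O central
  expect_equal(as.vector(table(ang$class_label)[
    c("CCH", "HCH", "HCO", "COH", "CCO")]), c(5L, 4L, 2L, 1L, 1L))
  expect_equal(nrow(ang), 13L)

  dih <- enumerate_dihedral_obs(eth, "element")
  expect_equal(nrow(dih), 12L) # brute-force path count, frozen
  expect_equal(as.vector(table(dih$class_label)[
    c("HCCH", "HCCO", "CCOH", "HCOH")]), c(6L, 3L, 1L, 2L))
  expect_equal(nrow(dih), brute_dihedral_count(eth))
})

test_that("angle observation count obeys the closed form sum of d(d-1)/2", {
  for (m in list(eth, perceive_bonds(make_methylamine()),
                 perceive_bonds(make_formaldehyde()),
                 perceive_bonds(make_water()))) {
    expect_equal(nrow(enumerate_angle_obs(m)), brute_angle_count(m))
    expect_equal(nrow(enumerate_bond_obs(m)), nrow(m$bonds))
  }
})

test_that("granularity changes labels, never observation counts", {
  a_el <- enumerate_angle_obs(eth, "element")
  a_conn <- enumerate_angle_obs(eth, "element+connectivity")
  expect_equal(nrow(a_conn), nrow(a_el))
  expect_equal(nrow(a_conn), 13L)
  d_el <- enumerate_dihedral_obs(eth, "element")
  d_conn <- enumerate_dihedral_obs(eth, "element+connectivity")
  expect_equal(nrow(d_conn), nrow(d_el))
})

test_that("measured values are geometrically correct", {
  w <- perceive_bonds(make_water())
  ang <- enumerate_angle_obs(w)
  expect_equal(nrow(ang), 1L)
  expect_equal(ang$value, 104.5, tolerance = 1e-6)

  # the staggered ethanol fixture has an exactly anti H-C-C-O path
  dih <- enumerate_dihedral_obs(eth, "element")
  hcco <- dih$value[dih$class_label == "HCCO"]
  expect_equal(sort(hcco), c(60, 60, 180), tolerance = 1e-6)
})

test_that("dihedral values are achiral: reflection leaves them unchanged", {
  mirror <- perceive_bonds(transform_molecule(eth, diag(c(-1, 1, 1))))
  d1 <- enumerate_dihedral_obs(eth)
  d2 <- enumerate_dihedral_obs(mirror)
  expect_equal(sort(d1$value), sort(d2$value), tolerance = 1e-9)
})

test_that("labels are canonical under atom-order reversal", {
  rev_eth <- perceive_bonds(permute_atoms(eth, rev(seq_len(n_atoms(eth)))))
  for (fam_fun in list(enumerate_bond_obs, enumerate_angle_obs,
                       enumerate_dihedral_obs)) {
    expect_equal(table(fam_fun(rev_eth)$class_label),
                 table(fam_fun(eth)$class_label))
  }
})

test_that("hydrogen-bond detection applies the 1.3-2.6 Angstrom H-acceptor window", {
  expect_equal(nrow(detect_hbond_obs(eth)), 0L) # no intramolecular H-bond

  probe <- perceive_bonds(make_hbond_probe(2.0))
  hb <- detect_hbond_obs(probe)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$class_label, "OH-O")
  expect_equal(hb$value, 2.0, tolerance = 1e-9)

  outside <- perceive_bonds(make_hbond_probe(2.7))
  expect_equal(nrow(detect_hbond_obs(outside)), 0L)
})

test_that("NH_x groups are counted per nitrogen", {
  expect_equal(count_nhx(perceive_bonds(make_methylamine())), c(`2` = 1L))
  expect_equal(count_nhx(perceive_bonds(make_ammonia())), c(`3` = 1L))
  expect_equal(length(count_nhx(eth)), 0L)

  # one secondary and one primary amine in the same molecule
  dimethyl <- molecule("nh_mix", tibble::tibble(
    element = c("N", "H", "C", "H", "H", "H", "N", "H", "H"),
    x = c(0, -0.5, 1.4, 1.8, 1.8, 1.8, 10, 10.5, 10.5),
    y = c(0, 0.85, 0.4, 1.0, -0.2, 1.0, 0, 0.85, -0.85),
    z = c(0, 0, 0.6, 1.4, 1.2, -0.3, 0, 0, 0)
  ))
  dimethyl <- perceive_bonds(dimethyl)
  expect_equal(count_nhx(dimethyl), c(`1` = 1L, `2` = 1L))
})

test_that("observation values are invariant under random rigid motion and permutation", {
  set.seed(7)
  base_obs <- molecule_observations(eth)
  for (k in 1:20) {
    rot <- random_rotation()
    moved <- perceive_bonds(transform_molecule(eth, rot, rnorm(3, 0, 3)))
    perm <- sample(n_atoms(eth))
    permuted <- perceive_bonds(permute_atoms(moved, perm))
    obs <- molecule_observations(permuted)
    expect_equal(table(obs$class_label), table(base_obs$class_label))
    expect_equal(sort(obs$value), sort(base_obs$value), tolerance = 1e-8)
  }
})
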