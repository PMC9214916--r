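test_that("each curation probe is removed with its own unique reason", {
  probes <- make_filter_probes()
  eth <- perceive_bonds(make_ethanol())
  eth$lowest_frequency <- 12.5
  rep <- apply_filters(c(probes, list(eth)))
  expect_equal(nrow(rep$removed), 6L)
  expect_setequal(rep$removed$reason,
                  c("imaginary_freq", "out_of_alphabet", "long_bond",
                    "tetravalent_N", "carbon_octet", "large_angle_C4"))
  expect_equal(rep$kept, "ethanol")
  # reasons match the constructed violations
  by_id <- setNames(rep$removed$reason, rep$removed$id)
  expect_equal(by_id[["probe_imaginary"]], "imaginary_freq")
  expect_equal(by_id[["probe_fluorine"]], "out_of_alphabet")
  expect_equal(by_id[["probe_long_bond"]], "long_bond")
  expect_equal(by_id[["probe_tetravalent_N"]], "tetravalent_N")
  expect_equal(by_id[["probe_carbon_octet"]], "carbon_octet")
  expect_equal(by_id[["probe_large_angle"]], "large_angle_C4")
  # kept + removed partition the input
  td <- tidy(rep)
  expect_equal(sort(td$id), sort(c(names(probes), "ethanol")))
})

test_that("filters are idempotent: re-filtering the kept set removes nothing", {
  ds <- shared_toy()
  rep1 <- apply_filters(ds$molecules)
  kept <- kept_molecules(ds$molecules, rep1)
  rep2 <- apply_filters(kept)
  expect_equal(nrow(rep2$removed), 0L)
  expect_equal(rep2$kept, rep1$kept)
})

test_that("an over-stretched bond is caught at the 1.6 Angstrom threshold", {
  p <- make_filter_probes()$probe_long_bond
  expect_gt(max(bond_lengths(p)$length), 1.6)
  rep <- apply_filters(list(p))
  expect_equal(rep$removed$reason, "long_bond")
  # a relaxed threshold keeps it
  rep2 <- apply_filters(list(p), filter_config(long_bond_threshold = 1.8))
  expect_equal(rep2$kept, p$id)
})

test_that("free-energy deduplication keeps one molecule per value, smallest id first", {
  mk <- function(id, fe) {
    m <- perceive_bonds(make_water()); m$id <- id; m$free_energy <- fe; m
  }
  # two identical values -> one kept
  rep <- dedupe_free_energy(list(mk("b", -10), mk("a", -10)))
  expect_equal(rep$kept, "a")
  expect_equal(rep$removed$reason, "duplicate_free_energy")
  # all distinct -> all kept
  rep2 <- dedupe_free_energy(list(mk("a", -1), mk("b", -2), mk("c", -3)))
  expect_equal(nrow(rep2$removed), 0L)
  # ties at two different values -> one kept per value
  rep3 <- dedupe_free_energy(list(mk("d", -1), mk("c", -1),
                                  mk("b", -2), mk("a", -2)))
  expect_setequal(rep3$kept, c("c", "a"))
  expect_equal(nrow(rep3$removed), 2L)
})

test_that("stoichiometry keys are canonical Hill-like formulas", {
  expect_equal(stoichiometry_key(make_ethanol()), "C2H6O1")
  expect_equal(stoichiometry_key(make_ammonia()), "H3N1")
  eth <- make_ethanol()
  expect_equal(stoichiometry_key(permute_atoms(eth, sample(n_atoms(eth)))),
               "C2H6O1")
})

test_that("split rules: singletons unassigned, pairs split one-and-one", {
  one <- list(make_ammonia())
  s1 <- split_by_stoichiometry(one, seed = 1)
  expect_equal(length(s1$unassigned), 1L)
  expect_equal(length(s1$train), 0L)
  expect_equal(length(s1$test), 0L)

  w1 <- make_water(); w1$id <- "w1"
  w2 <- make_water(); w2$id <- "w2"
  s2 <- split_by_stoichiometry(list(w1, w2), seed = 1)
  expect_equal(length(s2$train), 1L)
  expect_equal(length(s2$test), 1L)
  expect_setequal(c(s2$train, s2$test), c("w1", "w2"))
})

test_that("split is a deterministic partition and group sizes are stable across seeds", {
  ds <- shared_toy()
  s1 <- split_by_stoichiometry(ds$molecules, seed = 9)
  s2 <- split_by_stoichiometry(ds$molecules, seed = 9)
  expect_identical(s1, s2)
  ids <- vapply(ds$molecules, function(m) m$id, character(1))
  expect_setequal(c(s1$train, s1$test, s1$unassigned), ids)
  expect_equal(length(intersect(s1$train, s1$test)), 0L)

  s3 <- split_by_stoichiometry(ds$molecules, seed = 10)
  expect_equal(length(s3$train), length(s1$train))
  expect_equal(length(s3$test), length(s1$test))
  expect_equal(length(s3$unassigned), length(s1$unassigned))
  expect_false(identical(sort(s3$test), sort(s1$test)))
})

test_that("aggregate test share lands near the nominal fraction on a large pool", {
  # 100 stoichiometry groups of 100 molecules each, distinguished by H count
  pool <- list()
  k <- 0L
  for (g in 1:100) {
    atoms <- tibble::tibble(element = rep("H", g),
                            x = seq_len(g) * 2, y = 0, z = 0)
    for (r in 1:100) {
      k <- k + 1L
      pool[[k]] <- molecule(sprintf("g%03d_m%03d", g, r), atoms)
    }
  }
  s <- split_by_stoichiometry(pool, test_fraction = 0.33, seed = 4)
  share <- length(s$test) / length(pool)
  expect_gte(share, 0.31)
  expect_lte(share, 0.35)
  # ceil-based allocation: slightly more than the nominal 33%
  expect_gte(share, 0.33)
})
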