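fx <- make_count_fixture(300, 12, noise_sd = 0.5, seed = 21)
tr <- 1:240
te <- 241:300

test_that("linear regression recovers the generating coefficients", {
  m <- train_energy_model(fx$X[tr, ], fx$y[tr], model_config("mlr", lambda = 1e-10))
  est <- tidy(m)
  expect_equal(est$term[1], "(Intercept)")
  rel <- abs(est$estimate[-1] - fx$beta[-1]) / abs(fx$beta[-1])
  expect_lt(max(rel), 0.01)
  # noiseless data: exact recovery
  fx0 <- make_count_fixture(200, 8, noise_sd = 0, seed = 22)
  m0 <- train_energy_model(fx0$X, fx0$y, model_config("mlr", lambda = 1e-12))
  expect_equal(tidy(m0)$estimate, as.numeric(fx0$beta), tolerance = 1e-6)
})

test_that("kernel ridge regression interpolates its training set at tiny alpha", {
  # interpolation regime: a local kernel (width near the median pairwise
  # distance) and vanishing regularisation reproduce the training targets
  d <- as.numeric(dist(molkde:::feature_matrix(fx$X[tr, ])))
  med <- median(d[d > 0])
  m <- train_energy_model(fx$X[tr, ], fx$y[tr],
                          model_config("krr", sigma = med, alpha = 1e-10))
  expect_lt(evaluate_mae(predict(m, fx$X[tr, ]), fx$y[tr]), 1e-6)
})

test_that("the RBF kernel matches an independent kernel implementation", {
  skip_if_not_installed("kernlab")
  X <- feature_matrix(fx$X[1:40, ])
  sigma <- 50
  ours <- unname(molkde:::rbf_kernel(X, X, sigma))
  theirs <- matrix(kernlab::kernelMatrix(
    kernlab::rbfdot(sigma = 1 / (2 * sigma^2)), X), nrow(X))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("all families reproduce a constant target", {
  yconst <- rep(-7.25, length(tr))
  for (cfg in list(model_config("krr", alpha = 1e-8),
                   model_config("mlr"),
                   model_config("nn", epochs = 60, hidden_width = 16),
                   model_config("rfr", n_trees = 100))) {
    m <- train_energy_model(fx$X[tr, ], yconst, cfg)
    expect_lt(max(abs(predict(m, fx$X[te, ]) - -7.25)), 1e-3)
  }
})

test_that("prediction handles empty and duplicated inputs and guards the dictionary", {
  m <- train_energy_model(fx$X[tr, ], fx$y[tr], model_config("krr", alpha = 1e-8))
  expect_length(predict(m, fx$X[0, ]), 0L)
  dup <- fx$X[c(5, 5), ]
  p <- predict(m, dup)
  expect_equal(p[1], p[2])
  expect_error(predict(m, fx$X[, 1:6]), "length mismatch")

  ds <- shared_toy()
  eth <- perceive_bonds(make_ethanol())
  enc <- encode_molecules(list(eth), ds$dictionary)
  mm <- train_energy_model(enc, -1, model_config("mlr"),
                           dictionary = ds$dictionary)
  other <- build_dictionary(ds$molecules[1:10])
  expect_error(predict(mm, enc, dictionary = other), "fingerprint")
})

test_that("KRR is invariant under permutation of training rows and robust to duplicates", {
  Xs <- fx$X[tr, ]
  m1 <- train_energy_model(Xs, fx$y[tr], model_config("krr", alpha = 1e-8))
  perm <- sample(length(tr))
  m2 <- train_energy_model(Xs[perm, ], fx$y[tr][perm],
                           model_config("krr", alpha = 1e-8))
  p1 <- predict(m1, fx$X[te, ])
  p2 <- predict(m2, fx$X[te, ])
  expect_equal(p1, p2, tolerance = 1e-6)

  # appending a duplicate of an existing training point barely moves anything
  Xd <- dplyr::bind_rows(Xs, Xs[1, ])
  m3 <- train_energy_model(Xd, c(fx$y[tr], fx$y[tr][1]),
                           model_config("krr", alpha = 1e-8))
  expect_equal(predict(m3, fx$X[te, ]), p1, tolerance = 1e-3)
})

test_that("nan inputs and length mismatches are refused", {
  bad <- feature_matrix(fx$X[tr, ])
  bad[1, 1] <- NaN
  expect_error(train_energy_model(bad, fx$y[tr], model_config("mlr")),
               "non-finite")
  expect_error(train_energy_model(fx$X[tr, ], fx$y[1:10], model_config("mlr")),
               "nrow")
})

test_that("mean absolute error behaves as the metric definition demands", {
  expect_equal(evaluate_mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(evaluate_mae(c(3, 4), c(1, 2)), 2)
  expect_equal(evaluate_mae(c(1, -3), c(0, 0)), 2)
  expect_error(evaluate_mae(numeric(), numeric()), "non-empty")
})

test_that("learning curves are seeded, exhaustive at full size, and improve with data", {
  ds_y <- fx$y
  lc1 <- learning_curve(fx$X[tr, ], ds_y[tr], fx$X[te, ], ds_y[te],
                        sizes = c(60, 240), config = model_config("krr", alpha = 1e-8),
                        seed = 31)
  lc2 <- learning_curve(fx$X[tr, ], ds_y[tr], fx$X[te, ], ds_y[te],
                        sizes = c(60, 240), config = model_config("krr", alpha = 1e-8),
                        seed = 31)
  expect_identical(lc1, lc2)
  # full-pool entry equals a direct train/evaluate call
  direct <- train_energy_model(fx$X[tr, ], ds_y[tr],
                               model_config("krr", alpha = 1e-8))
  expect_equal(lc1$mae[lc1$size == 240],
               evaluate_mae(predict(direct, fx$X[te, ]), ds_y[te]),
               tolerance = 1e-9)
  # median over 3 seeds: more data never hurts on this synthetic task
  med <- sapply(c(50, 200), function(s) {
    median(sapply(1:3, function(sd) {
      learning_curve(fx$X[tr, ], ds_y[tr], fx$X[te, ], ds_y[te],
                     sizes = s, config = model_config("krr", alpha = 1e-8),
                     seed = sd)$mae
    }))
  })
  expect_lt(med[2], med[1])
  expect_error(
    learning_curve(fx$X[tr, ], ds_y[tr], fx$X[te, ], ds_y[te], sizes = 1e5),
    "exceeds")
})
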