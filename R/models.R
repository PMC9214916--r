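#' Model configuration
#'
#' One constructor per regressor family, with the published configurations
#' as defaults where the source pins them.
#'
#' * `krr`: kernel ridge regression with the RBF kernel
#'   `K(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`. `alpha` is the ridge
#'   regulariser (default 1e-11, the best-performing value); `sigma = NULL`
#'   selects the median pairwise training distance at fit time.
#' * `nn`: a two-hidden-layer ReLU multilayer perceptron with a linear
#'   output, mean-squared-error loss, batch size 64, uniform weight
#'   initialisation, and a choice of adam/sgd/rmsprop optimisers.
#' * `mlr`: L2-regularised linear least squares, solved exactly in closed
#'   form (the normal equations of the ridge objective).
#' * `rfr`: random forest regression via ranger.
#'
#' @param family One of `"krr"`, `"nn"`, `"mlr"`, `"rfr"`.
#' @param sigma,alpha KRR kernel width and regulariser.
#' @param hidden_width,epochs,batch_size,optimizer,learning_rate,l2 NN
#'   settings (two hidden layers of `hidden_width` units each).
#' @param lambda MLR ridge penalty.
#' @param n_trees,max_depth,max_features,max_samples RFR settings
#'   (`NULL` = ranger defaults; `max_features = NULL` uses all features,
#'   matching the best published setting).
#' @param standardize Z-score features before fitting. Off by default for
#'   krr/mlr/rfr: the 100-weighted atom counts are an intentional scale
#'   signal in kernel distances. The NN always standardises internally for
#'   optimisation (predictions are returned on the original scale).
#' @param seed Integer seed for the stochastic families (nn, rfr).
#' @return A list of settings, class `model_config`.
#' @export
model_config <- function(family = c("krr", "nn", "mlr", "rfr"),
                         sigma = NULL, alpha = 1e-11,
                         hidden_width = 64L, epochs = 300L, batch_size = 64L,
                         optimizer = c("adam", "sgd", "rmsprop"),
                         learning_rate = 1e-3, l2 = 0,
                         lambda = 1e-8,
                         n_trees = 500L, max_depth = NULL,
                         max_features = NULL, max_samples = 1,
                         standardize = FALSE, seed = 1L) {
  family <- match.arg(family)
  optimizer <- match.arg(optimizer)
  stopifnot(alpha > 0, is.null(sigma) || sigma > 0, batch_size >= 1,
            l2 >= 0, lambda >= 0)
  structure(list(
    family = family, sigma = sigma, alpha = alpha,
    hidden_width = as.integer(hidden_width), epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), optimizer = optimizer,
    learning_rate = learning_rate, l2 = l2, lambda = lambda,
    n_trees = as.integer(n_trees), max_depth = max_depth,
    max_features = max_features, max_samples = max_samples,
    standardize = standardize, seed = as.integer(seed)
  ), class = "model_config")
}

#' Train an energy regressor on encoded features
#'
#' @param X Feature tibble from [encode_molecules()] (a `molecule_id`
#'   column is dropped) or a numeric matrix.
#' @param y Numeric target energies, kcal/mol, one per row of `X`.
#' @param config A [model_config()].
#' @param dictionary Optional `feature_dictionary`; its fingerprint is
#'   stored and checked at prediction time so a model can never be applied
#'   to vectors from a different representation.
#' @param target Label for what is being predicted
#'   (`"electronic"`/`"free"`); metadata only.
#' @return An `energy_model`.
#' @export
train_energy_model <- function(X, y, config = model_config("krr"),
                               dictionary = NULL, target = "electronic") {
  Xm <- feature_matrix(X)
  y <- as.numeric(y)
  if (nrow(Xm) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (any(!is.finite(Xm)) || any(!is.finite(y))) {
    stop("non-finite values in X or y", call. = FALSE)
  }
  ctr <- rep(0, ncol(Xm)); scl <- rep(1, ncol(Xm))
  if (isTRUE(config$standardize)) {
    ctr <- colMeans(Xm)
    scl <- apply(Xm, 2, stats::sd); scl[scl == 0 | !is.finite(scl)] <- 1
    Xm <- sweep(sweep(Xm, 2, ctr), 2, scl, "/")
  }
  fit <- switch(config$family,
    krr = fit_krr(Xm, y, config),
    mlr = fit_mlr(Xm, y, config),
    nn = fit_mlp(Xm, y, config),
    rfr = fit_rfr(Xm, y, config)
  )
  structure(list(
    family = config$family, fit = fit, config = config,
    n_features = ncol(Xm), n_train = nrow(Xm),
    feature_names = colnames(Xm),
    center = ctr, scale = scl,
    fingerprint = if (!is.null(dictionary)) dictionary$fingerprint else NA_character_,
    target = target
  ), class = "energy_model")
}

fit_krr <- function(X, y, config) {
  sigma <- config$sigma
  if (is.null(sigma)) {
    # wide default: energies are smooth, near-additive functions of the
    # counts, so kernels far wider than the median pairwise distance
    # (approaching the linear-kernel limit) beat the bare median heuristic
    d <- as.numeric(stats::dist(X))
    d <- d[d > 0]
    sigma <- if (length(d)) 100 * stats::median(d) else 1
  }
  K <- rbf_kernel(X, X, sigma)
  w <- tryCatch(
    solve(K + diag(config$alpha, nrow(K)), y),
    error = function(e) stop(
      "singular kernel system at alpha = ", config$alpha,
      "; increase alpha (its role is to regularise this solve)", call. = FALSE)
  )
  list(X = X, weights = as.numeric(w), sigma = sigma, alpha = config$alpha)
}

rbf_kernel <- function(A, B, sigma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

fit_mlr <- function(X, y, config) {
  # ridge objective solved exactly via SVD (stable when p > n or columns
  # are collinear; the unpenalised intercept is handled by centring)
  xm <- colMeans(X); ym <- mean(y)
  sv <- svd(sweep(X, 2, xm))
  d <- sv$d
  shrink <- ifelse(d < max(d, 0) * 1e-12, 0, d / (d^2 + config$lambda))
  beta <- sv$v %*% (shrink * crossprod(sv$u, y - ym))
  coef <- stats::setNames(c(ym - sum(xm * beta), as.numeric(beta)),
                          c("(Intercept)", colnames(X)))
  list(coefficients = coef)
}

fit_rfr <- function(X, y, config) {
  df <- as.data.frame(X)
  names(df) <- make.names(names(df))
  df$.y <- y
  ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = config$n_trees,
    mtry = if (is.null(config$max_features)) ncol(X) else config$max_features,
    max.depth = if (is.null(config$max_depth)) 0 else config$max_depth,
    sample.fraction = config$max_samples,
    replace = TRUE, seed = config$seed, num.threads = 1
  )
}

# ---- two-hidden-layer ReLU MLP, trained with minibatch adam/sgd/rmsprop ----

fit_mlp <- function(X, y, config) {
  n <- nrow(X); p <- ncol(X); h <- config$hidden_width
  # internal standardisation of inputs and targets (optimisation only)
  xc <- colMeans(X); xs <- apply(X, 2, stats::sd)
  xs[xs == 0 | !is.finite(xs)] <- 1
  Xs <- sweep(sweep(X, 2, xc), 2, xs, "/")
  yc <- mean(y); ys <- stats::sd(y); if (!is.finite(ys) || ys == 0) ys <- 1
  ys_ <- (y - yc) / ys

  glorot <- function(fi, fo) {
    r <- sqrt(6 / (fi + fo))
    matrix(stats::runif(fi * fo, -r, r), fi, fo)
  }
  with_preserved_seed({
    set.seed(config$seed)
    # zero-output initialisation: the net starts at the target mean, which
    # also makes constant targets an exact fixed point
    par <- list(W1 = glorot(p, h), b1 = rep(0, h),
                W2 = glorot(h, h), b2 = rep(0, h),
                W3 = matrix(0, h, 1), b3 = 0)
    batch_order <- lapply(seq_len(config$epochs), function(e) sample(n))
  })
  opt_state <- lapply(par, function(w) list(m = w * 0, v = w * 0))
  lr0 <- config$learning_rate; l2 <- config$l2
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  step <- 0L
  for (e in seq_len(config$epochs)) {
    # cosine decay from the configured rate to 1/1000 of it
    lr <- lr0 / 1000 + 0.5 * (lr0 - lr0 / 1000) *
      (1 + cos(pi * (e - 1) / config$epochs))
    ord <- batch_order[[e]]
    for (start in seq(1, n, by = config$batch_size)) {
      ix <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- Xs[ix, , drop = FALSE]; yb <- ys_[ix]
      nb <- length(ix)
      # forward
      a1 <- xb %*% par$W1 + matrix(par$b1, nb, length(par$b1), byrow = TRUE)
      z1 <- pmax(a1, 0)
      a2 <- z1 %*% par$W2 + matrix(par$b2, nb, length(par$b2), byrow = TRUE)
      z2 <- pmax(a2, 0)
      out <- as.numeric(z2 %*% par$W3 + par$b3)
      # backward (MSE)
      dout <- matrix(2 * (out - yb) / nb, ncol = 1)
      gW3 <- crossprod(z2, dout); gb3 <- sum(dout)
      dz2 <- (dout %*% t(par$W3)) * (a2 > 0)
      gW2 <- crossprod(z1, dz2); gb2 <- colSums(dz2)
      dz1 <- (dz2 %*% t(par$W2)) * (a1 > 0)
      gW1 <- crossprod(xb, dz1); gb1 <- colSums(dz1)
      grads <- list(W1 = gW1 + l2 * par$W1, b1 = gb1,
                    W2 = gW2 + l2 * par$W2, b2 = gb2,
                    W3 = gW3 + l2 * par$W3, b3 = gb3)
      step <- step + 1L
      for (nm in names(par)) {
        g <- grads[[nm]]
        st <- opt_state[[nm]]
        upd <- switch(config$optimizer,
          sgd = lr * g,
          rmsprop = {
            st$v <- 0.9 * st$v + 0.1 * g^2
            opt_state[[nm]] <- st
            lr * g / (sqrt(st$v) + eps)
          },
          adam = {
            st$m <- b1m * st$m + (1 - b1m) * g
            st$v <- b2m * st$v + (1 - b2m) * g^2
            opt_state[[nm]] <- st
            mhat <- st$m / (1 - b1m^step)
            vhat <- st$v / (1 - b2m^step)
            lr * mhat / (sqrt(vhat) + eps)
          }
        )
        par[[nm]] <- par[[nm]] - upd
      }
    }
  }
  list(par = par, x_center = xc, x_scale = xs, y_center = yc, y_scale = ys)
}

predict_mlp <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$x_center), 2, fit$x_scale, "/")
  nb <- nrow(Xs)
  z1 <- pmax(Xs %*% fit$par$W1 +
               matrix(fit$par$b1, nb, length(fit$par$b1), byrow = TRUE), 0)
  z2 <- pmax(z1 %*% fit$par$W2 +
               matrix(fit$par$b2, nb, length(fit$par$b2), byrow = TRUE), 0)
  as.numeric(z2 %*% fit$par$W3 + fit$par$b3) * fit$y_scale + fit$y_center
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> %s, %d features, %d training molecules (%s energy)\n",
              x$family, x$n_features, x$n_train, x$target))
  invisible(x)
}

#' Predict energies from an energy model
#'
#' @param object An `energy_model`.
#' @param X Feature tibble or matrix with the same columns as training.
#' @param dictionary Optional `feature_dictionary`; when both the model
#'   and this argument carry a fingerprint they must match.
#' @param ... Unused.
#' @return Numeric vector of predicted energies, kcal/mol, in row order.
#' @export
predict.energy_model <- function(object, X, dictionary = NULL, ...) {
  Xm <- feature_matrix(X)
  if (nrow(Xm) == 0) return(numeric())
  if (ncol(Xm) != object$n_features) {
    stop("feature length mismatch: model expects ", object$n_features,
         ", got ", ncol(Xm), call. = FALSE)
  }
  if (!is.null(dictionary) && !is.na(object$fingerprint) &&
      !identical(dictionary$fingerprint, object$fingerprint)) {
    stop("feature dictionary fingerprint mismatch", call. = FALSE)
  }
  Xm <- sweep(sweep(Xm, 2, object$center), 2, object$scale, "/")
  switch(object$family,
    krr = {
      K <- rbf_kernel(Xm, object$fit$X, object$fit$sigma)
      as.numeric(K %*% object$fit$weights)
    },
    mlr = {
      as.numeric(cbind(1, Xm) %*% object$fit$coefficients)
    },
    nn = predict_mlp(object$fit, Xm),
    rfr = {
      df <- as.data.frame(Xm)
      names(df) <- make.names(object$feature_names)
      as.numeric(stats::predict(object$fit, data = df,
                                num.threads = 1)$predictions)
    }
  )
}

#' Mean absolute error
#' @param pred,truth Equal-length numeric vectors, kcal/mol.
#' @return Scalar MAE, kcal/mol.
#' @export
evaluate_mae <- function(pred, truth) {
  if (!length(pred) || length(pred) != length(truth)) {
    stop("pred and truth must be non-empty and of equal length", call. = FALSE)
  }
  mean(abs(pred - truth))
}

#' Learning curve: test MAE as a function of training-set size
#'
#' For each size a random (seeded) subset of the training pool is drawn,
#' the model trained on it, and the MAE measured on the fixed test set.
#'
#' @param train_X,train_y Training pool features/targets.
#' @param test_X,test_y Fixed evaluation set.
#' @param sizes Integer vector of training sizes (each <= pool size).
#' @param config A [model_config()].
#' @param seed Integer seed for the subset draws.
#' @return A tibble with columns `size`, `mae`.
#' @export
learning_curve <- function(train_X, train_y, test_X, test_y,
                           sizes, config = model_config("krr"), seed = 1L) {
  Xm <- feature_matrix(train_X)
  if (any(sizes > nrow(Xm))) {
    stop("a requested size exceeds the training pool", call. = FALSE)
  }
  subsets <- with_preserved_seed({
    set.seed(as.integer(seed))
    lapply(sizes, function(s) sort(sample(nrow(Xm), s)))
  })
  mae <- vapply(subsets, function(ix) {
    fit <- train_energy_model(Xm[ix, , drop = FALSE], train_y[ix], config)
    evaluate_mae(predict(fit, test_X), test_y)
  }, numeric(1))
  tibble::tibble(size = as.integer(sizes), mae = mae)
}

#' @export
tidy.energy_model <- function(x, ...) {
  switch(x$family,
    mlr = tibble::tibble(term = names(x$fit$coefficients),
                         estimate = as.numeric(x$fit$coefficients)),
    krr = tibble::tibble(term = sprintf("weight_%d", seq_along(x$fit$weights)),
                         estimate = x$fit$weights),
    stop("tidy() is defined for the mlr and krr families", call. = FALSE)
  )
}

#' @export
glance.energy_model <- function(x, ...) {
  tibble::tibble(
    family = x$family, n_train = x$n_train, n_features = x$n_features,
    target = x$target,
    sigma = if (x$family == "krr") x$fit$sigma else NA_real_,
    alpha = if (x$family == "krr") x$fit$alpha else NA_real_
  )
}
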