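#' Run the full pipeline on a set of molecules
#'
#' Composes the package end to end: curation filters, optional
#' free-energy deduplication, stoichiometry-grouped split, optional
#' distorted-replicate augmentation of the training set, feature
#' dictionary fit on the training molecules only (no test leakage —
#' `dict_on_all = TRUE` restores the literal fit-on-everything
#' behaviour), encoding, model training, and MAE evaluation on the test
#' set. Fully deterministic given the seeds in `config`.
#'
#' @param molecules List of bonded [molecule()]s carrying targets.
#' @param config Named list; the defaults of [pipeline_config()] are
#'   filled in for anything omitted.
#' @param out_dir Optional directory: when given, the dictionary JSON,
#'   predictions CSV, and a run manifest (JSON, incl. all seeds and the
#'   effective config) are written there.
#' @return A list of class `pipeline_result`: `filter_report`, `split`,
#'   `dictionary`, `model`, `predictions` (tibble id/truth/predicted),
#'   `train_mae`, `test_mae`, `config`.
#' @export
run_pipeline <- function(molecules, config = pipeline_config(), out_dir = NULL) {
  config <- utils::modifyList(pipeline_config(), config)
  target <- match.arg(config$target, c("electronic", "free"))

  report <- apply_filters(molecules, config$filter)
  mols <- kept_molecules(molecules, report)
  if (target == "free" && isTRUE(config$dedupe_free_energy)) {
    dd <- dedupe_free_energy(mols)
    report$removed <- dplyr::bind_rows(report$removed, dd$removed)
    report$kept <- setdiff(report$kept, dd$removed$id)
    mols <- kept_molecules(mols, dd)
  }
  if (!length(mols)) stop("pipeline: no molecules survive curation", call. = FALSE)

  split <- split_by_stoichiometry(mols, config$test_fraction, config$split_seed)
  ids <- vapply(mols, function(m) m$id, character(1))
  train <- mols[ids %in% split$train]
  test <- mols[ids %in% split$test]
  if (!length(train) || !length(test)) {
    stop("pipeline: empty train or test set after splitting", call. = FALSE)
  }

  if (length(config$distortion_deltas)) {
    train <- augment_training_set(train, config$distortion_deltas,
                                  config$replicates_per_delta,
                                  seed = config$distortion_seed)
  }

  dict_source <- if (isTRUE(config$dict_on_all)) c(train, test) else train
  dict <- build_dictionary(dict_source, config$featurizer)

  Xtr <- encode_molecules(train, dict)
  Xte <- encode_molecules(test, dict)
  ytr <- vapply(train, function(m) {
    if (target == "electronic") m$electronic_energy else m$free_energy
  }, numeric(1))
  yte <- vapply(test, function(m) {
    if (target == "electronic") m$electronic_energy else m$free_energy
  }, numeric(1))
  if (any(is.na(ytr)) || any(is.na(yte))) {
    stop("pipeline: missing ", target, " energies on some molecules",
         call. = FALSE)
  }

  model <- train_energy_model(Xtr, ytr, config$model, dictionary = dict,
                              target = target)
  pred_tr <- predict(model, Xtr, dictionary = dict)
  pred_te <- predict(model, Xte, dictionary = dict)
  result <- structure(list(
    filter_report = report,
    split = split,
    dictionary = dict,
    model = model,
    predictions = tibble::tibble(
      id = Xte$molecule_id, truth = yte, predicted = pred_te
    ),
    train_mae = evaluate_mae(pred_tr, ytr),
    test_mae = evaluate_mae(pred_te, yte),
    config = config
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dictionary(dict, file.path(out_dir, "dictionary.json"))
    utils::write.csv(result$predictions,
                     file.path(out_dir, "predictions.csv"), row.names = FALSE)
    manifest <- list(
      config = config_manifest(config),
      dictionary_fingerprint = dict$fingerprint,
      n_train = length(train), n_test = length(test),
      train_mae = result$train_mae, test_mae = result$test_mae
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @rdname run_pipeline
#' @param target `"electronic"` or `"free"`.
#' @param filter A [filter_config()].
#' @param featurizer A [featurizer_config()].
#' @param model A [model_config()].
#' @param test_fraction,split_seed Split settings.
#' @param distortion_deltas Numeric vector (empty = no augmentation).
#' @param replicates_per_delta,distortion_seed Augmentation settings.
#' @param dedupe_free_energy Drop exact free-energy duplicates before the
#'   free-energy split (default TRUE when `target = "free"`).
#' @param dict_on_all Fit the dictionary on train + test instead of train
#'   only (default FALSE).
#' @export
pipeline_config <- function(target = "electronic",
                            filter = filter_config(),
                            featurizer = featurizer_config(),
                            model = model_config("krr", alpha = 1e-8),
                            test_fraction = 0.33, split_seed = 1L,
                            distortion_deltas = numeric(),
                            replicates_per_delta = 1L, distortion_seed = 1L,
                            dedupe_free_energy = TRUE,
                            dict_on_all = FALSE) {
  list(target = target, filter = filter, featurizer = featurizer,
       model = model, test_fraction = test_fraction,
       split_seed = as.integer(split_seed),
       distortion_deltas = distortion_deltas,
       replicates_per_delta = as.integer(replicates_per_delta),
       distortion_seed = as.integer(distortion_seed),
       dedupe_free_energy = dedupe_free_energy,
       dict_on_all = dict_on_all)
}

config_manifest <- function(config) {
  lapply(config, function(x) if (is.list(x)) unclass(x) else x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %s energy, %s model\n  train MAE %.4f / test MAE %.4f kcal/mol (%d test molecules)\n",
    x$model$target, x$model$family, x$train_mae, x$test_mae,
    nrow(x$predictions)))
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    family = x$model$family, target = x$model$target,
    n_features = x$dictionary$n_features,
    n_train = x$model$n_train, n_test = nrow(x$predictions),
    train_mae = x$train_mae, test_mae = x$test_mae
  )
}
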