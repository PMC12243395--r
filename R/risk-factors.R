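#' Configuration for the risk-factor model
#'
#' Bundles the hyperparameter grid and pipeline settings for
#' [run_risk_factor_analysis()]. The grid covers the regularised
#' gradient-boosting hyperparameters: `nrounds` (trees), `eta` (learning
#' rate), `max_depth`, `min_child_weight`, `gamma` (minimum split gain) and
#' `reg_alpha` (L1 regularisation). The class-imbalance weight
#' (`scale_pos_weight`) is not tuned: it is fixed to the inverse class ratio
#' of the training data.
#'
#' @param grid Named list of hyperparameter value vectors; crossed
#'   exhaustively.
#' @param cv_folds Cross-validation folds for tuning (default 5).
#' @param test_fraction Held-out test fraction (default 0.2).
#' @param missingness_threshold Children missing more than this fraction of
#'   features are removed (default 0.30).
#' @param knn_k Neighbours for KNN imputation (default 5).
#' @param permutation_repeats Shuffles per feature for permutation importance
#'   (default 50).
#' @param seed Integer seed for the split, CV folds and permutations.
#' @return List of class `model_config`.
#' @export
model_config <- function(grid = list(nrounds = 50, eta = c(0.1, 0.3),
                                     max_depth = c(2, 4), min_child_weight = 1,
                                     gamma = 0, reg_alpha = c(0, 0.5)),
                         cv_folds = 5, test_fraction = 0.2,
                         missingness_threshold = 0.30, knn_k = 5,
                         permutation_repeats = 50, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, cv_folds >= 2,
            missingness_threshold >= 0, missingness_threshold <= 1,
            knn_k >= 1, permutation_repeats >= 1)
  need <- c("nrounds", "eta", "max_depth", "min_child_weight", "gamma", "reg_alpha")
  missing <- setdiff(need, names(grid))
  if (length(missing) > 0) stopf("grid lacks: %s", paste(missing, collapse = ", "))
  if (any(vapply(grid, length, integer(1)) == 0)) stopf("empty hyperparameter grid")
  structure(list(grid = grid, cv_folds = cv_folds, test_fraction = test_fraction,
                 missingness_threshold = missingness_threshold, knn_k = knn_k,
                 permutation_repeats = permutation_repeats, seed = as.integer(seed)),
            class = "model_config")
}

#' Build a transition-of-interest vs control-transition contrast
#'
#' For one significant transition cell, children from the source cluster who
#' moved to the destination of interest form the positive class (outcome 1,
#' "transition of interest"); children from the same source cluster who moved
#' to the control destination (the non-elevated group) form the negative
#' class ("control transition"). Children going anywhere else are excluded.
#'
#' @param linked Linked table from [link_waves()].
#' @param source Source group label.
#' @param destination Destination-of-interest group label.
#' @param control Control destination (default `"non_elevated"`).
#' @return Data frame `child_id`, `outcome` (1/0) of class
#'   `transition_contrast`, with class counts logged as attributes.
#' @export
build_contrast <- function(linked, source, destination, control = "non_elevated") {
  sub <- linked[linked$source == source &
                  linked$destination %in% c(destination, control), , drop = FALSE]
  out <- data.frame(child_id = sub$child_id,
                    outcome = as.integer(sub$destination == destination))
  n_pos <- sum(out$outcome == 1); n_neg <- sum(out$outcome == 0)
  if (n_pos == 0) stopf("empty class: no children transition to '%s'", destination)
  if (n_neg == 0) stopf("empty class: no children transition to control '%s'", control)
  structure(out, source = source, destination = destination, control = control,
            n_pos = n_pos, n_neg = n_neg,
            class = c("transition_contrast", "data.frame"))
}

#' Drop children missing too many features
#'
#' A child is retained iff the missing fraction over the feature columns is
#' at most `threshold` (the rule excludes children missing *more than* the
#' threshold, so a child at exactly the threshold stays).
#'
#' @param covariates Data frame with `child_id` plus feature columns.
#' @param threshold Maximum tolerated missing fraction (default 0.30).
#' @return The retained rows of `covariates`.
#' @export
filter_missingness <- function(covariates, threshold = 0.30) {
  feats <- setdiff(names(covariates), "child_id")
  frac <- rowMeans(is.na(covariates[, feats, drop = FALSE]))
  covariates[frac <= threshold, , drop = FALSE]
}

#' Stratified train/test split
#'
#' Splits ids into disjoint train and test sets, stratified by outcome: per
#' class, `round(fraction * n_class)` ids go to the test set, so class ratios
#' are preserved within rounding. Deterministic given the seed.
#'
#' @param ids Vector of child ids.
#' @param outcomes Binary outcome per id.
#' @param fraction Test fraction (default 0.2).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors.
#' @export
split_train_test <- function(ids, outcomes, fraction = 0.2, seed = 1L) {
  stopifnot(length(ids) == length(outcomes), fraction > 0, fraction < 1)
  classes <- split(ids, outcomes)
  if (length(classes) < 2) stopf("both outcome classes must be present")
  if (any(vapply(classes, length, integer(1)) < 2))
    stopf("each class needs at least 2 members to split")
  test <- with_seed(seed, unlist(lapply(classes, function(cl) {
    sample(cl, max(1, round(fraction * length(cl))))
  }), use.names = FALSE))
  list(train = setdiff(ids, test), test = test)
}

#' K-nearest-neighbour imputation fit on the training set
#'
#' Distances are mean squared differences over the feature coordinates
#' observed in both rows; each missing cell is filled with the mean of the
#' `k` nearest *training* rows that observe that feature. The imputer is a
#' function of the training table only and is applied unchanged to both
#' tables, guarding against train/test leakage. Features missing in every
#' training row are dropped from both tables with a warning.
#'
#' @param train,test Numeric feature matrices/data frames (same columns).
#' @param k Number of donor neighbours (default 5).
#' @return List with imputed `train` and `test` matrices (no missing cells).
#' @export
impute_knn <- function(train, test, k = 5) {
  train <- as.matrix(train); test <- as.matrix(test)
  all_missing <- colSums(!is.na(train)) == 0
  if (any(all_missing)) {
    warnf("dropping features missing in every training row: %s",
          paste(colnames(train)[all_missing], collapse = ", "))
    train <- train[, !all_missing, drop = FALSE]
    test <- test[, !all_missing, drop = FALSE]
  }
  impute_one <- function(X, is_train) {
    for (i in which(rowSums(is.na(X)) > 0)) {
      row <- X[i, ]
      obs <- !is.na(row)
      diffs <- sweep(train, 2, row)
      d <- rowMeans(diffs[, obs, drop = FALSE]^2, na.rm = TRUE)
      if (is_train) d[i] <- Inf  # a row cannot donate to itself
      for (j in which(!obs)) {
        donors <- which(!is.na(train[, j]) & is.finite(d))
        donors <- donors[order(d[donors])][seq_len(min(k, length(donors)))]
        X[i, j] <- if (length(donors) > 0) mean(train[donors, j])
                   else mean(train[, j], na.rm = TRUE)
      }
    }
    X
  }
  out_test <- impute_one(test, is_train = FALSE)
  out_train <- impute_one(train, is_train = TRUE)
  list(train = out_train, test = out_test)
}

#' Min-max scaling fit on the training set
#'
#' Per feature, `(x - train_min) / (train_max - train_min)`. Training columns
#' span `[0, 1]`; test values may fall outside. A constant training feature
#' is mapped to 0 with a warning.
#'
#' @param train,test Numeric feature matrices (imputed).
#' @return List with scaled `train` and `test` plus the `min`/`range` used.
#' @export
scale_minmax <- function(train, test) {
  train <- as.matrix(train); test <- as.matrix(test)
  mins <- apply(train, 2, min)
  rng <- apply(train, 2, max) - mins
  const <- rng == 0
  if (any(const)) {
    warnf("constant training features mapped to 0: %s",
          paste(colnames(train)[const], collapse = ", "))
    rng[const] <- 1
  }
  scale_it <- function(X) sweep(sweep(X, 2, mins), 2, rng, "/")
  list(train = scale_it(train), test = scale_it(test), min = mins, range = rng)
}

binary_metrics <- function(truth, prob, cutoff = 0.5) {
  pred <- as.integer(prob > cutoff)
  acc <- mean(pred == truth)
  tp <- sum(pred == 1 & truth == 1)
  prec <- if (sum(pred == 1) > 0) tp / sum(pred == 1) else 0
  rec <- if (sum(truth == 1) > 0) tp / sum(truth == 1) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = acc, f1 = f1)
}

stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

fit_xgb <- function(x, y, params, nrounds) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1)
  xgboost::xgb.train(params = c(params, list(objective = "binary:logistic",
                                             nthread = 1)),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}

predict_xgb <- function(model, x) {
  stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x), nthread = 1))
}

#' Tune the gradient-boosted classifier by grid search
#'
#' Exhaustive search over the config's hyperparameter grid with stratified
#' k-fold cross-validation on the training sample; the selection score is the
#' unweighted mean of accuracy and F1 averaged over folds. The
#' class-imbalance weight `scale_pos_weight` is fixed to
#' `n_negative / n_positive` of the training outcomes. Deterministic given
#' the config seed; grid ties resolve to the earliest grid row.
#'
#' @param x_train Scaled training feature matrix.
#' @param y_train Binary training outcomes.
#' @param config A [model_config()].
#' @return List with `model` (fit on the full training set at the winning
#'   configuration), `best_params`, `scale_pos_weight` and `cv_table`.
#' @export
tune_model <- function(x_train, y_train, config) {
  if (length(unique(y_train)) < 2) stopf("training outcomes must contain both classes")
  grid <- do.call(expand.grid, c(config$grid, KEEP.OUT.ATTRS = FALSE))
  spw <- sum(y_train == 0) / sum(y_train == 1)
  fold <- stratified_folds(y_train, config$cv_folds, config$seed)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- list(eta = grid$eta[g], max_depth = grid$max_depth[g],
                   min_child_weight = grid$min_child_weight[g],
                   gamma = grid$gamma[g], alpha = grid$reg_alpha[g],
                   scale_pos_weight = spw)
    fold_scores <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- fold != f
      if (length(unique(y_train[tr])) < 2) return(NA_real_)
      m <- fit_xgb(x_train[tr, , drop = FALSE], y_train[tr], params, grid$nrounds[g])
      mean(binary_metrics(y_train[!tr], predict_xgb(m, x_train[!tr, , drop = FALSE])))
    }, numeric(1))
    scores[g] <- mean(fold_scores, na.rm = TRUE)
  }
  best <- which.max(scores)
  best_params <- list(eta = grid$eta[best], max_depth = grid$max_depth[best],
                      min_child_weight = grid$min_child_weight[best],
                      gamma = grid$gamma[best], alpha = grid$reg_alpha[best],
                      scale_pos_weight = spw)
  model <- fit_xgb(x_train, y_train, best_params, grid$nrounds[best])
  list(model = model, best_params = c(best_params, nrounds = grid$nrounds[best]),
       scale_pos_weight = spw,
       cv_table = cbind(grid, cv_score = scores))
}

#' Per-feature gain importance of a fitted ensemble
#'
#' Gain is the total improvement in the split objective attributed to a
#' feature's splits (reported as each feature's share of the total).
#' Features the ensemble never splits on have gain exactly 0.
#'
#' @param model A fitted xgboost model.
#' @param feature_names All feature names (so unused features appear with 0).
#' @return Named nonnegative numeric vector over `feature_names`.
#' @export
gain_importance <- function(model, feature_names) {
  imp <- xgboost::xgb.importance(feature_names = feature_names, model = model)
  gains <- stats::setNames(rep(0, length(feature_names)), feature_names)
  if (!is.null(imp) && nrow(imp) > 0) gains[imp$Feature] <- imp$Gain
  gains
}

#' Select features by sweeping gain-importance thresholds
#'
#' Candidate thresholds are the distinct gain values; for each, the ensemble
#' is refit on the training set using only features with gain at or above
#' the threshold, and scored on the test set by the mean of accuracy and F1.
#' The feature set with the best test score wins; ties break toward fewer
#' features. All-zero gains yield an empty selection with a warning.
#'
#' @param x_train,y_train,x_test,y_test Scaled splits.
#' @param gains Named gain vector from [gain_importance()].
#' @param params,nrounds Winning hyperparameters from [tune_model()].
#' @return List with `features`, `threshold`, `score` and the `sweep` table.
#' @export
select_by_threshold <- function(x_train, y_train, x_test, y_test, gains,
                                params, nrounds) {
  if (all(gains == 0)) {
    warnf("all gains are zero; no features selected")
    return(list(features = character(0), threshold = NA_real_,
                score = NA_real_, sweep = NULL))
  }
  thresholds <- sort(unique(gains[gains > 0]))
  sweep_rows <- lapply(thresholds, function(t) {
    feats <- names(gains)[gains >= t]
    m <- fit_xgb(x_train[, feats, drop = FALSE], y_train, params, nrounds)
    sc <- mean(binary_metrics(y_test, predict_xgb(m, x_test[, feats, drop = FALSE])))
    data.frame(threshold = t, n_features = length(feats), score = sc)
  })
  sw <- do.call(rbind, sweep_rows)
  # best score; among ties, the highest threshold = fewest features
  best <- which(sw$score == max(sw$score))
  best <- best[which.max(sw$threshold[best])]
  list(features = names(gains)[gains >= sw$threshold[best]],
       threshold = sw$threshold[best], score = sw$score[best], sweep = sw)
}

#' Permutation importance with a survival flag
#'
#' For each feature, its test-set column is shuffled `repeats` times and the
#' mean decrease in test accuracy recorded. Because every drop shares the
#' same unshuffled baseline accuracy, a chance-high baseline shifts all drops
#' upward together; the drops are therefore centred by their median (the bulk
#' of candidate features is irrelevant, so the median estimates that shared
#' offset) before being compared to a noise floor. A feature survives iff its
#' raw mean drop is strictly positive, exceeds the sampling noise of the
#' accuracy estimate itself (one standard error,
#' `sqrt(acc (1 - acc) / n_test)` — a smaller drop cannot be distinguished
#' from evaluation noise), and its centred drop exceeds the floor: the 95th
#' percentile of the centred drops of zero-gain features, or, when the
#' ensemble touches every feature, of the magnitudes of negative centred
#' drops (a shuffle that *improves* accuracy can only be chance, so the
#' negative tail calibrates the chance scale). Reproducible given the seed.
#'
#' @param model Fitted ensemble (all features).
#' @param x_test,y_test Scaled test split.
#' @param gains Named gain vector (identifies the zero-gain noise features).
#' @param repeats Shuffles per feature (default 50).
#' @param seed Integer seed.
#' @return Data frame `feature`, `mean_drop`, `survives` with attribute
#'   `noise_floor`.
#' @export
permutation_survival <- function(model, x_test, y_test, gains, repeats = 50,
                                 seed = 1L) {
  if (repeats < 1) stopf("repeats must be at least 1")
  x_test <- as.matrix(x_test)
  base_acc <- binary_metrics(y_test, predict_xgb(model, x_test))[["accuracy"]]
  feats <- colnames(x_test)
  seeds <- derive_seeds(seed, length(feats))
  drops <- vapply(seq_along(feats), function(j) {
    accs <- with_seed(seeds[j], vapply(seq_len(repeats), function(r) {
      xp <- x_test
      xp[, j] <- xp[sample.int(nrow(xp)), j]
      binary_metrics(y_test, predict_xgb(model, xp))[["accuracy"]]
    }, numeric(1)))
    base_acc - mean(accs)
  }, numeric(1))
  centred <- drops - stats::median(drops)
  zero_gain <- feats[gains[feats] == 0]
  floor_zero <- if (length(zero_gain) > 0)
    stats::quantile(centred[match(zero_gain, feats)], 0.95, names = FALSE) else 0
  neg <- -centred[centred < 0]
  floor_mirror <- if (length(neg) > 0) stats::quantile(neg, 0.95, names = FALSE) else 0
  floor <- max(floor_zero, floor_mirror, 0)
  se_acc <- sqrt(base_acc * (1 - base_acc) / nrow(x_test))
  data.frame(feature = feats, mean_drop = drops,
             survives = drops > se_acc & centred > floor) |>
    structure(noise_floor = floor, base_accuracy = base_acc, se_accuracy = se_acc)
}

#' Combine thresholding and permutation survival into genuine risk factors
#'
#' A feature is a genuine risk factor iff it was selected by the gain
#' threshold sweep AND survived permutation importance.
#'
#' @param selection Result of [select_by_threshold()].
#' @param permutation Result of [permutation_survival()].
#' @param gains Named gain vector.
#' @param metrics Named test metrics (accuracy, f1) of the final model.
#' @return Object of class `risk_factor_result`: data frame `feature`,
#'   `gain`, `mean_drop`, `selected`, `survives`, `genuine`, sorted by gain
#'   descending, with test metrics as attributes.
#' @export
genuine_risk_factors <- function(selection, permutation, gains, metrics = NULL) {
  res <- data.frame(feature = names(gains), gain = unname(gains))
  res$mean_drop <- permutation$mean_drop[match(res$feature, permutation$feature)]
  res$selected <- res$feature %in% selection$features
  res$survives <- permutation$survives[match(res$feature, permutation$feature)]
  res$genuine <- res$selected & res$survives
  res <- res[order(-res$gain), ]
  rownames(res) <- NULL
  structure(res, metrics = metrics, threshold = selection$threshold,
            class = c("risk_factor_result", "data.frame"))
}

#' Run the full risk-factor identification pipeline for one contrast
#'
#' Chains the pipeline: missingness filter, stratified 80/20 split, KNN
#' imputation and min-max scaling (both fit on the training split only),
#' grid-search tuning with 5-fold CV, gain importance, threshold sweep on the
#' test split, permutation importance, and the genuine-risk-factor
#' intersection.
#'
#' @param contrast A [build_contrast()] result.
#' @param covariates Data frame with `child_id` plus numeric/binary feature
#'   columns (factor/character columns are one-hot encoded).
#' @param config A [model_config()].
#' @return A `risk_factor_result` (see [genuine_risk_factors()]) with the
#'   fitted model, selection and permutation tables attached as attributes.
#' @export
run_risk_factor_analysis <- function(contrast, covariates, config = model_config()) {
  covariates <- encode_features(covariates)
  covariates <- filter_missingness(covariates, config$missingness_threshold)
  dat <- merge(contrast, covariates, by = "child_id")
  feats <- setdiff(names(dat), c("child_id", "outcome"))
  split <- split_train_test(dat$child_id, dat$outcome,
                            fraction = config$test_fraction, seed = config$seed)
  tr <- dat[match(split$train, dat$child_id), ]
  te <- dat[match(split$test, dat$child_id), ]
  imp <- impute_knn(tr[, feats, drop = FALSE], te[, feats, drop = FALSE],
                    k = config$knn_k)
  scl <- scale_minmax(imp$train, imp$test)
  tuned <- tune_model(scl$train, tr$outcome, config)
  gains <- gain_importance(tuned$model, colnames(scl$train))
  sel <- select_by_threshold(scl$train, tr$outcome, scl$test, te$outcome,
                             gains, tuned$best_params[names(tuned$best_params) != "nrounds"],
                             tuned$best_params$nrounds)
  perm <- permutation_survival(tuned$model, scl$test, te$outcome, gains,
                               repeats = config$permutation_repeats,
                               seed = config$seed)
  metrics <- binary_metrics(te$outcome, predict_xgb(tuned$model, scl$test))
  res <- genuine_risk_factors(sel, perm, gains, metrics)
  attr(res, "model") <- tuned$model
  attr(res, "best_params") <- tuned$best_params
  attr(res, "selection") <- sel
  attr(res, "permutation") <- perm
  attr(res, "n_train") <- nrow(tr)
  attr(res, "n_test") <- nrow(te)
  res
}

# One-hot encode factor/character covariate columns; numeric columns pass
# through. NA cells stay NA in the derived indicator columns.
encode_features <- function(covariates) {
  out <- covariates["child_id"]
  for (nm in setdiff(names(covariates), "child_id")) {
    x <- covariates[[nm]]
    if (is.numeric(x) || is.logical(x)) {
      out[[nm]] <- as.numeric(x)
    } else {
      x <- factor(x)
      for (lv in levels(x)) out[[paste0(nm, "_", lv)]] <- as.numeric(x == lv)
    }
  }
  out
}

#' @export
print.risk_factor_result <- function(x, ...) {
  m <- attr(x, "metrics")
  cat("<risk_factor_result>", sum(x$genuine), "genuine risk factor(s) of",
      nrow(x), "features\n")
  if (!is.null(m))
    cat(sprintf("  test accuracy %.3f | f1 %.3f\n", m[["accuracy"]], m[["f1"]]))
  if (any(x$genuine))
    print(as.data.frame(x[x$genuine, c("feature", "gain", "mean_drop")]), row.names = FALSE)
  invisible(x)
}
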