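# Planted-effect binary outcome over noise features.
make_risk_data <- function(n, n_noise = 10, coef = 1.5, seed = 1L,
                           causal = c("x_causal_1", "x_causal_2")) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * (n_noise + length(causal))), n)
    colnames(X) <- c(causal, paste0("noise_", seq_len(n_noise)))
    eta <- X[, causal, drop = FALSE] %*% rep(coef, length(causal))
    y <- rbinom(n, 1, plogis(eta))
    list(x = X, y = as.integer(y),
         covariates = data.frame(child_id = seq_len(n), X))
  })
}

small_config <- function(seed = 1L, ...) {
  model_config(grid = list(nrounds = 40, eta = 0.3, max_depth = 3,
                           min_child_weight = 1, gamma = 0, reg_alpha = 0),
               permutation_repeats = 20, seed = seed, ...)
}

test_that("contrast building keeps only the two destinations and counts classes", {
  linked <- data.frame(
    child_id = 1:100,
    source = "cluster_1",
    destination = c(rep("cluster_2", 30), rep("non_elevated", 60), rep("cluster_3", 10)))
  ct <- build_contrast(linked, "cluster_1", "cluster_2")
  expect_equal(attr(ct, "n_pos"), 30)
  expect_equal(attr(ct, "n_neg"), 60)
  expect_equal(nrow(ct), 90)  # third-destination children excluded

  all_ctrl <- data.frame(child_id = 1:10, source = "cluster_1",
                         destination = "non_elevated")
  expect_error(build_contrast(all_ctrl, "cluster_1", "cluster_2"), "empty class")
})

test_that("missingness filter uses the strict more-than rule", {
  cov <- data.frame(child_id = 1:3,
                    a = c(NA, 1, 1), b = c(NA, 2, 2), c = c(NA, NA, 3),
                    d = c(NA, 4, 4), e = c(5, 5, 5),
                    f = c(6, 6, 6), g = c(7, 7, 7), h = c(8, 8, 8),
                    i = c(9, 9, 9), j = c(10, 10, 10))
  # child 1 misses 4/10 = 40% -> excluded; child 2 misses 1/10; child 3 none
  kept <- filter_missingness(cov, 0.30)
  expect_equal(kept$child_id, c(2, 3))
  # exactly at the threshold is retained
  cov30 <- data.frame(child_id = 1, a = NA, b = NA, c = NA,
                      d = 1, e = 1, f = 1, g = 1, h = 1, i = 1, j = 1)
  expect_equal(nrow(filter_missingness(cov30, 0.30)), 1)
  expect_equal(nrow(filter_missingness(cov, 1)), 3)
})

test_that("train/test split is stratified, disjoint and seed-stable", {
  ids <- 1:100; y <- rep(c(0, 1), c(70, 30))
  sp <- split_train_test(ids, y, fraction = 0.2, seed = 5)
  expect_equal(length(sp$test), 20)
  expect_equal(length(sp$train), 80)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sum(sp$test <= 70), 14)  # 20% of each class
  expect_equal(sum(sp$test > 70), 6)
  expect_identical(sp, split_train_test(ids, y, fraction = 0.2, seed = 5))
  expect_error(split_train_test(1:5, rep(0, 5), seed = 1), "both outcome classes")
})

test_that("KNN imputation copies the unique nearest neighbour at k = 1", {
  train <- rbind(c(0, 0, 0), c(10, 10, 10), c(0.1, 0.1, 0.2))
  colnames(train) <- c("a", "b", "c")
  test <- rbind(c(0, 0, NA))
  colnames(test) <- colnames(train)
  out <- impute_knn(train, test, k = 1)
  expect_equal(unname(out$test[1, "c"]), 0)  # nearest train row is (0,0,0)

  nomiss <- impute_knn(train, train, k = 2)
  expect_identical(nomiss$train, train)
  expect_identical(nomiss$test, train)
})

test_that("KNN beats column-mean imputation on correlated features", {
  withr::with_seed(7, {
    n <- 400
    z <- rnorm(n)
    X <- cbind(a = z + rnorm(n, 0, 0.3), b = z + rnorm(n, 0, 0.3),
               c = z + rnorm(n, 0, 0.3), d = rnorm(n))
    truth <- X
    mask <- matrix(runif(length(X)) < 0.1, nrow(X))
    X[mask] <- NA
    imp <- impute_knn(X, X[1:2, , drop = FALSE], k = 5)
    rmse_knn <- sqrt(mean((imp$train[mask] - truth[mask])^2))
    mean_imp <- apply(X, 2, function(col) { col[is.na(col)] <- mean(col, na.rm = TRUE); col })
    rmse_mean <- sqrt(mean((mean_imp[mask] - truth[mask])^2))
    expect_lt(rmse_knn, rmse_mean)
  })
})

test_that("min-max scaling follows the train-fit formula", {
  train <- cbind(a = c(2, 4, 6), b = c(1, 1, 1))
  test <- cbind(a = c(8), b = c(3))
  expect_warning(sc <- scale_minmax(train, test), "constant")
  expect_equal(sc$train[, "a"], c(0, 0.5, 1))
  expect_equal(unname(sc$test[1, "a"]), 1.5)  # test may exceed [0, 1]
  expect_equal(sc$train[, "b"], c(0, 0, 0))
})

test_that("tuning fixes the imbalance weight and separable data scores high", {
  # axis-aligned threshold outcome: linearly separable and tree-friendly
  d <- make_risk_data(300, n_noise = 3, coef = 50, seed = 9,
                      causal = "x_causal_1")
  cfg <- small_config(seed = 9)
  y_imb <- rep(c(0, 1), c(90, 10))
  x_imb <- matrix(rnorm(200), 100)
  colnames(x_imb) <- c("a", "b")
  tuned_imb <- tune_model(x_imb, y_imb, cfg)
  expect_equal(tuned_imb$scale_pos_weight, 9)

  sp <- split_train_test(seq_len(300), d$y, 0.2, seed = 9)
  tuned <- tune_model(d$x[sp$train, ], d$y[sp$train], cfg)
  expect_equal(nrow(tuned$cv_table), 1)  # singleton grid returns that config
  pred <- as.integer(predict(tuned$model,
                             xgboost::xgb.DMatrix(d$x[sp$test, ], nthread = 1)) > 0.5)
  expect_gte(mean(pred == d$y[sp$test]), 0.95)
})

test_that("gain importance concentrates on planted signal and is 0 for unused", {
  d <- make_risk_data(500, n_noise = 8, coef = 3, seed = 11)
  cfg <- small_config(seed = 11)
  tuned <- tune_model(d$x, d$y, cfg)
  gains <- gain_importance(tuned$model, colnames(d$x))
  expect_true(all(gains >= 0))
  expect_true(all(names(sort(gains, decreasing = TRUE))[1:2] %in%
                    c("x_causal_1", "x_causal_2")))

  # a feature absent from every split has gain exactly 0
  x_one <- cbind(signal = d$x[, 1], dead = rep(0, 500))
  t_one <- tune_model(x_one, d$y, cfg)
  expect_identical(unname(gain_importance(t_one$model, colnames(x_one))["dead"]), 0)
})

test_that("under a pure-noise outcome no feature's gain share dominates", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(100 + s, {
      X <- matrix(rnorm(500 * 10), 500)
      colnames(X) <- paste0("n", 1:10)
      y <- rbinom(500, 1, 0.5)
    })
    tuned <- tune_model(X, y, small_config(seed = s))
    gains <- gain_importance(tuned$model, colnames(X))
    max(gains) < 3 / ncol(X)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("threshold sweep keeps the dominant feature and prefers fewer on ties", {
  d <- make_risk_data(600, n_noise = 10, coef = 3, seed = 13,
                      causal = "x_causal_1")
  cfg <- small_config(seed = 13)
  sp <- split_train_test(seq_len(600), d$y, 0.2, seed = 13)
  tuned <- tune_model(d$x[sp$train, ], d$y[sp$train], cfg)
  gains <- gain_importance(tuned$model, colnames(d$x))
  params <- tuned$best_params[names(tuned$best_params) != "nrounds"]
  sel <- select_by_threshold(d$x[sp$train, ], d$y[sp$train],
                             d$x[sp$test, ], d$y[sp$test],
                             gains, params, tuned$best_params$nrounds)
  expect_true("x_causal_1" %in% sel$features)
  expect_lte(nrow(sel$sweep), length(unique(gains)))
  ties <- sel$sweep[sel$sweep$score == max(sel$sweep$score), ]
  expect_equal(length(sel$features), min(ties$n_features))

  zero <- setNames(rep(0, ncol(d$x)), colnames(d$x))
  expect_warning(empty <- select_by_threshold(d$x[sp$train, ], d$y[sp$train],
                                              d$x[sp$test, ], d$y[sp$test],
                                              zero, params, 40), "zero")
  expect_length(empty$features, 0)
})

test_that("permutation importance separates the sole predictor from unused features", {
  d <- make_risk_data(1000, n_noise = 3, coef = 50, seed = 17,
                      causal = "x_causal_1")
  cfg <- small_config(seed = 17)
  sp <- split_train_test(seq_len(1000), d$y, 0.2, seed = 17)
  tuned <- tune_model(d$x[sp$train, ], d$y[sp$train], cfg)
  gains <- gain_importance(tuned$model, colnames(d$x))
  perm <- permutation_survival(tuned$model, d$x[sp$test, ], d$y[sp$test],
                               gains, repeats = 50, seed = 17)
  drop_causal <- perm$mean_drop[perm$feature == "x_causal_1"]
  expect_gt(drop_causal, 0.2)
  unused <- perm$mean_drop[gains[perm$feature] == 0]
  expect_true(all(abs(unused) < 0.01))
  perm2 <- permutation_survival(tuned$model, d$x[sp$test, ], d$y[sp$test],
                                gains, repeats = 50, seed = 17)
  expect_identical(perm, perm2)
  expect_error(permutation_survival(tuned$model, d$x, d$y, gains, repeats = 0),
               "at least 1")
})

test_that("genuine factors are the intersection and respect set algebra", {
  sel <- list(features = c("a", "b", "c"), threshold = 0.1, score = 0.9)
  perm <- data.frame(feature = c("a", "b", "c", "d"),
                     mean_drop = c(0.2, -0.01, 0.1, 0.3),
                     survives = c(TRUE, FALSE, TRUE, TRUE))
  gains <- c(a = 0.5, b = 0.3, c = 0.15, d = 0.05)
  res <- genuine_risk_factors(sel, perm, gains)
  expect_setequal(res$feature[res$genuine], c("a", "c"))
  expect_true(all(res$feature[res$genuine] %in% sel$features))
  expect_true(all(res$feature[res$genuine] %in% perm$feature[perm$survives]))
  expect_false(is.unsorted(rev(res$gain)))

  none <- genuine_risk_factors(list(features = character(0), threshold = NA),
                               perm, gains)
  expect_equal(sum(none$genuine), 0)
})

test_that("imputation and scaling parameters never depend on the test split", {
  withr::with_seed(19, {
    train <- matrix(rnorm(50 * 4), 50); colnames(train) <- letters[1:4]
    train[sample(200, 20)] <- NA
    test_a <- matrix(rnorm(10 * 4), 10); colnames(test_a) <- letters[1:4]
    test_b <- matrix(rnorm(10 * 4, 5, 3), 10); colnames(test_b) <- letters[1:4]
  })
  imp_a <- impute_knn(train, test_a, k = 3)
  imp_b <- impute_knn(train, test_b, k = 3)
  expect_identical(imp_a$train, imp_b$train)
  sc_a <- scale_minmax(imp_a$train, imp_a$test)
  sc_b <- scale_minmax(imp_b$train, imp_b$test)
  expect_identical(sc_a$min, sc_b$min)
  expect_identical(sc_a$range, sc_b$range)
  expect_identical(sc_a$train, sc_b$train)
})

test_that("the full pipeline recovers planted covariates and is deterministic", {
  d <- make_risk_data(800, n_noise = 15, coef = 2, seed = 23)
  contrast <- structure(data.frame(child_id = seq_len(800), outcome = d$y),
                        class = c("transition_contrast", "data.frame"))
  cfg <- small_config(seed = 23)
  res <- run_risk_factor_analysis(contrast, d$covariates, cfg)
  expect_s3_class(res, "risk_factor_result")
  expect_true(all(c("x_causal_1", "x_causal_2") %in% res$feature[res$genuine]))
  res2 <- run_risk_factor_analysis(contrast, d$covariates, cfg)
  expect_identical(res$feature[res$genuine], res2$feature[res2$genuine])
  expect_identical(res$gain, res2$gain)
})
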