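group_df <- function(ids, groups) data.frame(child_id = ids, group = groups)

test_that("wave linking uses inner-join semantics and rejects duplicate keys", {
  t0 <- group_df(1:20, rep(c("a", "b"), 10))
  t1 <- group_df(11:30, rep("c", 20))
  linked <- link_waves(t0, t1)
  expect_equal(nrow(linked), 10)           # 10 of 20 linked
  expect_equal(sort(linked$child_id), 11:20)

  full <- link_waves(t0, group_df(1:20, rep("c", 20)))
  expect_equal(as.vector(table(full$source)), c(10, 10))

  expect_warning(empty <- link_waves(t0, group_df(101:110, rep("c", 10))), "no children")
  expect_equal(nrow(empty), 0)
  expect_error(link_waves(group_df(c(1, 1), c("a", "b")), t1), "duplicate")
})

test_that("equal-split null is 1/K", {
  expect_identical(equal_split_null(5), 0.2)
  expect_identical(equal_split_null(2), 0.5)
  expect_equal(equal_split_null(6), 1 / 6)
  expect_error(equal_split_null(1), "at least 2")
})

test_that("proportion z test matches closed form and an erf-based normal oracle", {
  res <- proportion_ztest(30, 100, 0.2)
  expect_identical(res$z, (0.3 - 0.2) / sqrt(0.2 * 0.8 / 100))  # = 2.5
  expect_equal(res$z, 2.5, tolerance = 1e-12)
  # independent two-sided p via the error function: p = 1 - erf(z/sqrt(2)),
  # with erf evaluated through the incomplete gamma function, not pnorm
  erf <- function(x) pgamma(x^2, 0.5)
  expect_equal(res$p, 1 - erf(2.5 / sqrt(2)), tolerance = 1e-6)

  null_res <- proportion_ztest(20, 100, 0.2)
  expect_equal(null_res$z, 0)
  expect_equal(null_res$p, 1)

  expect_error(proportion_ztest(30, 0, 0.2), "positive")
  expect_warning(proportion_ztest(1, 10, 0.2), "doubtful")
})

test_that("Bonferroni adjustment caps at 1 and preserves order", {
  expect_equal(bonferroni(0.01, m = 30), 0.3)
  expect_equal(bonferroni(0.5, m = 3), 1.0)
  p <- sort(runif(20))
  expect_false(is.unsorted(bonferroni(p)))
  expect_true(all(bonferroni(p) >= p))
})

test_that("transition table proportions, flags and families are coherent", {
  withr::with_seed(23, {
    linked <- data.frame(
      child_id = 1:600,
      source = rep(c("cluster_1", "cluster_2"), each = 300),
      destination = c(sample(c("cluster_1", "cluster_2", "non_elevated"), 300,
                             replace = TRUE, prob = c(0.6, 0.2, 0.2)),
                      sample(c("cluster_1", "cluster_2", "non_elevated"), 300,
                             replace = TRUE)))
    tt <- test_transitions(linked)
    expect_s3_class(tt, "transition_table")
    for (s in unique(tt$source))
      expect_equal(sum(tt$p_ij[tt$source == s]), 1, tolerance = 1e-9)
    expect_true(all(tt$p_adj >= tt$p_raw))
    expect_true(all(tt$p_ij[tt$significant] > tt$p0[tt$significant]))
    expect_true(tt$significant[tt$source == "cluster_1" & tt$destination == "cluster_1"])
    expect_equal(attr(tt, "K"), 3)
    expect_equal(attr(tt, "m"), nrow(tt))
  })
  expect_error(test_transitions(data.frame(child_id = 1, source = "a",
                                           destination = "b")[0, ]), "no linked")
  one_dest <- data.frame(child_id = 1:10, source = "a", destination = "b")
  expect_error(test_transitions(one_dest), "at least 2 destination")
})

test_that("z test agrees with the exact binomial test in direction and level", {
  withr::with_seed(29, {
    for (i in 1:25) {
      n <- sample(50:400, 1); p0 <- sample(c(0.2, 1 / 3, 0.25), 1)
      x <- rbinom(1, n, p0 + runif(1, -0.1, 0.1))
      zt <- suppressWarnings(proportion_ztest(x, n, p0))
      bt <- binom.test(x, n, p0)
      expect_equal(sign(x / n - p0), sign(zt$z))
      # the exact test's p is discrete: its doubled-tail definition moves in
      # jumps of the boundary point mass, so the normal approximation can only
      # be expected to agree up to that granularity
      if (n * p0 * (1 - p0) >= 9)
        expect_lt(abs(zt$p - bt$p.value), 0.01 + 2 * dbinom(x, n, p0))
    }
  })
})

test_that("family-wise type-I error under the equal-split null stays controlled", {
  # 200 simulated wave pairs, 2 source groups x 4 destinations, 500 per source
  n_sims <- 200
  dests <- paste0("d", 1:4)
  false_flag <- withr::with_seed(31, vapply(seq_len(n_sims), function(s) {
    linked <- data.frame(
      child_id = 1:1000, source = rep(c("s1", "s2"), each = 500),
      destination = sample(dests, 1000, replace = TRUE))
    any(test_transitions(linked)$significant)
  }, logical(1)))
  expect_lte(mean(false_flag), 0.07)
})

test_that("a planted 0.45 cell against p0 = 0.2 is flagged almost always", {
  n_sims <- 200
  dests <- paste0("d", 1:5)
  hits <- withr::with_seed(37, vapply(seq_len(n_sims), function(s) {
    dest <- sample(dests, 500, replace = TRUE,
                   prob = c(0.45, rep(0.55 / 4, 4)))
    linked <- data.frame(child_id = 1:500, source = "s1", destination = dest)
    tt <- test_transitions(linked, destination_groups = dests)
    tt$significant[tt$destination == "d1"]
  }, logical(1)))
  expect_gte(mean(hits), 0.95)
})

test_that("silhouette validation finds borderline-driven transitions and not null ones", {
  blobs <- make_blobs(rbind(c(0, 0), c(6, 0), c(0, 6)), 170, sd = 0.8, seed = 41)
  labs <- cluster_k(blobs$coords, 3, seed = 41)
  vm <- validity_metrics(blobs$coords, labs)
  sol <- structure(list(coordinates = blobs$coords, labels = labs, k = 3,
                        per_child_silhouette = vm$per_child_silhouette,
                        wave = "w1", accepted = TRUE),
                   class = "cluster_solution")
  cl <- which(labs == 1)

  # whole cluster vs itself: KS statistic 0
  same <- validate_transition(sol, 1, cl)
  expect_equal(same$statistic, 0)

  # uniformly drawn members: null calibration, p < .05 in <= 10% of sims
  pvals <- withr::with_seed(43, vapply(1:100, function(i)
    validate_transition(sol, 1, sample(cl, 100))$p, numeric(1)))
  expect_lte(mean(pvals < 0.05), 0.10)

  # members forced to the lowest-silhouette decile: strongly detected
  low <- cl[order(vm$per_child_silhouette[cl])][1:17]
  expect_lt(validate_transition(sol, 1, low)$p, 0.01)

  skipped <- validate_transition(sol, 1, cl[1:3])
  expect_true(skipped$skipped)
  expect_match(skipped$reason, "members")
})

test_that("one planted above-chance transition per source is recovered exactly", {
  dests <- paste0("d", 1:5)
  ok <- withr::with_seed(47, vapply(1:50, function(s) {
    planted <- c(s1 = "d2", s2 = "d4")
    linked <- do.call(rbind, lapply(names(planted), function(src) {
      prob <- rep(0.6 / 4, 5); prob[dests == planted[src]] <- 0.4  # 2 x p0
      data.frame(child_id = seq_len(500), source = src,
                 destination = sample(dests, 500, replace = TRUE, prob = prob))
    }))
    tt <- test_transitions(linked, destination_groups = dests)
    flagged <- tt[tt$significant, c("source", "destination")]
    nrow(flagged) == 2 &&
      all(flagged$destination[order(flagged$source)] == planted[order(names(planted))])
  }, logical(1)))
  expect_gte(mean(ok), 0.9)
})
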