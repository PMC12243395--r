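#' Draw 25 SDQ item responses for children of one profile
#'
#' Each subscale's five items are drawn independently as
#' `Binomial(2, p)` with `p = clamp(mean/10 + noise, 0, 1)` and
#' `noise ~ Normal(0, dispersion)` drawn per item and child, so the expected
#' subscale sum equals the profile mean (exactly when `dispersion = 0`).
#' Items 21-25 are the raw prosocial items, drawn with mean
#' `10 - antisocial mean` so that the reverse-scored antisocial subscale has
#' the requested mean.
#'
#' @param profile_means Named numeric of length 5 over
#'   `c("emotional","conduct","hyperactivity","peer","antisocial")`, in `[0,10]`.
#' @param dispersion Nonnegative SD of the probability-scale noise; scalar or
#'   length 5 (per subscale).
#' @param n Number of children to draw.
#' @param item_map Item-to-subscale assignment; see [default_item_map()].
#' @return Integer matrix `n x 25` with values in `{0, 1, 2}`, columns
#'   `item_01`..`item_25`.
#' @export
sample_items <- function(profile_means, dispersion = 0, n = 1,
                         item_map = default_item_map()) {
  if (is.null(names(profile_means))) names(profile_means) <- SDQ_SUBSCALES
  if (length(profile_means) != 5 || any(profile_means < 0 | profile_means > 10))
    stopf("profile means must be 5 values in [0, 10]")
  if (length(dispersion) == 1) dispersion <- rep(dispersion, 5)
  names(dispersion) <- SDQ_SUBSCALES

  # Generating means per item block; prosocial items encode 10 - antisocial.
  block_means <- c(profile_means[c("emotional", "conduct", "hyperactivity", "peer")],
                   prosocial = unname(10 - profile_means["antisocial"]))
  block_disp <- c(dispersion[c("emotional", "conduct", "hyperactivity", "peer")],
                  prosocial = unname(dispersion["antisocial"]))

  out <- matrix(0L, nrow = n, ncol = 25, dimnames = list(NULL, item_cols()))
  for (b in names(block_means)) {
    idx <- item_map[[b]]
    p <- clamp01(block_means[[b]] / 10 +
                   matrix(stats::rnorm(n * 5, 0, block_disp[[b]]), n, 5))
    out[, item_cols()[idx]] <- matrix(stats::rbinom(n * 5, 2, p), n, 5)
  }
  out
}

#' Assign next-wave group labels by covariate-modulated Markov transitions
#'
#' Each child's destination is drawn from a multinomial whose logits are the
#' log of the child's source row of the base transition matrix plus, for every
#' planted effect matching (source, destination), `coefficient * covariate`,
#' renormalised. With no effects (or all-zero coefficients) this reduces
#' exactly to the base matrix; base probabilities of zero stay zero.
#'
#' @param labels_t Character vector of current group labels.
#' @param transition_matrix Row-stochastic matrix; rownames = source groups,
#'   colnames = destination groups.
#' @param covariates Data frame of covariate values, one row per child in the
#'   order of `labels_t` (complete; effects are applied before missingness).
#' @param effect_spec List of `list(source, destination, covariate, coefficient)`.
#' @return Character vector of destination labels.
#' @export
assign_transitions <- function(labels_t, transition_matrix,
                               covariates = NULL, effect_spec = list()) {
  if (any(transition_matrix < 0) || any(abs(rowSums(transition_matrix) - 1) > 1e-9))
    stopf("transition matrix rows must be nonnegative and sum to 1")
  if (!all(labels_t %in% rownames(transition_matrix)))
    stopf("labels contain groups absent from the transition matrix rows")
  for (ef in effect_spec) {
    if (is.null(covariates) || !ef$covariate %in% names(covariates))
      stopf("covariate named in effect_spec absent: '%s'", ef$covariate)
  }
  n <- length(labels_t)
  dests <- colnames(transition_matrix)
  logits <- log(transition_matrix[labels_t, , drop = FALSE])  # -Inf for p = 0
  for (ef in effect_spec) {
    hit <- labels_t == ef$source
    if (any(hit)) {
      j <- match(ef$destination, dests)
      if (is.na(j)) stopf("effect destination '%s' not a destination group", ef$destination)
      shift <- ef$coefficient * covariates[[ef$covariate]][hit]
      logits[hit, j] <- logits[hit, j] + shift  # -Inf + finite stays -Inf
    }
  }
  probs <- exp(logits - apply(logits, 1, max))
  probs <- probs / rowSums(probs)
  u <- stats::runif(n)
  cum <- t(apply(probs, 1, cumsum))
  dests[max.col(cum >= u, ties.method = "first")]
}

#' Mask covariate cells according to a missingness spec
#'
#' MCAR: each cell of the covariate is masked independently with the stated
#' rate. MAR: the per-child masking probability is
#' `plogis(qlogis(rate) + slope * z)` where `z` is the standardised value of
#' the named conditioning covariate (its pre-masking values), so the average
#' rate stays near the stated rate while depending on the conditioner. Truth
#' labels are never masked.
#'
#' @param cohort A `synthetic_cohort`.
#' @param missingness Named list per covariate:
#'   `list(rate=, mechanism=("MCAR"|"MAR"), condition_on=, slope=)`.
#' @return The cohort with masked covariate cells.
#' @export
inject_missingness <- function(cohort, missingness) {
  cov <- cohort$covariates
  base <- cov  # condition MAR on pre-masking values
  for (nm in names(missingness)) {
    ms <- missingness[[nm]]
    if (!nm %in% names(cov)) stopf("missingness names unknown covariate '%s'", nm)
    if (ms$rate < 0 || ms$rate > 1) stopf("missing probability for '%s' must lie in [0,1]", nm)
    if (ms$rate == 0) next
    n <- nrow(cov)
    if ((ms$mechanism %||% "MCAR") == "MAR") {
      z <- base[[ms$condition_on]]
      sdz <- stats::sd(z)
      z <- if (is.finite(sdz) && sdz > 0) (z - mean(z)) / sdz else rep(0, n)
      p <- stats::plogis(stats::qlogis(min(max(ms$rate, 1e-12), 1 - 1e-12)) +
                           (ms$slope %||% 1) * z)
    } else {
      p <- rep(ms$rate, n)
    }
    cov[[nm]][stats::runif(n) < p] <- NA
  }
  cohort$covariates <- cov
  cohort
}

draw_covariates <- function(covariate_spec, n) {
  out <- data.frame(child_id = seq_len(n))
  for (cv in covariate_spec) {
    par <- cv$parameters %||% list()
    out[[cv$name]] <- switch(cv$family,
      normal = stats::rnorm(n, par$mean %||% 0, par$sd %||% 1),
      bernoulli = stats::rbinom(n, 1, par$prob %||% 0.5),
      uniform = stats::runif(n, par$min %||% 0, par$max %||% 1),
      stopf("unknown covariate family '%s'", cv$family))
  }
  out
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws wave-1 group labels from the spec's initial distribution, propagates
#' them through the covariate-modulated Markov transitions
#' ([assign_transitions()]), draws 25 item responses per child and wave from
#' that wave's group profile ([sample_items()]), applies per-wave dropout,
#' and finally masks covariates ([inject_missingness()]). Deterministic given
#' the spec's seed.
#'
#' @param spec A validated [cohort_spec()].
#' @return Object of class `synthetic_cohort`: list with `records` (one row
#'   per present (child, wave): `child_id`, `wave`, `item_01`..`item_25`),
#'   `covariates` (child-level, possibly with `NA` cells), `truth` (`child_id`,
#'   `wave`, generating `group` — never masked) and `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_children
    waves <- spec$waves
    covariates <- draw_covariates(spec$covariate_spec, n)

    labels <- vector("list", length(waves))
    names(labels) <- waves
    p0 <- spec$initial_distribution
    labels[[1]] <- sample(names(p0), n, replace = TRUE, prob = p0)
    present <- matrix(TRUE, n, length(waves), dimnames = list(NULL, waves))
    for (t in seq_len(length(waves) - 1)) {
      labels[[t + 1]] <- assign_transitions(labels[[t]], spec$transition_matrices[[t]],
                                            covariates, spec$effect_spec)
      drop_now <- stats::runif(n) < spec$dropout
      present[, t + 1] <- present[, t] & !drop_now
    }

    rec_list <- list(); truth_list <- list()
    for (t in seq_along(waves)) {
      w <- waves[t]
      profs <- spec$cluster_profiles[[w]]
      items <- matrix(0L, n, 25, dimnames = list(NULL, item_cols()))
      for (g in names(profs)) {
        idx <- which(labels[[t]] == g)
        if (length(idx) > 0)
          items[idx, ] <- sample_items(profs[[g]], spec$profile_dispersion, length(idx))
      }
      keep <- which(present[, t])
      rec_list[[t]] <- data.frame(child_id = keep, wave = w,
                                  items[keep, , drop = FALSE])
      truth_list[[t]] <- data.frame(child_id = keep, wave = w,
                                    group = labels[[t]][keep])
    }
    cohort <- structure(
      list(records = do.call(rbind, rec_list),
           covariates = covariates,
           truth = do.call(rbind, truth_list),
           spec = spec),
      class = "synthetic_cohort")
    rownames(cohort$records) <- rownames(cohort$truth) <- NULL
    inject_missingness(cohort, spec$missingness)
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", x$spec$n_children, "children,",
      length(x$spec$waves), "waves,", nrow(x$records), "child-wave records\n")
  n_cov <- ncol(x$covariates) - 1
  if (n_cov > 0) {
    cat("  covariates:", n_cov,
        sprintf("(%.1f%% cells missing)",
                100 * mean(is.na(as.matrix(x$covariates[, -1, drop = FALSE])))), "\n")
  } else {
    cat("  covariates: none\n")
  }
  invisible(x)
}

#' Write a synthetic cohort to delimited text tables
#'
#' Writes `records.csv`, `covariates.csv` and `truth.csv` into `dir`.
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$records, file.path(dir, "records.csv"), row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
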