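#' Specify a synthetic longitudinal cohort
#'
#' A `cohort_spec` fully parameterises the generator: per-wave latent cluster
#' profiles over the five SDQ subscales (including one designated
#' "non_elevated" profile per wave), Markov transition matrices between
#' consecutive waves, child-level covariates with planted effects on
#' transition log-odds, covariate missingness, and a seed. The generator is
#' deterministic given the spec.
#'
#' @param n_children Positive integer; cohort size at the first wave.
#' @param waves Character vector of wave labels, length >= 2.
#' @param cluster_profiles Named list (one element per wave); each element is a
#'   named list of numeric mean vectors of length 5 over
#'   `c("emotional","conduct","hyperactivity","peer","antisocial")`, every mean
#'   in `[0, 10]`. Each wave must include a profile named `"non_elevated"`.
#' @param profile_dispersion Nonnegative spread of the per-item success
#'   probability around `mean/10`; scalar or length-5 vector (per subscale).
#' @param transition_matrices List of length `length(waves) - 1`; element `t`
#'   is a row-stochastic matrix with rownames = wave-`t` group names and
#'   colnames = wave-`t+1` group names.
#' @param initial_distribution Named probability vector over the first wave's
#'   groups. Default: `non_elevated_share` to the non-elevated group, the rest
#'   split uniformly over the elevated profiles.
#' @param non_elevated_share Share of the first wave assigned to the
#'   non-elevated group when `initial_distribution` is not given (default 0.6,
#'   a non-elevated majority).
#' @param covariate_spec List of covariate definitions, each
#'   `list(name=, family=("normal"|"bernoulli"), parameters=list(...))` with
#'   parameters `mean`/`sd` or `prob`.
#' @param effect_spec List of planted effects, each
#'   `list(source=, destination=, covariate=, coefficient=)`: the coefficient
#'   is added, times the covariate value, to the log-odds of that destination
#'   for children leaving that source group.
#' @param missingness Named list (per covariate) of
#'   `list(rate=, mechanism=("MCAR"|"MAR"), condition_on=, slope=)`; MAR rates
#'   are modulated on the logit scale by the named (standardised) conditioning
#'   covariate with the given slope (default 1).
#' @param dropout Per-wave probability that a child present at wave `t` is
#'   lost before wave `t+1` (monotone attrition). Default 0.
#' @param seed Integer seed; every random draw descends from it.
#' @return A validated object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_children,
                        waves,
                        cluster_profiles,
                        transition_matrices,
                        profile_dispersion = 0.05,
                        initial_distribution = NULL,
                        non_elevated_share = 0.6,
                        covariate_spec = list(),
                        effect_spec = list(),
                        missingness = list(),
                        dropout = 0,
                        seed = 1L) {
  spec <- structure(
    list(n_children = as.integer(n_children), waves = as.character(waves),
         cluster_profiles = cluster_profiles,
         profile_dispersion = profile_dispersion,
         initial_distribution = initial_distribution,
         non_elevated_share = non_elevated_share,
         transition_matrices = transition_matrices,
         covariate_spec = covariate_spec, effect_spec = effect_spec,
         missingness = missingness, dropout = dropout, seed = as.integer(seed)),
    class = "cohort_spec")
  if (is.null(spec$initial_distribution)) {
    groups <- names(cluster_profiles[[waves[1]]])
    elev <- setdiff(groups, "non_elevated")
    p <- stats::setNames(rep((1 - non_elevated_share) / length(elev), length(elev)), elev)
    spec$initial_distribution <- c(p, non_elevated = non_elevated_share)
  }
  validate_cohort_spec(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_children, "children;",
      length(x$waves), "waves:", paste(x$waves, collapse = " -> "), "\n")
  for (w in x$waves)
    cat("  ", w, ": groups ", paste(names(x$cluster_profiles[[w]]), collapse = ", "), "\n", sep = "")
  cat("  covariates:", length(x$covariate_spec),
      "| planted effects:", length(x$effect_spec),
      "| seed:", x$seed, "\n")
  invisible(x)
}

#' Validate a cohort spec against its invariants
#'
#' Errors name the violated invariant.
#' @param spec A `cohort_spec`.
#' @return The spec, invisibly usable, if valid.
#' @export
validate_cohort_spec <- function(spec) {
  if (!is.numeric(spec$n_children) || spec$n_children < 1)
    stopf("invariant violated: n_children must be a positive integer")
  if (length(spec$waves) < 2)
    stopf("invariant violated: at least 2 waves are required")
  if (!setequal(names(spec$cluster_profiles), spec$waves))
    stopf("invariant violated: cluster_profiles must name every wave")
  for (w in spec$waves) {
    profs <- spec$cluster_profiles[[w]]
    if (!"non_elevated" %in% names(profs))
      stopf("invariant violated: wave '%s' lacks the designated non_elevated profile", w)
    for (g in names(profs)) {
      m <- profs[[g]]
      if (length(m) != 5 || any(m < 0 | m > 10))
        stopf("invariant violated: profile '%s'/'%s' means must be 5 values in [0,10]", w, g)
    }
  }
  disp <- spec$profile_dispersion
  if (!length(disp) %in% c(1L, 5L) || any(disp < 0))
    stopf("invariant violated: profile_dispersion must be nonnegative (scalar or length 5)")
  if (length(spec$transition_matrices) != length(spec$waves) - 1)
    stopf("invariant violated: need one transition matrix per consecutive wave pair")
  for (t in seq_along(spec$transition_matrices)) {
    M <- spec$transition_matrices[[t]]
    src <- names(spec$cluster_profiles[[spec$waves[t]]])
    dst <- names(spec$cluster_profiles[[spec$waves[t + 1]]])
    if (!setequal(rownames(M), src) || !setequal(colnames(M), dst))
      stopf("invariant violated: transition matrix %d dimnames must match wave group names", t)
    if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-9))
      stopf("invariant violated: transition matrix %d rows must sum to 1 (within 1e-9)", t)
  }
  p0 <- spec$initial_distribution
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-9 ||
      !setequal(names(p0), names(spec$cluster_profiles[[spec$waves[1]]])))
    stopf("invariant violated: initial_distribution must be a probability vector over wave-1 groups")
  cov_names <- vapply(spec$covariate_spec, function(cv) cv$name, character(1))
  if (anyDuplicated(cov_names)) stopf("invariant violated: duplicate covariate names")
  for (ef in spec$effect_spec) {
    if (!all(c("source", "destination", "covariate", "coefficient") %in% names(ef)))
      stopf("invariant violated: effect entries need source, destination, covariate, coefficient")
    if (!ef$covariate %in% cov_names)
      stopf("covariate named in effect_spec absent: '%s'", ef$covariate)
  }
  for (nm in names(spec$missingness)) {
    ms <- spec$missingness[[nm]]
    if (ms$rate < 0 || ms$rate > 1)
      stopf("invariant violated: missing probability for '%s' must lie in [0,1]", nm)
    mech <- ms$mechanism %||% "MCAR"
    if (!mech %in% c("MCAR", "MAR"))
      stopf("invariant violated: missingness mechanism must be MCAR or MAR")
    if (mech == "MAR" && !(ms$condition_on %||% "") %in% cov_names)
      stopf("invariant violated: MAR missingness for '%s' must condition on a named covariate", nm)
  }
  if (spec$dropout < 0 || spec$dropout >= 1)
    stopf("invariant violated: dropout must lie in [0,1)")
  spec
}

#' Read a cohort spec from a YAML or JSON file
#'
#' The file mirrors the [cohort_spec()] arguments; transition matrices are
#' given as named row lists. Rows whose probabilities sum to 1 only within
#' the serialisation precision (1e-6) are renormalised exactly; larger
#' deviations still fail validation.
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  profiles <- lapply(raw$cluster_profiles, function(wv) lapply(wv, as.numeric))
  mats <- lapply(raw$transition_matrices, function(m) {
    rows <- lapply(m, unlist)
    M <- do.call(rbind, rows)
    rownames(M) <- names(rows)
    rs <- rowSums(M)
    ok <- abs(rs - 1) < 1e-6
    M[ok, ] <- M[ok, , drop = FALSE] / rs[ok]
    M
  })
  cohort_spec(
    n_children = raw$n_children, waves = raw$waves, cluster_profiles = profiles,
    transition_matrices = mats,
    profile_dispersion = raw$profile_dispersion %||% 0.05,
    initial_distribution = if (!is.null(raw$initial_distribution)) unlist(raw$initial_distribution),
    non_elevated_share = raw$non_elevated_share %||% 0.6,
    covariate_spec = raw$covariate_spec %||% list(),
    effect_spec = raw$effect_spec %||% list(),
    missingness = raw$missingness %||% list(),
    dropout = raw$dropout %||% 0,
    seed = raw$seed %||% 1L)
}
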