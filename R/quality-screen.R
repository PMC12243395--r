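#' Flag univariate outliers (> k SDs from the median)
#'
#' A child is flagged if, on any subscale, the absolute deviation from that
#' subscale's median exceeds `k_sd` standard deviations, both statistics
#' computed within the supplied group. The boundary is strict: a value at
#' exactly `median + k_sd * SD` is not flagged. A zero-variance subscale is
#' skipped with a warning.
#'
#' @param scores Table with the five subscale columns (>= 3 rows).
#' @param k_sd Threshold in SD units (default 3).
#' @return Logical vector, one flag per row.
#' @export
univariate_flags <- function(scores, k_sd = 3) {
  X <- as.matrix(scores[, SDQ_SUBSCALES, drop = FALSE])
  if (nrow(X) < 3) stopf("univariate screening needs at least 3 children")
  flag <- rep(FALSE, nrow(X))
  skipped <- character(0)
  for (s in SDQ_SUBSCALES) {
    sdev <- stats::sd(X[, s])
    if (!is.finite(sdev) || sdev == 0) {
      skipped <- c(skipped, s)
      next
    }
    flag <- flag | abs(X[, s] - stats::median(X[, s])) > k_sd * sdev
  }
  if (length(skipped) > 0)
    warnf("zero variance subscale(s) skipped in univariate screening: %s",
          paste(skipped, collapse = ", "))
  flag
}

#' Flag multivariate outliers by Mahalanobis distance
#'
#' Squared Mahalanobis distance to the group mean under the classical sample
#' covariance, compared against the chi-square quantile with `df = 5` (one per
#' subscale) at probability `alpha`; flagged iff strictly greater.
#'
#' @param scores Table with the five subscale columns (>= 6 rows).
#' @param alpha Chi-square quantile probability (default 0.999).
#' @return Logical vector, one flag per row.
#' @export
mahalanobis_flags <- function(scores, alpha = 0.999) {
  X <- as.matrix(scores[, SDQ_SUBSCALES, drop = FALSE])
  if (nrow(X) < 6) stopf("Mahalanobis screening needs at least 6 children")
  S <- stats::cov(X)
  if (!is.finite(determinant(S)$modulus) || abs(det(S)) < 1e-12)
    stopf(paste("sample covariance is singular; consider a small ridge or",
                "removing a redundant subscale"))
  d2 <- stats::mahalanobis(X, colMeans(X), S)
  d2 > stats::qchisq(alpha, df = ncol(X))
}

#' Screen outliers within each (wave, partition group) stratum
#'
#' Runs [univariate_flags()] and [mahalanobis_flags()] on the same input
#' within every (wave, label) stratum and removes the union of flagged
#' children. Both rules are scale-relative, so the flag set is unchanged by
#' positive rescaling of the scores.
#'
#' @param scores Subscale score table (`child_id`, `wave`, subscales).
#' @param partition Partition table from [partition_sample()].
#' @param k_sd,alpha Thresholds passed to the two rules.
#' @return List with `retained` (screened score table, partition label
#'   attached) and `report` (class `screen_report`: one row per stratum with
#'   `n_input`, `n_univariate_flagged`, `n_multivariate_flagged`, `n_retained`)
#'   plus a `flagged` attribute listing flagged children and reasons.
#' @export
apply_screen <- function(scores, partition, k_sd = 3, alpha = 0.999) {
  merged <- merge(scores, partition[, c("child_id", "wave", "label")],
                  by = c("child_id", "wave"))
  strata <- split(merged, list(wave = merged$wave, group = merged$label), drop = TRUE)
  report <- list(); kept <- list(); flagged <- list()
  for (nm in names(strata)) {
    st <- strata[[nm]]
    # strata too small to estimate spread (or covariance) pass through unscreened
    uni <- if (nrow(st) >= 3) univariate_flags(st, k_sd) else rep(FALSE, nrow(st))
    multi <- if (nrow(st) >= 6) mahalanobis_flags(st, alpha) else rep(FALSE, nrow(st))
    any_flag <- uni | multi
    reason <- ifelse(uni & multi, "univariate+multivariate",
                     ifelse(uni, "univariate", "multivariate"))
    flagged[[nm]] <- data.frame(child_id = st$child_id[any_flag],
                                wave = st$wave[any_flag],
                                group = st$label[any_flag],
                                reason = reason[any_flag])
    kept[[nm]] <- st[!any_flag, , drop = FALSE]
    report[[nm]] <- data.frame(
      wave = st$wave[1], group = st$label[1], n_input = nrow(st),
      n_univariate_flagged = sum(uni), n_multivariate_flagged = sum(multi),
      n_retained = sum(!any_flag))
  }
  report <- do.call(rbind, report); rownames(report) <- NULL
  retained <- do.call(rbind, kept); rownames(retained) <- NULL
  stopifnot(sum(report$n_retained) + nrow(do.call(rbind, flagged)) == nrow(merged))
  attr(report, "flagged") <- do.call(rbind, flagged)
  class(report) <- c("screen_report", class(report))
  list(retained = retained, report = report)
}
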