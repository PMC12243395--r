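#' Link children's group memberships across two consecutive waves
#'
#' Inner join on `child_id`: children absent at the later wave drop out of the
#' transition denominators. Duplicate `(child_id)` keys within either wave are
#' an error; a disjoint id set yields an empty table with a warning.
#'
#' @param groups_t,groups_t1 Data frames with `child_id` and `group` (cluster
#'   label or `"non_elevated"`) for the source and destination wave.
#' @return Data frame `child_id`, `source`, `destination`.
#' @export
link_waves <- function(groups_t, groups_t1) {
  for (g in list(groups_t, groups_t1))
    if (anyDuplicated(g$child_id)) stopf("duplicate child_id keys in a wave table")
  linked <- merge(groups_t[, c("child_id", "group")],
                  groups_t1[, c("child_id", "group")],
                  by = "child_id", suffixes = c("_t", "_t1"))
  names(linked) <- c("child_id", "source", "destination")
  if (nrow(linked) == 0) warnf("no children shared between the two waves")
  linked
}

#' Equal-split null proportion
#'
#' Under the equal-split null, children from a source group distribute
#' uniformly over the `K` destination groups, so the null proportion for
#' every cell is `1/K` (e.g. 0.20 for five destination groups).
#'
#' @param K Number of destination groups (>= 2).
#' @return `1/K`.
#' @export
equal_split_null <- function(K) {
  if (K < 2) stopf("equal-split null needs at least 2 destination groups")
  1 / K
}

#' One-sample proportion z test
#'
#' `z = (x/n - p0) / sqrt(p0 (1 - p0) / n)` with a two-sided p value from the
#' standard normal. Warns when the normal approximation is doubtful
#' (`n p0 < 5` or `n (1 - p0) < 5`).
#'
#' @param x Success count (`0 <= x <= n`).
#' @param n Trials (> 0).
#' @param p0 Null proportion in `(0, 1)`.
#' @return List with `z` and `p` (two-sided).
#' @export
proportion_ztest <- function(x, n, p0) {
  if (n <= 0) stopf("n must be positive")
  if (x < 0 || x > n) stopf("x must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) stopf("p0 must lie strictly in (0, 1)")
  if (n * p0 < 5 || n * (1 - p0) < 5)
    warnf("normal approximation doubtful: n*p0 = %.1f, n*(1-p0) = %.1f", n * p0, n * (1 - p0))
  z <- (x / n - p0) / sqrt(p0 * (1 - p0) / n)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)`; order-preserving.
#' @param p Vector of raw p values.
#' @param m Number of comparisons in the family (default `length(p)`).
#' @return Adjusted p values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) stopf("m must be at least 1")
  pmin(1, p * m)
}

#' Test every transition cell against the equal-split null
#'
#' Builds the source-by-destination table of counts and proportions over the
#' linked children and tests each cell with a two-sided proportion z test
#' against `p0 = 1/K`, where `K` counts all destination groups (including the
#' non-elevated group) by default. p values are Bonferroni-corrected over all
#' tested cells of the table; a cell is flagged significant only when its
#' adjusted p is below `alpha` AND its observed proportion exceeds `p0`
#' (only above-chance transitions are reported).
#'
#' @param linked Linked table from [link_waves()].
#' @param alpha Family-wise significance level (default 0.05).
#' @param destination_groups Optional character vector fixing the destination
#'   group set (hence `K`); defaults to all groups observed at the later wave.
#' @return Object of class `transition_table`: a data frame with one row per
#'   (source, destination) cell — `n_ij`, `n_i`, `p_ij`, `p0`, `z`, `p_raw`,
#'   `p_adj`, `significant` — with attributes `K` and `m`.
#' @export
test_transitions <- function(linked, alpha = 0.05, destination_groups = NULL) {
  if (nrow(linked) == 0) stopf("no linked children to test")
  dests <- destination_groups %||% sort(unique(linked$destination))
  K <- length(dests)
  if (K < 2) stopf("transition testing needs at least 2 destination groups")
  p0 <- equal_split_null(K)
  sources <- sort(unique(linked$source))
  counts <- table(factor(linked$source, levels = sources),
                  factor(linked$destination, levels = dests))
  rows <- expand.grid(source = sources, destination = dests,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$n_ij <- counts[cbind(rows$source, rows$destination)]
  rows$n_i <- as.integer(rowSums(counts))[match(rows$source, sources)]
  rows <- rows[rows$n_i > 0, , drop = FALSE]
  rows$p_ij <- rows$n_ij / rows$n_i
  rows$p0 <- p0
  zt <- suppressWarnings(mapply(function(x, n) unlist(proportion_ztest(x, n, p0)),
                                rows$n_ij, rows$n_i))
  rows$z <- zt["z", ]
  rows$p_raw <- zt["p", ]
  m <- nrow(rows)
  rows$p_adj <- bonferroni(rows$p_raw, m)
  rows$significant <- rows$p_adj < alpha & rows$p_ij > p0
  rows <- rows[order(rows$source, rows$destination), ]
  rownames(rows) <- NULL
  structure(rows, K = K, m = m, alpha = alpha,
            class = c("transition_table", "data.frame"))
}

#' Validate a significant transition against the silhouette distribution
#'
#' Compares the source-wave silhouette scores of the children in a flagged
#' transition cell with the scores of their entire source cluster
#' (two-sample Kolmogorov-Smirnov test). A low p value indicates that the
#' transitioning children sit systematically differently within the cluster
#' (e.g. borderline members whose cluster assignment is imprecise), so the
#' transition may be an artefact of clustering imprecision rather than
#' behavioural change.
#'
#' @param solution Source-wave `cluster_solution` (from [select_k()]).
#' @param cluster_label Source cluster (integer label in the solution).
#' @param member_idx Indices (rows of the solution's coordinates) of the
#'   children in the transition cell.
#' @param min_members Minimum cell size to attempt validation (default 5).
#' @return List of class `transition_validation`: `statistic`, `p`,
#'   `member_scores`, `cluster_scores`; or, below `min_members`, a skipped
#'   result with a `reason`.
#' @export
validate_transition <- function(solution, cluster_label, member_idx,
                                min_members = 5) {
  stopifnot(inherits(solution, "cluster_solution"))
  cluster_scores <- solution$per_child_silhouette[solution$labels == cluster_label]
  member_scores <- solution$per_child_silhouette[member_idx]
  if (length(member_scores) < min_members) {
    return(structure(list(skipped = TRUE,
                          reason = sprintf("only %d members (< %d)",
                                           length(member_scores), min_members)),
                     class = "transition_validation"))
  }
  ks <- suppressWarnings(stats::ks.test(member_scores, cluster_scores))
  structure(list(skipped = FALSE, statistic = unname(ks$statistic),
                 p = ks$p.value, member_scores = member_scores,
                 cluster_scores = cluster_scores),
            class = "transition_validation")
}
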