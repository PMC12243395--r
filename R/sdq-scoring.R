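#' Score 25 SDQ items into the five difficulty subscales
#'
#' Each subscale is the sum of its five items (responses 0 = not true,
#' 1 = somewhat true, 2 = certainly true), giving scores from 0 to 10. The
#' prosocial subscale is reverse-scored into "antisocial" difficulty:
#' `antisocial = 10 - sum(prosocial items)`, so that higher scores reflect
#' greater difficulties on every subscale.
#'
#' Children with any missing item are excluded from the returned table (the
#' analysis requires complete SDQ responses); their `(child_id, wave)` keys are
#' recorded in the `"excluded"` attribute. An out-of-range item value is an
#' error.
#'
#' @param records Data frame with columns `child_id`, `wave` and
#'   `item_01`..`item_25`, responses in `{0, 1, 2}` or `NA`.
#' @param item_map Named list assigning item indices (1-25) to the subscales
#'   `emotional`, `conduct`, `hyperactivity`, `peer` and `prosocial`; see
#'   [default_item_map()].
#' @return Data frame with `child_id`, `wave` and one integer column per
#'   subscale (`emotional`, `conduct`, `hyperactivity`, `peer`, `antisocial`),
#'   each in `[0, 10]`. Attribute `"excluded"` holds the keys of children
#'   dropped for incomplete responses.
#' @export
score_subscales <- function(records, item_map = default_item_map()) {
  cols <- item_cols()
  missing_cols <- setdiff(c("child_id", "wave", cols), names(records))
  if (length(missing_cols) > 0)
    stopf("records table lacks columns: %s", paste(missing_cols, collapse = ", "))
  items <- as.matrix(records[, cols])
  bad <- !is.na(items) & !(items %in% 0:2)
  if (any(bad))
    stopf("item responses must be 0, 1 or 2; found %s", items[bad][1])

  incomplete <- rowSums(is.na(items)) > 0
  excluded <- records[incomplete, c("child_id", "wave"), drop = FALSE]
  keep <- records[!incomplete, , drop = FALSE]
  items <- items[!incomplete, , drop = FALSE]

  sums <- vapply(item_map, function(idx) {
    if (length(idx) != 5) stopf("each subscale must map to exactly 5 items")
    rowSums(items[, cols[idx], drop = FALSE])
  }, numeric(nrow(items)))
  if (nrow(items) == 1L) sums <- matrix(sums, nrow = 1, dimnames = list(NULL, names(item_map)))

  out <- data.frame(
    child_id = keep$child_id,
    wave = keep$wave,
    emotional = as.integer(sums[, "emotional"]),
    conduct = as.integer(sums[, "conduct"]),
    hyperactivity = as.integer(sums[, "hyperactivity"]),
    peer = as.integer(sums[, "peer"]),
    antisocial = as.integer(10 - sums[, "prosocial"])
  )
  attr(out, "excluded") <- excluded
  out
}

#' Default three-band cutpoints for the parent-rated SDQ
#'
#' The published parent-report banding: per subscale, scores up to `cut1` are
#' "normal", scores in `(cut1, cut2]` are "borderline", and scores above
#' `cut2` are "abnormal". The antisocial row is the prosocial banding mapped
#' through the reversal `antisocial = 10 - prosocial`. The table ships as a
#' YAML file (`inst/extdata/bands_parent_sdq.yaml`) and is data, not code:
#' pass any table with the same shape to use different cutpoints.
#'
#' @param path Optional path to a YAML or JSON band table.
#' @return Data frame with columns `subscale`, `cut1`, `cut2`.
#' @export
default_bands <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "bands_parent_sdq.yaml", package = "sdqtransitions")
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  bands <- data.frame(
    subscale = names(raw),
    cut1 = vapply(raw, function(b) as.numeric(b$cut1), numeric(1)),
    cut2 = vapply(raw, function(b) as.numeric(b$cut2), numeric(1)),
    row.names = NULL
  )
  validate_bands(bands)
  bands
}

validate_bands <- function(bands) {
  need <- c("subscale", "cut1", "cut2")
  if (!all(need %in% names(bands))) stopf("band table needs columns %s", paste(need, collapse = ", "))
  if (!all(SDQ_SUBSCALES %in% bands$subscale))
    stopf("band table must cover subscales: %s", paste(SDQ_SUBSCALES, collapse = ", "))
  ok <- bands$cut1 >= 0 & bands$cut1 < bands$cut2 & bands$cut2 <= 10
  if (!all(ok))
    stopf("invalid cutpoints for subscale '%s': need 0 <= cut1 < cut2 <= 10",
          bands$subscale[!ok][1])
  invisible(bands)
}

#' Assign a subscale score to its three-band category
#'
#' Normal if `score <= cut1`, borderline if `cut1 < score <= cut2`, abnormal
#' otherwise. The boundary convention (normal includes `cut1`, borderline
#' includes `cut2`) is fixed and monotone in the score.
#'
#' @param score Numeric vector of subscale scores in `[0, 10]`.
#' @param subscale Subscale name (one of [SDQ_SUBSCALES] values).
#' @param bands Band table as returned by [default_bands()].
#' @return Factor with levels `normal`, `borderline`, `abnormal`.
#' @export
band_subscale <- function(score, subscale, bands = default_bands()) {
  validate_bands(bands)
  if (any(score < 0 | score > 10, na.rm = TRUE)) stopf("scores must lie in [0, 10]")
  row <- bands[bands$subscale == subscale, ]
  if (nrow(row) != 1) stopf("unknown subscale '%s'", subscale)
  out <- ifelse(score <= row$cut1, "normal",
                ifelse(score <= row$cut2, "borderline", "abnormal"))
  factor(out, levels = c("normal", "borderline", "abnormal"))
}

#' Partition children into elevated and non-elevated difficulty groups
#'
#' A child is "non_elevated" if and only if all five subscale bands are
#' normal; any borderline or abnormal band makes the child "elevated".
#'
#' @param scores Subscale score table from [score_subscales()].
#' @param bands Band table; see [default_bands()].
#' @return Data frame with `child_id`, `wave`, per-subscale band columns
#'   (`band_emotional`, ...) and `label` in `{elevated, non_elevated}`.
#' @export
partition_sample <- function(scores, bands = default_bands()) {
  band_cols <- lapply(SDQ_SUBSCALES, function(s) {
    if (any(is.na(scores[[s]]))) stopf("missing band input for subscale '%s'", s)
    band_subscale(scores[[s]], s, bands)
  })
  names(band_cols) <- paste0("band_", SDQ_SUBSCALES)
  all_normal <- Reduce(`&`, lapply(band_cols, function(b) b == "normal"))
  out <- data.frame(child_id = scores$child_id, wave = scores$wave, band_cols,
                    label = ifelse(all_normal, "non_elevated", "elevated"))
  out
}

#' Standardise subscale scores within a group
#'
#' z-scores each subscale column within the supplied table, which by design is
#' one wave's elevated, outlier-screened group (the population the clustering
#' operates on). Uses the sample standard deviation (n - 1 denominator) by
#' default.
#'
#' @param scores Subscale score table (>= 2 rows).
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return The table with subscale columns replaced by their z-scores; each
#'   column has mean 0 and the chosen SD equal to 1.
#' @export
zscore_subscales <- function(scores, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (nrow(scores) < 2) stopf("z-scoring needs at least 2 children")
  out <- scores
  for (s in SDQ_SUBSCALES) {
    x <- scores[[s]]
    n <- length(x)
    sdev <- stats::sd(x)
    if (sd_type == "population") sdev <- sdev * sqrt((n - 1) / n)
    if (!is.finite(sdev) || sdev == 0)
      stopf("subscale '%s' has zero variance; cannot z-score", s)
    out[[s]] <- (x - mean(x)) / sdev
  }
  out
}
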