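#' UMAP embedding parameters
#'
#' Defaults follow the analysis configuration: a relatively high neighbourhood
#' size (`n_neighbors = 50`) to suppress fine-grained noise structure, a low
#' `min_dist = 0.01` for dense, well-separated clusters, a correlation
#' distance metric over the five z-scored subscales, and a two-dimensional
#' target space.
#'
#' @param n_neighbors Positive integer (default 50).
#' @param min_dist Nonnegative (default 0.01).
#' @param metric Distance metric name (default `"correlation"`).
#' @param n_components Embedding dimension (default 2).
#' @param seed Integer seed for the embedding optimiser.
#' @return List of class `embedding_params`.
#' @export
embedding_params <- function(n_neighbors = 50, min_dist = 0.01,
                             metric = "correlation", n_components = 2,
                             seed = 42L) {
  stopifnot(n_neighbors >= 2, min_dist >= 0, n_components >= 1)
  structure(list(n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
                 metric = metric, n_components = as.integer(n_components),
                 seed = as.integer(seed)),
            class = "embedding_params")
}

#' Embed z-scored subscale profiles with UMAP
#'
#' Deterministic given the parameter seed (single-threaded optimisation).
#' Because the five subscales are discrete 0-10 sums, cohorts contain many
#' children with exactly identical profiles; the embedding is therefore fit on
#' the unique profile rows and duplicates receive their representative's
#' coordinates. This keeps nearest-neighbour sets spanning distinct profiles
#' rather than stacks of ties (the same handling umap-learn offers via
#' `unique=True`) and guarantees identical inputs get identical coordinates.
#' The parameters used are attached to the result as the `"params"` attribute.
#'
#' @param z Matrix or data frame of z-scored subscale columns (rows = children;
#'   any `child_id`/`wave`/`label` columns are carried through, not embedded).
#' @param params An [embedding_params()] object. At least `n_neighbors + 1`
#'   unique rows are required.
#' @return Numeric matrix `n x n_components` (columns `x`, `y` for 2-D).
#' @export
embed_profiles <- function(z, params = embedding_params()) {
  X <- as.matrix(if (is.data.frame(z)) z[, intersect(SDQ_SUBSCALES, names(z)), drop = FALSE] else z)
  storage.mode(X) <- "double"
  key <- apply(X, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  if (sum(first) < params$n_neighbors + 1)
    stopf("embedding needs at least n_neighbors + 1 = %d unique rows; got %d",
          params$n_neighbors + 1, sum(first))
  unique_coords <- with_seed(params$seed,
    uwot::umap(X[first, , drop = FALSE],
               n_neighbors = params$n_neighbors, min_dist = params$min_dist,
               metric = params$metric, n_components = params$n_components,
               n_threads = 1, n_sgd_threads = 0))
  coords <- unique_coords[match(key, key[first]), , drop = FALSE]
  colnames(coords) <- if (params$n_components == 2) c("x", "y")
                      else paste0("dim", seq_len(params$n_components))
  attr(coords, "params") <- params
  coords
}

#' k-means clustering of embedded coordinates
#'
#' Standard k-means with `n_init` random restarts (k-means++-style behaviour
#' comes from the multiple restarts of Hartigan-Wong); deterministic given the
#' seed.
#'
#' @param coords Embedding coordinates (matrix).
#' @param k Number of clusters (`2 <= k < n`).
#' @param seed Integer seed.
#' @param n_init Number of restarts (default 10).
#' @return Integer label vector in `1..k`.
#' @export
cluster_k <- function(coords, k, seed = 1L, n_init = 10) {
  n <- nrow(coords)
  if (k < 2 || k >= n) stopf("k must satisfy 2 <= k < n (n = %d)", n)
  fit <- with_seed(seed,
    stats::kmeans(coords, centers = k, nstart = n_init, iter.max = 100))
  fit$cluster
}

# Calinski-Harabasz index: (between-dispersion/(k-1)) / (within-dispersion/(n-k)).
calinski_harabasz <- function(coords, labels) {
  X <- as.matrix(coords)
  n <- nrow(X); ks <- unique(labels); k <- length(ks)
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(X)
  W <- 0; B <- 0
  for (g in ks) {
    Xg <- X[labels == g, , drop = FALSE]
    cg <- colMeans(Xg)
    W <- W + sum(sweep(Xg, 2, cg)^2)
    B <- B + nrow(Xg) * sum((cg - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Cluster validity metrics: silhouette and Calinski-Harabasz
#'
#' Silhouette uses the standard `(b - a)/max(a, b)` definition with Euclidean
#' distance in the embedding; the Calinski-Harabasz index is the ratio of
#' between- to within-cluster dispersion, each scaled by its degrees of
#' freedom.
#'
#' @param coords Embedding coordinates.
#' @param labels Cluster labels (>= 2 clusters, each nonempty).
#' @return List with `mean_silhouette`, `per_cluster_silhouette` (named),
#'   `per_child_silhouette`, and `calinski_harabasz`.
#' @export
validity_metrics <- function(coords, labels) {
  labels <- as.integer(factor(labels))
  k <- length(unique(labels)); n <- length(labels)
  if (k < 2) stopf("validity metrics need at least 2 clusters")
  if (k == n) stopf("silhouette is undefined when every cluster is a singleton")
  sil <- cluster::silhouette(labels, stats::dist(coords))
  widths <- sil[, "sil_width"]
  per_cluster <- tapply(widths, labels, mean)
  list(mean_silhouette = mean(widths),
       per_cluster_silhouette = per_cluster,
       per_child_silhouette = widths,
       calinski_harabasz = calinski_harabasz(coords, labels))
}

#' Jaccard similarity of two index sets
#'
#' `|A intersect B| / |A union B|`; 1 iff the sets are equal, symmetric.
#' @param a,b Vectors interpreted as sets (duplicates count once).
#' @return Numeric in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Bootstrap Jaccard stability of a clustering
#'
#' For each of `B` bootstrap resamples of the rows (with replacement), k-means
#' is refit (same `k`, fresh seed stream) on the resampled coordinates; each
#' original cluster is matched to the bootstrap cluster with the best Jaccard
#' overlap, computed over the children present in the resample (a child drawn
#' several times counts once). Reported per cluster as the mean best overlap
#' over the `B` resamples; the stability criterion is mean >= 0.85.
#'
#' @param coords Embedding coordinates.
#' @param labels Accepted cluster labels on `coords`.
#' @param B Number of bootstrap iterations (default 1000).
#' @param seed Integer seed for the resampling and refit stream.
#' @param n_init k-means restarts per refit.
#' @return Named numeric: mean Jaccard per original cluster.
#' @export
bootstrap_jaccard <- function(coords, labels, B = 1000, seed = 1L, n_init = 10) {
  if (B < 1) stopf("B must be at least 1")
  labels <- as.integer(factor(labels))
  k <- length(unique(labels)); n <- nrow(coords)
  orig <- split(seq_len(n), labels)
  seeds <- derive_seeds(seed, B)
  acc <- matrix(0, nrow = B, ncol = k)
  for (b in seq_len(B)) {
    idx <- with_seed(seeds[b], sample.int(n, n, replace = TRUE))
    boot_labels <- cluster_k(coords[idx, , drop = FALSE], k, seed = seeds[b],
                             n_init = n_init)
    present <- unique(idx)
    # each unique child takes the label of its first occurrence (identical
    # coordinates always cluster together)
    first <- match(present, idx)
    boot <- split(present, boot_labels[first])
    for (j in seq_len(k)) {
      a <- intersect(orig[[j]], present)
      acc[b, j] <- max(vapply(boot, function(bc) jaccard(a, bc), numeric(1)))
    }
  }
  stats::setNames(colMeans(acc), names(orig))
}

#' Select the number of clusters by the tri-criterion validity rule
#'
#' For each `k` in `k_range`, k-means labels and validity metrics are
#' computed. Candidates are the `k` whose mean silhouette exceeds
#' `sil_threshold` and whose per-cluster silhouette means are all positive.
#' Candidates are ranked by the "steep increase" of the Calinski-Harabasz
#' index, scored as the backward relative jump
#' `(CH(k) - CH(k-1)) / CH(k-1)` (0 for the smallest `k` in the range, where
#' no preceding value exists); with `ch_rule = "max"` plain CH is used
#' instead. Starting from the highest-ranked candidate, bootstrap Jaccard
#' stability is evaluated and the first candidate whose per-cluster mean
#' Jaccard all reach `jac_threshold` is accepted. If no candidate passes (or
#' the candidate set is empty) the best available solution is returned with
#' `accepted = FALSE` and diagnostics for every `k`.
#'
#' @param coords Embedding coordinates for one wave's elevated group.
#' @param k_range Integer range of cluster counts to scan (default `2:10`).
#' @param sil_threshold Mean-silhouette acceptance threshold (default 0.5).
#' @param jac_threshold Per-cluster bootstrap Jaccard threshold (default 0.85).
#' @param B Bootstrap iterations for the stability check (default 1000).
#' @param seed Integer seed driving k-means and the bootstrap.
#' @param ch_rule `"relative_jump"` (default) or `"max"`.
#' @param wave Optional wave label stored in the solution.
#' @return Object of class `cluster_solution`: `wave`, `coordinates`, `k`,
#'   `labels`, `mean_silhouette`, `per_cluster_silhouette`,
#'   `per_child_silhouette`, `calinski_harabasz`, `per_cluster_jaccard`,
#'   `accepted`, and `diagnostics` (one row per scanned `k`).
#' @export
select_k <- function(coords, k_range = 2:10, sil_threshold = 0.5,
                     jac_threshold = 0.85, B = 1000, seed = 1L,
                     ch_rule = c("relative_jump", "max"), wave = NA_character_) {
  ch_rule <- match.arg(ch_rule)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 1 || min(k_range) < 2 || max(k_range) >= nrow(coords))
    stopf("k_range must lie within [2, n-1]")
  seeds <- derive_seeds(seed, length(k_range) + 1L)

  scan <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    labels <- cluster_k(coords, k, seed = seeds[i])
    vm <- validity_metrics(coords, labels)
    scan[[i]] <- list(k = k, labels = labels, vm = vm)
  }
  ch <- vapply(scan, function(s) s$vm$calinski_harabasz, numeric(1))
  msil <- vapply(scan, function(s) s$vm$mean_silhouette, numeric(1))
  min_cluster_sil <- vapply(scan, function(s) min(s$vm$per_cluster_silhouette), numeric(1))
  ch_jump <- c(0, diff(ch) / ch[-length(ch)])
  score <- if (ch_rule == "relative_jump") ch_jump else ch
  candidate <- msil > sil_threshold & min_cluster_sil > 0

  diagnostics <- data.frame(k = k_range, mean_silhouette = msil,
                            min_cluster_silhouette = min_cluster_sil,
                            calinski_harabasz = ch, ch_jump = ch_jump,
                            candidate = candidate)

  build <- function(i, accepted, jac) {
    s <- scan[[i]]
    structure(list(wave = wave, coordinates = coords, k = s$k,
                   labels = s$labels,
                   mean_silhouette = s$vm$mean_silhouette,
                   per_cluster_silhouette = s$vm$per_cluster_silhouette,
                   per_child_silhouette = s$vm$per_child_silhouette,
                   calinski_harabasz = s$vm$calinski_harabasz,
                   per_cluster_jaccard = jac, accepted = accepted,
                   diagnostics = diagnostics),
              class = "cluster_solution")
  }

  if (!any(candidate)) {
    best <- which.max(msil)
    return(build(best, accepted = FALSE, jac = NULL))
  }
  order_cand <- order(-score, k_range)  # ties toward smaller k
  order_cand <- order_cand[candidate[order_cand]]
  jac_seen <- list()
  for (i in order_cand) {
    jac <- bootstrap_jaccard(coords, scan[[i]]$labels, B = B,
                             seed = seeds[length(seeds)])
    jac_seen[[as.character(k_range[i])]] <- jac
    if (all(jac >= jac_threshold)) return(build(i, accepted = TRUE, jac = jac))
  }
  top <- order_cand[1]
  build(top, accepted = FALSE, jac = jac_seen[[as.character(k_range[top])]])
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution>", if (!is.na(x$wave)) paste0("wave ", x$wave, ";"),
      "k =", x$k, if (isTRUE(x$accepted)) "(accepted)" else "(NOT accepted)", "\n")
  cat(sprintf("  mean silhouette %.3f | CH %.1f\n",
              x$mean_silhouette, x$calinski_harabasz))
  if (!is.null(x$per_cluster_jaccard))
    cat("  bootstrap Jaccard:",
        paste(sprintf("%.3f", x$per_cluster_jaccard), collapse = " "), "\n")
  invisible(x)
}
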