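#' Cluster one wave's elevated group end-to-end
#'
#' Convenience wrapper chaining the per-wave stages: score the 25 items,
#' partition into elevated/non-elevated, screen outliers within each group,
#' z-score the retained elevated children's subscales, embed with UMAP and
#' select the cluster solution under the tri-criterion rule.
#'
#' @param records Item records for one wave (`child_id`, `wave`,
#'   `item_01`..`item_25`).
#' @param bands Band table (default [default_bands()]).
#' @param params Embedding parameters (default [embedding_params()]).
#' @param k_range,B,sil_threshold,jac_threshold Passed to [select_k()].
#' @param k_sd,alpha Passed to [apply_screen()].
#' @param seed Seed for clustering and the bootstrap.
#' @return List with `scores`, `partition`, `screen` (report), `elevated`
#'   (retained z-scored table), `solution` (a `cluster_solution`), and
#'   `groups`: per-child group labels (`cluster_<j>` for elevated children in
#'   the accepted solution, `non_elevated` otherwise) for transition linking.
#' @export
cluster_wave <- function(records, bands = default_bands(),
                         params = embedding_params(), k_range = 2:10,
                         B = 1000, sil_threshold = 0.5, jac_threshold = 0.85,
                         k_sd = 3, alpha = 0.999, seed = 1L) {
  wave <- unique(records$wave)
  if (length(wave) != 1) stopf("cluster_wave expects records from exactly one wave")
  scores <- score_subscales(records)
  partition <- partition_sample(scores, bands)
  screened <- apply_screen(scores, partition, k_sd = k_sd, alpha = alpha)
  elev <- screened$retained[screened$retained$label == "elevated", , drop = FALSE]
  z <- zscore_subscales(elev)
  coords <- embed_profiles(z, params)
  solution <- select_k(coords, k_range = k_range, sil_threshold = sil_threshold,
                       jac_threshold = jac_threshold, B = B, seed = seed,
                       wave = wave)
  nonelev <- screened$retained[screened$retained$label == "non_elevated", ]
  groups <- rbind(
    data.frame(child_id = elev$child_id,
               group = paste0("cluster_", solution$labels)),
    if (nrow(nonelev) > 0)
      data.frame(child_id = nonelev$child_id, group = "non_elevated"))
  list(scores = scores, partition = partition, screen = screened$report,
       elevated = z, solution = solution, groups = groups)
}

#' Write a cluster solution to delimited text outputs
#'
#' Writes `clusters_<wave>.csv` (child_id, x, y, label) and
#' `solution_<wave>.json` (k, validity metrics, acceptance) into `dir`.
#'
#' @param wave_result Result of [cluster_wave()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_wave_result <- function(wave_result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sol <- wave_result$solution
  coords <- as.data.frame(sol$coordinates)
  out <- data.frame(child_id = wave_result$elevated$child_id, coords,
                    label = sol$labels)
  utils::write.csv(out, file.path(dir, sprintf("clusters_%s.csv", sol$wave)),
                   row.names = FALSE)
  meta <- list(wave = sol$wave, k = sol$k, accepted = sol$accepted,
               mean_silhouette = sol$mean_silhouette,
               per_cluster_silhouette = as.list(sol$per_cluster_silhouette),
               calinski_harabasz = sol$calinski_harabasz,
               per_cluster_jaccard = as.list(sol$per_cluster_jaccard))
  jsonlite::write_json(meta, file.path(dir, sprintf("solution_%s.json", sol$wave)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
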