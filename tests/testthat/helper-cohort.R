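# Shared fixtures, built in code.

subscales <- c("emotional", "conduct", "hyperactivity", "peer", "antisocial")

# A records row from explicit item values.
make_records <- function(items_matrix, wave = "w1") {
  colnames(items_matrix) <- sprintf("item_%02d", 1:25)
  data.frame(child_id = seq_len(nrow(items_matrix)), wave = wave, items_matrix)
}

# Minimal two-wave spec with two elevated profiles plus non_elevated.
tiny_spec <- function(n = 200, seed = 1L, dispersion = 0.05,
                      transition = NULL, effect_spec = list(),
                      covariate_spec = list(), missingness = list(),
                      dropout = 0) {
  profiles <- list(
    hi_conduct = c(emotional = 1, conduct = 8, hyperactivity = 2, peer = 1, antisocial = 1),
    hi_emotional = c(emotional = 8, conduct = 1, hyperactivity = 1, peer = 2, antisocial = 1),
    non_elevated = c(emotional = 1, conduct = 1, hyperactivity = 1, peer = 1, antisocial = 1))
  if (is.null(transition)) {
    transition <- matrix(1 / 3, 3, 3,
                         dimnames = list(names(profiles), names(profiles)))
  }
  cohort_spec(
    n_children = n, waves = c("w1", "w2"),
    cluster_profiles = list(w1 = profiles, w2 = profiles),
    transition_matrices = list(transition),
    profile_dispersion = dispersion,
    covariate_spec = covariate_spec, effect_spec = effect_spec,
    missingness = missingness, dropout = dropout, seed = seed)
}

# Well-separated planted blobs in 2-D (embedding-space stand-in).
make_blobs <- function(centers, n_per, sd = 0.5, seed = 1L) {
  withr::with_seed(seed, {
    coords <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
    }))
    list(coords = coords, truth = rep(seq_len(nrow(centers)), each = n_per))
  })
}

# A spec with well-separated elevated profiles (pairwise profile distance
# >= 4x the pooled within-profile SD of the binomial item noise) whose first
# wave is entirely elevated: used for planted-k recovery. The archetypes
# mirror internalizing, externalizing and peer/social difficulty patterns.
separated_spec <- function(n, k = 3, seed = 1L, dispersion = 0.05,
                           transition = NULL, non_elevated_share = 0) {
  base <- c(emotional = 1, conduct = 1, hyperactivity = 1, peer = 1, antisocial = 1)
  arch <- list(c(emotional = 9),                      # internalizing
               c(conduct = 9, hyperactivity = 6),     # externalizing
               c(peer = 9, antisocial = 6),           # peer/social
               c(hyperactivity = 9, emotional = 6),
               c(antisocial = 9, conduct = 6))
  profs <- lapply(seq_len(k), function(i) {
    p <- base
    p[names(arch[[i]])] <- arch[[i]]
    p
  })
  names(profs) <- paste0("elev_", seq_len(k))
  profs$non_elevated <- base
  groups <- names(profs)
  if (is.null(transition)) {
    M <- diag(length(groups)); dimnames(M) <- list(groups, groups)
  } else {
    M <- transition
  }
  share <- (1 - non_elevated_share) / k
  init <- setNames(rep(share, k), names(profs)[seq_len(k)])
  init <- c(init, non_elevated = non_elevated_share)
  cohort_spec(n_children = n, waves = c("w1", "w2"),
              cluster_profiles = list(w1 = profs, w2 = profs),
              transition_matrices = list(M),
              profile_dispersion = dispersion,
              initial_distribution = init, seed = seed)
}
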