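#' Generator configurations for a synthetic study cohort
#'
#' Builds per-dyad generator configurations emulating the study design:
#' `n_good + n_poor` patient-therapist dyads over a shared 8-state space.
#' All patients follow one mixed distance/frequency law (their
#' transitions retain a clear distance dependence); therapists follow an
#' almost purely frequency-driven law. Therapists of poor-outcome dyads
#' additionally receive a per-subject perturbation of their target state
#' frequencies, making their dynamics mutually heterogeneous — the
#' feature that drives a positive poor-poor DeltaCorr. Patient profiles
#' carry 2 sub-1% states and therapist profiles 3, so 1%-share pruning
#' of an 8-state solution leaves 6 and 5 active states.
#'
#' @param n_good,n_poor dyads per outcome class (default 4 and 4).
#' @param n_blocks series length per dyad (default 1000).
#' @param seed base seed; per-dyad sub-seeds are derived via
#'   [derive_seed()].
#' @param coupling therapist-copies-patient probability (default 0.3).
#' @param ther_heterogeneity log-normal sd of the poor-outcome
#'   therapists' frequency perturbation (default 0.7).
#' @return A list of dyad specs: `subject_id`, `outcome`, `config_pat`,
#'   `config_ther`, `seed`.
#' @export
cohort_configs <- function(n_good = 4L, n_poor = 4L, n_blocks = 1000L,
                           seed = 1L, coupling = 0.3,
                           ther_heterogeneity = 0.7) {
  outcomes <- c(rep("good", n_good), rep("poor", n_poor))
  ids <- c(paste0("good", seq_len(n_good), recycle0 = TRUE),
           paste0("poor", seq_len(n_poor), recycle0 = TRUE))
  # rare "outlier" states sit far outside the major cube, as scarce
  # states do in the study's scaled phase space; their target shares are
  # set so their realized (stationary) occupancy stays below the 1%
  # pruning threshold despite the distance kernel's self-transition pull
  cents_pat <- default_centroids(8L)
  cents_pat[7:8, ] <- cents_pat[7:8, ] * 5
  cents_ther <- default_centroids(8L)
  cents_ther[6:8, ] <- cents_ther[6:8, ] * 5
  state_map <- c(1L, 2L, 3L, 4L, 5L, 1L, 2L, 3L)
  lapply(seq_along(ids), function(s) {
    dyad_seed <- derive_seed(seed, 100L + s)
    pat <- generator_config(
      k = 8L, centroids = cents_pat,
      target_freqs = default_target_freqs(8L, n_rare = 2L,
                                          rare_share = 0.0008),
      w_dist = 0.005, w_freq = 0.995, length_scale = 2,
      emission_sd = 0.35, n_blocks = n_blocks, coupling = coupling,
      seed = dyad_seed,
      feature_means = rep(0.15, 3), feature_sds = rep(0.025, 3)
    )
    f_ther <- default_target_freqs(8L, n_rare = 3L, rare_share = 0.004)
    if (outcomes[s] == "poor") {
      set.seed(derive_seed(seed, 200L + s))
      major <- seq_len(5L)
      f_ther[major] <- f_ther[major] *
        exp(stats::rnorm(5L, 0, ther_heterogeneity))
      f_ther[major] <- f_ther[major] / sum(f_ther[major]) *
        (1 - sum(f_ther[-major]))
    }
    ther <- generator_config(
      k = 8L, centroids = cents_ther, target_freqs = f_ther,
      w_dist = 0, w_freq = 1, length_scale = 2,
      emission_sd = 0.35, n_blocks = n_blocks, coupling = coupling,
      seed = dyad_seed,
      feature_means = rep(0.15, 3), feature_sds = rep(0.025, 3)
    )
    list(subject_id = ids[s], outcome = outcomes[s],
         config_pat = pat, config_ther = ther, seed = dyad_seed,
         state_map = state_map)
  })
}

#' Simulate a cohort of dyads
#'
#' @param configs output of [cohort_configs()].
#' @return A list per dyad: the [simulate_dyad()] output plus
#'   `subject_id` and `outcome`.
#' @export
simulate_cohort <- function(configs) {
  lapply(configs, function(cfg) {
    sim <- simulate_dyad(cfg$config_pat, cfg$config_ther, seed = cfg$seed,
                         state_map = cfg$state_map %||%
                           seq_len(cfg$config_ther$k))
    sim$pat_states$subject_id <- cfg$subject_id
    sim$ther_states$subject_id <- cfg$subject_id
    sim$subject_id <- cfg$subject_id
    sim$outcome <- cfg$outcome
    sim
  })
}

pair_class <- function(o1, o2) {
  paste(sort(c(o1, o2)), collapse = "-")
}

#' Run the full symbolic-dynamics pipeline on a cohort
#'
#' End-to-end orchestration: pool each role's block features across
#' subjects, standardize and fit k-means states, prune scarcely
#' populated states on the pooled occupancy, relabel every subject,
#' estimate individual and dyadic transition matrices, compute the
#' correlation panels, DeltaCorr records and class summaries, fit the
#' transition-law regressions with mode comparison and cohort summary,
#' and screen every sequence for first-third vs. last-third occupancy
#' drift. Deterministic given the seeds recorded in `config`.
#'
#' @param series_list list with one element per dyad: `subject_id`,
#'   `outcome`, `series` (block-series tibble). Typically from
#'   [simulate_cohort()], or built from loaded files.
#' @param k number of states (default 8).
#' @param n_restarts k-means restarts (default 50).
#' @param seed seed for the clustering stage.
#' @param min_share pruning threshold (default 0.01).
#' @param cell_policy MTM-correlation cell policy.
#' @param include_diagonal keep diagonal cells in the regression design.
#' @param correction drift-test correction.
#' @param out_dir optional directory; when given, CSV/JSON outputs are
#'   written there.
#' @return A list with `models`, `sequences`, `mtms`, `panels`,
#'   `delta_records`, `class_summaries`, `regressions`, `mode_tables`,
#'   `cohort`, `drift`, `manifest`.
#' @export
run_pipeline <- function(series_list, k = 8L, n_restarts = 50L, seed = 1L,
                         min_share = 0.01, cell_policy = "both_defined",
                         include_diagonal = TRUE, correction = "yates",
                         out_dir = NULL) {
  if (length(series_list) < 2L) {
    stop("pipeline stage 'input': need at least 2 dyads", call. = FALSE)
  }
  ids <- vapply(series_list, function(x) x$subject_id, character(1))
  outcomes <- vapply(series_list, function(x) x$outcome, character(1))

  roles <- c("patient", "therapist")
  models <- list()
  sequences <- list()
  for (role in roles) {
    feats <- lapply(series_list, function(x) role_features(x$series, role))
    pooled <- do.call(rbind, feats)
    std <- standardize_features(pooled)
    model <- fit_states(std$z, k = k, n_restarts = n_restarts, seed = seed,
                        constants = std, role = role)
    # pruning decision on pooled occupancy, applied per subject
    share <- model$occupancy / sum(model$occupancy)
    active <- which(share >= min_share)
    if (length(active) == 0L) {
      stop("pipeline stage 'prune': every state below min_share",
           call. = FALSE)
    }
    model$active_states <- as.integer(active)
    models[[role]] <- model
    sequences[[role]] <- lapply(seq_along(series_list), function(s) {
      seq_full <- assign_states(series_list[[s]]$series, model,
                                subject_id = ids[s])
      restrict_to_states(seq_full, active)
    })
  }

  mtms <- list(
    patient = lapply(sequences$patient, function(s) mtm(s, k)),
    therapist = lapply(sequences$therapist, function(s) mtm(s, k)),
    p2t = lapply(seq_along(ids), function(s) {
      dyad_mtm(sequences$patient[[s]], sequences$therapist[[s]], k, "P2T")
    }),
    t2p = lapply(seq_along(ids), function(s) {
      dyad_mtm(sequences$patient[[s]], sequences$therapist[[s]], k, "T2P")
    })
  )

  panels <- lapply(mtms, correlation_panel, cell_policy = cell_policy)

  delta_records <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq(i + 1L, length(ids))) {
      delta_records[[length(delta_records) + 1L]] <- delta_corr(
        mtms$patient[[i]], mtms$patient[[j]],
        mtms$therapist[[i]], mtms$therapist[[j]],
        pair = c(ids[i], ids[j]),
        class = pair_class(outcomes[i], outcomes[j]),
        cell_policy = cell_policy
      )
    }
  }
  delta_records <- do.call(rbind, delta_records)
  class_counts <- table(delta_records$class)
  summarisable <- names(class_counts)[class_counts >= 2]
  class_summaries <- do.call(rbind, lapply(
    intersect(c("good-good", "good-poor", "poor-poor"), summarisable),
    function(cl) class_summary(delta_records, cl)
  ))

  regressions <- list()
  mode_tables <- list()
  for (role in roles) {
    dists <- centroid_distances(models[[role]])
    for (s in seq_along(ids)) {
      freqs <- state_frequencies(sequences[[role]][[s]], k)
      design <- build_design(mtms[[role]][[s]], dists, freqs,
                             include_diagonal = include_diagonal)
      regressions[[length(regressions) + 1L]] <-
        fit_model(design, "full", subject_id = ids[s], role = role)
      mode_tables[[length(mode_tables) + 1L]] <-
        compare_modes(mtms[[role]][[s]], dists, freqs,
                      subject_id = ids[s], role = role,
                      include_diagonal = include_diagonal)
    }
  }
  regressions <- do.call(rbind, regressions)
  mode_tables <- do.call(rbind, mode_tables)
  cohort <- cohort_summary(regressions)

  drift <- do.call(rbind, lapply(roles, function(role) {
    do.call(rbind, lapply(sequences[[role]], drift_screen,
                          correction = correction))
  }))

  manifest <- list(
    package_version = as.character(utils::packageVersion("symdyad")),
    subjects = ids, outcomes = outcomes,
    k = k, n_restarts = n_restarts, seed = seed, min_share = min_share,
    cell_policy = cell_policy, include_diagonal = include_diagonal,
    correction = correction,
    active_states = lapply(models, function(m) m$active_states),
    variance_explained = lapply(models, function(m) m$variance_explained)
  )

  out <- list(models = models, sequences = sequences, mtms = mtms,
              panels = panels, delta_records = delta_records,
              class_summaries = class_summaries, regressions = regressions,
              mode_tables = mode_tables, cohort = cohort, drift = drift,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Write pipeline outputs to a directory
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(result$delta_records, "delta_corr_pairs.csv")
  w(result$class_summaries, "delta_corr_class_summary.csv")
  w(result$regressions, "transition_model_subjects.csv")
  w(result$mode_tables, "transition_model_modes.csv")
  w(result$cohort$by_role, "transition_model_cohort.csv")
  w(result$drift, "drift_screen.csv")
  for (grp in names(result$mtms)) {
    for (m in result$mtms[[grp]]) {
      write_mtm_csv(m, file.path(out_dir,
                                 sprintf("mtm_%s_%s.csv", grp, m$subject_id)))
    }
  }
  for (role in names(result$panels)) {
    w(result$panels[[role]]$pairs, sprintf("correlation_panel_%s.csv", role))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
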