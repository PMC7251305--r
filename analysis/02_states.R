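# Discretize the cohort into symbolic state sequences: pool each role's
# block features across subjects, z-score, fit 8 k-means states, prune
# states holding under 1% of pooled occupancy, and relabel every
# subject's series. Writes the two cluster models (JSON) and the pruned
# label sequences (CSV).
source(file.path("analysis", "00_common.R"))

seed <- parse_seed()
series_list <- read_cohort_series()
out <- res_dir("states")

for (role in c("patient", "therapist")) {
  pooled <- do.call(rbind, lapply(series_list,
                                  function(x) role_features(x$series, role)))
  std <- standardize_features(pooled)
  model <- fit_states(std$z, k = 8, n_restarts = 50, seed = seed,
                      constants = std, role = role)
  share <- model$occupancy / sum(model$occupancy)
  model$active_states <- which(share >= 0.01)
  write_cluster_model(model, file.path(out, paste0("model_", role, ".json")))

  seqs <- lapply(series_list, function(x) {
    restrict_to_states(
      assign_states(x$series, model, subject_id = x$subject_id),
      model$active_states
    )
  })
  write_state_sequences(seqs, file.path(out, paste0("labels_", role, ".csv")))

  cat(sprintf(
    "%s: variance explained %.1f%%, %d/8 states survive 1%% pruning (dropped: %s)\n",
    role, 100 * model$variance_explained, length(model$active_states),
    paste(setdiff(1:8, model$active_states), collapse = ",")
  ))
}
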