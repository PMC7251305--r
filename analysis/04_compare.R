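# Direct comparison of the transition networks: pairwise Pearson
# correlations between subjects' matrices within each role and dyad
# direction, the DeltaCorr index (patient-side minus therapist-side
# similarity) for every dyad pair, and outcome-class summaries with
# normal-approximation 95% confidence intervals.
source(file.path("analysis", "00_common.R"))

out <- res_dir("comparison")
manifest <- jsonlite::read_json(file.path("results", "cohort",
                                          "cohort_manifest.json"),
                                simplifyVector = TRUE)
outcome_of <- stats::setNames(manifest$outcomes, manifest$subjects)

mats <- list()
for (role in c("patient", "therapist")) {
  model <- read_cluster_model(file.path("results", "states",
                                        paste0("model_", role, ".json")))
  seqs <- read_state_sequences(file.path("results", "states",
                                         paste0("labels_", role, ".csv")),
                               active_states = model$active_states)
  mats[[role]] <- lapply(seqs, mtm, k = 8)
  names(mats[[role]]) <- vapply(seqs, function(s) s$subject_id, "")
}

for (role in names(mats)) {
  panel <- correlation_panel(unname(mats[[role]]))
  utils::write.csv(panel$pairs,
                   file.path(out, paste0("correlation_panel_", role, ".csv")),
                   row.names = FALSE)
  cat(sprintf("%s matrices: mean pairwise r = %.3f (sd %.3f)\n",
              role, panel$mean, panel$sd))
}

ids <- names(mats$patient)
records <- list()
for (i in seq_len(length(ids) - 1)) {
  for (j in seq(i + 1, length(ids))) {
    records[[length(records) + 1]] <- delta_corr(
      mats$patient[[ids[i]]], mats$patient[[ids[j]]],
      mats$therapist[[ids[i]]], mats$therapist[[ids[j]]],
      pair = c(ids[i], ids[j]),
      class = paste(sort(c(outcome_of[ids[i]], outcome_of[ids[j]])),
                    collapse = "-")
    )
  }
}
records <- do.call(rbind, records)
utils::write.csv(records, file.path(out, "delta_corr_pairs.csv"),
                 row.names = FALSE)

summaries <- do.call(rbind, lapply(
  intersect(c("good-good", "good-poor", "poor-poor"), unique(records$class)),
  function(cl) class_summary(records, cl)
))
utils::write.csv(summaries, file.path(out, "delta_corr_class_summary.csv"),
                 row.names = FALSE)
for (i in seq_len(nrow(summaries))) {
  with(summaries[i, ], cat(sprintf(
    "DeltaCorr %s: mean %.3f (sd %.3f), 95%% CI [%.3f, %.3f]%s\n",
    class, mean, sd, ci_lower, ci_upper,
    if (ci_lower > 0 || ci_upper < 0) " - excludes zero" else ""
  )))
}
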