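# Model-mediated comparison: regress each subject's linearized
# transition probabilities on inter-state centroid distance and
# composite state frequency (standardized OLS), compare the four
# candidate transition laws by adjusted R2, and summarise by role,
# including the cross-role distance-dependence ratio.
source(file.path("analysis", "00_common.R"))

out <- res_dir("transition_law")

fits <- list(); modes <- list()
for (role in c("patient", "therapist")) {
  model <- read_cluster_model(file.path("results", "states",
                                        paste0("model_", role, ".json")))
  seqs <- read_state_sequences(file.path("results", "states",
                                         paste0("labels_", role, ".csv")),
                               active_states = model$active_states)
  dists <- centroid_distances(model)
  for (s in seqs) {
    Tm <- mtm(s, model$k)
    freqs <- state_frequencies(s, model$k)
    design <- build_design(Tm, dists, freqs)
    fits[[length(fits) + 1]] <- fit_model(design, "full",
                                          subject_id = s$subject_id,
                                          role = role)
    modes[[length(modes) + 1]] <- compare_modes(Tm, dists, freqs,
                                                subject_id = s$subject_id,
                                                role = role)
  }
}
fits <- do.call(rbind, fits)
modes <- do.call(rbind, modes)
utils::write.csv(fits, file.path(out, "per_subject_fits.csv"),
                 row.names = FALSE)
utils::write.csv(modes, file.path(out, "mode_comparison.csv"),
                 row.names = FALSE)

summary <- cohort_summary(fits)
utils::write.csv(summary$by_role, file.path(out, "cohort_summary.csv"),
                 row.names = FALSE)

for (i in seq_len(nrow(summary$by_role))) {
  with(summary$by_role[i, ], cat(sprintf(
    "%s: mean beta_dist %+.3f, beta_comp %+.3f, adj R2 %.3f\n",
    role, beta_dist, beta_comp, adj_r2
  )))
}
best <- table(modes$mode[modes$rank == 1])
cat("best-ranked law per subject-role:",
    paste(names(best), best, sep = "=", collapse = ", "), "\n")
cat(sprintf("cross-role |beta_dist| ratio (patient/therapist): %.2f\n",
            summary$cross_role_dist_ratio))
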