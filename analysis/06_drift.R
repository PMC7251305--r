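# Non-stationarity: odds-ratio drift tests comparing each state's
# occupancy between the first and last thirds of every sequence
# (Yates-corrected chi-square, raw-alpha flags plus a
# Benjamini-Hochberg-adjusted column).
source(file.path("analysis", "00_common.R"))

out <- res_dir("drift")

screens <- list()
for (role in c("patient", "therapist")) {
  model <- read_cluster_model(file.path("results", "states",
                                        paste0("model_", role, ".json")))
  seqs <- read_state_sequences(file.path("results", "states",
                                         paste0("labels_", role, ".csv")),
                               active_states = model$active_states)
  for (s in seqs) {
    screens[[length(screens) + 1]] <- drift_screen(s)
  }
}
screens <- do.call(rbind, screens)
utils::write.csv(screens, file.path(out, "drift_screen.csv"),
                 row.names = FALSE)

flagged <- screens[screens$flagged, ]
cat(sprintf("drift screen: %d of %d subject-state tests flagged at alpha = 0.05 (%d after BH)\n",
            nrow(flagged), nrow(screens), sum(screens$p_bh < 0.05)))
if (nrow(flagged) > 0) {
  shown <- flagged[order(flagged$p_value), ][seq_len(min(5, nrow(flagged))), ]
  for (i in seq_len(nrow(shown))) {
    with(shown[i, ], cat(sprintf(
      "  %s (%s) state %d: %d/%d -> %d/%d, OR %.2f, p = %.4f\n",
      subject_id, role, state, a, n1, b, n2, odds_ratio, p_value
    )))
  }
}
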