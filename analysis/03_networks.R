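# Estimate the Markov transition networks: one 8x8 matrix per subject
# per role (undefined rows kept blank, so all matrices share one index
# space), the interleaved patient-to-therapist and therapist-to-patient
# dyad matrices, state frequencies, and a DOT/GraphML network export of
# the first subject with row-maximum transitions flagged.
source(file.path("analysis", "00_common.R"))

out <- res_dir("networks")

for (role in c("patient", "therapist")) {
  model <- read_cluster_model(file.path("results", "states",
                                        paste0("model_", role, ".json")))
  seqs <- read_state_sequences(file.path("results", "states",
                                         paste0("labels_", role, ".csv")),
                               active_states = model$active_states)
  for (s in seqs) {
    Tm <- mtm(s, model$k)
    write_mtm_csv(Tm, file.path(out, sprintf("mtm_%s_%s.csv",
                                             role, s$subject_id)))
  }
  freqs <- t(vapply(seqs, state_frequencies, numeric(8), k = 8))
  utils::write.csv(data.frame(subject_id = rownames(freqs), freqs,
                              check.names = FALSE),
                   file.path(out, paste0("state_frequencies_", role, ".csv")),
                   row.names = FALSE)
}

pat_model <- read_cluster_model(file.path("results", "states",
                                          "model_patient.json"))
pat <- read_state_sequences(file.path("results", "states",
                                      "labels_patient.csv"),
                            active_states = pat_model$active_states)
ther_model <- read_cluster_model(file.path("results", "states",
                                           "model_therapist.json"))
ther <- read_state_sequences(file.path("results", "states",
                                       "labels_therapist.csv"),
                             active_states = ther_model$active_states)
ids <- sort(unique(vapply(pat, function(s) s$subject_id, "")))
for (id in ids) {
  p <- pat[[paste0(id, ".patient")]]
  h <- ther[[paste0(id, ".therapist")]]
  for (dir in c("P2T", "T2P")) {
    Tm <- dyad_mtm(p, h, 8, dir)
    write_mtm_csv(Tm, file.path(out, sprintf("mtm_%s_%s.csv", tolower(dir), id)))
  }
}

first <- mtm(pat[[paste0(ids[1], ".patient")]], 8)
edges <- export_network(first, file.path(out, paste0("network_", ids[1], ".dot")),
                        "dot")
export_network(first, file.path(out, paste0("network_", ids[1], ".graphml")),
               "graphml")
cat(sprintf("wrote %d individual + %d dyadic matrices; %s's network has %d edges (%d row maxima)\n",
            2 * length(ids), 2 * length(ids), ids[1], nrow(edges),
            sum(edges$is_row_max)))
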