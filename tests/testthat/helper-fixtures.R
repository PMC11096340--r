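# fixtures shared across test files

.star_net <- function(k, extra = 0) {
  # hub H connected to S1..Sk; optionally `extra` isolated pairs
  edges <- data.frame(protein_a = "H", protein_b = paste0("S", 1:k),
                      weight = 0.05)
  if (extra > 0)
    edges <- rbind(edges, data.frame(protein_a = paste0("U", 1:extra),
                                     protein_b = paste0("V", 1:extra),
                                     weight = 0.05))
  interaction_network(edges)
}


# builds a small on-disk behaviour dataset: 6 training drugs + 2 test
# drugs + shared controls on one plate
.behavior_fixture <- function(dir, n_fish = 4, frame_rate = 5, seed = 42) {
  sched <- stimulus_schedule(acclimation_s = 5, n_cycles = 1,
                             intermission_s = 120, psrb_s = 120)
  panel <- data.frame(
    treatment = c("control", names(default_assignment()), "drugX", "drugY"),
    archetype = c("control", "AA", "AA", "AA", "AA", "other", "other",
                  "AA", "other"),
    dose_level = c(0, rep(3, 8)))
  p <- simulate_plate(panel, n_fish, sched, frame_rate = frame_rate,
                      seed = seed)
  write_tracks(p$tracks, file.path(dir, "tracks.csv"),
               file.path(dir, "metadata.csv"))
  write_schedule(sched, file.path(dir, "schedule.yaml"))
  run_config(tracks = file.path(dir, "tracks.csv"),
             metadata = file.path(dir, "metadata.csv"),
             schedule_path = file.path(dir, "schedule.yaml"),
             assignment = c(as.list(default_assignment()),
                            list(drugX = "test", drugY = "test")),
             putative = list(drugX = "AA", drugY = "other"), frame_rate = 5,
             seed = 7)
}

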