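# Small designs shared across tests. Noise-free variants make pipeline
# output an exact image of the ground truth; noisy variants use the study's
# data density (3 replicates, time grid 0/30/60/90 min).

design_noiseless <- function(...) {
  sim_design(noise_sigma = 0, missing_rate = 0, ...)
}

design_noisy <- function(...) {
  sim_design(noise_sigma = 0.2, missing_rate = 0.05, ...)
}

# Expected ground-truth labeling per protein and time, from a simulator truth
# table.
truth_table <- function(truth, time_grid) {
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    tibble::tibble(
      protein_id = tr$protein_id,
      time_min = time_grid,
      FL_true = truth_labeling_curve(time_grid, tr$k_a, tr$k_m, tr$T_d)
    )
  })
}
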