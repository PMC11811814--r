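# shared fixture builders (everything generated in code at test time)

# single-droplet phenotype row with given rates
one_droplet <- function(n_cells = 1L, nox = FALSE, loss = 0, igg = 0,
                        lactate = 0, ros = 0, condition = "control") {
  data.frame(n_cells = as.integer(n_cells), nox_active = nox,
             terminal_loss_pct = loss, igg_rate = igg,
             lactate_rate = lactate, ros_slope = ros,
             condition = condition, stringsAsFactors = FALSE)
}

# noiseless trace set for a vector of phenotype rows
quiet_traces <- function(ph, seed = 1L, n_frames = 6L) {
  generate_trace_set(chamber_spec(nrow(ph)),
                     acquisition_spec(n_frames = n_frames, noise_sd = 0),
                     ph, seed = seed)
}

# control chamber: every droplet holds a cell, no NOX activity, Gaussian
# frame noise only (probe-only null for threshold work)
null_chamber <- function(n, seed, noise_sd = 5) {
  ph <- sample_phenotypes(n, lambda_occupancy = 0, nox_fraction = 0,
                          igg_secretor_fraction = 0, seed = seed)
  ph$n_cells <- 1L
  ph$lactate_rate <- 0.3
  ph$ros_slope <- 10
  generate_trace_set(chamber_spec(n),
                     acquisition_spec(noise_sd = noise_sd), ph, seed = seed)
}
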