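# shared fixtures: the standard 8-pulse recording protocol and noise-free
# gain-of-function-like ground truths used across trace-processing tests

std_protocol <- function(...) {
  make_protocol(n_gaba_steps = 6, conc_range = c(1e-8, 1e-3),
                pulse_s = 20, washout_s = 300, ...)
}

gof_truth <- function(po_basal = 0.07, f_end = 1, noise_sd = 0, seed = 1L,
                      ...) {
  gating_truth(po_basal = po_basal, rundown = c(f_end, 600),
               noise_sd = noise_sd, seed = seed, ...)
}

ptx_ratio <- function(responses) {
  i <- which(responses$ligand == "PTX")
  responses$amplitude[i[length(i)]] / responses$amplitude[i[1]]
}
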