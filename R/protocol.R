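#' Construct a TEVC recording protocol
#'
#' Builds the standard pulse schedule used to estimate unliganded open
#' probability from a single oocyte: one pulse of the pore blocker picrotoxin
#' (PTX) to reveal the zero-current baseline, an ascending series of
#' log-spaced GABA pulses, and a final PTX pulse, separated by washout
#' intervals long enough for currents to return to baseline.
#'
#' @param n_gaba_steps Number of GABA concentrations (>= 1).
#' @param conc_range Length-2 numeric, low and high GABA concentration in
#'   molar; concentrations are log-spaced between them (a single step uses
#'   the high end).
#' @param pulse_s GABA pulse duration in seconds (PTX pulses are
#'   `ptx_pulse_s`).
#' @param washout_s Washout interval between pulses in seconds. Typical
#'   experimental values are 300--900 s (5--15 min).
#' @param ptx_pulse_s PTX pulse duration in seconds, default 10 s.
#' @param ptx_conc PTX concentration in molar, default 1 mM.
#' @param lead_s Ligand-free time before the first pulse and after the last,
#'   seconds.
#' @param sample_rate_Hz Sampling rate of the simulated recording.
#' @param holding_mV Holding potential, millivolts.
#'
#' @return An object of class `recording_protocol`: a list with elements
#'   `pulses` (data frame with columns `ligand`, `conc_M`, `onset_s`,
#'   `duration_s`), `holding_mV`, `sample_rate_Hz`, and `total_s`.
#' @export
#' @examples
#' p <- make_protocol(n_gaba_steps = 6, conc_range = c(1e-8, 1e-3))
#' p
make_protocol <- function(n_gaba_steps,
                          conc_range,
                          pulse_s = 20,
                          washout_s = 300,
                          ptx_pulse_s = 10,
                          ptx_conc = 1e-3,
                          lead_s = 60,
                          sample_rate_Hz = 10,
                          holding_mV = -70) {
  if (n_gaba_steps < 1) stop("n_gaba_steps must be >= 1")
  if (length(conc_range) != 2 || any(conc_range <= 0))
    stop("conc_range must be two positive concentrations (molar)")
  if (n_gaba_steps > 1 && conc_range[1] >= conc_range[2])
    stop("conc_range must be increasing: low < high")
  if (pulse_s <= 0 || washout_s <= 0 || ptx_pulse_s <= 0 || lead_s <= 0)
    stop("durations must be positive")
  if (ptx_conc <= 0) stop("ptx_conc must be positive")
  if (sample_rate_Hz <= 0) stop("sample_rate_Hz must be positive")

  gaba_conc <- if (n_gaba_steps == 1) conc_range[2] else
    exp(seq(log(conc_range[1]), log(conc_range[2]), length.out = n_gaba_steps))

  ligand <- c("PTX", rep("GABA", n_gaba_steps), "PTX")
  conc <- c(ptx_conc, gaba_conc, ptx_conc)
  dur <- c(ptx_pulse_s, rep(pulse_s, n_gaba_steps), ptx_pulse_s)
  onset <- numeric(length(dur))
  onset[1] <- lead_s
  for (i in seq_along(dur)[-1]) onset[i] <- onset[i - 1] + dur[i - 1] + washout_s

  pulses <- data.frame(ligand = ligand, conc_M = conc,
                       onset_s = onset, duration_s = dur,
                       stringsAsFactors = FALSE)
  new_protocol(pulses, holding_mV = holding_mV,
               sample_rate_Hz = sample_rate_Hz,
               total_s = onset[length(onset)] + dur[length(dur)] + lead_s)
}

#' Assemble a recording protocol from an explicit pulse table
#'
#' Lower-level constructor used by [make_protocol()] and by the file readers;
#' validates ordering, overlap and positivity.
#'
#' @param pulses Data frame with columns `ligand`, `conc_M`, `onset_s`,
#'   `duration_s`, time-ordered.
#' @param holding_mV Holding potential, mV.
#' @param sample_rate_Hz Sampling rate, Hz.
#' @param total_s Total recording duration, seconds; defaults to the end of
#'   the last pulse plus 60 s.
#' @return A `recording_protocol`.
#' @export
new_protocol <- function(pulses, holding_mV = -70, sample_rate_Hz = 10,
                         total_s = NULL) {
  need <- c("ligand", "conc_M", "onset_s", "duration_s")
  if (!all(need %in% names(pulses)))
    stop("pulses must have columns: ", paste(need, collapse = ", "))
  if (nrow(pulses) > 0) {
    if (any(pulses$duration_s <= 0)) stop("pulse durations must be > 0")
    if (any(pulses$conc_M < 0)) stop("concentrations must be >= 0")
    if (is.unsorted(pulses$onset_s, strictly = TRUE) && nrow(pulses) > 1)
      stop("pulses must be strictly time-ordered")
    ends <- pulses$onset_s + pulses$duration_s
    if (nrow(pulses) > 1 && any(pulses$onset_s[-1] < ends[-nrow(pulses)]))
      stop("pulses must not overlap")
  }
  if (sample_rate_Hz <= 0) stop("sample_rate_Hz must be positive")
  if (is.null(total_s)) {
    total_s <- if (nrow(pulses)) max(pulses$onset_s + pulses$duration_s) + 60 else 60
  }
  structure(list(pulses = pulses, holding_mV = holding_mV,
                 sample_rate_Hz = sample_rate_Hz, total_s = total_s),
            class = "recording_protocol")
}

#' @export
print.recording_protocol <- function(x, ...) {
  cat("TEVC recording protocol: holding", x$holding_mV, "mV,",
      x$sample_rate_Hz, "Hz,", round(x$total_s), "s total\n")
  print(x$pulses, row.names = FALSE)
  invisible(x)
}

gaba_pulses <- function(protocol) {
  which(protocol$pulses$ligand == "GABA")
}

ptx_pulses <- function(protocol) {
  which(protocol$pulses$ligand == "PTX")
}
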