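#' Ground-truth gating parameters for synthetic recordings
#'
#' Collects the generative parameters of the macroscopic current model used by
#' [simulate_trace()]. The dose dependence of open probability follows a Hill
#' curve running from `po_basal` (no agonist) to `po_max` (saturating
#' agonist); channel loss during the recording ("rundown") follows a single
#' exponential relaxing to a plateau; solution exchange and pore block are
#' first-order lags.
#'
#' Defaults describe a gain-of-function-like oocyte in which saturating GABA
#' drives the channels to an open probability of essentially 1, so that the
#' pore-blocker-anchored estimator is unbiased.
#'
#' @param po_basal Unliganded open probability, in \[0, 1\].
#' @param po_max Open probability at saturating agonist, `po_basal <= po_max <= 1`.
#' @param ec50 Agonist EC50, molar.
#' @param n_h Hill slope (> 0).
#' @param n0 Initial active-channel count.
#' @param unitary_current Lumped current per channel at unit open probability,
#'   microamperes (so `n0 * unitary_current` is the saturating amplitude).
#' @param leak Ohmic leak current, microamperes (negative = inward).
#' @param tau_exchange Solution-exchange time constant, seconds.
#' @param tau_block Pore-block onset/recovery time constant, seconds.
#' @param rundown Length-2 numeric `c(fraction_remaining_at_end, tau_rundown_s)`;
#'   `c(1, Inf)` disables rundown.
#' @param noise_sd Additive white Gaussian noise SD, microamperes.
#' @param seed Integer seed making the trace reproducible.
#' @return An object of class `gating_truth`.
#' @export
#' @examples
#' tr <- gating_truth(po_basal = 0.07, noise_sd = 0)
#' po_of_concentration(1e-5, tr)  # at EC50: midway between basal and max
gating_truth <- function(po_basal = 0.07,
                         po_max = 1,
                         ec50 = 1e-5,
                         n_h = 1.2,
                         n0 = 2000,
                         unitary_current = 5e-3,
                         leak = 0,
                         tau_exchange = 2,
                         tau_block = 3,
                         rundown = c(1, Inf),
                         noise_sd = 0.1,
                         seed = 1L) {
  if (po_basal < 0 || po_max > 1 || po_basal > po_max)
    stop("need 0 <= po_basal <= po_max <= 1")
  if (ec50 <= 0) stop("ec50 must be positive")
  if (n_h <= 0) stop("n_h must be positive")
  if (tau_exchange <= 0 || tau_block <= 0) stop("time constants must be positive")
  if (length(rundown) != 2 || rundown[1] <= 0 || rundown[1] > 1 || rundown[2] <= 0)
    stop("rundown must be c(fraction_remaining in (0,1], tau_rundown > 0)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(po_basal = po_basal, po_max = po_max, ec50 = ec50, n_h = n_h,
                 n0 = n0, unitary_current = unitary_current, leak = leak,
                 tau_exchange = tau_exchange, tau_block = tau_block,
                 rundown = c(fraction_remaining = unname(rundown[1]),
                             tau_s = unname(rundown[2])),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "gating_truth")
}

#' @export
print.gating_truth <- function(x, ...) {
  cat(sprintf(
    "gating truth: Po %g -> %g, EC50 %.3g M, nH %g, Imax %.3g uA, rundown to %g (tau %g s), noise %g uA, seed %d\n",
    x$po_basal, x$po_max, x$ec50, x$n_h, x$n0 * x$unitary_current,
    x$rundown[1], x$rundown[2], x$noise_sd, x$seed))
  invisible(x)
}

#' Ground-truth open probability at an agonist concentration
#'
#' Hill dose dependence lifted to run from the basal to the maximal open
#' probability: `po_basal + (po_max - po_basal) / (1 + (ec50/c)^n_h)`.
#' At `c = 0` this is `po_basal`; it is monotone non-decreasing in `c` and
#' saturates at `po_max`.
#'
#' @param c Agonist concentration, molar (vectorised, values >= 0).
#' @param truth A [gating_truth()].
#' @return Open probabilities in \[0, 1\].
#' @export
po_of_concentration <- function(c, truth) {
  if (any(c < 0)) stop("concentrations must be >= 0")
  occ <- ifelse(c > 0, 1 / (1 + (truth$ec50 / c)^truth$n_h), 0)
  truth$po_basal + (truth$po_max - truth$po_basal) * occ
}

#' Fraction of active channels remaining at time t
#'
#' Single-exponential rundown to a plateau:
#' `f(t) = f_end + (1 - f_end) * exp(-t / tau)`, so `f(0) = 1` and channel
#' count decays fastest at the start of the recording, matching the typical
#' phenomenology of spontaneously active oocyte recordings.
#'
#' @param t Time since recording start, seconds (vectorised, >= 0).
#' @param truth A [gating_truth()].
#' @return Fractions in (0, 1].
#' @export
rundown_factor <- function(t, truth) {
  if (any(t < 0)) stop("t must be >= 0")
  f_end <- truth$rundown[["fraction_remaining"]]
  tau <- truth$rundown[["tau_s"]]
  if (!is.finite(tau)) return(rep(1, length(t)))
  f_end + (1 - f_end) * exp(-t / tau)
}

# first-order low-pass of a command series u with time constant tau on a
# uniform grid with spacing dt; exact exponential update, initial state x0
lag_filter <- function(u, dt, tau, x0 = 0) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter(u * (1 - a), filter = a,
                           method = "recursive", init = x0))
}

#' Simulate a TEVC current trace with known ground truth
#'
#' Generates a whole-oocyte current trace at a fixed holding potential.
#' The model is
#' `I(t) = -n0 * f(t) * i_u * Po_eff(t) + leak + noise`, where `f(t)` is the
#' rundown factor, `i_u` the lumped unitary current, and `Po_eff(t)` follows
#' the Hill dose dependence of the exchange-filtered agonist concentration
#' (first-order lag `tau_exchange`), multiplied by the unblocked fraction,
#' which relaxes toward 0 with time constant `tau_block` during a pore-blocker
#' (PTX) pulse and recovers after washout. Chloride current at -70 mV is
#' inward, hence negative.
#'
#' Identical `(protocol, truth)` including the seed give bit-identical traces.
#'
#' @param protocol A [recording_protocol][make_protocol].
#' @param truth A [gating_truth()].
#' @param construct Optional construct label stored in metadata.
#' @param oocyte_id Optional oocyte identifier stored in metadata.
#' @return An object of class `tevc_trace`: list with `time_s`, `current_uA`,
#'   `protocol`, `truth`, `metadata`.
#' @export
#' @examples
#' p <- make_protocol(4, c(1e-7, 1e-3), washout_s = 120)
#' tr <- simulate_trace(p, gating_truth(po_basal = 0.07, noise_sd = 0))
#' tr
simulate_trace <- function(protocol, truth, construct = "synthetic",
                           oocyte_id = "oo1") {
  stopifnot(inherits(protocol, "recording_protocol"),
            inherits(truth, "gating_truth"))
  dt <- 1 / protocol$sample_rate_Hz
  time_s <- seq(0, protocol$total_s, by = dt)
  n <- length(time_s)

  # commanded concentration series for agonist and blocker
  cmd_gaba <- numeric(n)
  cmd_block <- numeric(n)
  for (i in seq_len(nrow(protocol$pulses))) {
    p <- protocol$pulses[i, ]
    in_pulse <- time_s >= p$onset_s & time_s < p$onset_s + p$duration_s
    if (p$ligand == "PTX") cmd_block[in_pulse] <- 1
    else cmd_gaba[in_pulse] <- p$conc_M
  }

  c_eff <- lag_filter(cmd_gaba, dt, truth$tau_exchange)
  blocked <- lag_filter(cmd_block, dt, truth$tau_block)
  po_eff <- po_of_concentration(c_eff, truth) * (1 - blocked)

  f <- rundown_factor(time_s, truth)
  current <- -truth$n0 * f * truth$unitary_current * po_eff + truth$leak
  if (truth$noise_sd > 0) {
    rng <- local({ set.seed(truth$seed); stats::rnorm(n, 0, truth$noise_sd) })
    current <- current + rng
  }

  structure(list(time_s = time_s, current_uA = current,
                 protocol = protocol, truth = truth,
                 metadata = list(construct = construct, oocyte_id = oocyte_id,
                                 generator = "gatecalc::simulate_trace")),
            class = "tevc_trace")
}

#' Wrap an existing time/current series as a TEVC trace
#'
#' For recordings read from file or constructed in tests; the protocol
#' annotation is optional but required by the automated baseline selection.
#'
#' @param time_s Uniformly spaced, strictly increasing time grid, seconds.
#' @param current_uA Current samples, microamperes; same length as `time_s`.
#' @param protocol Optional [recording_protocol][make_protocol].
#' @param truth Optional [gating_truth()] (ground truth, if known).
#' @param metadata Optional list of labels.
#' @return A `tevc_trace`.
#' @export
tevc_trace <- function(time_s, current_uA, protocol = NULL, truth = NULL,
                       metadata = list()) {
  if (length(time_s) != length(current_uA))
    stop("time_s and current_uA must have equal length")
  if (length(time_s) > 1) {
    d <- diff(time_s)
    if (any(d <= 0)) stop("time_s must be strictly increasing")
    if (max(d) - min(d) > 1e-9 * mean(d)) stop("time_s must be uniformly spaced")
  }
  if (any(!is.finite(current_uA))) stop("current_uA must be finite")
  structure(list(time_s = time_s, current_uA = current_uA,
                 protocol = protocol, truth = truth, metadata = metadata),
            class = "tevc_trace")
}

#' @export
print.tevc_trace <- function(x, ...) {
  cat(sprintf("TEVC trace: %d samples, %.1f s at %.3g Hz, current %.3g to %.3g uA\n",
              length(x$time_s), max(x$time_s),
              1 / mean(diff(x$time_s)),
              min(x$current_uA), max(x$current_uA)))
  if (!is.null(x$protocol))
    cat(sprintf("  protocol: %d pulses (%s)\n", nrow(x$protocol$pulses),
                paste(unique(x$protocol$pulses$ligand), collapse = ", ")))
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' @export
plot.tevc_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$current_uA, type = "l",
                 xlab = "time (s)", ylab = expression("current (" * mu * "A)"),
                 ...)
  if (!is.null(x$protocol) && nrow(x$protocol$pulses)) {
    p <- x$protocol$pulses
    graphics::rect(p$onset_s, graphics::par("usr")[3],
                   p$onset_s + p$duration_s, graphics::par("usr")[4],
                   col = grDevices::adjustcolor(
                     ifelse(p$ligand == "PTX", "red", "blue"), 0.12),
                   border = NA)
  }
  invisible(x)
}

#' Write / read a trace with its protocol sidecar
#'
#' The trace is two-column delimited text with header `time_s,current_uA`;
#' the protocol (and, for synthetic traces, the ground truth) is written as a
#' JSON sidecar `<prefix>.protocol.json` with keys
#' `pulses[{ligand, conc_M, onset_s, duration_s}]`, `holding_mV`,
#' `sample_rate_Hz`.
#'
#' @param trace A `tevc_trace`.
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.protocol.json`.
#' @return `write_trace` invisibly returns the file paths; `read_trace`
#'   returns a `tevc_trace`.
#' @export
write_trace <- function(trace, prefix) {
  stopifnot(inherits(trace, "tevc_trace"))
  csv <- paste0(prefix, ".csv")
  utils::write.csv(data.frame(time_s = trace$time_s,
                              current_uA = trace$current_uA),
                   csv, row.names = FALSE, quote = FALSE)
  side <- paste0(prefix, ".protocol.json")
  doc <- list(holding_mV = trace$protocol$holding_mV,
              sample_rate_Hz = trace$protocol$sample_rate_Hz,
              total_s = trace$protocol$total_s,
              pulses = trace$protocol$pulses,
              metadata = trace$metadata)
  if (!is.null(trace$truth)) doc$truth <- unclass(trace$truth)
  jsonlite::write_json(doc, side, auto_unbox = TRUE, digits = NA)
  invisible(c(trace = csv, protocol = side))
}

#' @rdname write_trace
#' @export
read_trace <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  side <- paste0(prefix, ".protocol.json")
  d <- utils::read.csv(csv)
  protocol <- NULL
  truth <- NULL
  metadata <- list()
  if (file.exists(side)) {
    doc <- jsonlite::read_json(side, simplifyVector = TRUE)
    protocol <- new_protocol(as.data.frame(doc$pulses),
                             holding_mV = doc$holding_mV,
                             sample_rate_Hz = doc$sample_rate_Hz,
                             total_s = doc$total_s)
    if (!is.null(doc$truth))
      truth <- do.call(gating_truth, c(
        doc$truth[c("po_basal", "po_max", "ec50", "n_h", "n0",
                    "unitary_current", "leak", "tau_exchange", "tau_block",
                    "noise_sd", "seed")],
        list(rundown = unlist(doc$truth$rundown, use.names = FALSE))))
    if (!is.null(doc$metadata)) metadata <- doc$metadata
  }
  tevc_trace(d$time_s, d$current_uA, protocol = protocol, truth = truth,
             metadata = metadata)
}
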