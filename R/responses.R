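# asymptote of a first-order relaxation y(t) = y_inf + (y0 - y_inf) exp(-t/tau)
# fitted over one pulse window; tau is profiled over a grid (linear LS in the
# other two parameters at each tau), which cannot fail to converge.
relaxation_asymptote <- function(t, y, tau_max = NULL) {
  t <- t - t[1]
  if (length(t) < 5 || stats::sd(y) == 0) return(mean(y))
  if (is.null(tau_max)) tau_max <- max(t)
  taus <- exp(seq(log(max(t) / 50), log(tau_max), length.out = 40))
  best <- NULL
  for (tau in taus) {
    e <- exp(-t / tau)
    fit <- stats::lm.fit(cbind(1, e), y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, y_inf = fit$coefficients[1])
  }
  unname(best$y_inf)
}

#' Extract per-pulse response amplitudes
#'
#' Measures, on the working series (rundown-normalized when available,
#' detrended otherwise), one amplitude per protocol pulse. Agonist (GABA)
#' pulses report by default the asymptote of a first-order relaxation fitted
#' to the inward deflection within the pulse window: for pulses long enough
#' to plateau (limited desensitization), this corrects for the
#' solution-exchange lag and, unlike a raw extremum, is not biased upward by
#' picking the largest noise excursion. `agonist_amplitude = "peak"` instead
#' takes the peak inward deflection within the window plus `search_margin`
#' (appropriate for desensitizing responses). Pore-blocker (PTX) pulses
#' likewise report the relaxation asymptote of the outward deflection, which
#' corrects for block onset slower than the pulse; `ptx_amplitude =
#' "steady_window"` instead takes the mean over the last 20% of the window.
#'
#' @param result A [detrend()] result (optionally rundown-normalized).
#' @param protocol Protocol; taken from the trace when NULL.
#' @param search_margin Seconds past the pulse end searched for the agonist
#'   peak, default 5.
#' @param agonist_amplitude `"exp_asymptote"` (default) or `"peak"`.
#' @param ptx_amplitude `"exp_asymptote"` (default) or `"steady_window"`.
#' @return Data frame of class `pulse_responses` with columns `pulse`,
#'   `ligand`, `conc_M`, `amplitude` (deflection magnitude, microamperes or
#'   standing-current units), `t_peak_s`.
#' @export
extract_pulse_responses <- function(result, protocol = NULL, search_margin = 5,
                                    agonist_amplitude = c("exp_asymptote",
                                                          "peak"),
                                    ptx_amplitude = c("exp_asymptote",
                                                      "steady_window")) {
  stopifnot(inherits(result, "detrend_result"))
  agonist_amplitude <- match.arg(agonist_amplitude)
  ptx_amplitude <- match.arg(ptx_amplitude)
  if (is.null(protocol)) protocol <- result$trace$protocol
  if (is.null(protocol)) stop("no protocol available")
  y <- if (is.null(result$normalized)) result$detrended else result$normalized
  t <- result$trace$time_s
  p <- protocol$pulses
  out <- data.frame(pulse = seq_len(nrow(p)), ligand = p$ligand,
                    conc_M = p$conc_M, amplitude = NA_real_,
                    t_peak_s = NA_real_)
  for (i in seq_len(nrow(p))) {
    on <- p$onset_s[i]; off <- on + p$duration_s[i]
    if (on < min(t) || off > max(t))
      stop(sprintf("pulse %d window [%.1f, %.1f] s outside the trace", i, on, off))
    if (p$ligand[i] == "PTX") {
      if (ptx_amplitude == "exp_asymptote") {
        w <- which(t >= on & t < off)
        out$amplitude[i] <- relaxation_asymptote(t[w], y[w])
      } else {
        w <- which(t >= on + 0.8 * p$duration_s[i] & t < off)
        out$amplitude[i] <- mean(y[w])         # outward (positive) deflection
      }
      out$t_peak_s[i] <- mean(t[w])
    } else if (agonist_amplitude == "exp_asymptote") {
      w <- which(t >= on & t < off)
      out$amplitude[i] <- -relaxation_asymptote(t[w], y[w])
      out$t_peak_s[i] <- t[w[which.min(y[w])]]
    } else {
      w <- which(t >= on & t <= off + search_margin)
      k <- w[which.min(y[w])]
      out$amplitude[i] <- -y[k]                # inward deflection magnitude
      out$t_peak_s[i] <- t[k]
    }
  }
  structure(out, class = c("pulse_responses", "data.frame"))
}

#' Estimate unliganded open probability from PTX and maximal GABA responses
#'
#' The macroscopic estimator: application of a pore blocker reveals the
#' zero-current baseline (open probability 0) and saturating agonist drives
#' the channels toward open probability 1, so the basal open probability is
#' the fraction of pore-blocker-sensitive to total current,
#' `Po = I_PTX / (I_PTX + I_GABAmax)`.
#'
#' When the PTX-sensitive deflection is not resolvable above the recording
#' noise (below `resolvability_mult` baseline residual SDs), the estimate is
#' only an upper bound on the true open probability, and free energies
#' derived from it are correspondingly lower bounds; the flag records this.
#'
#' @param ptx_response,max_gaba_response Single rows of a
#'   [pulse_responses][extract_pulse_responses] table (or any objects with an
#'   `amplitude` field), both amplitudes >= 0 after clipping.
#' @param baseline_sd Residual SD of the working series on baseline regions,
#'   used for the resolvability flag; NA disables the flag.
#' @param resolvability_mult Multiple of `baseline_sd` below which the PTX
#'   deflection is deemed unresolved, default 3.
#' @param construct Construct label carried into the estimate.
#' @return An object of class `po_estimate`: list with `po`, `i_ptx`,
#'   `i_total`, `is_upper_bound`, `construct`.
#' @export
estimate_po_basal <- function(ptx_response, max_gaba_response,
                              baseline_sd = NA_real_,
                              resolvability_mult = 3,
                              construct = "unknown") {
  a <- max(0, ptx_response$amplitude)
  b <- max(0, max_gaba_response$amplitude)
  if (a + b == 0)
    stop("no PTX- or GABA-elicited current: oocyte expresses no channels")
  po <- min(1, max(0, a / (a + b)))
  upper <- !is.na(baseline_sd) && a < resolvability_mult * baseline_sd
  structure(list(po = po, i_ptx = a, i_total = a + b,
                 is_upper_bound = upper, construct = construct),
            class = "po_estimate")
}

#' @export
print.po_estimate <- function(x, ...) {
  cat(sprintf("Po estimate [%s]: %.4g%s  (I_PTX %.4g / I_total %.4g)\n",
              x$construct, x$po,
              if (x$is_upper_bound) " (upper bound)" else "",
              x$i_ptx, x$i_total))
  invisible(x)
}

#' Run the full trace-conditioning and Po-estimation chain
#'
#' Convenience wrapper: select baseline regions, fit and subtract the spline
#' baseline, optionally normalize out rundown, extract pulse responses, and
#' estimate the basal open probability from the final PTX pulse and the
#' highest-concentration GABA pulse.
#'
#' `normalize_rundown = "auto"` applies the normalization when the standing
#' current is resolvable (gain-of-function-like traces) and falls back to the
#' detrended series otherwise (wild-type-like traces, where the standing
#' current is near zero and the normalization is undefined).
#'
#' @param trace A `tevc_trace` with protocol annotation.
#' @param normalize_rundown `"auto"`, `TRUE`, or `FALSE`.
#' @param margin Baseline-exclusion margin after each pulse, seconds.
#' @param search_margin Peak-search margin, seconds.
#' @param construct Construct label for the Po estimate; defaults to trace
#'   metadata.
#' @return An object of class `trace_analysis`: list with elements `detrend`
#'   (a `detrend_result`), `responses` (a `pulse_responses` table), `po`
#'   (a `po_estimate`), and `baseline_sd`.
#' @export
#' @examples
#' p <- make_protocol(4, c(1e-7, 1e-3), washout_s = 120)
#' tr <- simulate_trace(p, gating_truth(po_basal = 0.07, noise_sd = 0.05))
#' process_trace(tr)$po
process_trace <- function(trace, normalize_rundown = "auto", margin = 30,
                          search_margin = 5, construct = NULL) {
  stopifnot(inherits(trace, "tevc_trace"))
  if (is.null(construct))
    construct <- if (!is.null(trace$metadata$construct))
      trace$metadata$construct else "unknown"
  d <- detrend(trace, margin = margin)
  if (isTRUE(normalize_rundown)) {
    d <- rundown_normalize(d)
  } else if (identical(normalize_rundown, "auto")) {
    d <- tryCatch(rundown_normalize(d), error = function(e) d)
  }
  resp <- extract_pulse_responses(d, search_margin = search_margin)
  y <- if (is.null(d$normalized)) d$detrended else d$normalized
  m <- region_mask(trace$time_s, d$regions)
  baseline_sd <- stats::sd(y[m])

  ig <- gaba_pulses(trace$protocol)
  ip <- ptx_pulses(trace$protocol)
  if (length(ig) == 0 || length(ip) == 0)
    stop("protocol must contain at least one GABA and one PTX pulse")
  gmax <- ig[which.max(trace$protocol$pulses$conc_M[ig])]
  pfin <- ip[length(ip)]   # the final PTX pulse anchors the estimate
  po <- estimate_po_basal(resp[pfin, ], resp[gmax, ],
                          baseline_sd = baseline_sd, construct = construct)
  structure(list(detrend = d, responses = resp, po = po,
                 baseline_sd = baseline_sd),
            class = "trace_analysis")
}

#' @export
print.trace_analysis <- function(x, ...) {
  print(x$po)
  cat(sprintf("  %d pulse responses; baseline residual SD %.3g%s\n",
              nrow(x$responses), x$baseline_sd,
              if (!is.null(x$detrend$normalized))
                "; rundown-normalized" else ""))
  invisible(x)
}

#' Write a per-recording results table
#'
#' Delimited-text export of the pulse responses from a [process_trace()]
#' analysis.
#'
#' @param analysis A `trace_analysis`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_responses <- function(analysis, path) {
  stopifnot(inherits(analysis, "trace_analysis"))
  utils::write.csv(as.data.frame(analysis$responses), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
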