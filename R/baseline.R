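#' Select ligand-free baseline regions from the protocol
#'
#' Automated, reproducible stand-in for manual baseline selection: every
#' maximal time interval lying outside all pulse windows, each window widened
#' by `pre_margin` before the onset and `margin` after the end (to skip
#' solution-exchange tails and washout relaxation).
#'
#' @param trace A `tevc_trace` with a protocol annotation.
#' @param margin Seconds excluded after each pulse end, default 30.
#' @param pre_margin Seconds excluded before each pulse onset, default 2.
#' @return An object of class `baseline_regions`: data frame with columns
#'   `start_s`, `end_s`.
#' @export
select_baseline_regions <- function(trace, margin = 30, pre_margin = 2) {
  stopifnot(inherits(trace, "tevc_trace"))
  if (is.null(trace$protocol))
    stop("trace has no protocol annotation; supply baseline regions manually ",
         "via baseline_regions()")
  t0 <- min(trace$time_s); t1 <- max(trace$time_s)
  p <- trace$protocol$pulses
  if (nrow(p) == 0)
    return(baseline_regions(data.frame(start_s = t0, end_s = t1)))
  lo <- pmax(p$onset_s - pre_margin, t0)
  hi <- pmin(p$onset_s + p$duration_s + margin, t1)
  # merge overlapping exclusion windows, then complement within [t0, t1]
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  mlo <- lo[1]; mhi <- hi[1]
  ex <- NULL
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= mhi) mhi <- max(mhi, hi[i])
    else { ex <- rbind(ex, c(mlo, mhi)); mlo <- lo[i]; mhi <- hi[i] }
  }
  ex <- rbind(ex, c(mlo, mhi))
  starts <- c(t0, ex[, 2])
  ends <- c(ex[, 1], t1)
  keep <- ends > starts
  baseline_regions(data.frame(start_s = starts[keep], end_s = ends[keep]))
}

#' @rdname select_baseline_regions
#' @param regions Data frame with columns `start_s`, `end_s`, non-overlapping
#'   and ordered; used to supply manually chosen regions.
#' @export
baseline_regions <- function(regions) {
  stopifnot(all(c("start_s", "end_s") %in% names(regions)))
  if (any(regions$end_s <= regions$start_s))
    stop("each region must satisfy start_s < end_s")
  o <- order(regions$start_s)
  regions <- regions[o, , drop = FALSE]
  if (nrow(regions) > 1 &&
      any(regions$start_s[-1] < regions$end_s[-nrow(regions)]))
    stop("baseline regions must not overlap")
  structure(regions, class = c("baseline_regions", "data.frame"))
}

region_mask <- function(time_s, regions) {
  m <- rep(FALSE, length(time_s))
  for (i in seq_len(nrow(regions)))
    m <- m | (time_s >= regions$start_s[i] & time_s <= regions$end_s[i])
  m
}

#' Fit a smoothing-spline baseline to ligand-free regions
#'
#' A cubic smoothing spline is fitted only to samples inside the baseline
#' regions and evaluated on the full time grid, interpolating across pulse
#' windows. The smoothing parameter is chosen by generalized cross-validation
#' by default; pass `spar` or `df` to override.
#'
#' @param trace A `tevc_trace`.
#' @param regions A [baseline_regions][select_baseline_regions].
#' @param spar,df Optional smoothing overrides passed to
#'   [stats::smooth.spline()].
#' @return Numeric vector of baseline values on the full grid, with the
#'   fitted spline and smoothing parameter as attributes.
#' @export
fit_baseline_spline <- function(trace, regions, spar = NULL, df = NULL) {
  stopifnot(inherits(trace, "tevc_trace"))
  m <- region_mask(trace$time_s, regions)
  if (sum(m) < 4)
    stop("baseline regions contain fewer than 4 samples")
  args <- list(x = trace$time_s[m], y = trace$current_uA[m], cv = FALSE)
  if (!is.null(spar)) args$spar <- spar
  if (!is.null(df)) args$df <- df
  fit <- do.call(stats::smooth.spline, args)
  base <- stats::predict(fit, trace$time_s)$y
  attr(base, "spar") <- fit$spar
  attr(base, "df") <- fit$df
  base
}

#' Subtract the spline baseline from a trace
#'
#' @param trace A `tevc_trace`.
#' @param baseline Per-sample baseline values from [fit_baseline_spline()],
#'   or NULL to fit one with default settings (regions auto-selected).
#' @param regions Baseline regions; auto-selected from the protocol when NULL.
#' @param margin Passed to [select_baseline_regions()] when regions are
#'   auto-selected.
#' @return An object of class `detrend_result`: list with the input `trace`,
#'   `baseline_spline`, `detrended` (`raw - baseline`, per sample),
#'   `normalized` (NULL until [rundown_normalize()] is applied), `regions`
#'   and the smoothing parameter used.
#' @export
#' @examples
#' p <- make_protocol(3, c(1e-6, 1e-3), washout_s = 120)
#' tr <- simulate_trace(p, gating_truth(noise_sd = 0))
#' d <- detrend(tr)
#' d
detrend <- function(trace, baseline = NULL, regions = NULL, margin = 30) {
  stopifnot(inherits(trace, "tevc_trace"))
  if (is.null(regions)) regions <- select_baseline_regions(trace, margin = margin)
  if (is.null(baseline)) baseline <- fit_baseline_spline(trace, regions)
  if (length(baseline) != length(trace$time_s))
    stop("baseline must be defined on the full time grid")
  structure(list(trace = trace,
                 baseline_spline = as.numeric(baseline),
                 detrended = trace$current_uA - as.numeric(baseline),
                 normalized = NULL,
                 leak_estimate = NULL,
                 regions = regions,
                 spar = attr(baseline, "spar")),
            class = "detrend_result")
}

#' @export
print.detrend_result <- function(x, ...) {
  cat(sprintf("detrended TEVC trace: %d samples, %d baseline regions, spar %s\n",
              length(x$detrended), nrow(x$regions),
              if (is.null(x$spar)) "manual" else format(x$spar, digits = 3)))
  if (!is.null(x$normalized))
    cat(sprintf("  rundown-normalized (leak estimate %.4g uA)\n",
                x$leak_estimate))
  invisible(x)
}

#' @export
plot.detrend_result <- function(x, ...) {
  y <- if (is.null(x$normalized)) x$detrended else x$normalized
  lab <- if (is.null(x$normalized)) expression("detrended current (" * mu * "A)")
         else "normalized current (standing-current units)"
  graphics::plot(x$trace$time_s, x$trace$current_uA, type = "l", col = "grey60",
                 xlab = "time (s)", ylab = expression("current (" * mu * "A)"), ...)
  graphics::lines(x$trace$time_s, x$baseline_spline, col = "red")
  graphics::legend("bottomright", c("raw", "spline baseline"),
                   col = c("grey60", "red"), lty = 1, bty = "n")
  graphics::plot(x$trace$time_s, y, type = "l",
                 xlab = "time (s)", ylab = lab, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

# leak from the blocked level of the last blocker pulse: during full pore
# block the conductive current is zero, so the asymptote of the within-pulse
# relaxation of the raw current is leak.
estimate_leak_from_ptx <- function(trace) {
  if (is.null(trace$protocol)) return(0)
  ip <- ptx_pulses(trace$protocol)
  if (length(ip) == 0) return(0)
  p <- trace$protocol$pulses[ip[length(ip)], ]
  w <- which(trace$time_s >= p$onset_s &
             trace$time_s < p$onset_s + p$duration_s)
  if (length(w) == 0) return(0)
  relaxation_asymptote(trace$time_s[w], trace$current_uA[w])
}

#' Normalize out rundown of the active-channel pool
#'
#' For spontaneously open (gain-of-function-like) recordings, the magnitude
#' of the standing spontaneous current is a proxy for the number of active
#' channels, so dividing the detrended current by the magnitude of the spline
#' baseline (less the leak estimate) corrects for progressive channel loss.
#' After normalization, pore-blocker-sensitive deflections at the start and
#' end of the recording have equal magnitude even under strong rundown.
#'
#' Not applicable to wild-type-like traces whose standing current is near
#' zero: the division would blow up, which is what the floor guards against.
#'
#' @param result A [detrend()] result.
#' @param floor Minimum allowed `|baseline - leak|`, microamperes; defaults
#'   to 5% of its maximum. Falling below it raises an error naming the
#'   offending time interval.
#' @param leak_estimate Leak current, microamperes; by default estimated from
#'   the steady level of the final pore-blocker pulse (0 when none exists).
#' @return The `detrend_result` with `normalized` filled in
#'   (`detrended / |baseline - leak|`, dimensionless in units of the local
#'   standing current).
#' @export
rundown_normalize <- function(result, floor = NULL, leak_estimate = NULL) {
  stopifnot(inherits(result, "detrend_result"))
  if (is.null(leak_estimate)) leak_estimate <- estimate_leak_from_ptx(result$trace)
  denom <- abs(result$baseline_spline - leak_estimate)
  if (is.null(floor)) floor <- 0.05 * max(denom)
  if (any(denom < floor)) {
    bad <- range(result$trace$time_s[denom < floor])
    stop(sprintf(paste0("standing-current magnitude falls below the floor ",
                        "(%.3g uA) in the interval [%.1f, %.1f] s; rundown ",
                        "normalization is only valid for spontaneously open ",
                        "recordings with a resolvable standing current"),
                 floor, bad[1], bad[2]))
  }
  result$normalized <- result$detrended / denom
  result$leak_estimate <- leak_estimate
  result
}
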