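#' Donor-acceptor distances from coordinate series
#'
#' Elementwise Euclidean distance between donor and acceptor atom positions,
#' one per trajectory frame.
#'
#' @param donor,acceptor Numeric matrices (or data frames) with columns
#'   x, y, z in angstroms, equal row counts.
#' @return Numeric vector of distances, angstroms.
#' @export
distances_from_coordinates <- function(donor, acceptor) {
  donor <- as.matrix(donor); acceptor <- as.matrix(acceptor)
  if (!all(dim(donor) == dim(acceptor)))
    stop("donor and acceptor series must have equal dimensions")
  if (ncol(donor) != 3) stop("coordinates must have 3 columns (x, y, z)")
  sqrt(rowSums((donor - acceptor)^2))
}

validate_distance_series <- function(series) {
  need <- c("system", "state", "replicate", "subunit", "time_ns", "distance_A")
  if (!all(need %in% names(series)))
    stop("distance series must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(series$distance_A) | series$distance_A <= 0))
    stop("distances must be positive and finite")
  if (any(series$time_ns < 0)) stop("frame times must be non-negative")
  structure(as.data.frame(series), class = c("distance_series", "data.frame"))
}

#' Generate synthetic donor-acceptor distance series
#'
#' Emulates per-state H-bond distance distributions from equilibrium MD:
#' each group (system, state, subunit) draws frames from a unimodal normal
#' or a two-component normal mixture, truncated below a steric floor by
#' rejection. An intact N-H...O=C main-chain H-bond sits just below 3 A;
#' broken/weakened bonds shift the mode up and widen the tail.
#'
#' @param groups Data frame with one row per group: columns `system`,
#'   `state`, `subunit`, `mean_A`, `sd_A`, and optionally `mean2_A`,
#'   `sd2_A`, `weight2` (mixture weight of the second component, 0 gives a
#'   single normal).
#' @param n_replicates Independent replicate simulations per group.
#' @param duration_ns Simulated time per replicate, nanoseconds.
#' @param cadence_ns Analysis interval, nanoseconds; each replicate yields
#'   `duration_ns / cadence_ns` frames (for example 500 ns at 2 ns cadence
#'   gives 250 frames, so 4 replicates give 1000 samples per group).
#' @param steric_floor_A Minimum physical distance, default 2.2 A; draws
#'   below it are rejected and redrawn.
#' @param seed Integer seed; identical arguments give identical output.
#' @return A `distance_series` data frame with columns `system`, `state`,
#'   `replicate`, `subunit`, `time_ns`, `distance_A`.
#' @export
#' @examples
#' g <- data.frame(system = "a1b2g2", state = c("+BIC", "+GABA"),
#'                 subunit = "b2-A", mean_A = c(2.9, 3.6), sd_A = c(0.15, 0.4))
#' s <- synth_distance_series(g, n_replicates = 4, duration_ns = 500,
#'                            cadence_ns = 2, seed = 7)
#' table(s$state)   # 1000 frames per state
synth_distance_series <- function(groups, n_replicates = 4, duration_ns = 500,
                                  cadence_ns = 2, steric_floor_A = 2.2,
                                  seed = 1L) {
  need <- c("system", "state", "subunit", "mean_A", "sd_A")
  if (!all(need %in% names(groups)))
    stop("groups must have columns: ", paste(need, collapse = ", "))
  if (n_replicates < 1 || duration_ns <= 0 || cadence_ns <= 0)
    stop("replicate count and durations must be positive")
  n_frames <- round(duration_ns / cadence_ns)
  times <- cadence_ns * seq_len(n_frames)
  set.seed(as.integer(seed))

  draw <- function(n, g) {
    w2 <- if (!is.null(g$weight2) && !is.na(g$weight2)) g$weight2 else 0
    from2 <- stats::runif(n) < w2
    x <- ifelse(from2,
                stats::rnorm(n, g$mean2_A, g$sd2_A),
                stats::rnorm(n, g$mean_A, g$sd_A))
    for (it in 1:100) {
      bad <- x <= steric_floor_A
      if (!any(bad)) break
      x[bad] <- ifelse(from2[bad],
                       stats::rnorm(sum(bad), g$mean2_A, g$sd2_A),
                       stats::rnorm(sum(bad), g$mean_A, g$sd_A))
    }
    x
  }

  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(system = g$system, state = g$state,
                 replicate = r, subunit = g$subunit,
                 time_ns = times, distance_A = draw(n_frames, g))
    }))
  }))
  validate_distance_series(out)
}

#' Summarize distance distributions per group
#'
#' Pools frames across replicates within each group and computes count,
#' mean, median, SD, a fixed-bin histogram, and the fraction of frames at or
#' below the H-bond distance cutoff (a distance-only proxy for H-bond
#' presence; no angle criterion).
#'
#' @param series A `distance_series` data frame (see
#'   [synth_distance_series()] for the columns).
#' @param group_by Grouping columns, default `c("system", "state", "subunit")`.
#' @param cutoff H-bond N...O distance cutoff, angstroms, default 3.5.
#' @param binwidth_A Histogram bin width, default 0.05 A.
#' @param range_A Histogram range, default `c(2, 6)` A, widened in whole bins
#'   when the data exceed it.
#' @return A list of `distance_summary` objects (one per group), each with
#'   `group`, `n`, `mean`, `median`, `sd`, `breaks`, `counts`, `density`,
#'   `frac_le_cutoff`, `cutoff`.
#' @export
aggregate_distances <- function(series,
                                group_by = c("system", "state", "subunit"),
                                cutoff = 3.5, binwidth_A = 0.05,
                                range_A = c(2, 6)) {
  series <- validate_distance_series(series)
  if (!all(group_by %in% names(series)))
    stop("unknown grouping columns: ",
         paste(setdiff(group_by, names(series)), collapse = ", "))
  lo <- min(range_A[1], binwidth_A * floor(min(series$distance_A) / binwidth_A))
  hi <- max(range_A[2], binwidth_A * ceiling(max(series$distance_A) / binwidth_A))
  breaks <- seq(lo, hi, by = binwidth_A)
  key <- interaction(series[group_by], drop = TRUE, sep = "/")
  lapply(split(series, key), function(d) {
    if (nrow(d) == 0) stop("empty group")
    h <- graphics::hist(d$distance_A, breaks = breaks, plot = FALSE)
    structure(list(group = as.list(d[1, group_by, drop = FALSE]),
                   n = nrow(d),
                   mean = mean(d$distance_A),
                   median = stats::median(d$distance_A),
                   sd = stats::sd(d$distance_A),
                   breaks = h$breaks, counts = h$counts,
                   density = h$density,
                   frac_le_cutoff = mean(d$distance_A <= cutoff),
                   cutoff = cutoff),
              class = "distance_summary")
  })
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf(
    "distance summary [%s]: n = %d, mean %.2f A, median %.2f A, SD %.2f A, %.0f%% <= %.2f A\n",
    paste(unlist(x$group), collapse = "/"), x$n, x$mean, x$median, x$sd,
    100 * x$frac_le_cutoff, x$cutoff))
  invisible(x)
}

#' @export
plot.distance_summary <- function(x, ...) {
  mid <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  graphics::plot(mid, x$density, type = "h",
                 xlab = "donor-acceptor distance (Å)", ylab = "density",
                 ...)
  graphics::abline(v = x$cutoff, lty = 3, col = "red")
  invisible(x)
}

#' State-dependence shift between two distance distributions
#'
#' Compares two group summaries (for example antagonist-bound "closed"
#' versus agonist-bound "activated") on a shared histogram binning: median
#' and mean shifts (`b - a`, positive = separation increases, H-bond
#' weakens) and the overlap coefficient
#' `sum(min(density_a, density_b)) * binwidth` in \[0, 1\].
#'
#' @param summary_a,summary_b `distance_summary` objects from the same
#'   [aggregate_distances()] call (identical bins required).
#' @return List with `median_shift_A`, `mean_shift_A`, `overlap`.
#' @export
state_shift <- function(summary_a, summary_b) {
  stopifnot(inherits(summary_a, "distance_summary"),
            inherits(summary_b, "distance_summary"))
  if (length(summary_a$breaks) != length(summary_b$breaks) ||
      any(summary_a$breaks != summary_b$breaks))
    stop("summaries use incompatible histogram bins; aggregate them together")
  bw <- diff(summary_a$breaks[1:2])
  list(median_shift_A = summary_b$median - summary_a$median,
       mean_shift_A = summary_b$mean - summary_a$mean,
       overlap = sum(pmin(summary_a$density, summary_b$density)) * bw)
}

#' Read / write distance series as delimited text
#'
#' Header `system,state,replicate,subunit,time_ns,distance_A`; alternatively
#' a coordinate table with `donor_x..donor_z, acceptor_x..acceptor_z` in
#' place of `distance_A`, in which case distances are computed on read.
#'
#' @param series A `distance_series`.
#' @param path CSV path.
#' @return `read_distance_series` returns a `distance_series`;
#'   `write_distance_series` invisibly returns the path.
#' @export
write_distance_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_series
#' @export
read_distance_series <- function(path) {
  d <- utils::read.csv(path)
  cc <- c("donor_x", "donor_y", "donor_z",
          "acceptor_x", "acceptor_y", "acceptor_z")
  if (!("distance_A" %in% names(d)) && all(cc %in% names(d))) {
    d$distance_A <- distances_from_coordinates(d[, cc[1:3]], d[, cc[4:6]])
  }
  validate_distance_series(d)
}
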