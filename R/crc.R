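#' Normalize per-oocyte concentration-response data
#'
#' Each oocyte's responses are divided by that oocyte's own maximum response
#' (so I/Imax runs to 1 per cell), then group mean and SEM are computed at
#' each concentration across oocytes.
#'
#' @param series Data frame with columns `oocyte_id`, `conc_M`, `response`
#'   (response magnitudes, any consistent unit).
#' @param construct Construct label.
#' @param min_conc_per_oocyte Minimum concentrations required per oocyte,
#'   default 3 (the series should include a near-saturating concentration for
#'   the per-cell normalization to be meaningful).
#' @return An object of class `crc_data`: list with `normalized` (per-oocyte
#'   I/Imax table), `means` (per-concentration `conc_M`, `mean`, `sem`, `n`;
#'   SEM is NA for n < 2), `construct`.
#' @export
#' @examples
#' d <- data.frame(oocyte_id = rep(1:2, each = 4),
#'                 conc_M = rep(10^(-7:-4), 2),
#'                 response = c(1, 4, 9, 10, 2, 8, 18, 20))
#' normalize_responses(d)
normalize_responses <- function(series, construct = "unknown",
                                min_conc_per_oocyte = 3) {
  need <- c("oocyte_id", "conc_M", "response")
  if (!all(need %in% names(series)))
    stop("series must have columns: ", paste(need, collapse = ", "))
  if (any(series$conc_M <= 0)) stop("concentrations must be positive")
  parts <- split(series, series$oocyte_id)
  norm <- do.call(rbind, lapply(parts, function(d) {
    if (nrow(d) < min_conc_per_oocyte)
      stop("oocyte ", d$oocyte_id[1], " has fewer than ",
           min_conc_per_oocyte, " concentrations")
    mx <- max(d$response)
    if (mx <= 0) stop("oocyte ", d$oocyte_id[1], " has zero maximum response")
    d$norm_response <- d$response / mx
    d[order(d$conc_M), ]
  }))
  rownames(norm) <- NULL
  means <- do.call(rbind, lapply(split(norm, norm$conc_M), function(d) {
    n <- nrow(d)
    data.frame(conc_M = d$conc_M[1], mean = mean(d$norm_response),
               sem = if (n >= 2) stats::sd(d$norm_response) / sqrt(n) else NA_real_,
               n = n)
  }))
  means <- means[order(means$conc_M), ]
  rownames(means) <- NULL
  structure(list(normalized = norm, means = means, construct = construct),
            class = "crc_data")
}

#' @export
print.crc_data <- function(x, ...) {
  cat(sprintf("concentration-response data [%s]: %d oocytes, %d concentrations\n",
              x$construct, length(unique(x$normalized$oocyte_id)),
              nrow(x$means)))
  print(x$means, row.names = FALSE, digits = 4)
  invisible(x)
}

hill_curve <- function(c, ec50, n_h, amplitude = 1) {
  amplitude / (1 + exp(n_h * (log(ec50) - log(c))))
}

#' Fit the Hill equation to concentration-response data
#'
#' Least-squares fit of the Hill model
#' `I/Imax = 1 / (1 + (EC50 / c)^nH)`
#' parameterised in `log(EC50)` for numerical stability, with amplitude
#' fixed at 1 by default (the normalization already scales each oocyte to its
#' own maximum). Levenberg-Marquardt optimization is multi-started from a
#' log-spaced EC50 grid spanning the data with `nH = 1`; the best start by
#' residual sum of squares wins, ties broken toward the smaller Hill slope.
#'
#' @param formula A model formula `response ~ conc` (concentration in molar),
#'   or a [crc_data][normalize_responses] object (fit to the group means), or
#'   a numeric concentration vector (then supply `response`).
#' @param data Data frame for the formula interface.
#' @param response Numeric responses for the default interface.
#' @param weights Optional fit weights.
#' @param init Optional starting values `c(ec50, n_h)`; when supplied the
#'   multi-start grid is skipped.
#' @param free_amplitude Fit a free maximal amplitude instead of fixing it
#'   at 1 (off by default).
#' @param n_starts Size of the EC50 starting grid, default 7.
#' @param ... Unused.
#' @return An object of class `hill_fit` with components `ec50` (molar),
#'   `n_h`, `amplitude`, `rss`, `se` (standard errors), `converged`,
#'   `fitted`, `residuals`, `data`.
#' @export
#' @examples
#' conc <- 10^seq(-8, -3, length.out = 8)
#' y <- 1 / (1 + (1e-5 / conc)^1.5)
#' fit <- hill_fit(y ~ conc)
#' coef(fit)
hill_fit <- function(formula, ...) UseMethod("hill_fit")

#' @rdname hill_fit
#' @export
hill_fit.formula <- function(formula, data = environment(formula), ...) {
  mf <- stats::model.frame(formula, data)
  hill_fit.default(mf[[2]], mf[[1]], ...)
}

#' @rdname hill_fit
#' @export
hill_fit.crc_data <- function(formula, ...) {
  crc <- formula
  fit <- hill_fit.default(crc$means$conc_M, crc$means$mean, ...)
  fit$construct <- crc$construct
  fit
}

#' @rdname hill_fit
#' @export
hill_fit.default <- function(formula, response, weights = NULL, init = NULL,
                             free_amplitude = FALSE, n_starts = 7, ...) {
  conc <- as.numeric(formula)
  y <- as.numeric(response)
  if (length(conc) != length(y)) stop("conc and response lengths differ")
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (length(conc) < 4)
    stop("need at least 4 concentration points spanning the inflection")
  if (is.null(weights)) weights <- rep(1, length(y))
  d <- data.frame(conc = conc, y = y, w = weights)

  starts <- if (!is.null(init)) {
    list(c(lec = log(init[1]), nh = init[2]))
  } else {
    lapply(seq(log(min(conc)), log(max(conc)), length.out = n_starts),
           function(l) c(lec = l, nh = 1))
  }

  form <- if (free_amplitude) y ~ amp / (1 + exp(nh * (lec - log(conc))))
          else y ~ 1 / (1 + exp(nh * (lec - log(conc))))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)

  best <- NULL
  for (s in starts) {
    start <- as.list(s)
    lower <- c(lec = -Inf, nh = 1e-6)
    if (free_amplitude) { start$amp <- max(y); lower <- c(lower, amp = 1e-9) }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = d, start = start, weights = d$w,
                        lower = lower, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    nh <- stats::coef(fit)[["nh"]]
    if (is.null(best) || rss < best$rss - 1e-15 ||
        (abs(rss - best$rss) <= 1e-15 && nh < best$nh)) {
      best <- list(fit = fit, rss = rss, nh = nh)
    }
  }
  if (is.null(best))
    stop("Hill fit failed to converge from any start; check that the data ",
         "span the inflection (concentrations ",
         format(min(conc)), "..", format(max(conc)), " M)")

  cf <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))), error = function(e)
    stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  ec50 <- exp(cf[["lec"]])
  out <- list(ec50 = ec50,
              n_h = cf[["nh"]],
              amplitude = if (free_amplitude) cf[["amp"]] else 1,
              rss = best$rss,
              se = c(ec50 = ec50 * unname(se["lec"]),  # delta method
                     n_h = unname(se["nh"]),
                     if (free_amplitude) c(amplitude = unname(se["amp"]))),
              converged = best$fit$convInfo$isConv,
              fitted = stats::fitted(best$fit),
              residuals = stats::residuals(best$fit),
              data = d,
              construct = "unknown")
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit [%s]: EC50 = %.4g uM, nH = %.3f%s (RSS %.3g%s)\n",
              x$construct, x$ec50 * 1e6, x$n_h,
              if (x$amplitude != 1) sprintf(", amplitude = %.3f", x$amplitude)
              else "",
              x$rss,
              if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  cat("Hill equation fit: I/Imax = 1 / (1 + (EC50/c)^nH)\n")
  est <- data.frame(
    estimate = c(object$ec50, object$n_h),
    std_error = c(object$se[["ec50"]], object$se[["n_h"]]),
    row.names = c("EC50 (M)", "nH"))
  if (object$amplitude != 1)
    est <- rbind(est, `amplitude` = c(object$amplitude,
                                      object$se[["amplitude"]]))
  print(est, digits = 4)
  cat(sprintf("residual SS: %.4g on %d points; converged: %s\n",
              object$rss, nrow(object$data), object$converged))
  invisible(object)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(ec50 = object$ec50, n_h = object$n_h,
    if (object$amplitude != 1) c(amplitude = object$amplitude))
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.data.frame(newdata)) newdata$conc
          else as.numeric(newdata)
  hill_curve(conc, object$ec50, object$n_h, object$amplitude)
}

#' @export
fitted.hill_fit <- function(object, ...) object$fitted

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
plot.hill_fit <- function(x, ...) {
  cg <- exp(seq(log(min(x$data$conc)), log(max(x$data$conc)),
                length.out = 200))
  graphics::plot(x$data$conc, x$data$y, log = "x",
                 xlab = "concentration (M)", ylab = "I / Imax", ...)
  graphics::lines(cg, predict(x, cg), col = "red")
  graphics::abline(v = x$ec50, h = 0.5 * x$amplitude, lty = 3, col = "grey50")
  invisible(x)
}

#' EC50 fold-shift between two fitted concentration-response curves
#'
#' `ec50_a / ec50_b`: a value above 1 means curve `b` is left-shifted
#' (more sensitive) relative to curve `a`.
#'
#' @param fit_a,fit_b Converged [hill_fit()] objects.
#' @return Dimensionless fold shift.
#' @export
fold_shift <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "hill_fit"), inherits(fit_b, "hill_fit"))
  if (!fit_a$converged || !fit_b$converged)
    stop("fold_shift requires converged fits")
  fit_a$ec50 / fit_b$ec50
}
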