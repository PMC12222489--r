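#' Gas constant in kcal/(mol K)
#' @keywords internal
R_KCAL <- 1.9872e-3

clip_po <- function(po, eps = 1e-12) {
  if (any(po < 0 | po > 1)) stop("open probability must lie in [0, 1]")
  if (any(po <= eps | po >= 1 - eps))
    warning("open probability at the boundary clipped to [", eps, ", 1-", eps, "]")
  pmin(pmax(po, eps), 1 - eps)
}

#' Closed-open free energy from an open probability
#'
#' The Boltzmann relation for a two-state closed-open equilibrium:
#' `dG = -RT ln(Po / (1 - Po))`, with R = 1.9872e-3 kcal/(mol K). Negative
#' values mean the open state is favored. If the supplied open probability is
#' an upper bound (unresolvable pore-blocker-sensitive current), the returned
#' free energy is flagged as a lower bound.
#'
#' @param po Open probability, in (0, 1) after clipping to
#'   `[1e-12, 1 - 1e-12]`; a [po_estimate][estimate_po_basal] is also
#'   accepted and its bound flag propagated.
#' @param temperature Absolute temperature, kelvin; 298.15 K is laboratory
#'   room temperature.
#' @return An object of class `energy_result`: list with `delta_g` (kcal/mol),
#'   `temperature`, `rt`, `po`, `is_lower_bound`.
#' @export
#' @examples
#' delta_g(0.5)             # 0 by symmetry
#' delta_g(0.002)$delta_g   # ~ +3.68 kcal/mol: closed strongly favored
delta_g <- function(po, temperature = 298.15) {
  if (temperature <= 0) stop("temperature must be positive (kelvin)")
  is_upper <- FALSE
  if (inherits(po, "po_estimate")) {
    is_upper <- isTRUE(po$is_upper_bound)
    po <- po$po
  }
  p <- clip_po(po)
  rt <- R_KCAL * temperature
  structure(list(delta_g = -rt * log(p / (1 - p)),
                 temperature = temperature, rt = rt, po = po,
                 is_lower_bound = is_upper),
            class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("dG(closed->open) = %+.3f kcal/mol%s  (Po = %.4g, T = %.2f K)\n",
              x$delta_g, if (x$is_lower_bound) " (lower bound)" else "",
              x$po, x$temperature))
  invisible(x)
}

#' Open probability from a closed-open free energy
#'
#' Inverse of [delta_g()]: `Po = 1 / (1 + exp(dG / RT))`.
#'
#' @param delta_g Free energy, kcal/mol (numeric or an `energy_result`).
#' @param temperature Kelvin.
#' @return Open probability.
#' @export
po_from_delta_g <- function(delta_g, temperature = 298.15) {
  if (inherits(delta_g, "energy_result")) {
    temperature <- delta_g$temperature
    delta_g <- delta_g$delta_g
  }
  1 / (1 + exp(delta_g / (R_KCAL * temperature)))
}

#' Perturbation free energy between two conditions
#'
#' `ddG = dG(po_perturbed) - dG(po_reference)`: the shift of the closed-open
#' equilibrium caused by a perturbation (for example ablating a main-chain
#' hydrogen bond by amide-to-ester substitution). Antisymmetric under
#' argument swap; negative values mean the perturbation favors opening.
#'
#' @param po_reference,po_perturbed Open probabilities (or `po_estimate`s).
#' @param temperature Kelvin.
#' @return ddG in kcal/mol (numeric, with bound flags as attributes when
#'   either input carried one).
#' @export
#' @examples
#' delta_delta_g(1e-5, 0.07)   # ~ -5.3 kcal/mol
delta_delta_g <- function(po_reference, po_perturbed, temperature = 298.15) {
  a <- delta_g(po_reference, temperature)
  b <- delta_g(po_perturbed, temperature)
  out <- b$delta_g - a$delta_g
  if (a$is_lower_bound || b$is_lower_bound)
    attr(out, "is_bound") <- TRUE
  out
}

#' Agonist activation energy from basal and maximal open probabilities
#'
#' The chemical energy that agonist binding delivers to the closed-open
#' equilibrium: `dG(po_max) - dG(po_basal)`, negative for activation.
#'
#' @param po_basal,po_max Open probabilities without and with saturating
#'   agonist; `po_basal < po_max` is required.
#' @param temperature Kelvin.
#' @return Activation energy, kcal/mol.
#' @export
#' @examples
#' activation_energy(0.002, 0.8)   # ~ -4.5 kcal/mol
#' activation_energy(1e-5, 0.8)    # ~ -7.6 kcal/mol
activation_energy <- function(po_basal, po_max, temperature = 298.15) {
  pb <- if (inherits(po_basal, "po_estimate")) po_basal$po else po_basal
  pm <- if (inherits(po_max, "po_estimate")) po_max$po else po_max
  if (pb >= pm) stop("po_basal must be < po_max for an activation energy")
  delta_delta_g(po_basal, po_max, temperature)
}

#' Fraction of the activation energy attributable to a perturbation
#'
#' `|perturbation| / |activation|`: how much of the agonist-driven shift of
#' the closed-open equilibrium a single perturbation accounts for.
#'
#' @param perturbation Perturbation ddG, kcal/mol.
#' @param activation Activation energy, kcal/mol; must be nonzero.
#' @return Dimensionless fraction.
#' @export
#' @examples
#' energy_fraction(-5.3, -7.6)   # ~ 0.70
#' energy_fraction(1.5, 4.5)     # ~ 1/3
energy_fraction <- function(perturbation, activation) {
  if (activation == 0) stop("activation energy is zero")
  abs(perturbation) / abs(activation)
}

#' Per-subunit share of a perturbation energy
#'
#' A receptor carrying the perturbation in each of two identical subunits
#' reports the two-bond total; this halves it on request.
#'
#' @param delta_delta_g Two-subunit ddG, kcal/mol.
#' @param n_subunits Number of perturbed subunits, default 2.
#' @return Per-subunit ddG, kcal/mol.
#' @export
per_subunit_energy <- function(delta_delta_g, n_subunits = 2) {
  as.numeric(delta_delta_g) / n_subunits
}

#' Per-group free-energy summaries across oocytes
#'
#' Converts one open-probability estimate per oocyte into per-oocyte free
#' energies and summarizes each group with median and interquartile interval,
#' matching the box-plot convention for such data. Bound flags are carried
#' through: a group containing any upper-bound Po yields lower-bound
#' energies.
#'
#' @param estimates List of [po_estimate][estimate_po_basal] objects (or bare
#'   open probabilities); each contributes one oocyte.
#' @param group Character vector of group labels, one per estimate; defaults
#'   to the construct labels.
#' @param temperature Kelvin.
#' @return Data frame of class `energy_group` with one row per group:
#'   `group`, `n`, `median_dg`, `q25_dg`, `q75_dg`, `median_po`,
#'   `any_bound`.
#' @export
group_energetics <- function(estimates, group = NULL, temperature = 298.15) {
  if (length(estimates) == 0) stop("no estimates supplied")
  if (inherits(estimates, "po_estimate")) estimates <- list(estimates)
  po <- vapply(estimates, function(e)
    if (inherits(e, "po_estimate")) e$po else as.numeric(e), numeric(1))
  bound <- vapply(estimates, function(e)
    inherits(e, "po_estimate") && isTRUE(e$is_upper_bound), logical(1))
  if (is.null(group))
    group <- vapply(estimates, function(e)
      if (inherits(e, "po_estimate")) e$construct else "all", character(1))
  dg <- vapply(po, function(p) delta_g(p, temperature)$delta_g, numeric(1))
  out <- do.call(rbind, lapply(split(seq_along(po), group), function(i) {
    q <- stats::quantile(dg[i], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(group = group[i[1]], n = length(i),
               median_dg = q[2], q25_dg = q[1], q75_dg = q[3],
               median_po = stats::median(po[i]),
               any_bound = any(bound[i]))
  }))
  rownames(out) <- NULL
  attr(out, "temperature") <- temperature
  structure(out, class = c("energy_group", "data.frame"))
}

#' @export
print.energy_group <- function(x, ...) {
  cat("closed-open free energies by group (kcal/mol, T =",
      attr(x, "temperature"), "K):\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  if (any(x$any_bound))
    cat("  groups flagged any_bound contain upper-bound Po estimates;\n",
        " their free energies are lower bounds\n")
  invisible(x)
}
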