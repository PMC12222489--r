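test_that("baseline regions are the protocol complement with margins", {
  p <- std_protocol()
  tr <- simulate_trace(p, gof_truth())

  # 8 mid-trace pulses -> 9 regions
  reg <- select_baseline_regions(tr, margin = 30)
  expect_equal(nrow(reg), 9)

  # interval-complement oracle: no region sample falls inside any widened
  # pulse window, and regions + windows tile the recording
  m <- gatecalc:::region_mask(tr$time_s, reg)
  for (i in seq_len(nrow(p$pulses))) {
    w <- tr$time_s > p$pulses$onset_s[i] - 2 &
         tr$time_s < p$pulses$onset_s[i] + p$pulses$duration_s[i] + 30
    expect_false(any(m & w))
  }
  covered <- sum(reg$end_s - reg$start_s) +
    sum(pmin(p$pulses$onset_s + p$pulses$duration_s + 30, max(tr$time_s)) -
        pmax(p$pulses$onset_s - 2, 0))
  expect_equal(covered, diff(range(tr$time_s)), tolerance = 1e-9)

  # no pulses -> one region spanning the trace
  p0 <- new_protocol(data.frame(ligand = character(), conc_M = numeric(),
                                onset_s = numeric(), duration_s = numeric()),
                     total_s = 100)
  tr0 <- simulate_trace(p0, gof_truth())
  reg0 <- select_baseline_regions(tr0)
  expect_equal(nrow(reg0), 1)
  expect_equal(c(reg0$start_s, reg0$end_s), range(tr0$time_s))

  # single mid-trace pulse -> exactly two regions
  p1 <- new_protocol(data.frame(ligand = "GABA", conc_M = 1e-5,
                                onset_s = 100, duration_s = 20),
                     total_s = 300)
  expect_equal(nrow(select_baseline_regions(simulate_trace(p1, gof_truth()))), 2)

  # missing protocol -> instructive error
  bare <- tevc_trace(0:99, rnorm(100))
  expect_error(select_baseline_regions(bare), "manually")
})

test_that("the GCV spline recovers smooth baselines to high accuracy", {
  p <- std_protocol()
  tru <- gof_truth(po_basal = 0.07, f_end = 0.4, leak = -0.3)
  tr <- simulate_trace(p, tru)
  reg <- select_baseline_regions(tr)

  # exact cubic on the regions -> residuals < 1e-8 relative
  cubic <- tevc_trace(tr$time_s,
                      2 + 1e-3 * tr$time_s - 1e-6 * tr$time_s^2 +
                        1e-10 * tr$time_s^3,
                      protocol = p)
  b <- fit_baseline_spline(cubic, reg)
  m <- gatecalc:::region_mask(tr$time_s, reg)
  expect_lt(max(abs(b[m] - cubic$current_uA[m])) /
              diff(range(cubic$current_uA)), 1e-8)

  # constant trace -> spline is that constant everywhere
  const <- tevc_trace(tr$time_s, rep(-2.5, length(tr$time_s)), protocol = p)
  expect_equal(fit_baseline_spline(const, reg),
               rep(-2.5, length(tr$time_s)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # exponential-rundown standing current tracked to < 1% on regions,
  # and interpolated across pulse windows to < 1%
  truth_base <- -tru$n0 * rundown_factor(tr$time_s, tru) *
    tru$unitary_current * tru$po_basal + tru$leak
  b2 <- fit_baseline_spline(tr, reg)
  expect_lt(max(abs(b2 - truth_base) / abs(truth_base)), 0.01)

  # linear drift + pulses: spline recovers the drift on pulse windows
  drift <- tevc_trace(tr$time_s,
                      tr$current_uA - truth_base + (-1 + 5e-4 * tr$time_s),
                      protocol = p)
  b3 <- fit_baseline_spline(drift, reg)
  expect_lt(max(abs(b3 - (-1 + 5e-4 * tr$time_s))) /
              diff(range(-1 + 5e-4 * tr$time_s)), 0.01)

  expect_error(fit_baseline_spline(
    tr, baseline_regions(data.frame(start_s = 0, end_s = 0.2))), "fewer")
})

test_that("detrending zeroes the baseline and preserves pulse deflections", {
  p <- std_protocol()
  tru <- gof_truth(po_basal = 0.07, f_end = 0.4)
  tr <- simulate_trace(p, tru)
  d <- detrend(tr)

  # detrended ~ 0 on baseline regions
  m <- gatecalc:::region_mask(tr$time_s, d$regions)
  expect_lt(max(abs(d$detrended[m])), 1e-4)
  expect_equal(d$detrended, tr$current_uA - d$baseline_spline)

  # PTX deflection equals the standing current n0 f(t) i_u po_basal
  resp <- extract_pulse_responses(d)
  i1 <- which(resp$ligand == "PTX")[1]
  f1 <- rundown_factor(resp$t_peak_s[i1], tru)
  expect_equal(resp$amplitude[i1],
               tru$n0 * f1 * tru$unitary_current * tru$po_basal,
               tolerance = 0.01)

  # idempotence: detrending the already-flat series changes it by < 1e-6
  flat <- tevc_trace(tr$time_s, d$detrended, protocol = p)
  d2 <- detrend(flat)
  expect_lt(max(abs(d2$detrended[m] - d$detrended[m])), 1e-6)

  # baseline = trace -> identically zero
  d3 <- detrend(tr, baseline = tr$current_uA)
  expect_true(all(d3$detrended == 0))

  # flat baseline leaves pulse-window deflections unchanged to < 1%
  no_rd <- simulate_trace(p, gof_truth(po_basal = 0.07))
  r_raw <- extract_pulse_responses(detrend(no_rd, baseline = rep(
    -no_rd$truth$n0 * no_rd$truth$unitary_current * 0.07,
    length(no_rd$time_s))))
  r_fit <- extract_pulse_responses(detrend(no_rd))
  ig <- r_raw$ligand == "GABA"
  expect_equal(r_fit$amplitude[ig], r_raw$amplitude[ig], tolerance = 0.01)
})

test_that("rundown normalization equalizes start/end PTX deflections", {
  p <- std_protocol()

  # no rundown: normalized = detrended / constant; ratio 1 to < 1e-6
  tr1 <- simulate_trace(p, gof_truth(po_basal = 0.07, f_end = 1))
  n1 <- rundown_normalize(detrend(tr1))
  expect_lt(abs(ptx_ratio(extract_pulse_responses(n1)) - 1), 1e-6)

  # strong rundown, noise-free: normalized ratio in [0.99, 1.01],
  # unnormalized ratio tracks the rundown factor instead
  tr2 <- simulate_trace(p, gof_truth(po_basal = 0.07, f_end = 0.4))
  d2 <- detrend(tr2)
  n2 <- rundown_normalize(d2)
  expect_gt(ptx_ratio(extract_pulse_responses(n2)), 0.99)
  expect_lt(ptx_ratio(extract_pulse_responses(n2)), 1.01)
  raw_ratio <- ptx_ratio(extract_pulse_responses(d2))
  i <- which(p$pulses$ligand == "PTX")
  f_expect <- rundown_factor(p$pulses$onset_s[i[2]], tr2$truth) /
    rundown_factor(p$pulses$onset_s[i[1]], tr2$truth)
  expect_equal(raw_ratio, f_expect, tolerance = 0.05)

  # WT-like trace (near-zero standing current): the floor guards the division
  wt <- simulate_trace(p, gating_truth(po_basal = 1e-4, noise_sd = 0.05,
                                       seed = 5L))
  expect_error(rundown_normalize(detrend(wt), floor = 0.5), "floor")
})

test_that("pulse responses are tagged, monotone, and match the generator", {
  p <- std_protocol()
  tru <- gof_truth(po_basal = 0.07, f_end = 0.4)
  tr <- simulate_trace(p, tru)
  d <- rundown_normalize(detrend(tr))
  resp <- extract_pulse_responses(d)
  expect_equal(resp$ligand, p$pulses$ligand)
  expect_equal(resp$conc_M, p$pulses$conc_M)
  expect_true(all(resp$t_peak_s >= p$pulses$onset_s &
                  resp$t_peak_s <= p$pulses$onset_s + p$pulses$duration_s + 5))

  # normalized GABA amplitudes match (Po(c) - po_basal) / po_basal
  ig <- which(resp$ligand == "GABA")
  po_c <- po_of_concentration(resp$conc_M[ig], tru)
  expect_equal(resp$amplitude[ig], (po_c - 0.07) / 0.07, tolerance = 0.02)

  # monotone non-decreasing across the ascending series
  expect_true(all(diff(resp$amplitude[ig]) >= -1e-9))

  # zero trace -> all responses 0
  z <- detrend(tevc_trace(tr$time_s, numeric(length(tr$time_s)),
                          protocol = p),
               baseline = numeric(length(tr$time_s)))
  expect_true(all(extract_pulse_responses(z)$amplitude == 0))

  # window outside the trace errors
  bad <- new_protocol(data.frame(ligand = "GABA", conc_M = 1e-5,
                                 onset_s = 1e5, duration_s = 10),
                      total_s = 1e5 + 20)
  expect_error(extract_pulse_responses(d, protocol = bad), "outside")
})

test_that("the Po estimator is anchored, clipped and bound-flagged", {
  a <- list(amplitude = 0); b <- list(amplitude = 3)
  expect_equal(estimate_po_basal(a, b)$po, 0)
  expect_equal(estimate_po_basal(b, a)$po, 1)
  e <- estimate_po_basal(list(amplitude = 1), list(amplitude = 3))
  expect_equal(e$po, 0.25)
  expect_equal(e$i_ptx, 1)
  expect_equal(e$i_total, 4)
  expect_error(estimate_po_basal(a, list(amplitude = 0)), "no PTX")

  # resolvability flag: PTX deflection below 3 baseline SDs
  expect_true(estimate_po_basal(list(amplitude = 0.02), b,
                                baseline_sd = 0.01)$is_upper_bound)
  expect_false(estimate_po_basal(list(amplitude = 0.05), b,
                                 baseline_sd = 0.01)$is_upper_bound)

  # negative (noise-dominated) amplitudes clip to zero
  expect_equal(estimate_po_basal(list(amplitude = -0.01), b)$po, 0)
})

test_that("the full chain recovers basal Po from noise-free traces", {
  p <- std_protocol()
  for (po in c(0.002, 0.07, 0.3)) {
    a <- process_trace(simulate_trace(p, gof_truth(po_basal = po)))
    expect_lt(abs(a$po$po - po), 1e-3)
  }
  # with rundown + normalization, still within 1e-3
  a <- process_trace(simulate_trace(p, gof_truth(po_basal = 0.07,
                                                 f_end = 0.4)))
  expect_false(is.null(a$detrend$normalized))
  expect_lt(abs(a$po$po - 0.07), 1e-3)

  # estimates always normalized into [0, 1] with non-negative components
  expect_true(a$po$po >= 0 && a$po$po <= 1)
  expect_true(a$po$i_ptx >= 0 && a$po$i_total >= 0)
})
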