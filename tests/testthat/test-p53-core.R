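test_that("the basal rest state is a verified stable steady state", {
  pars <- p53_params()
  rest <- p53_rest_state(pars, dsb_level = 2)
  f <- p53dyn:::p53_rhs(0, as.numeric(rest), 2, pars)
  expect_lt(sqrt(sum(f^2)), 1e-10)
  sim <- p53dyn:::integrate_const_dsb(rest, pars, 2, t_end = 100, dt = 0.5)
  drift <- max(abs(as.numeric(sim[nrow(sim), -1]) - as.numeric(rest)))
  expect_lt(drift, 1e-6)
  expect_true(all(rest >= 0))
})

test_that("with no damage and no production the origin is the rest state", {
  pars <- p53_params(b_P = 0, b_Mm = 0, b_Wm = 0, k_TM = 0, k_TW = 0)
  rest <- p53_rest_state(pars, dsb_level = 0)
  expect_lt(max(abs(rest)), 1e-8)
})

test_that("a brief damage burst excites one isolated full pulse", {
  pars <- p53_params()
  rest <- p53_rest_state(pars, 2)
  burst <- step_track(20, 1.5, d_lo = 2, t_end = 60)
  sim <- simulate_cell(burst, pars, t_end = 24)
  p <- detect_pulses(
    tibble::tibble(cell_id = "c", time_h = sim$time_h, value = sim$p53),
    min_amplitude = 1.5)
  expect_equal(nrow(p), 1L)
  expect_lt(p$peak_time_h, 4)
  # the cell relaxes back to its rest state
  expect_lt(abs(sim$p53[nrow(sim)] - rest[["p53"]]), 0.05)
})

test_that("persistent damage sustains oscillations for 48 h", {
  pars <- p53_params()
  sim <- simulate_cell(const_track(30), pars, t_end = 48)
  p <- detect_pulses(
    tibble::tibble(cell_id = "c", time_h = sim$time_h, value = sim$p53),
    min_amplitude = 0.5)
  expect_gte(nrow(p), 7L)
  expect_gt(max(p$peak_time_h), 42)
  ipis <- diff(sort(p$peak_time_h))
  expect_equal(stats::median(ipis), 5, tolerance = 0.2)
  # amplitudes essentially uniform on the cycle
  expect_lt(stats::sd(p$amplitude) / mean(p$amplitude), 0.1)
})

test_that("transient damage gives oscillations, then a clean return to rest", {
  pars <- p53_params()
  rest <- p53_rest_state(pars, 2)[["p53"]]
  med <- step_track(30, 12, d_lo = 2, t_end = 60)
  sim <- simulate_cell(med, pars, t_end = 48)
  pk <- p53dyn:::series_peak_times(sim$time_h, sim$p53)
  pv <- stats::approx(sim$time_h, sim$p53, xout = pk)$y - rest
  full <- pv[pv > 0.5]
  expect_gte(length(full), 3L)
  # pulse shape conserved: last full pulse within 15% of the first
  expect_lt(abs(full[length(full)] - full[1]) / full[1], 0.15)
  # quiet by the end of the recording
  expect_lt(max(pk[pv > 0.5]), 30)
})

test_that("interventions validate targets and factor one is a no-op", {
  pars <- p53_params()
  tr <- step_track(20, 1.5)
  ctrl <- simulate_cell(tr, pars, t_end = 12)
  same <- simulate_cell(tr, pars, t_end = 12,
                        interventions = list(
                          list(time = 2, target = "k_dsb", factor = 1)))
  expect_identical(ctrl$p53, same$p53)
  expect_error(simulate_cell(tr, pars, t_end = 12,
                             interventions = list(
                               list(time = 1, target = "nope", factor = 0.5))),
               "unknown intervention target")
})

test_that("earlier ATM inhibition truncates the pulse more", {
  pars <- p53_params()
  tr <- step_track(30, 3, d_lo = 2, t_end = 60)
  ctrl <- max(simulate_cell(tr, pars, t_end = 20)$p53)
  peaks <- vapply(c(0.5, 1, 2), function(ti) {
    iv <- list(list(time = ti, target = "k_dsb", factor = 0.02),
               list(time = ti, target = "v_s", factor = 0.02))
    max(simulate_cell(tr, pars, t_end = 20, interventions = iv)$p53)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
  expect_lt(peaks[1], ctrl)
  expect_equal(peaks[3], ctrl, tolerance = 0.01)
})

test_that("the excitation threshold is directional: ATM/Wip1 matter, p53/Mdm2 do not", {
  pars <- p53_params()
  rest <- p53_rest_state(pars, 2)
  # +-50% kicks in p53 and Mdm2 never elicit a full pulse
  dirs <- matrix(0, 5, 6)
  dirs[1, 2] <- 0.5 * rest[["p53"]]; dirs[2, 2] <- -0.5 * rest[["p53"]]
  dirs[3, 4] <- 0.5 * rest[["Mdm2"]]; dirs[4, 4] <- -0.5 * rest[["Mdm2"]]
  # row 5 is the zero perturbation
  res <- excitation_threshold(pars, directions = dirs)
  expect_true(all(!res$full_pulse))
  # the critical ATM* kick grows with the cell's Wip1 expression
  crit <- vapply(c(1, 1.4, 2), function(ws) {
    mean(excitation_threshold(p53_params(wip1_scale = ws),
                              directions = "ATM_a"))
  }, numeric(1))
  expect_true(all(diff(crit) > 0))
})

test_that("pulse amplitudes are all-or-none over a fine grid of ATM kicks", {
  pars <- p53_params()
  kicks <- seq(0, 1, length.out = 50)
  dirs <- matrix(0, length(kicks), 6)
  dirs[, 1] <- kicks
  res <- excitation_threshold(pars, directions = dirs)
  ref <- attr(res, "reference_amplitude")
  frac <- res$peak_p53 / ref
  expect_lt(mean(frac > 0.2 & frac < 0.8), 0.05)
  # both modes populated
  expect_gt(mean(frac <= 0.2), 0.1)
  expect_gt(mean(frac >= 0.8), 0.2)
})
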