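# peak values of the readout above half the maximum deflection
readout_peaks <- function(sim, readout = "x") {
  pk <- p53dyn:::series_peak_times(sim$time_h, sim[[readout]])
  pv <- stats::approx(sim$time_h, sim[[readout]], xout = pk)$y
  pv[pv > 0.5 * max(pv)]
}

test_that("both models rest stably at zero input", {
  for (nm in c("NF", "NPF")) {
    m <- abstract_model(nm)
    rest <- model_rest_state(m)
    # 1% perturbations relax back
    pert <- rest + 0.01 * (abs(rest) + 0.1)
    sim <- simulate_model(m, 0, t_end = 80, x0 = pert)
    final <- as.numeric(sim[nrow(sim), m$species])
    expect_lt(sqrt(sum((final - rest)^2)), 1e-4)
  }
})

test_that("NF responds gradedly: amplitude grows with transient strength", {
  nf <- abstract_model("NF")
  rc <- response_curve(nf, c(0, 0.3, 0.6, 1, 1.5), duration = 1)
  expect_equal(rc$amplitude[1], 0)
  expect_true(all(diff(rc$amplitude) > 0))
  expect_true(is.na(attr(rc, "threshold")))
})

test_that("NF oscillates between two onsets with vanishing amplitude", {
  nf <- abstract_model("NF")
  sc <- bifurcation_scan(nf, c(0.05, 0.15, 0.25, 0.45, 0.65, 1, 1.5, 1.9,
                               2.3, 3),
                         t_end = 250, dt = 0.1)
  osc <- sc$oscillating
  expect_false(osc[1])                  # stable below the first onset
  expect_false(osc[length(osc)])        # stable above the second
  expect_true(any(osc))
  o <- sc[osc, ]
  # amplitudes shrink toward both boundaries
  expect_lt(o$amplitude[1], max(o$amplitude))
  expect_lt(o$amplitude[nrow(o)], max(o$amplitude))
  expect_identical(as.character(classify_onset(sc, "lower")), "hopf_like")
  expect_identical(as.character(classify_onset(sc, "upper")), "hopf_like")
})

test_that("NPF shows an all-or-none response with a sharp threshold", {
  npf <- abstract_model("NPF")
  rc <- response_curve(npf, seq(0, 0.4, by = 0.02), duration = 1)
  expect_equal(rc$amplitude[1], 0)
  thr <- attr(rc, "threshold")
  expect_false(is.na(thr))
  sub <- max(rc$amplitude[rc$strength < thr])
  supra <- min(rc$amplitude[rc$strength > thr])
  expect_lt(sub / supra, 0.2)
  # amplitude saturates: pulse at s and 2 s nearly identical
  a1 <- rc$amplitude[which.min(abs(rc$strength - 1.5 * thr))]
  a2 <- rc$amplitude[which.min(abs(rc$strength - 3 * thr))]
  expect_equal(a1, a2, tolerance = 0.1)
})

test_that("NPF oscillation onset is homoclinic-like: full amplitude, diverging period", {
  npf <- abstract_model("NPF")
  sc <- bifurcation_scan(npf, c(0.015, 0.021, 0.024, 0.03, 0.05, 0.07,
                                0.09, 0.12),
                         t_end = 700, dt = 0.1)
  o <- sc[sc$oscillating & !is.na(sc$oscillating), ]
  mid_amp <- stats::median(o$amplitude)
  expect_gte(o$amplitude[1], 0.8 * mid_amp)   # born at full strength
  expect_identical(as.character(classify_onset(sc)), "homoclinic_like")
})

test_that("sustained NPF oscillation keeps constant peak amplitudes", {
  npf <- abstract_model("NPF")
  rest <- model_rest_state(npf)
  sim <- simulate_model(npf, 0.06, t_end = 500, dt = 0.1,
                        x0 = rest + c(0.05, 0))
  late <- sim[sim$time_h > 200, ]
  pv <- readout_peaks(late)
  pv <- utils::tail(pv, 5)
  expect_lt(stats::sd(pv) / mean(pv), 0.02)
})

test_that("decaying input: NPF keeps full pulses until it stops, NF fades", {
  npf <- abstract_model("NPF")
  sus <- simulate_model(npf, 0.07, t_end = 500, dt = 0.1,
                        x0 = model_rest_state(npf) + c(0.05, 0))
  sus_amp <- mean(utils::tail(readout_peaks(sus[sus$time_h > 200, ]), 5))
  dec <- simulate_model(npf,
                        stimulus_protocol("decaying", strength = 0.07,
                                          half_life = 60),
                        t_end = 400, dt = 0.1)
  pv <- readout_peaks(dec)
  expect_gte(length(pv), 2)
  expect_true(all(abs(pv - sus_amp) / sus_amp < 0.1))

  nf <- abstract_model("NF")
  nf_dec <- simulate_model(nf,
                           stimulus_protocol("decaying", strength = 1,
                                             half_life = 15),
                           t_end = 120, dt = 0.05)
  pk <- p53dyn:::series_peak_times(nf_dec$time_h, nf_dec$x)
  pvn <- stats::approx(nf_dec$time_h, nf_dec$x, xout = pk)$y
  pvn <- pvn[pvn > 0.05 * max(pvn)]
  expect_gte(length(pvn), 3)
  expect_true(all(diff(pvn) < 0))
})

test_that("onset classification matches normal-form oracles", {
  # supercritical Hopf: amplitude ~ sqrt(s - s_c), bounded period
  s <- seq(0, 1, by = 0.05)
  hopf <- tibble::tibble(parameter = s, oscillating = s > 0.3,
                         amplitude = ifelse(s > 0.3, sqrt(pmax(s - 0.3, 0)), 0),
                         period = ifelse(s > 0.3, 5 + 0.3 * (s - 0.3), NA))
  expect_identical(as.character(classify_onset(hopf)), "hopf_like")
  # SNIC: constant amplitude, period ~ 1/sqrt(s - s_c)
  snic <- tibble::tibble(parameter = s, oscillating = s > 0.3,
                         amplitude = ifelse(s > 0.3, 2, 0),
                         period = ifelse(s > 0.3, 5 / sqrt(pmax(s - 0.3, 1e-9)), NA))
  expect_identical(as.character(classify_onset(snic)), "homoclinic_like")
  # unbracketed onset errors
  allosc <- tibble::tibble(parameter = s, oscillating = TRUE,
                           amplitude = 1, period = 5)
  expect_error(classify_onset(allosc), "bracket")
})

test_that("timed inhibition separates signal relays from the excitation loop", {
  npf <- abstract_model("NPF")
  times <- c(0.5, 1, 2, 4)
  sig <- inhibition_experiment(npf, "signal", t_inhibit = times,
                               factor = 0.05, strength = 0.35, duration = 1)
  ctrl <- inhibition_experiment(npf, "signal", t_inhibit = 30,
                                factor = 1, strength = 0.35, duration = 1)
  # all-or-none response untouched by signal inhibition after ignition
  expect_true(all(sig$amplitude > 0.8 * ctrl$amplitude))
  spx <- inhibition_experiment(npf, "species_x", t_inhibit = times,
                               factor = 0.05, strength = 0.35, duration = 1)
  expect_true(all(diff(spx$amplitude) > 0))        # graded in time
  expect_lt(spx$amplitude[1], 0.5 * ctrl$amplitude)
  # factor 1 is a no-op
  noop <- inhibition_experiment(npf, "species_x", t_inhibit = 1, factor = 1,
                                strength = 0.35, duration = 1)
  expect_equal(noop$amplitude, ctrl$amplitude, tolerance = 1e-8)
  expect_error(inhibition_experiment(npf, "signal", t_inhibit = 100,
                                     factor = 0.1, t_end = 40),
               "beyond")
})
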