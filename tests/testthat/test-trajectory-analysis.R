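test_that("noiseless pulse trains are detected at the right times", {
  tr <- make_pulse_train(pulse_train_spec(c(5, 10, 15), amplitudes = 1,
                                          widths = 2.355, baseline = 0.1),
                         times = grid20(20))
  p <- detect_pulses(tr)
  expect_equal(nrow(p), 3L)
  expect_equal(sort(p$peak_time_h), c(5, 10, 15), tolerance = 1 / 3)

  flat <- tibble::tibble(time_h = grid20(48), value = 1)
  expect_equal(nrow(detect_pulses(flat)), 0L)
})

test_that("spline refinement recovers Gaussian amplitude and FWHM", {
  tr <- make_pulse_train(pulse_train_spec(10, amplitudes = 2,
                                          widths = 2.355, baseline = 0.5),
                         times = seq(0, 20, by = 0.25))
  p <- detect_pulses(tr)
  expect_equal(nrow(p), 1L)
  expect_true(p$refined)
  expect_equal(p$amplitude, 2, tolerance = 0.03)
  expect_equal(p$width_h, 2.355, tolerance = 0.05)
})

test_that("overlapping pulses three hours apart are both refined", {
  tr <- make_pulse_train(pulse_train_spec(c(10, 13), amplitudes = 2,
                                          widths = 2, baseline = 0.2),
                         times = seq(0, 24, by = 0.25))
  p <- detect_pulses(tr)
  expect_equal(nrow(p), 2L)
  expect_equal(sort(p$peak_time_h), c(10, 13), tolerance = 0.25)
})

test_that("detector recall and false positives behave under noise", {
  spec <- pulse_train_spec(c(10, 20, 30), amplitudes = 1, widths = 2.5,
                           baseline = 0.2)
  clean <- make_pulse_train(spec, times = seq(0, 40, by = 0.05))
  recall_at <- function(sigma, n_trial, seed0) {
    hits <- 0; fps <- 0
    for (k in seq_len(n_trial)) {
      obs <- emulate_microscopy(clean,
                                noise_model(additive_sigma = sigma,
                                            sampling_dt = 1 / 3,
                                            duration = 40),
                                seed = seed0 + k)
      p <- detect_pulses(obs)
      matched <- vapply(c(10, 20, 30), function(t0) {
        any(abs(p$peak_time_h - t0) < 1.5)
      }, logical(1))
      hits <- hits + sum(matched)
      fps <- fps + max(0, nrow(p) - sum(matched))
    }
    c(recall = hits / (3 * n_trial), fp = fps / n_trial)
  }
  r5 <- recall_at(1 / 5, 100, 4000)   # SNR 5
  expect_gte(r5["recall"], 0.95)
  expect_lte(r5["fp"], 0.05)
  # recall monotone non-increasing as noise grows
  r0 <- recall_at(0, 10, 5000)
  r10 <- recall_at(1 / 10, 30, 6000)
  r3 <- recall_at(1 / 3, 30, 7000)
  expect_true(r0["recall"] >= r10["recall"] - 1e-9)
  expect_true(r10["recall"] >= r5["recall"] - 0.02)
  expect_true(r5["recall"] >= r3["recall"] - 0.02)
})

test_that("detector is equivariant under time shifts and value scaling", {
  spec <- pulse_train_spec(c(8, 16), amplitudes = c(1, 1.5), widths = 2,
                           baseline = 0.3)
  tr <- make_pulse_train(spec, times = grid20(30))
  p0 <- detect_pulses(tr)
  shifted <- dplyr::mutate(tr, time_h = time_h + 7)
  p_shift <- detect_pulses(shifted)
  # tolerance: one step of the refinement grid (floating-point jitter can
  # flip the argmax between two near-equal fine-grid points)
  expect_equal(p_shift$peak_time_h, p0$peak_time_h + 7, tolerance = 0.02)
  scaled <- dplyr::mutate(tr, value = value * 3)
  p_scale <- detect_pulses(scaled)
  expect_equal(p_scale$amplitude, p0$amplitude * 3, tolerance = 1e-3)
  expect_equal(p_scale$peak_time_h, p0$peak_time_h, tolerance = 0.02)
  expect_equal(p_scale$width_h, p0$width_h, tolerance = 0.02)
})

test_that("IPI bookkeeping follows the eligibility rules", {
  pulses <- tibble::tibble(cell_id = c("a", "a", "a", "b", "c", "c"),
                           peak_time_h = c(2, 7, 12, 5, 3, 9))
  st <- compute_ipis(pulses)
  expect_equal(sort(st$all), c(5, 5, 6))
  expect_equal(st$per_cell$first_ipi[st$per_cell$cell_id == "a"], 5)
  expect_equal(st$per_cell$last_ipi[st$per_cell$cell_id == "a"], 5)
  # single-pulse cell contributes nothing
  expect_false("b" %in% st$per_cell$cell_id[!is.na(st$per_cell$first_ipi)])
  # two-pulse cell: first and last coincide
  expect_equal(st$per_cell$first_ipi[st$per_cell$cell_id == "c"],
               st$per_cell$last_ipi[st$per_cell$cell_id == "c"])
})

test_that("KL divergence is zero on identical samples and positive otherwise", {
  set.seed(10)
  x <- stats::rnorm(500)
  expect_equal(kld(x, x), 0)
  y <- stats::rnorm(500, mean = 6)
  expect_gt(kld(x, y), 1)
  expect_gt(kld(y, x), 1)
  # asymmetric in general
  z <- stats::rnorm(500, sd = 3)
  expect_false(isTRUE(all.equal(kld(x, z), kld(z, x))))
  expect_error(kld(numeric(), x), "non-empty")
})

test_that("pulse counts over a window include silent cells", {
  pulses <- tibble::tibble(cell_id = c("a", "a", "b"),
                           peak_time_h = c(5, 50, 10))
  pc <- pulse_count_stats(pulses, window = 48, cell_ids = c("a", "b", "c"))
  expect_equal(pc$n_pulses[match(c("a", "b", "c"), pc$cell_id)], c(1L, 1L, 0L))
})
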