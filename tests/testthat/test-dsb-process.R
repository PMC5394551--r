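test_that("next-jump waiting times follow the piecewise-exponential law", {
  # pure-birth basal regime: exponential with rate b_b
  p <- dsb_params(b_b = 0.7, b_s = 0, T_s = 0)
  set.seed(1)
  w <- replicate(1e4, sample_next_jump(c(0, 0), t_now = 10, p)$waiting_time)
  expect_equal(mean(w), 1 / 0.7, tolerance = 0.05)

  # pure-death: rate n * r, only isolated repairs
  p2 <- dsb_params(b_b = 0, b_s = 0, r = 0.35)
  set.seed(2)
  draws <- replicate(2e3, sample_next_jump(c(5, 0), t_now = 1, p2),
                     simplify = FALSE)
  w2 <- vapply(draws, `[[`, numeric(1), "waiting_time")
  ev <- vapply(draws, `[[`, character(1), "event")
  expect_equal(mean(w2), 1 / (5 * 0.35), tolerance = 0.1)
  expect_true(all(ev == "repair_i"))

  # step-rate crossing: CDF 1 - exp(-b_s min(t, T_s) - b_b max(t - T_s, 0))
  p3 <- dsb_params(b_b = 0.7, b_s = 10, T_s = 0.5)
  set.seed(3)
  w3 <- replicate(1e5, sample_next_jump(c(0, 0), t_now = 0, p3)$waiting_time)
  Fn <- stats::ecdf(w3)
  tt <- seq(0.01, 4, by = 0.01)
  Fa <- 1 - exp(-10 * pmin(tt, 0.5) - 0.7 * pmax(tt - 0.5, 0))
  expect_lt(max(abs(Fn(tt) - Fa)), 0.01)

  # absorbing state only when all rates vanish
  p4 <- dsb_params(b_b = 0, b_s = 0)
  expect_equal(sample_next_jump(c(0, 0), 0, p4)$waiting_time, Inf)
})

test_that("simulated tracks reach the printed background level b_b/r = 2", {
  p <- dsb_params()
  expect_equal(p$b_b / p$r, 2)
  trks <- lapply(1:60, function(i) simulate_dsb_track(p, 200, seed = i))
  g <- seq(50, 200, by = 1)
  means <- vapply(trks, function(tr) mean(dsb_count_at(tr, g)), numeric(1))
  sem <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 2), 3 * sem + 0.05)
})

test_that("track invariants hold and empty processes stay empty", {
  tr <- simulate_dsb_track(dsb_params(b_s = 40, T_s = 0.5), 30, seed = 5)
  expect_true(all(tr$total == tr$idsb + tr$cdsb))
  expect_true(all(tr$idsb >= 0 & tr$cdsb >= 0))
  expect_true(!is.unsorted(tr$time_h))
  # single-unit jumps (excluding the closing row at t_end)
  n <- nrow(tr)
  steps <- abs(diff(tr$idsb[-n])) + abs(diff(tr$cdsb[-n]))
  expect_true(all(steps == 1))

  none <- simulate_dsb_track(dsb_params(b_b = 0, b_s = 0), 10, seed = 1)
  expect_equal(nrow(none), 2L)  # initial state + closing row
  expect_true(all(none$total == 0))
})

test_that("seeded runs are bit-reproducible", {
  a <- simulate_dsb_track(dsb_params(b_s = 20), 40, seed = 42)
  b <- simulate_dsb_track(dsb_params(b_s = 20), 40, seed = 42)
  expect_identical(a, b)
})

test_that("basal stationary law is Poisson(b_b/r)", {
  p <- dsb_params(f_c = 0)
  trks <- lapply(1:40, function(i) simulate_dsb_track(p, 270, seed = 100 + i))
  # sample far apart in time so draws are close to independent
  g <- seq(20, 270, by = 10)
  x <- unlist(lapply(trks, function(tr) dsb_count_at(tr, g)))
  kmax <- max(x)
  obs <- tabulate(x + 1L, nbins = kmax + 1L)
  pr <- stats::dpois(0:kmax, 2)
  # pool the sparse tail so expected counts stay reasonable
  keep <- pr * length(x) >= 5
  obs2 <- c(obs[keep], sum(obs[!keep]))
  pr2 <- c(pr[keep], 1 - sum(pr[keep]))
  gof <- suppressWarnings(stats::chisq.test(obs2, p = pr2))
  expect_gt(gof$p.value, 0.01)
})

test_that("mean_dsb matches the closed form and its degenerate limit", {
  p <- dsb_params()
  expect_equal(mean_dsb(0, 50, p), 50)
  expect_equal(mean_dsb(4, 50, p), 2 + 48 * exp(-1.4))
  expect_equal(mean_dsb(1e6, 50, p), 2, tolerance = 1e-10)
  expect_warning(lim <- mean_dsb(3, 10, dsb_params(r = 0)), "degenerate")
  expect_equal(lim, 10 + 0.7 * 3)
})

test_that("ensemble mean follows the decay law within 3 SEM", {
  p <- dsb_params(f_c = 0)
  trks <- lapply(1:200, function(i) {
    simulate_dsb_track(p, 20, init = c(50L, 0L), seed = 300 + i)
  })
  tp <- seq(1, 20, length.out = 20)
  counts <- vapply(trks, function(tr) dsb_count_at(tr, tp),
                   numeric(length(tp)))
  m <- rowMeans(counts)
  sem <- apply(counts, 1, stats::sd) / sqrt(ncol(counts))
  expect_true(all(abs(m - mean_dsb(tp, 50, p)) < 3 * sem + 0.05))
})

test_that("two-class total mean is the sum of the single-class means", {
  p <- dsb_params(b_b = 0, b_s = 0, f_c = 0.5)
  trks <- lapply(1:300, function(i) {
    simulate_dsb_track(p, 15, init = c(30L, 30L), seed = 500 + i)
  })
  tp <- c(2, 5, 10, 15)
  counts <- vapply(trks, function(tr) dsb_count_at(tr, tp),
                   numeric(length(tp)))
  m <- rowMeans(counts)
  expected <- 30 * exp(-p$r * tp) + 30 * exp(-p$r_c * tp)
  sem <- apply(counts, 1, stats::sd) / sqrt(ncol(counts))
  expect_true(all(abs(m - expected) < 3 * sem + 0.05))
})

test_that("ensemble median decays monotonically after the damage burst", {
  p <- dsb_params(b_s = dose_break_rate(60), T_s = 0.5)
  trks <- lapply(1:80, function(i) simulate_dsb_track(p, 30, seed = 700 + i))
  tp <- seq(1, 30, by = 1)
  med <- apply(vapply(trks, function(tr) dsb_count_at(tr, tp),
                      numeric(length(tp))), 1, stats::median)
  expect_true(all(diff(med) <= 0.5))  # allow unit-count plateau wiggle
  expect_lt(med[length(med)], med[1] / 5)
})

test_that("mean repair time follows ln(N_s)/r and rejects no-transient input", {
  p <- dsb_params()
  expect_equal(mean_repair_time(1000, p), log(1000) / 0.35)
  expect_lt(mean_repair_time(1000, p), 20)
  expect_equal(mean_repair_time(exp(1), dsb_params(r = 1, b_b = 0.5)), 1)
  expect_error(mean_repair_time(1.5, p), "transient")
})

test_that("mean repair time agrees with simulated first-return times", {
  p <- dsb_params(f_c = 0)
  rt <- vapply(1:200, function(i) {
    tr <- simulate_dsb_track(p, 40, init = c(50L, 0L), seed = 900 + i)
    first_return_time(tr, 2)
  }, numeric(1))
  expect_equal(mean(rt, na.rm = TRUE), mean_repair_time(50, p),
               tolerance = 0.25)
})
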