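# --- cell-population ensembles --------------------------------------------

#' Sample per-cell Wip1 production rates
#'
#' Cell-to-cell variability in Wip1 expression is modeled as a lognormal
#' distribution of wip1 mRNA production rates, applied as the
#' `wip1_scale` multiplier of [p53_params()]. The default log-scale SD is
#' calibrated so the simulated steady-state wip1 mRNA CV across a basal
#' population is about 0.52.
#'
#' @param n number of cells.
#' @param meanlog,sdlog lognormal parameters (log scale); `sdlog = 0`
#'   yields a homogeneous population at `exp(meanlog)`.
#' @param seed optional integer seed.
#' @return Numeric vector of `n` production-rate multipliers.
#' @export
sample_wip1_rates <- function(n, meanlog = 0, sdlog = 0.49, seed = NULL) {
  stopifnot(n >= 1, sdlog >= 0)
  if (!is.null(seed)) set.seed(seed)
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

#' Simulate a heterogeneous cell population
#'
#' Runs `n_cells` independent cells: each gets its own DSB realization (dose
#' expressed as the target maximal number of inflicted breaks `N_s`) and its
#' own lognormal Wip1 production rate, the two sources of cell-to-cell
#' variability carried by the model. Trajectories are analyzed with the
#' wavelet pulse detector; a cell is a *responder* if it shows a detected
#' pulse with peak time within the first `responder_window` hours.
#'
#' @param n_cells number of cells.
#' @param N_s dose: target maximal number of inflicted DSBs (0 = basal).
#' @param params a [p53_params()] (per-cell `wip1_scale` is multiplied on
#'   top of this).
#' @param dsb_params a [dsb_params()]; its `b_s`/`T_s` are overridden by the
#'   dose unless `N_s = 0`.
#' @param meanlog,sdlog Wip1 heterogeneity law (see [sample_wip1_rates()]).
#' @param t_end recording length, hours.
#' @param sample_dt sampling interval, hours.
#' @param seed root seed; all per-cell seeds derive from it.
#' @param min_amplitude pulse amplitude floor passed to [detect_pulses()];
#'   the default (0.5) is about a quarter of the full-pulse amplitude.
#' @param responder_window hours within which the first pulse must fall for
#'   the cell to count as a responder.
#' @param keep_trajectories keep the full per-cell trajectories (needed for
#'   snapshot statistics such as the wip1 mRNA CV).
#' @return An object of class `p53_ensemble`: list with `cells` (per-cell
#'   summary tibble), `pulses` (pooled pulse tibble), `ipis` (an
#'   [compute_ipis()] result), `trajectories` (tibble or `NULL`) and the
#'   configuration. [generics::tidy()] returns the per-cell table,
#'   [generics::glance()] a one-row summary.
#' @export
run_ensemble <- function(n_cells, N_s = 0, params = p53_params(),
                         dsb_params = p53dyn::dsb_params(),
                         meanlog = 0, sdlog = 0.49,
                         t_end = 48, sample_dt = 1 / 3, seed = 1,
                         min_amplitude = 0.5, responder_window = 6,
                         keep_trajectories = FALSE) {
  stopifnot(n_cells >= 1)
  seeds <- derive_seeds(seed, n_cells)
  rates <- sample_wip1_rates(n_cells, meanlog, sdlog)
  dp <- dsb_params
  if (N_s > 0) {
    dp$b_s <- dose_break_rate(N_s, dp$T_s)
  } else {
    dp$b_s <- 0
  }

  cells <- vector("list", n_cells)
  pulses <- vector("list", n_cells)
  trajs <- if (keep_trajectories) vector("list", n_cells) else NULL
  for (i in seq_len(n_cells)) {
    cid <- sprintf("cell_%04d", i)
    res <- try({
      track <- simulate_dsb_track(dp, t_end + 1, seed = seeds[i])
      p_i <- params
      p_i$wip1_scale <- params$wip1_scale * rates[i]
      traj <- simulate_cell(track, p_i, t_end = t_end, sample_dt = sample_dt)
      pl <- detect_pulses(
        tibble::tibble(cell_id = cid, time_h = traj$time_h,
                       value = traj$p53),
        min_amplitude = min_amplitude)
      list(track = track, traj = traj, pulses = pl)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("cell ", cid, " (seed ", seeds[i], ") failed and was excluded: ",
              attr(res, "condition")$message)
      next
    }
    pl <- res$pulses
    pt <- sort(pl$peak_time_h)
    ipis <- diff(pt)
    cells[[i]] <- tibble::tibble(
      cell_id = cid, seed = seeds[i], wip1_rate = rates[i],
      max_dsb = max(res$track$total), n_pulses = nrow(pl),
      responder = any(pl$peak_time_h <= responder_window),
      first_ipi = if (length(ipis)) ipis[1L] else NA_real_,
      last_ipi = if (length(ipis)) ipis[length(ipis)] else NA_real_
    )
    pulses[[i]] <- pl
    if (keep_trajectories) {
      trajs[[i]] <- tibble::add_column(res$traj, cell_id = cid, .before = 1)
    }
  }

  cells <- dplyr::bind_rows(cells)
  pulses <- dplyr::bind_rows(pulses)
  structure(list(
    cells = cells,
    pulses = pulses,
    ipis = compute_ipis(pulses),
    trajectories = if (keep_trajectories) dplyr::bind_rows(trajs) else NULL,
    config = list(n_cells = n_cells, N_s = N_s, meanlog = meanlog,
                  sdlog = sdlog, t_end = t_end, sample_dt = sample_dt,
                  seed = seed, min_amplitude = min_amplitude,
                  responder_window = responder_window)
  ), class = "p53_ensemble")
}

#' @export
print.p53_ensemble <- function(x, ...) {
  cat(sprintf("<p53_ensemble: %d cells, dose N_s = %g, seed %d>\n",
              nrow(x$cells), x$config$N_s, x$config$seed))
  cat(sprintf("  responders (first %g h): %.0f%%; median pulses/cell: %g\n",
              x$config$responder_window, 100 * mean(x$cells$responder),
              stats::median(x$cells$n_pulses)))
  if (length(x$ipis$all)) {
    cat(sprintf("  pooled IPIs: n = %d, median = %.2f h\n",
                length(x$ipis$all), stats::median(x$ipis$all)))
  }
  invisible(x)
}

#' @describeIn run_ensemble per-cell summary table.
#' @param x a `p53_ensemble`.
#' @param ... unused.
#' @export
tidy.p53_ensemble <- function(x, ...) x$cells

#' @describeIn run_ensemble one-row population summary.
#' @export
glance.p53_ensemble <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells), N_s = x$config$N_s,
    responder_fraction = mean(x$cells$responder),
    median_pulses = stats::median(x$cells$n_pulses),
    median_ipi_h = if (length(x$ipis$all)) stats::median(x$ipis$all) else NA_real_,
    seed = x$config$seed
  )
}

#' Pulse probability over the dose-by-Wip1 plane
#'
#' Simulates small cohorts of cells at fixed (dose, Wip1 production rate)
#' combinations and reports the probability of a p53 pulse within the first
#' six hours, mapping the responsive and unresponsive regions of the
#' DSB-Wip1 plane.
#'
#' @param ns_grid doses (target maximal inflicted DSBs).
#' @param wip1_grid Wip1 production-rate multipliers.
#' @param n_per_bin cells per grid point.
#' @param params,dsb_params model and DSB process parameters.
#' @param seed root seed.
#' @param ... further arguments passed to [run_ensemble()].
#' @return A tibble (`N_s`, `wip1_rate`, `p_pulse`, `n`) of class
#'   `responsiveness_map`.
#' @export
responsiveness_map <- function(ns_grid, wip1_grid, n_per_bin = 10,
                               params = p53_params(),
                               dsb_params = p53dyn::dsb_params(), seed = 1,
                               ...) {
  combos <- expand.grid(N_s = ns_grid, wip1_rate = wip1_grid)
  seeds <- derive_seeds(seed, nrow(combos))
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    p_k <- params
    p_k$wip1_scale <- params$wip1_scale * combos$wip1_rate[k]
    ens <- run_ensemble(n_per_bin, N_s = combos$N_s[k], params = p_k,
                        dsb_params = dsb_params, sdlog = 0,
                        seed = seeds[k], ...)
    n_ok <- nrow(ens$cells)
    tibble::tibble(N_s = combos$N_s[k], wip1_rate = combos$wip1_rate[k],
                   p_pulse = if (n_ok) mean(ens$cells$responder) else NA_real_,
                   n = n_ok)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("responsiveness_map", class(out)))
}

#' Fixed-dose population experiment
#'
#' Emulates treating a heterogeneous population with one dose of a damaging
#' agent: Wip1 production rates are sampled from the lognormal law, DSB
#' dynamics are simulated per cell, and the population responder fraction is
#' the share of cells pulsing within the first six hours.
#'
#' @inheritParams run_ensemble
#' @param dose target maximal number of inflicted DSBs.
#' @return A list with `cells` (per-cell tibble: `max_dsb`, `wip1_rate`,
#'   `responder`, ...), `responder_fraction`, and the underlying
#'   `p53_ensemble`.
#' @export
dose_experiment <- function(dose, n_cells = 100, params = p53_params(),
                            meanlog = 0, sdlog = 0.49, seed = 1, ...) {
  stopifnot(dose >= 0)
  ens <- run_ensemble(n_cells, N_s = dose, params = params,
                      meanlog = meanlog, sdlog = sdlog, seed = seed, ...)
  list(cells = ens$cells,
       responder_fraction = mean(ens$cells$responder),
       ensemble = ens)
}

#' Local sensitivity of model outputs to parameters
#'
#' Central-difference relative sensitivities
#' `S = (f(p(1+delta)) - f(p(1-delta))) / (2 delta f(p))` of selected model
#' outputs with respect to individual rate constants.
#'
#' Outputs: `"threshold"` -- the critical ATM* kick size at the basal rest
#' state (from [excitation_threshold()]); `"period"` and `"amplitude"` --
#' limit-cycle period and peak-to-trough p53 span under sustained damage.
#'
#' @param params a [p53_params()].
#' @param output which model output to differentiate.
#' @param delta relative perturbation (<= 0.2).
#' @param param_names parameters to scan; defaults to the main kinetic
#'   constants of all network arms.
#' @param dsb_level constant damage level for period/amplitude (oscillatory
#'   regime) evaluations.
#' @return A tibble (`parameter`, `sensitivity`, `rank`) sorted by absolute
#'   sensitivity; parameters where the output is undefined (left the
#'   excitable/oscillatory regime) carry `NA`.
#' @export
sensitivity_scan <- function(params = p53_params(),
                             output = c("threshold", "period", "amplitude"),
                             delta = 0.1, param_names = NULL,
                             dsb_level = 15) {
  output <- match.arg(output)
  stopifnot(delta >= 0, delta <= 0.2)
  if (is.null(param_names)) {
    param_names <- c("k_dsb", "d_A", "k4", "K5", "b_P", "k_ub",
                     "b_Wm", "k_TW", "k_trlW", "d_W", "d_Wm",
                     "k_TM", "k_trlM", "d_M")
  }
  f <- switch(output,
    threshold = function(p) {
      unname(mean(excitation_threshold(p, directions = "ATM_a")))
    },
    period = function(p) cycle_metrics(p, dsb_level)$period,
    amplitude = function(p) cycle_metrics(p, dsb_level)$amplitude
  )
  f0 <- f(params)
  if (delta == 0) {
    return(tibble::tibble(parameter = param_names, sensitivity = 0,
                          rank = seq_along(param_names)))
  }
  sens <- vapply(param_names, function(nm) {
    out <- try({
      pp <- params; pp[[nm]] <- params[[nm]] * (1 + delta)
      pm <- params; pm[[nm]] <- params[[nm]] * (1 - delta)
      (f(pp) - f(pm)) / (2 * delta * f0)
    }, silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) NA_real_ else out
  }, numeric(1))
  out <- tibble::tibble(parameter = param_names, sensitivity = unname(sens))
  out <- out[order(-abs(out$sensitivity)), ]
  out$rank <- seq_len(nrow(out))
  out
}

# limit-cycle period and amplitude at a constant damage level
cycle_metrics <- function(params, dsb_level, t_end = 80) {
  rest <- suppressWarnings(p53_rest_state(params, 2))
  st <- rest; st[["ATM_a"]] <- 0.9
  sim <- integrate_const_dsb(st, params, dsb_level, t_end)
  late <- sim[sim$time_h > 0.4 * t_end, ]
  pk <- series_peak_times(late$time_h, late$p53)
  if (length(pk) < 3L || diff(range(late$p53)) < 0.5) {
    stop("no sustained oscillation at this damage level", call. = FALSE)
  }
  list(period = mean(utils::tail(diff(pk), 5L)),
       amplitude = diff(range(late$p53)))
}
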