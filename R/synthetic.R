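#' Specify a ground-truth pulse train
#'
#' @param peak_times pulse peak times, hours (sorted internally).
#' @param amplitudes pulse amplitudes above baseline (recycled).
#' @param widths pulse FWHM in hours (recycled).
#' @param baseline constant baseline level.
#' @param shape pulse kernel: symmetric `"gaussian"` or `"gamma"` (skewed,
#'   slower decay than rise, as real p53 pulses are).
#' @return An object of class `pulse_train_spec`.
#' @export
pulse_train_spec <- function(peak_times, amplitudes = 1, widths = 2,
                             baseline = 0.1,
                             shape = c("gaussian", "gamma")) {
  shape <- match.arg(shape)
  n <- length(peak_times)
  amplitudes <- rep_len(amplitudes, n)
  widths <- rep_len(widths, n)
  stopifnot(all(amplitudes > 0), all(widths > 0))
  ord <- order(peak_times)
  structure(list(peak_times = peak_times[ord], amplitudes = amplitudes[ord],
                 widths = widths[ord], baseline = baseline, shape = shape),
            class = "pulse_train_spec")
}

# unit-peak kernels parameterized by peak position and FWHM
pulse_kernel <- function(t, peak, fwhm, shape) {
  if (shape == "gaussian") {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    exp(-(t - peak)^2 / (2 * s^2))
  } else {
    # gamma-shaped (k = 3) kernel, mode aligned to `peak`, unit peak height;
    # scale chosen so the FWHM matches (FWHM of gamma(k=3) ~ 3.3302 * theta)
    k <- 3
    theta <- fwhm / 3.3302
    u <- t - peak + (k - 1) * theta      # mode at (k-1) * theta
    y <- ifelse(u > 0, (u / ((k - 1) * theta))^(k - 1) *
                  exp(-(u - (k - 1) * theta) / theta), 0)
    y
  }
}

#' Build a synthetic pulse-train trajectory
#'
#' Superimposes shape kernels on a constant baseline and returns both the
#' trajectory and the ground-truth pulse table, so detectors can be scored
#' against known answers.
#'
#' @param spec a [pulse_train_spec()].
#' @param times sampling grid, hours.
#' @param cell_id cell identifier for the output tibble.
#' @return A tibble (`cell_id`, `time_h`, `value`) with the true pulse table
#'   attached as attribute `"truth"` (columns `peak_time_h`, `amplitude`,
#'   `width_h`).
#' @examples
#' tr <- make_pulse_train(pulse_train_spec(c(5, 10, 15)), seq(0, 20, 0.25))
#' attr(tr, "truth")
#' @export
make_pulse_train <- function(spec, times, cell_id = "cell_1") {
  stopifnot(inherits(spec, "pulse_train_spec"))
  v <- rep(spec$baseline, length(times))
  for (i in seq_along(spec$peak_times)) {
    v <- v + spec$amplitudes[i] *
      pulse_kernel(times, spec$peak_times[i], spec$widths[i], spec$shape)
  }
  if (any(v < 0)) {
    warning("negative trajectory values clipped to zero")
    v <- pmax(v, 0)
  }
  out <- tibble::tibble(cell_id = cell_id, time_h = times, value = v)
  attr(out, "truth") <- tibble::tibble(
    cell_id = cell_id,
    peak_time_h = spec$peak_times,
    amplitude = spec$amplitudes,
    width_h = spec$widths
  )
  out
}

#' Microscopy noise model
#'
#' @param additive_sigma SD of additive Gaussian noise, value units.
#' @param multiplicative_cv CV of multiplicative Gaussian noise.
#' @param sampling_dt imaging interval, hours (15--20 min in typical
#'   live-cell experiments).
#' @param duration recording length, hours.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(additive_sigma = 0, multiplicative_cv = 0,
                        sampling_dt = 1 / 3, duration = 48) {
  stopifnot(additive_sigma >= 0, multiplicative_cv >= 0,
            sampling_dt > 0, duration > 0)
  structure(list(additive_sigma = additive_sigma,
                 multiplicative_cv = multiplicative_cv,
                 sampling_dt = sampling_dt, duration = duration),
            class = "noise_model")
}

#' Emulate a live-cell microscopy recording of a trajectory
#'
#' Resamples the trajectory at the imaging interval over the recording
#' duration and applies multiplicative and additive Gaussian noise:
#' `value * (1 + eps_m) + eps_a`.
#'
#' @param traj trajectory tibble (`time_h`, `value`, optional `cell_id`).
#' @param noise a [noise_model()].
#' @param seed optional integer seed.
#' @return A trajectory tibble sampled at `floor(duration / sampling_dt) + 1`
#'   time points per cell.
#' @export
emulate_microscopy <- function(traj, noise = noise_model(), seed = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  if (!"cell_id" %in% names(traj)) traj$cell_id <- "cell_1"
  grid <- seq(0, noise$duration, by = noise$sampling_dt)
  out <- lapply(split(traj, traj$cell_id), function(d) {
    v <- stats::approx(d$time_h, d$value, xout = grid, rule = 2,
                       ties = "ordered")$y
    eps_m <- stats::rnorm(length(grid), 0, noise$multiplicative_cv)
    eps_a <- stats::rnorm(length(grid), 0, noise$additive_sigma)
    tibble::tibble(cell_id = d$cell_id[1L], time_h = grid,
                   value = v * (1 + eps_m) + eps_a)
  })
  dplyr::bind_rows(out)
}

#' Generate synthetic foci-count tracks
#'
#' Wraps [simulate_dsb_track()]: simulates `n_cells` independent DSB
#' realizations, samples the counts at imaging times and optionally applies
#' binomial detection noise (each focus seen with probability
#' `detection_p`). The exact underlying tracks are returned alongside so
#' estimators can be scored against the generating truth.
#'
#' @param params a [dsb_params()].
#' @param n_cells number of cells.
#' @param t_end recording length, hours.
#' @param sample_dt imaging interval, hours.
#' @param detection_p per-focus detection probability (1 = noise off).
#' @param init initial `c(idsb, cdsb)` state for every cell.
#' @param seed root seed; per-cell seeds are derived deterministically.
#' @return A list with `observed` (tidy tibble `cell_id`, `time_h`, `count`)
#'   and `tracks` (list of `dsb_track`).
#' @export
make_foci_tracks <- function(params, n_cells, t_end = 48, sample_dt = 1 / 3,
                             detection_p = 0.9, init = c(0L, 0L),
                             seed = NULL) {
  stopifnot(n_cells >= 1, detection_p > 0, detection_p <= 1)
  seeds <- derive_seeds(seed, n_cells)
  grid <- seq(0, t_end, by = sample_dt)
  tracks <- vector("list", n_cells)
  obs <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    tr <- simulate_dsb_track(params, t_end, init = init, seed = seeds[i])
    cnt <- dsb_count_at(tr, grid)
    if (detection_p < 1) {
      cnt <- stats::rbinom(length(cnt), size = as.integer(cnt),
                           prob = detection_p)
    }
    tracks[[i]] <- tr
    obs[[i]] <- tibble::tibble(cell_id = sprintf("cell_%03d", i),
                               time_h = grid, count = cnt)
  }
  list(observed = dplyr::bind_rows(obs), tracks = tracks)
}

# one root seed -> deterministic per-unit child seeds (31-bit)
derive_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
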