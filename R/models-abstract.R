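# --- generic feedback toy models and the numerical bifurcation engine -----

#' Construct an abstract feedback model
#'
#' Two minimal signal-response circuits used to reason about pulse
#' generation:
#'
#' * `"NF"` -- pure negative feedback: the input signal `s` drives
#'   production of the response species `x`, which (through the
#'   intermediate `y`) induces the repressor `z` closing a delayed negative
#'   loop. Such circuits enter and leave their oscillatory regime through
#'   supercritical Hopf bifurcations: oscillation amplitudes grow from zero
#'   and the response to transient inputs is graded.
#' * `"NPF"` -- negative plus positive feedback: `x` additionally activates
#'   its own production through a sigmoidal self-interaction, while the slow
#'   inhibitor `y` provides the negative loop. This makes the system
#'   excitable (type I): transient inputs trigger all-or-none pulses and the
#'   oscillatory regime is entered with finite amplitude and diverging
#'   period (saddle-homoclinic/SNIC onset).
#'
#' @param name `"NF"` or `"NPF"`.
#' @param params optional named list overriding individual rate constants.
#' @return An object of class `dyn_model`: list with `name`, `species`,
#'   `readout` (the pulse-carrying species), `params`, and the vector field
#'   `rhs(t, x, s, params)` where `s` is the instantaneous signal.
#' @export
abstract_model <- function(name = c("NF", "NPF"), params = list()) {
  name <- match.arg(name)
  if (name == "NF") {
    # delayed repression with a small repression-independent leak: the leak
    # dominates production at high input, quenching the loop gain, so the
    # oscillatory regime is closed by a second Hopf at high signal
    p <- list(v = 5, b0 = 0.04, Kz = 0.2, h = 9, d_x = 1, k_y = 1, k_z = 1)
    p[names(params)] <- params
    m <- list(
      name = "NF",
      species = c("x", "y", "z"),
      readout = "x",
      feedback_param = "v",
      params = p,
      rhs = function(t, x, s, p) {
        c(s * (p$b0 + p$v / (1 + (x[3] / p$Kz)^p$h)) - p$d_x * x[1],
          p$k_y * (x[1] - x[2]),
          p$k_z * (x[2] - x[3]))
      }
    )
  } else {
    # cubic autocatalytic activator (positive self-interaction with an
    # activation threshold at x = a) under a slow inhibitor whose sigmoidal
    # activation saturates below the upper knee of the cubic: the rest state
    # is lost through a saddle-node on the pulse loop, so oscillations are
    # born at full amplitude with diverging period (type I excitability)
    p <- list(c = 4, a = 0.15, ymax = 0.6, Kx = 0.45, h = 6, eps = 0.2)
    p[names(params)] <- params
    m <- list(
      name = "NPF",
      species = c("x", "y"),
      readout = "x",
      feedback_param = "c",
      params = p,
      rhs = function(t, x, s, p) {
        yinf <- p$ymax * x[1]^p$h / (p$Kx^p$h + x[1]^p$h)
        c(p$c * x[1] * (x[1] - p$a) * (1 - x[1]) - x[2] + s,
          p$eps * (yinf - x[2]))
      }
    )
  }
  structure(m, class = "dyn_model")
}

#' @export
print.dyn_model <- function(x, ...) {
  cat(sprintf("<dyn_model %s: %d species (%s), readout %s>\n",
              x$name, length(x$species), paste(x$species, collapse = ", "),
              x$readout))
  invisible(x)
}

#' Stimulus protocols
#'
#' @param kind `"transient"` (rectangular input of given duration),
#'   `"sustained"` (step that stays on), or `"decaying"` (exponential decay
#'   from the onset value).
#' @param strength signal amplitude at onset (>= 0).
#' @param onset time the stimulus starts, hours.
#' @param duration duration of a transient stimulus, hours.
#' @param half_life half-life of a decaying stimulus, hours.
#' @return An object of class `stimulus_protocol`; calling
#'   [signal_at()] evaluates it at arbitrary times.
#' @export
stimulus_protocol <- function(kind = c("transient", "sustained", "decaying"),
                              strength = 1, onset = 0, duration = 1,
                              half_life = 10) {
  kind <- match.arg(kind)
  stopifnot(strength >= 0, onset >= 0)
  if (kind == "transient") stopifnot(duration > 0)
  if (kind == "decaying") stopifnot(half_life > 0)
  structure(list(kind = kind, strength = strength, onset = onset,
                 duration = duration, half_life = half_life),
            class = "stimulus_protocol")
}

#' Evaluate a stimulus protocol
#' @param protocol a [stimulus_protocol()].
#' @param t times, hours.
#' @return Signal values at `t`.
#' @export
signal_at <- function(protocol, t) {
  with(protocol, switch(kind,
    transient = ifelse(t >= onset & t < onset + duration, strength, 0),
    sustained = ifelse(t >= onset, strength, 0),
    decaying = ifelse(t >= onset,
                      strength * 2^(-(t - onset) / half_life), 0)
  ))
}

# --- rest states -----------------------------------------------------------

# Newton iteration with numerical Jacobian, preceded by relaxation
find_rest_state <- function(rhs, x0, t_relax = 500, tol = 1e-10,
                            max_iter = 50L, strict = TRUE) {
  # relax first so Newton starts in the right basin (transients near an
  # oscillatory regime can be long). The relaxation runs at moderate
  # tolerance; the Newton polish below supplies the final precision.
  sol <- suppressWarnings(
    deSolve::lsoda(y = x0, times = c(0, t_relax),
                   func = function(t, x, p) list(rhs(t, x)),
                   parms = NULL, rtol = 1e-7, atol = 1e-9,
                   maxsteps = 50000))
  x <- as.numeric(sol[nrow(sol), -1])
  f <- rhs(0, x)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(f^2)) < tol) break
    J <- num_jacobian(function(z) rhs(0, z), x)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) break
    x_new <- x - step
    x_new[x_new < 0 & x_new > -1e-12] <- 0
    f_new <- rhs(0, x_new)
    if (!all(is.finite(f_new))) break
    x <- x_new; f <- f_new
  }
  if (sqrt(sum(f^2)) > 1e-6) {
    if (strict) {
      stop("rest-state search did not converge (residual ",
           format(sqrt(sum(f^2))), ")", call. = FALSE)
    }
    # no stable rest state (e.g. spontaneously pulsing cell): return the
    # relaxed endpoint as a usable initial condition
    x <- as.numeric(sol[nrow(sol), -1])
  }
  x
}

num_jacobian <- function(f, x, h = 1e-7) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    dx <- h * max(abs(x[j]), 1)
    xp <- x; xp[j] <- xp[j] + dx
    J[, j] <- (f(xp) - f0) / dx
  }
  J
}

#' Rest state of an abstract model
#'
#' @param model a [abstract_model()].
#' @param s constant signal level (default 0).
#' @return Named numeric vector of steady-state concentrations.
#' @export
model_rest_state <- function(model, s = 0) {
  rhs <- function(t, x) model$rhs(t, x, s, model$params)
  x <- find_rest_state(rhs, x0 = rep(0.01, length(model$species)))
  stats::setNames(x, model$species)
}

# --- simulation ------------------------------------------------------------

#' Simulate an abstract model under a stimulus protocol
#'
#' Integrates the model from its unstimulated rest state (or a supplied
#' initial state) with a tolerance-controlled stiff-capable solver.
#'
#' @param model a [abstract_model()].
#' @param protocol a [stimulus_protocol()] (or a single number, shorthand
#'   for a sustained signal of that strength).
#' @param t_end end time, hours.
#' @param dt output sampling interval, hours.
#' @param x0 initial state; default is the `s = 0` rest state.
#' @param signal_scale optional function of time multiplying the signal
#'   (used for inhibition experiments); default none.
#' @param param_scale optional function `(t, params) -> params` applied at
#'   each evaluation (used for species/feedback inhibition).
#' @return A tibble with `time_h`, one column per species, and `signal`.
#' @export
simulate_model <- function(model, protocol, t_end = 100, dt = 0.05,
                           x0 = NULL, signal_scale = NULL,
                           param_scale = NULL) {
  if (is.numeric(protocol)) {
    protocol <- stimulus_protocol("sustained", strength = protocol)
  }
  if (is.null(x0)) x0 <- model_rest_state(model)
  times <- seq(0, t_end, by = dt)
  func <- function(t, x, p) {
    s <- signal_at(protocol, t)
    if (!is.null(signal_scale)) s <- s * signal_scale(t)
    pp <- if (!is.null(param_scale)) param_scale(t, model$params) else model$params
    list(model$rhs(t, x, s, pp))
  }
  sol <- deSolve::lsoda(y = stats::setNames(as.numeric(x0), model$species),
                        times = times, func = func, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "time_h"
  out$signal <- signal_at(protocol, out$time_h)
  out
}

# --- oscillation detection and the bifurcation scan ------------------------

# peak times of a sampled series by local quadratic interpolation;
# `min_height` (fraction of the series span above the minimum) suppresses
# numerical ripples
series_peak_times <- function(t, y, min_height = 0.2) {
  n <- length(y)
  if (n < 3L) return(numeric())
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  idx <- idx[idx > 1L & idx < n]
  if (min_height > 0 && length(idx)) {
    idx <- idx[(y[idx] - min(y)) >= min_height * diff(range(y))]
  }
  vapply(idx, function(i) {
    # vertex of the parabola through the three points around the maximum
    denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
    if (denom == 0) return(t[i])
    t[i] + 0.5 * (y[i - 1L] - y[i + 1L]) / denom * (t[i] - t[i - 1L])
  }, numeric(1))
}

# oscillation metrics on the post-transient window of one readout series
oscillation_metrics <- function(t, y, rest_scale, transient_frac = 0.4,
                                rel_tol = 0.01) {
  keep <- t >= transient_frac * max(t)
  tt <- t[keep]; yy <- y[keep]
  span <- diff(range(yy))
  osc <- is.finite(span) && span > rel_tol * max(abs(rest_scale), 1e-8)
  if (!osc) {
    return(list(oscillating = FALSE, amplitude = 0, period = NA_real_))
  }
  pk <- series_peak_times(tt, yy)
  # only count full-size peaks (exclude numerical ripples)
  if (length(pk) >= 2L) {
    ipis <- diff(pk)
    period <- mean(utils::tail(ipis, 5L))
  } else {
    period <- NA_real_
    osc <- FALSE  # no repeated peaks -> not sustained oscillation
  }
  list(oscillating = osc, amplitude = span, period = period)
}

#' Numerical bifurcation scan
#'
#' Classifies the long-run behavior of a model at each value of a scanned
#' constant input: integrate for `t_end`, discard the initial transient
#' (first 40% of the run), and call the point oscillating when the
#' post-transient peak-to-trough span of the readout exceeds 1% of the
#' rest-state magnitude and at least two maxima recur. Amplitude is the
#' post-transient span; the period is the mean spacing of the last (up to
#' five) readout maxima, located by local quadratic interpolation.
#'
#' @param model a [abstract_model()] (or any `dyn_model`).
#' @param grid values of the constant input signal to scan.
#' @param t_end integration time per grid point, hours.
#' @param dt output sampling interval, hours.
#' @param perturb small kick (fraction of rest magnitude, applied to the
#'   readout) so that unstable rest states reveal their limit cycle.
#' @return A tibble of class `scan_result`: `parameter`, `oscillating`,
#'   `amplitude`, `period` (NA where not oscillating).
#' @export
bifurcation_scan <- function(model, grid, t_end = 300, dt = 0.05,
                             perturb = 0.02) {
  rest0 <- try(model_rest_state(model), silent = TRUE)
  if (inherits(rest0, "try-error")) rest0 <- rep(0.1, length(model$species))
  rest_scale <- max(sqrt(sum(rest0^2)), 0.05)
  rows <- lapply(grid, function(s) {
    res <- try({
      x0 <- rest0
      x0[model$readout] <- x0[model$readout] + perturb * rest_scale + 1e-4
      sim <- simulate_model(model, s, t_end = t_end, dt = dt, x0 = x0)
      m <- oscillation_metrics(sim$time_h, sim[[model$readout]], rest_scale)
      tibble::tibble(parameter = s, oscillating = m$oscillating,
                     amplitude = if (m$oscillating) m$amplitude else 0,
                     period = if (m$oscillating) m$period else NA_real_,
                     failed = FALSE)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      tibble::tibble(parameter = s, oscillating = NA, amplitude = NA_real_,
                     period = NA_real_, failed = TRUE)
    } else res
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("scan_result", class(out)))
}

#' Classify an oscillation onset
#'
#' Distinguishes the two generic routes into an oscillatory regime from a
#' numerical scan: at a (supercritical) Hopf bifurcation the limit-cycle
#' amplitude grows from zero while the period stays bounded; at a
#' saddle-homoclinic/SNIC onset (type I excitability) oscillations appear
#' with finite amplitude while the period diverges. The rule applied to the
#' scan: if the period at the oscillating point nearest the onset exceeds
#' twice the mid-regime period, the onset is `"homoclinic_like"`; otherwise
#' `"hopf_like"`.
#'
#' @param scan a `scan_result` from [bifurcation_scan()] (or a tibble with
#'   `parameter`, `oscillating`, `amplitude`, `period`).
#' @param onset which onset to classify when the oscillatory regime has two
#'   boundaries: `"lower"` (default) or `"upper"`.
#' @return `"hopf_like"` or `"homoclinic_like"`, with attributes
#'   `period_near`, `period_mid`, `amplitude_near`, `amplitude_mid`.
#' @export
classify_onset <- function(scan, onset = c("lower", "upper")) {
  onset <- match.arg(onset)
  sc <- scan[!is.na(scan$oscillating), ]
  sc <- sc[order(sc$parameter), ]
  osc_idx <- which(sc$oscillating)
  if (!length(osc_idx) || length(osc_idx) == nrow(sc)) {
    stop("scan does not bracket an oscillation onset", call. = FALSE)
  }
  near_i <- if (onset == "lower") osc_idx[1L] else osc_idx[length(osc_idx)]
  if (onset == "lower" && near_i == 1L ||
      onset == "upper" && near_i == nrow(sc)) {
    stop("requested onset is not bracketed by the scan grid", call. = FALSE)
  }
  # mid-regime reference: the oscillating point nearest the centre of the
  # oscillatory parameter range (robust to grids clustered near the onset)
  prange <- range(sc$parameter[osc_idx])
  mid_i <- osc_idx[which.min(abs(sc$parameter[osc_idx] - mean(prange)))]
  period_near <- sc$period[near_i]
  period_mid <- sc$period[mid_i]
  verdict <- if (is.finite(period_near) && is.finite(period_mid) &&
                 period_near > 2 * period_mid) {
    "homoclinic_like"
  } else "hopf_like"
  structure(verdict,
            period_near = period_near, period_mid = period_mid,
            amplitude_near = sc$amplitude[near_i],
            amplitude_mid = sc$amplitude[mid_i])
}

#' Peak response amplitude versus stimulus strength
#'
#' Applies transient stimuli of increasing strength from rest and records
#' the peak readout deflection. For excitable (NPF-type) models the curve is
#' a step; the detected threshold is reported as the midpoint of the
#' bracketing strengths.
#'
#' @param model a [abstract_model()].
#' @param strengths ascending grid of stimulus strengths.
#' @param duration transient stimulus duration, hours.
#' @param t_end simulation length per stimulus, hours.
#' @return A tibble of class `response_curve` with `strength`, `amplitude`;
#'   attributes `threshold` and `threshold_bracket` (NA for graded models
#'   without an all-or-none jump).
#' @export
response_curve <- function(model, strengths, duration = 1, t_end = 60) {
  stopifnot(!is.unsorted(strengths))
  rest <- model_rest_state(model)
  amp <- vapply(strengths, function(s) {
    if (s == 0) return(0)
    sim <- simulate_model(
      model, stimulus_protocol("transient", strength = s,
                               duration = duration),
      t_end = t_end, x0 = rest)
    max(sim[[model$readout]]) - rest[[model$readout]]
  }, numeric(1))
  out <- tibble::tibble(strength = strengths, amplitude = amp)
  # all-or-none jump: largest relative gap between consecutive amplitudes
  thr <- NA_real_; bracket <- c(NA_real_, NA_real_)
  if (length(amp) > 2L) {
    jumps <- diff(amp)
    k <- which.max(jumps)
    if (max(amp) > 0 && jumps[k] > 0.5 * max(amp)) {
      bracket <- c(strengths[k], strengths[k + 1L])
      thr <- mean(bracket)
    }
  }
  structure(out, class = c("response_curve", class(out)),
            threshold = thr, threshold_bracket = bracket)
}

#' Timed-inhibition experiment on an excitable model
#'
#' Applies a suprathreshold transient stimulus and, at `t_inhibit`, scales
#' either the activating signal or the self-activating species' positive
#' feedback by `factor`. Signal inhibition after the excitation loop has
#' fired does not change the all-or-none outcome, whereas inhibiting the
#' feedback species itself truncates the pulse in a graded,
#' inhibition-time-dependent way.
#'
#' @param model an NPF-type [abstract_model()].
#' @param target `"signal"` or `"species_x"`.
#' @param t_inhibit inhibition times, hours.
#' @param factor multiplicative inhibition factor in `[0, 1]`.
#' @param strength stimulus strength (must be suprathreshold).
#' @param duration stimulus duration, hours.
#' @param t_end simulation length, hours.
#' @return A tibble with `t_inhibit` and pulse `amplitude`.
#' @export
inhibition_experiment <- function(model, target = c("signal", "species_x"),
                                  t_inhibit, factor = 0.05, strength = 0.5,
                                  duration = 1, t_end = 40) {
  target <- match.arg(target)
  stopifnot(factor >= 0, factor <= 1)
  if (any(t_inhibit > t_end)) {
    stop("t_inhibit beyond the simulation end", call. = FALSE)
  }
  rest <- model_rest_state(model)
  # the rate constant carrying the positive self-interaction
  fb <- if (!is.null(model$feedback_param)) model$feedback_param else "c"
  protocol <- stimulus_protocol("transient", strength = strength,
                                duration = duration)
  amp <- vapply(t_inhibit, function(ti) {
    if (target == "signal") {
      sim <- simulate_model(model, protocol, t_end = t_end, x0 = rest,
                            signal_scale = function(t) {
                              ifelse(t >= ti, factor, 1)
                            })
    } else {
      sim <- simulate_model(model, protocol, t_end = t_end, x0 = rest,
                            param_scale = function(t, p) {
                              if (t >= ti) p[[fb]] <- p[[fb]] * factor
                              p
                            })
    }
    max(sim[[model$readout]]) - rest[[model$readout]]
  }, numeric(1))
  tibble::tibble(t_inhibit = t_inhibit, amplitude = amp)
}
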