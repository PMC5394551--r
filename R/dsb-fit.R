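# --- rate estimation from foci-count tracks -------------------------------
#
# Basal mode exploits two stationary properties of the immigration-death
# (M/M/inf) count process: the stationary mean is b/r and the stationary
# autocovariance decays as m * exp(-r * lag). Decay mode fits the closed-form
# ensemble-mean decay (N_s - N_b) exp(-r t) + N_b by nonlinear least squares.

# coerce tracks (list of dsb_track, or tidy tibble cell_id/time_h/count) to a
# cells x grid count matrix
resample_tracks <- function(tracks, grid, column = "total") {
  if (inherits(tracks, "data.frame")) {
    cn <- if (column %in% names(tracks)) column else "count"
    stopifnot(all(c("cell_id", "time_h") %in% names(tracks)),
              cn %in% names(tracks))
    split_tr <- split(tracks, tracks$cell_id)
    mat <- vapply(split_tr, function(d) {
      stats::approx(d$time_h, d[[cn]], xout = grid, rule = 2,
                    ties = "ordered")$y
    }, numeric(length(grid)))
  } else {
    stopifnot(is.list(tracks))
    mat <- vapply(tracks, function(tr) dsb_count_at(tr, grid, column),
                  numeric(length(grid)))
  }
  t(mat)  # one row per cell
}

track_spans <- function(tracks) {
  if (inherits(tracks, "data.frame")) {
    vapply(split(tracks$time_h, tracks$cell_id),
           function(t) diff(range(t)), numeric(1))
  } else {
    vapply(tracks, function(tr) diff(range(tr$time_h)), numeric(1))
  }
}

# point estimate (b, r) from a stationary count matrix. The stationary
# autocovariance of the immigration-death count process is c(k) =
# m * exp(-r * k * dt), so the ratio c(2)/c(1) = exp(-r * dt) identifies r
# without using the lag-0 variance; this makes the estimator insensitive to
# white observation noise (e.g. per-focus detection errors), which inflates
# c(0) but leaves c(k >= 1) proportionally scaled.
basal_point_estimate <- function(mat, dt, max_lag) {
  m_hat <- mean(mat)
  grand <- m_hat
  n <- ncol(mat)
  pooled_cov <- function(k) {
    a <- mat[, seq_len(n - k), drop = FALSE] - grand
    b <- mat[, seq(k + 1L, n), drop = FALSE] - grand
    mean(a * b)
  }
  c1 <- pooled_cov(1L); c2 <- pooled_cov(2L)
  if (c1 <= 0 || c2 <= 0) stop("autocovariance too noisy to fit a decay rate",
                               call. = FALSE)
  r_hat <- -log(c2 / c1) / dt
  if (!is.finite(r_hat) || r_hat <= 0) {
    stop("autocovariance ratio gave a non-positive repair rate", call. = FALSE)
  }
  c(b = m_hat * r_hat, r = r_hat)
}

decay_point_estimate <- function(mat, grid) {
  mbar <- colMeans(mat)
  df <- data.frame(t = grid, y = mbar)
  nb0 <- max(mean(utils::tail(mbar, max(3L, length(mbar) %/% 10))), 1e-3)
  ns0 <- max(mbar[1L], nb0 * 2)
  span <- diff(range(grid))
  r0 <- log(max(ns0 / nb0, 2)) / max(span / 2, 1e-6)
  fit <- try(stats::nls(y ~ (Ns - Nb) * exp(-r * t) + Nb, data = df,
                        start = list(Ns = ns0, Nb = nb0, r = r0),
                        algorithm = "port",
                        lower = c(Ns = 0, Nb = 0, r = 1e-6)),
             silent = TRUE)
  if (inherits(fit, "try-error") && requireNamespace("minpack.lm", quietly = TRUE)) {
    fit <- minpack.lm::nlsLM(y ~ (Ns - Nb) * exp(-r * t) + Nb, data = df,
                             start = list(Ns = ns0, Nb = nb0, r = r0),
                             lower = c(0, 0, 1e-6))
  }
  if (inherits(fit, "try-error")) stop("decay-law fit failed", call. = FALSE)
  cf <- stats::coef(fit)
  c(b = unname(cf["Nb"] * cf["r"]), r = unname(cf["r"]),
    N_s = unname(cf["Ns"]), N_b = unname(cf["Nb"]))
}

#' Estimate break and repair rates from foci-count tracks
#'
#' Fits the birth--death model of DSB kinetics to a collection of observed
#' (or simulated) break-count tracks.
#'
#' In `"basal"` mode the tracks are assumed stationary: the repair rate is
#' the exponential decay rate of the pooled count autocovariance and the
#' break rate follows from the stationary mean (`mean = b/r`). In `"decay"`
#' mode the ensemble mean is fit by least squares to the mean-decay law
#' `(N_s - N_b) exp(-r t) + N_b`; a single noiseless mean curve is a valid
#' input in this mode.
#'
#' @param tracks a list of `dsb_track` objects, or a tidy tibble with
#'   columns `cell_id`, `time_h` and a count column (`total` or `count`).
#' @param mode `"basal"` or `"decay"`.
#' @param dt sampling interval (hours) used to put all tracks on a common
#'   grid before fitting.
#' @param max_lag_h largest autocovariance lag (hours) used in basal mode.
#' @param n_boot bootstrap replicates (over cells) for confidence intervals;
#'   0 disables the bootstrap.
#' @param conf_level bootstrap confidence level.
#' @return An object of class `dsb_fit` with point estimates `b_hat`,
#'   `r_hat` (and `N_s_hat`, `N_b_hat` in decay mode) plus percentile
#'   bootstrap intervals. Use [generics::tidy()] / [generics::glance()] for
#'   tabular summaries.
#' @examples
#' trks <- lapply(1:20, function(i)
#'   simulate_dsb_track(dsb_params(f_c = 0), t_end = 100, seed = i))
#' fit <- estimate_rates(trks, mode = "basal", n_boot = 0)
#' tidy(fit)
#' @export
estimate_rates <- function(tracks, mode = c("basal", "decay"), dt = 0.5,
                           max_lag_h = 10, n_boot = 200, conf_level = 0.95) {
  mode <- match.arg(mode)
  n_tracks <- if (inherits(tracks, "data.frame")) {
    length(unique(tracks$cell_id))
  } else length(tracks)
  if (mode == "basal" && n_tracks < 10L) {
    stop("basal-mode estimation needs at least 10 tracks", call. = FALSE)
  }
  spans <- track_spans(tracks)
  if (any(spans < 3 * dt)) {
    stop("tracks shorter than 3 sampling intervals are rejected", call. = FALSE)
  }
  span <- min(spans)
  grid <- seq(0, span, by = dt)
  mat <- resample_tracks(tracks, grid)

  if (mode == "basal") {
    max_lag <- max(3L, min(length(grid) - 2L, round(max_lag_h / dt)))
    est <- basal_point_estimate(mat, dt, max_lag)
    boot_fun <- function(idx) basal_point_estimate(mat[idx, , drop = FALSE],
                                                   dt, max_lag)
  } else {
    est <- decay_point_estimate(mat, grid)
    boot_fun <- function(idx) decay_point_estimate(mat[idx, , drop = FALSE],
                                                   grid)
  }

  ci <- NULL
  if (n_boot > 0 && n_tracks > 1L) {
    reps <- replicate(n_boot, {
      out <- try(boot_fun(sample.int(nrow(mat), replace = TRUE)), silent = TRUE)
      if (inherits(out, "try-error")) rep(NA_real_, length(est)) else out
    })
    a <- (1 - conf_level) / 2
    ci <- apply(reps, 1L, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  }

  structure(list(mode = mode, estimates = est, ci = ci,
                 n_tracks = n_tracks, dt = dt, span_h = span,
                 conf_level = conf_level),
            class = "dsb_fit")
}

#' @export
print.dsb_fit <- function(x, ...) {
  cat(sprintf("<dsb_fit: %s mode, %d tracks, %.1f h span>\n",
              x$mode, x$n_tracks, x$span_h))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn estimate_rates one row per fitted rate with bootstrap CI.
#' @param x a `dsb_fit` object.
#' @param ... unused.
#' @export
tidy.dsb_fit <- function(x, ...) {
  terms <- names(x$estimates)
  out <- tibble::tibble(term = terms, estimate = unname(x$estimates))
  if (!is.null(x$ci)) {
    out$conf.low <- x$ci[1L, terms]
    out$conf.high <- x$ci[2L, terms]
  }
  out
}

#' @describeIn estimate_rates one-row model-level summary.
#' @export
glance.dsb_fit <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_tracks = x$n_tracks, span_h = x$span_h,
                 b_hat = unname(x$estimates["b"]),
                 r_hat = unname(x$estimates["r"]))
}
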