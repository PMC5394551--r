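#' Detect pulses in single-cell trajectories
#'
#' Continuous-wavelet ridge-line pulse detection. Each trajectory is put on
#' a uniform grid (linear interpolation; segments separated by sampling gaps
#' longer than `gap_tol` samples are analyzed independently), its Ricker CWT
#' is computed over a log-spaced grid of scales, coefficient maxima are
#' linked across adjacent scales into ridge lines, and ridges are filtered
#' by minimum length and signal-to-noise ratio. One pulse is reported per
#' surviving ridge, located at the ridge's best scale.
#'
#' The SNR of a ridge is its largest CWT coefficient divided by a robust
#' noise level, the median absolute deviation of the coefficients at the
#' smallest scale.
#'
#' @param data a tibble with columns `time_h` and `value`, and optionally
#'   `cell_id` (pulses are then detected per cell).
#' @param scales wavelet scales in hours; default 10 log-spaced values
#'   spanning plausible pulse widths (0.5--6 h).
#' @param snr_min minimum ridge signal-to-noise ratio.
#' @param min_ridge_len minimum number of scales a ridge must span.
#' @param gap_tol sampling gaps longer than this many median intervals split
#'   a trajectory into independently analyzed segments.
#' @param refine if `TRUE` (default), amplitudes and widths are refined with
#'   [refine_pulses()].
#' @param min_amplitude discard pulses whose (refined) amplitude falls below
#'   this value; useful on noiseless model output where the SNR criterion
#'   alone cannot separate full pulses from subthreshold ripples.
#' @return A tibble with one row per pulse: `cell_id`, `peak_time_h`,
#'   `amplitude`, `width_h` (FWHM), `detection_scale_h`, `snr`, `refined`.
#' @examples
#' tr <- make_pulse_train(pulse_train_spec(c(5, 10, 15)),
#'                        times = seq(0, 20, by = 0.25))
#' detect_pulses(tr)
#' @export
detect_pulses <- function(data, scales = default_scales(), snr_min = 3,
                          min_ridge_len = 3L, gap_tol = 3, refine = TRUE,
                          min_amplitude = 0) {
  stopifnot(all(c("time_h", "value") %in% names(data)))
  if (!"cell_id" %in% names(data)) data$cell_id <- "cell_1"
  res <- dplyr::bind_rows(lapply(split(data, data$cell_id), function(d) {
    p <- detect_pulses_one(d$time_h, d$value, scales, snr_min,
                           min_ridge_len, gap_tol)
    if (nrow(p)) p$cell_id <- d$cell_id[1L]
    p
  }))
  if (!nrow(res)) {
    res <- tibble::tibble(cell_id = character(), peak_time_h = numeric(),
                          amplitude = numeric(), width_h = numeric(),
                          detection_scale_h = numeric(), snr = numeric(),
                          refined = logical())
  }
  res <- dplyr::relocate(res, "cell_id")
  res <- dplyr::arrange(res, .data$cell_id, .data$peak_time_h)
  if (refine && nrow(res)) {
    res <- refine_pulses(data, res)
    res <- merge_close_pulses(res)
  }
  if (min_amplitude > 0) res <- res[res$amplitude >= min_amplitude, ]
  res
}

# refinement can pull two ridges onto the same maximum; keep the stronger
# of any pair of same-cell pulses closer than half the smaller width
merge_close_pulses <- function(res) {
  if (nrow(res) < 2L) return(res)
  res <- dplyr::arrange(res, .data$cell_id, .data$peak_time_h)
  drop <- logical(nrow(res))
  for (i in 2:nrow(res)) {
    if (res$cell_id[i] != res$cell_id[i - 1L] || drop[i - 1L]) next
    gap <- res$peak_time_h[i] - res$peak_time_h[i - 1L]
    if (gap < 0.5 * min(res$width_h[i], res$width_h[i - 1L])) {
      drop[if (res$amplitude[i] >= res$amplitude[i - 1L]) i - 1L else i] <- TRUE
    }
  }
  res[!drop, ]
}

default_scales <- function(from = 0.5, to = 6, n = 10L) {
  exp(seq(log(from), log(to), length.out = n))
}

detect_pulses_one <- function(times, values, scales, snr_min,
                              min_ridge_len, gap_tol) {
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  if (length(times) < 3L) return(empty_pulse_tbl())
  ord <- order(times)
  times <- times[ord]; values <- values[ord]
  dt <- stats::median(diff(times))
  # split at long sampling gaps
  gaps <- which(diff(times) > gap_tol * dt)
  seg_start <- c(1L, gaps + 1L)
  seg_end <- c(gaps, length(times))
  out <- list()
  for (s in seq_along(seg_start)) {
    idx <- seg_start[s]:seg_end[s]
    if (length(idx) < 5L) next
    tt <- times[idx]; vv <- values[idx]
    grid <- seq(tt[1L], tt[length(tt)], by = dt)
    x <- stats::approx(tt, vv, xout = grid, rule = 2, ties = "ordered")$y
    span <- grid[length(grid)] - grid[1L]
    sc <- scales[scales < span / 2]
    if (length(sc) < length(scales)) {
      warning("trajectory shorter than the largest scales; scale grid truncated")
    }
    if (length(sc) < min_ridge_len) next
    out[[length(out) + 1L]] <-
      pulses_from_cwt(x, grid, dt, sc, snr_min, min_ridge_len)
  }
  if (!length(out)) return(empty_pulse_tbl())
  dplyr::bind_rows(out)
}

pulses_from_cwt <- function(x, grid, dt, scales, snr_min, min_ridge_len) {
  cw <- cwt_ricker(x, dt, scales)
  noise <- stats::mad(cw[1L, ])
  if (noise <= 0) noise <- stats::sd(cw[1L, ])
  if (!is.finite(noise) || noise <= 0) noise <- .Machine$double.eps
  ridges <- link_ridges(cw, scales, dt)
  keep <- list()
  for (rd in ridges) {
    len <- length(rd$pos)
    if (len < min_ridge_len) next
    coefs <- cw[cbind(rd$scale_idx, rd$pos)]
    best <- which.max(coefs)
    snr <- coefs[best] / noise
    if (!is.finite(snr) || snr < snr_min) next
    j <- rd$scale_idx[best]; p <- rd$pos[best]
    keep[[length(keep) + 1L]] <- tibble::tibble(
      peak_time_h = grid[p],
      amplitude = max(x[max(1L, p - 1L):min(length(x), p + 1L)]) - min(x),
      width_h = 2.355 * scales[j],   # Gaussian-equivalent FWHM at this scale
      detection_scale_h = scales[j],
      snr = snr,
      refined = FALSE
    )
  }
  if (!length(keep)) return(empty_pulse_tbl())
  res <- dplyr::bind_rows(keep)
  # merge duplicate calls of the same peak (ridges closer than half a width)
  res <- dplyr::arrange(res, .data$peak_time_h)
  drop <- logical(nrow(res))
  if (nrow(res) > 1L) {
    for (i in 2:nrow(res)) {
      if (res$peak_time_h[i] - res$peak_time_h[i - 1L] <
          0.5 * min(res$detection_scale_h[i], res$detection_scale_h[i - 1L])) {
        drop[if (res$snr[i] >= res$snr[i - 1L]) i - 1L else i] <- TRUE
      }
    }
  }
  res[!drop, ]
}

empty_pulse_tbl <- function() {
  tibble::tibble(peak_time_h = numeric(), amplitude = numeric(),
                 width_h = numeric(), detection_scale_h = numeric(),
                 snr = numeric(), refined = logical())
}

#' Refine pulse amplitudes and widths with localized smoothing splines
#'
#' For every detected pulse a smoothing spline (smoothness chosen by
#' generalized cross-validation) is fitted to the trajectory in a window of
#' `window_factor` detection scales around the peak. The pulse amplitude is
#' the spline maximum minus the window baseline (the smaller of the spline
#' values at the two window edges) and the width is the full width at half
#' maximum of the baseline-subtracted spline. Windows with fewer than 7
#' samples are left unrefined (detection-scale width kept, `refined =
#' FALSE`); pulses whose refined amplitude is not positive are dropped.
#'
#' @param data trajectory tibble (`time_h`, `value`, optional `cell_id`).
#' @param pulses pulse tibble from [detect_pulses()].
#' @param window_factor half-window size in units of the detection scale.
#' @param spar optional fixed smoothing parameter passed to
#'   [stats::smooth.spline()]; default `NULL` uses GCV per window.
#' @return The pulse tibble with refined `amplitude`, `width_h`,
#'   `peak_time_h` and `refined` flags.
#' @export
refine_pulses <- function(data, pulses, window_factor = 1.5, spar = NULL) {
  if (!"cell_id" %in% names(data)) data$cell_id <- "cell_1"
  if (!nrow(pulses)) return(pulses)
  if (!"cell_id" %in% names(pulses)) pulses$cell_id <- "cell_1"
  by_cell <- split(data, data$cell_id)
  out <- vector("list", nrow(pulses))
  for (i in seq_len(nrow(pulses))) {
    pl <- pulses[i, ]
    d <- by_cell[[pl$cell_id]]
    out[[i]] <- refine_one_pulse(d$time_h, d$value, pl, window_factor, spar)
  }
  res <- dplyr::bind_rows(out)
  res[is.na(res$amplitude) | res$amplitude > 0, ]
}

refine_one_pulse <- function(times, values, pulse, window_factor, spar) {
  a <- pulse$detection_scale_h
  hw <- window_factor * a
  sel <- times >= pulse$peak_time_h - hw & times <= pulse$peak_time_h + hw
  if (sum(sel) < 7L) {
    pulse$refined <- FALSE
    return(pulse)
  }
  tt <- times[sel]; vv <- values[sel]
  fit <- try(suppressWarnings(
    if (is.null(spar)) stats::smooth.spline(tt, vv)
    else stats::smooth.spline(tt, vv, spar = spar)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    pulse$refined <- FALSE
    return(pulse)
  }
  fine <- seq(min(tt), max(tt), length.out = 400L)
  yy <- stats::predict(fit, fine)$y
  baseline <- min(yy[1L], yy[length(yy)])
  ymax_i <- which.max(yy)
  amp <- yy[ymax_i] - baseline
  if (!is.finite(amp) || amp <= 0) {
    pulse$amplitude <- 0
    return(pulse)
  }
  half <- baseline + amp / 2
  above <- yy >= half
  # FWHM: crossings bracketing the maximum, linearly interpolated
  li <- ymax_i
  while (li > 1L && above[li - 1L]) li <- li - 1L
  ri <- ymax_i
  while (ri < length(yy) && above[ri + 1L]) ri <- ri + 1L
  t_left <- if (li > 1L) {
    interp_cross(fine[li - 1L], fine[li], yy[li - 1L], yy[li], half)
  } else fine[1L]
  t_right <- if (ri < length(yy)) {
    interp_cross(fine[ri], fine[ri + 1L], yy[ri], yy[ri + 1L], half)
  } else fine[length(yy)]
  pulse$amplitude <- amp
  pulse$width_h <- t_right - t_left
  pulse$peak_time_h <- fine[ymax_i]
  pulse$refined <- TRUE
  pulse
}

interp_cross <- function(t0, t1, y0, y1, level) {
  if (y1 == y0) return((t0 + t1) / 2)
  t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}

#' Inter-pulse-interval statistics
#'
#' Computes consecutive peak-time differences per cell, pooled across cells,
#' together with each eligible cell's first and last IPI. A cell contributes
#' a first/last IPI only if it has at least `min_pulses` pulses; with
#' exactly two pulses the first and last IPI coincide.
#'
#' @param pulses pulse tibble (needs `cell_id`, `peak_time_h`).
#' @param min_pulses minimum pulses for first/last-IPI eligibility.
#' @return An object of class `ipi_stats`: list with `all` (pooled IPIs,
#'   hours), `first`, `last` (per eligible cell) and `per_cell` (tibble of
#'   cell-level summaries).
#' @export
compute_ipis <- function(pulses, min_pulses = 2L) {
  stopifnot(min_pulses >= 2L)
  if (!nrow(pulses)) {
    return(structure(list(all = numeric(), first = numeric(),
                          last = numeric(),
                          per_cell = tibble::tibble(cell_id = character(),
                                                    n_pulses = integer(),
                                                    first_ipi = numeric(),
                                                    last_ipi = numeric())),
                     class = "ipi_stats"))
  }
  per <- lapply(split(pulses, pulses$cell_id), function(d) {
    pt <- sort(d$peak_time_h)
    ipis <- diff(pt)
    eligible <- length(pt) >= min_pulses
    tibble::tibble(cell_id = d$cell_id[1L], n_pulses = length(pt),
                   first_ipi = if (eligible) ipis[1L] else NA_real_,
                   last_ipi = if (eligible) ipis[length(ipis)] else NA_real_,
                   ipis = list(ipis))
  })
  per <- dplyr::bind_rows(per)
  structure(list(
    all = unlist(per$ipis, use.names = FALSE),
    first = per$first_ipi[!is.na(per$first_ipi)],
    last = per$last_ipi[!is.na(per$last_ipi)],
    per_cell = per[, c("cell_id", "n_pulses", "first_ipi", "last_ipi")]
  ), class = "ipi_stats")
}

#' @export
print.ipi_stats <- function(x, ...) {
  cat(sprintf("<ipi_stats: %d pooled IPIs from %d cells; median %.2f h>\n",
              length(x$all), nrow(x$per_cell),
              if (length(x$all)) stats::median(x$all) else NA_real_))
  invisible(x)
}

#' Kullback-Leibler divergence between two samples
#'
#' Bins both samples on shared equal-width bin edges spanning their pooled
#' range and computes `D(P || Q) = sum p_i log(p_i / q_i)` in nats. Each
#' histogram receives `1/(2n)` pseudo-mass per bin (n = its sample size)
#' before normalization, so empty bins do not produce infinities; identical
#' samples give exactly zero.
#'
#' @param p_samples,q_samples numeric samples (P is the "test", Q the
#'   reference distribution).
#' @param bins number of shared equal-width bins.
#' @param edges optional explicit bin edges (overrides `bins`); use one set
#'   of edges when comparing several divergences.
#' @return Divergence in nats (non-negative up to regularization).
#' @export
kld <- function(p_samples, q_samples, bins = 20L, edges = NULL) {
  if (!length(p_samples) || !length(q_samples)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (is.null(edges)) {
    rng <- range(c(p_samples, q_samples), finite = TRUE)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  }
  bin_probs <- function(x) {
    cnt <- graphics::hist(pmin(pmax(x, edges[1L]), edges[length(edges)]),
                          breaks = edges, plot = FALSE)$counts
    n <- length(x)
    w <- cnt + 1 / (2 * n)
    w / sum(w)
  }
  p <- bin_probs(p_samples)
  q <- bin_probs(q_samples)
  sum(p * log(p / q))
}

#' Pulse-count statistics over an observation window
#'
#' @param pulses pulse tibble (`cell_id`, `peak_time_h`).
#' @param window observation window in hours; pulses with peak times in
#'   `[0, window]` are counted.
#' @param cell_ids optional full roster of cells, so that cells without any
#'   detected pulse contribute zero counts.
#' @return A tibble with `cell_id` and `n_pulses`, one row per cell.
#' @export
pulse_count_stats <- function(pulses, window = 48, cell_ids = NULL) {
  inwin <- pulses[pulses$peak_time_h >= 0 & pulses$peak_time_h <= window, ]
  counts <- table(inwin$cell_id)
  if (is.null(cell_ids)) cell_ids <- names(counts)
  n <- integer(length(cell_ids))
  names(n) <- as.character(cell_ids)
  n[names(counts)] <- as.integer(counts)
  tibble::tibble(cell_id = as.character(cell_ids), n_pulses = unname(n))
}
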