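# --- Ricker continuous wavelet transform and ridge lines ------------------
#
# Pulse calling follows the mass-spectrometry peak-picking strategy: compute
# the CWT of the trajectory over a grid of scales, link local maxima of the
# coefficient matrix across adjacent scales into ridge lines, and keep
# ridges that are long and strong enough. Each surviving ridge yields one
# pulse at its best (highest-coefficient) scale.

# Ricker (Mexican hat) wavelet, L2-normalized in continuous time
ricker <- function(u) {
  (2 / (sqrt(3) * pi^0.25)) * (1 - u^2) * exp(-u^2 / 2)
}

# CWT matrix: rows = scales (hours), cols = time points (uniform grid, dt)
cwt_ricker <- function(x, dt, scales) {
  n <- length(x)
  out <- matrix(0, nrow = length(scales), ncol = n)
  for (j in seq_along(scales)) {
    a <- scales[j]
    m <- max(1L, ceiling(4 * a / dt))
    u <- (seq(-m, m) * dt) / a
    k <- ricker(u) * dt / sqrt(a)
    # reflect-pad so edge coefficients stay usable
    left <- x[pmin(m + 1L, n):2L]
    if (length(left) < m) left <- c(rep(x[1L], m - length(left)), left)
    right <- x[(n - 1L):max(1L, n - m)]
    if (length(right) < m) right <- c(right, rep(x[n], m - length(right)))
    xp <- c(left, x, right)
    conv <- stats::filter(xp, k, method = "convolution", sides = 2L)
    out[j, ] <- conv[(m + 1L):(m + n)]
  }
  out
}

# indices of strict positive local maxima, thinned to one per +/- w window
local_maxima <- function(v, w = 1L) {
  n <- length(v)
  if (n < 3L) return(integer())
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n] &
               v[2:(n - 1)] > 0) + 1L
  if (length(idx) < 2L || w <= 1L) return(idx)
  keep <- logical(length(idx))
  ord <- order(v[idx], decreasing = TRUE)
  taken <- rep(FALSE, n)
  for (i in ord) {
    p <- idx[i]
    win <- max(1L, p - w):min(n, p + w)
    if (!any(taken[win])) { keep[i] <- TRUE; taken[p] <- TRUE }
  }
  sort(idx[keep])
}

# Link maxima across scales (largest scale first) into ridge lines.
# Returns a list of ridges; each ridge is a data.frame(scale_idx, pos).
link_ridges <- function(cwt, scales, dt, gap_max = 1L) {
  ns <- length(scales)
  maxima <- lapply(seq_len(ns), function(j) {
    local_maxima(cwt[j, ], w = max(1L, round(0.25 * scales[j] / dt)))
  })
  ridges <- list()        # active: list(scale_idx = int vec, pos = int vec, gap)
  done <- list()
  for (j in seq(ns, 1L)) {
    mx <- maxima[[j]]
    used <- rep(FALSE, length(mx))
    tol <- max(2L, round(0.5 * scales[j] / dt))
    if (length(ridges)) {
      for (i in seq_along(ridges)) {
        rd <- ridges[[i]]
        if (is.null(rd)) next
        p <- rd$pos[length(rd$pos)]
        cand <- which(!used & abs(mx - p) <= tol)
        if (length(cand)) {
          ck <- cand[which.min(abs(mx[cand] - p))]
          used[ck] <- TRUE
          rd$scale_idx <- c(rd$scale_idx, j)
          rd$pos <- c(rd$pos, mx[ck])
          rd$gap <- 0L
          ridges[[i]] <- rd
        } else {
          rd$gap <- rd$gap + 1L
          if (rd$gap > gap_max || j == 1L) {
            done[[length(done) + 1L]] <- rd
            ridges[i] <- list(NULL)
          } else ridges[[i]] <- rd
        }
      }
      ridges <- Filter(Negate(is.null), ridges)
    }
    if (any(!used)) {
      for (p in mx[!used]) {
        ridges[[length(ridges) + 1L]] <-
          list(scale_idx = j, pos = p, gap = 0L)
      }
    }
  }
  c(done, ridges)
}
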