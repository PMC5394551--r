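# --- the excitable ATM-p53-Mdm2-Wip1 core ---------------------------------
#
# Six dynamic species: active ATM (A, fraction of a conserved kinase pool),
# p53 (P), mdm2 mRNA (Mm), Mdm2 protein (M), wip1 mRNA (Wm), Wip1 protein
# (W). The DSB count D(t) enters as a forcing. Network logic:
#   * damage-gated ATM activation with a positive self-interaction
#     (autophosphorylation/gammaH2AX spreading condensed into one
#     sigmoidal autocatalytic term), both opposed by Wip1 two ways:
#     direct dephosphorylation of ATM* (mass-action, k4) and cooperative
#     interference with the activation/self-activation step (K5, m5);
#   * ATM* stabilizes p53 by attenuating Mdm2-mediated degradation (K3)
#     and by destabilizing Mdm2 itself (k2);
#   * p53 transcribes mdm2 and wip1; translation and first-order decay
#     close the two delayed negative feedback loops.
# Concentrations are in arbitrary units, time in hours.

#' Parameters of the excitable p53 network model
#'
#' Returns the model's rate constants as a named list; any subset can be
#' overridden. `wip1_scale` is the per-cell Wip1 mRNA production multiplier
#' used to model cell-to-cell variability in Wip1 expression (1 = nominal).
#'
#' @param ... named overrides of individual parameters.
#' @return An object of class `p53_params`.
#' @export
p53_params <- function(...) {
  p <- list(
    # ATM module
    k_dsb = 0.6,   # MRN-seeded ATM activation per break (1/h per DSB)
    v_s   = 30,    # maximal self-activation rate (1/h)
    K_D   = 1.5,   # damage saturation of the self-interaction (breaks)
    K_A   = 0.25,  # self-activation midpoint (ATM* a.u.)
    n_A   = 6,     # self-activation cooperativity
    K5    = 0.35,  # Wip1 interference midpoint (Wip1 a.u.)
    m5    = 4,     # Wip1 interference cooperativity
    d_A   = 0.8,   # basal ATM* dephosphorylation (1/h)
    k4    = 4,     # Wip1-mediated ATM* dephosphorylation (1/(a.u. h))
    # p53 module
    b_P   = 2,     # p53 production (a.u./h)
    k_ub  = 4,     # Mdm2-mediated p53 ubiquitination/degradation (1/(a.u. h))
    K3    = 0.3,   # ATM* midpoint for p53 stabilization (a.u.)
    d_P   = 0.2,   # Mdm2-independent p53 decay (1/h)
    # transcription (shared promoter logic for mdm2/wip1)
    b_Mm  = 0.05,  # basal mdm2 transcription (a.u./h)
    k_TM  = 3.2,   # p53-dependent mdm2 transcription (a.u./h)
    b_Wm  = 0.15,  # basal wip1 transcription (a.u./h)
    k_TW  = 3.2,   # p53-dependent wip1 transcription (a.u./h)
    K_TP  = 3.2,   # p53 midpoint for transactivation (a.u.)
    n_T   = 8,     # transactivation cooperativity
    d_Mm  = 0.7,   # mdm2 mRNA decay (1/h)
    d_Wm  = 1.2,   # wip1 mRNA decay (1/h)
    # proteins
    k_trlM = 1.4,  # Mdm2 translation (1/h)
    d_M    = 0.7,  # basal Mdm2 decay (1/h)
    k2     = 3,    # ATM*-enhanced Mdm2 destabilization (fold)
    K2     = 0.3,  # ATM* midpoint for Mdm2 destabilization (a.u.)
    k_trlW = 4.1,  # Wip1 translation (1/h)
    d_W    = 1.2,  # Wip1 decay (1/h)
    wip1_scale = 1 # per-cell wip1 production multiplier
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    p[names(over)] <- over
  }
  stopifnot(all(vapply(p, function(v) is.numeric(v) && is.finite(v) && v > 0 ||
                         identical(v, 0), logical(1))))
  structure(p, class = "p53_params")
}

p53_species <- c("ATM_a", "p53", "mdm2_mRNA", "Mdm2", "wip1_mRNA", "Wip1")

# vector field; D = instantaneous DSB count
p53_rhs <- function(t, x, D, p) {
  A <- x[1]; P <- x[2]; Mm <- x[3]; M <- x[4]; Wm <- x[5]; W <- x[6]
  # MRN-seeded activation scales with the break count; the self-interaction
  # (gammaH2AX spreading at damage foci) saturates once breaks are present
  self_act <- p$v_s * A^p$n_A / (p$K_A^p$n_A + A^p$n_A) * D / (p$K_D + D)
  interf <- 1 / (1 + (W / p$K5)^p$m5)
  kact <- (p$k_dsb * D + self_act) * interf
  trans <- P^p$n_T / (p$K_TP^p$n_T + P^p$n_T)
  c(
    kact * (1 - A) - (p$d_A + p$k4 * W) * A,
    p$b_P - p$k_ub * M * P / (1 + (A / p$K3)^2) - p$d_P * P,
    p$b_Mm + p$k_TM * trans - p$d_Mm * Mm,
    p$k_trlM * Mm - p$d_M * (1 + p$k2 * A^2 / (p$K2^2 + A^2)) * M,
    p$wip1_scale * (p$b_Wm + p$k_TW * trans) - p$d_Wm * Wm,
    p$k_trlW * Wm - p$d_W * W
  )
}

# closure with all rate constants bound as locals: avoids repeated list
# access in the solver's inner loop (same math as p53_rhs)
make_p53_rhs <- function(p) {
  e <- list2env(p, parent = baseenv())
  with(e, {
    function(t, x, D) {
      A <- x[1]; P <- x[2]; Mm <- x[3]; M <- x[4]; Wm <- x[5]; W <- x[6]
      hillA <- A^n_A
      self_act <- v_s * hillA / (K_A^n_A + hillA) * D / (K_D + D)
      kact <- (k_dsb * D + self_act) / (1 + (W / K5)^m5)
      trans <- P^n_T / (K_TP^n_T + P^n_T)
      c(kact * (1 - A) - (d_A + k4 * W) * A,
        b_P - k_ub * M * P / (1 + (A / K3)^2) - d_P * P,
        b_Mm + k_TM * trans - d_Mm * Mm,
        k_trlM * Mm - d_M * (1 + k2 * A^2 / (K2^2 + A^2)) * M,
        wip1_scale * (b_Wm + k_TW * trans) - d_Wm * Wm,
        k_trlW * Wm - d_W * W)
    }
  })
}

#' Wrap the p53 network as a scannable dynamical model
#'
#' Exposes the six-species model through the same interface as
#' [abstract_model()], with the (constant) DSB count playing the role of the
#' input signal, so [bifurcation_scan()] and [classify_onset()] apply
#' directly.
#'
#' @param params a [p53_params()] object.
#' @return A `dyn_model` whose signal is the constant DSB count and whose
#'   readout is p53.
#' @export
p53_model <- function(params = p53_params()) {
  structure(list(
    name = "p53",
    species = p53_species,
    readout = "p53",
    feedback_param = "k_dsb",
    params = params,
    rhs = function(t, x, s, p) p53_rhs(t, x, s, p)
  ), class = "dyn_model")
}

#' Rest state of the p53 network at a constant damage level
#'
#' Finds the stable steady state by relaxation plus Newton polishing and
#' verifies it (residual below `1e-10`; integration from the root stays
#' put).
#'
#' @param params a [p53_params()].
#' @param dsb_level constant DSB count (default: the background level 2).
#' @param strict error when no stable root is found; with `strict = FALSE`
#'   the relaxed trajectory endpoint is returned instead (cells without a
#'   stable rest state, e.g. under strong Wip1 knockdown, pulse
#'   spontaneously and have no steady state to find).
#' @return Named state vector.
#' @export
p53_rest_state <- function(params = p53_params(), dsb_level = 2,
                           strict = TRUE) {
  stopifnot(dsb_level >= 0)
  f_rhs <- make_p53_rhs(params)
  rhs <- function(t, x) f_rhs(t, x, dsb_level)
  x0 <- c(0.01, 0.5, 0.1, 0.2, 0.1, 0.2)
  # 120 h is far beyond the slowest relaxation time of the stable rest
  # state; cells without one (spontaneous oscillators) return their
  # relaxed endpoint under strict = FALSE
  x <- find_rest_state(rhs, x0, t_relax = 120, strict = strict)
  if (any(x < -1e-9)) stop("rest state has negative components", call. = FALSE)
  stats::setNames(pmax(x, 0), p53_species)
}

#' Simulate one cell driven by a DSB track
#'
#' Integrates the six-species network with the DSB count entering as a
#' piecewise-constant (zero-order hold) forcing between the jump times of
#' the supplied track. Integration restarts at every jump and at every
#' intervention time, so discontinuities are handled exactly.
#'
#' Interventions are instantaneous multiplicative changes to a named
#' parameter, supplied as a list of `list(time, target, factor)`; targets
#' are parameter names of [p53_params()] (e.g. `k_dsb` to emulate ATM
#' inhibition, `wip1_scale` for Wip1 over/under-expression).
#'
#' @param dsb_track a `dsb_track` (or any tibble with `time_h`, `total`).
#' @param params a [p53_params()].
#' @param t_end end of the simulation, hours (must be covered by the track).
#' @param sample_dt output sampling interval, hours.
#' @param x0 initial state; default is the rest state at the track's initial
#'   count, capped at the background level so pre-damage cells start at
#'   their basal steady state.
#' @param interventions list of `list(time, target, factor)`.
#' @param rest_dsb constant damage level used for the default initial state.
#' @return A tibble with `time_h`, the six species columns and `dsb` (the
#'   forcing), of class `p53_trajectory`.
#' @export
simulate_cell <- function(dsb_track, params = p53_params(), t_end = 48,
                          sample_dt = 1 / 3, x0 = NULL,
                          interventions = list(), rest_dsb = 2) {
  stopifnot(max(dsb_track$time_h) >= t_end, sample_dt > 0)
  if (is.null(x0)) x0 <- p53_rest_state(params, dsb_level = rest_dsb, strict = FALSE)
  if (length(interventions)) {
    # factor-one interventions are no-ops; drop them so they do not perturb
    # the integrator's segmenting (bitwise reproducibility of controls)
    interventions <- Filter(function(iv) iv$factor != 1, interventions)
  }
  if (length(interventions)) {
    ord <- order(vapply(interventions, `[[`, numeric(1), "time"))
    interventions <- interventions[ord]
    for (iv in interventions) {
      if (!iv$target %in% names(params)) {
        stop("unknown intervention target: ", iv$target, call. = FALSE)
      }
      stopifnot(iv$factor > 0)
    }
  }

  jump_t <- dsb_track$time_h[dsb_track$time_h < t_end]
  jump_d <- dsb_track$total[dsb_track$time_h < t_end]
  iv_times <- vapply(interventions, `[[`, numeric(1), "time")
  # segment boundaries: jumps, interventions, end
  bounds <- sort(unique(c(0, jump_t, iv_times[iv_times < t_end], t_end)))
  out_times <- seq(0, t_end, by = sample_dt)

  d_at <- stats::approxfun(jump_t, jump_d, method = "constant", rule = 2,
                           ties = "ordered")
  rhs_cache <- new.env(parent = emptyenv())
  hash_key <- "base"
  p_cur <- params
  state <- as.numeric(x0)
  res_t <- numeric(0); res_x <- NULL
  applied <- logical(length(interventions))

  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    for (k in seq_along(interventions)) {
      if (!applied[k] && iv_times[k] <= t0) {
        iv <- interventions[[k]]
        p_cur[[iv$target]] <- p_cur[[iv$target]] * iv$factor
        applied[k] <- TRUE
        hash_key <- paste0(hash_key, "|", k)
      }
    }
    D <- d_at(t0)
    seg_out <- out_times[out_times >= t0 & out_times <= t1]
    times <- sort(unique(c(t0, seg_out, t1)))
    if (length(times) < 2L) times <- c(t0, t1)
    if (is.null(rhs_cache[[hash_key]])) {
      rhs_cache[[hash_key]] <- make_p53_rhs(p_cur)
    }
    f_rhs <- rhs_cache[[hash_key]]
    sol <- deSolve::lsoda(y = state, times = times,
                          func = function(t, x, q) list(f_rhs(t, x, D)),
                          parms = NULL, rtol = 1e-8, atol = 1e-10)
    if (attr(sol, "istate")[1L] < 0) {
      stop("integration failed in segment [", signif(t0, 4), ", ",
           signif(t1, 4), "]", call. = FALSE)
    }
    state <- as.numeric(sol[nrow(sol), -1])
    if (any(state < -1e-6)) {
      stop("negative state beyond solver tolerance at t = ", signif(t1, 4),
           call. = FALSE)
    }
    state <- pmax(state, 0)
    keep <- sol[, 1] %in% seg_out & !(sol[, 1] %in% res_t)
    if (any(keep)) {
      res_t <- c(res_t, sol[keep, 1])
      res_x <- rbind(res_x, sol[keep, -1, drop = FALSE])
    }
  }

  out <- tibble::as_tibble(as.data.frame(res_x))
  names(out) <- p53_species
  out <- tibble::add_column(out, time_h = res_t, .before = 1)
  out$dsb <- d_at(out$time_h)
  structure(out, class = c("p53_trajectory", class(out)), params = params)
}

#' Sample the excitation threshold around the rest state
#'
#' Perturbs the system instantaneously from its rest state and classifies
#' each perturbation as eliciting a full p53 pulse or only a subthreshold
#' excursion. The full-pulse reference amplitude is the p53 peak after a
#' strongly suprathreshold ATM* kick; a response counts as a full pulse if
#' its p53 peak deflection exceeds `cut` times the reference.
#'
#' @param params a [p53_params()].
#' @param directions a matrix of perturbation vectors (rows; columns in
#'   species order), or the name of a single species to bisect along.
#' @param dsb_level constant damage level during the probe.
#' @param t_probe probe simulation length, hours.
#' @param cut full-pulse classification fraction of the reference amplitude.
#' @return For matrix input: tibble with one row per perturbation
#'   (`full_pulse`, `peak_p53`, and the perturbed state). For a species
#'   name: the bracketed critical perturbation size (named vector
#'   `lower`/`upper`).
#' @export
excitation_threshold <- function(params = p53_params(), directions = "ATM_a",
                                 dsb_level = 2, t_probe = 15, cut = 0.5) {
  rest <- p53_rest_state(params, dsb_level)
  ref <- pulse_reference_amplitude(params, rest, dsb_level, t_probe)
  probe <- function(state) {
    state <- pmax(state, 0)
    sim <- integrate_const_dsb(state, params, dsb_level, t_probe)
    # response deflection: peak p53 above both the rest level and the
    # perturbed starting level, so a decaying p53 kick does not count as a
    # pulse of its own size
    max(sim$p53) - max(rest[["p53"]], state[["p53"]])
  }
  if (is.character(directions)) {
    sp <- match.arg(directions, p53_species)
    # bisect the critical kick size along one species axis
    lo <- 0; hi <- max(1, 4 * rest[[sp]])
    state_k <- function(k) { s <- rest; s[[sp]] <- s[[sp]] + k; s }
    if (probe(state_k(hi)) < cut * ref) {
      stop("no full pulse elicited within the perturbation budget",
           call. = FALSE)
    }
    for (i in 1:25) {
      mid <- (lo + hi) / 2
      if (probe(state_k(mid)) >= cut * ref) hi <- mid else lo <- mid
    }
    return(c(lower = lo, upper = hi))
  }
  stopifnot(is.matrix(directions), ncol(directions) == 6L)
  rows <- lapply(seq_len(nrow(directions)), function(i) {
    st <- rest + directions[i, ]
    pk <- probe(st)
    tibble::tibble(full_pulse = pk >= cut * ref, peak_p53 = pk,
                   !!!stats::setNames(as.list(pmax(st, 0)), p53_species))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "reference_amplitude") <- ref
  attr(out, "rest") <- rest
  out
}

# p53 peak after a strongly suprathreshold ATM* kick (reference full pulse)
pulse_reference_amplitude <- function(params, rest, dsb_level, t_probe) {
  st <- rest; st[["ATM_a"]] <- 0.9
  sim <- integrate_const_dsb(st, params, dsb_level, t_probe)
  max(sim$p53) - rest[["p53"]]
}

# integrate the model at a constant DSB level (no track needed)
integrate_const_dsb <- function(state, params, dsb_level, t_end,
                                dt = 0.05) {
  f_rhs <- make_p53_rhs(params)
  sol <- deSolve::lsoda(y = as.numeric(state), times = seq(0, t_end, by = dt),
                        func = function(t, x, q) list(f_rhs(t, x, dsb_level)),
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out) <- c("time_h", p53_species)
  out
}
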