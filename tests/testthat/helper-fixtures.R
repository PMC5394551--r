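# shared fixtures built in code

# a step-function DSB forcing track built by hand (no simulation):
# level `d_hi` until `t_switch`, then `d_lo` until t_end
step_track <- function(d_hi, t_switch, d_lo = 2, t_end = 60) {
  tibble::tibble(
    time_h = c(0, t_switch, t_end),
    idsb = c(d_hi, d_lo, d_lo),
    cdsb = 0L,
    total = c(d_hi, d_lo, d_lo)
  )
}

# constant-level track
const_track <- function(d, t_end = 60) step_track(d, t_end / 2, d, t_end)

# uniform 20-min sampling grid over `dur` hours
grid20 <- function(dur = 48) seq(0, dur, by = 1 / 3)

# cache expensive shared objects across test files within one run
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, .fixture_env)) {
    assign(name, force(expr), .fixture_env)
  }
  get(name, .fixture_env)
}

# three-regime ensembles shared by the statistics and acceptance tests;
# basal needs many cells because only a minority contribute IPIs
regime_ensembles <- function() {
  fixture("regimes", {
    list(
      basal = run_ensemble(80, N_s = 0, seed = 101, t_end = 48),
      medium = run_ensemble(40, N_s = 50, seed = 102, t_end = 48),
      high = run_ensemble(100, N_s = 400, seed = 103, t_end = 48)
    )
  })
}
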