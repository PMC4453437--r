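# Shared expensive objects, built once per test session.
.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.test_cache[[name]])) .test_cache[[name]] <- force(expr)
  .test_cache[[name]]
}

fcc_fixture <- function() cached("fcc_map", {
  set.seed(101); make_fixture("fcc", a = 0.35, resolution = 48)
})
hcp_fixture <- function() cached("hcp_map", {
  set.seed(102); make_fixture("hcp", a = 0.35, resolution = 48)
})
fcc_ac <- function() cached("fcc_ac", autocorr3d(fcc_fixture(), max_lag = 38))
hcp_ac <- function() cached("hcp_ac", autocorr3d(hcp_fixture(), max_lag = 38))
fcc_scores <- function() cached("fcc_scores", {
  ac <- fcc_ac(); d <- grid_spacing(ac)
  bp <- best_plane(ac, d)
  c(fcc_hcp_scores(ac, d, bp), list(bp = bp, d = d))
})
hcp_scores <- function() cached("hcp_scores", {
  ac <- hcp_ac(); d <- grid_spacing(ac)
  bp <- best_plane(ac, d)
  c(fcc_hcp_scores(ac, d, bp), list(bp = bp, d = d))
})

# Reduced-scale learning run shared by the simulation-property tests:
# 27 output units, 8^3 place inputs, 4 million steps (the spacing
# stabilizes at 3-4 million), standard parameters.
reduced_run <- function() cached("reduced_run", {
  cfg <- sim_config(n_mec = 27, per_axis_inp = 8)
  rc <- run_config(cfg, n_steps = 4e6, seed = 7)
  run_simulation(rc)
})

# spacing of every unit at one checkpoint (first autocorrelogram peak)
run_spacings <- function(run, checkpoint) {
  n <- dim(run$maps[[checkpoint]])[4]
  vapply(seq_len(n), function(i) {
    suppressWarnings(grid_spacing(autocorr3d(rate_map(run, i, checkpoint))))
  }, numeric(1))
}
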