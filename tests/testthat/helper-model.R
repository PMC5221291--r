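# shared fixtures, computed once per test run and memoised

.fixtures <- new.env(parent = emptyenv())

# the calibrated failing-heart baseline (fixed point of the shipped
# defaults, so this is cheap)
calibrated_model <- function() {
  if (is.null(.fixtures$cal))
    .fixtures$cal <- calibrate_baseline(cv_model())
  .fixtures$cal
}

# the full 3 x 3 condition-by-group grid on the calibrated baseline
study_grid <- function() {
  if (is.null(.fixtures$grid))
    .fixtures$grid <- run_grid(calibrated_model())
  .fixtures$grid
}

grid_cell <- function(grid, cond, grp, metric) {
  grid[[metric]][grid$condition == cond & grid$group == grp]
}

# integrate the scalar cross-bridge ODE under a prescribed ca(t) with
# deSolve; independent route used as oracle against closed forms
integrate_xb <- function(ca_fun, mp, t_end, a0 = 0, n = 2000) {
  f <- function(t, y, p) list(xb_rhs(y, ca_fun(t), mp))
  out <- deSolve::ode(c(a = a0), seq(0, t_end, length.out = n), f, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  as.data.frame(out)
}
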