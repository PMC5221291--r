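#' Extract one steady-state cycle from a simulation
#'
#' Returns exactly one basic cycle length of data starting at
#' `window_start`, the half-open window `[window_start,
#' window_start + bcl)`. The defaults (start 18.6 s, BCL 600 ms from the
#' model) select the steady-state measurement cycle from 18.6 to 19.2 s of
#' a 20 s run.
#'
#' @param sim A `cv_sim` object.
#' @param window_start Start of the measurement window, s.
#' @param bcl_ms Cycle length, ms; defaults to the model's drive period.
#' @return A data.frame slice of `sim$series` (class `cv_cycle`, with the
#'   cycle length stored in attribute `bcl`).
#' @export
extract_cycle <- function(sim, window_start = 18.6, bcl_ms = NULL) {
  stopifnot(inherits(sim, "cv_sim"))
  if (is.null(bcl_ms)) bcl_ms <- sim$model$calcium$bcl * 1000
  bcl <- bcl_ms / 1000
  t <- sim$series$time
  if (window_start < min(t) || window_start + bcl > max(t) + 1e-12)
    stop("requested cycle window [", window_start, ", ",
         window_start + bcl, "] lies outside the simulated series")
  sel <- t >= window_start - 1e-12 & t < window_start + bcl - 1e-12
  cyc <- sim$series[sel, , drop = FALSE]
  rownames(cyc) <- NULL
  attr(cyc, "bcl") <- bcl
  class(cyc) <- c("cv_cycle", class(cyc))
  cyc
}

#' Stroke work from a pressure--volume loop
#'
#' Signed shoelace (polygon) area of the closed loop traced by one cycle
#' of pressure and volume samples, orientation-corrected to be
#' non-negative for an ejecting loop. In mmHg.mL. Invariant to cyclic
#' rotation of the samples and to reversing the traversal direction; zero
#' for a degenerate (isovolumic) loop.
#'
#' @param p Pressure samples over one closed cycle, mmHg.
#' @param v Volume samples over the same cycle, mL (same length as `p`,
#'   at least 3).
#' @return Loop area, mmHg.mL (>= 0).
#' @export
#' @examples
#' # rectangular loop, 100 mmHg x 20 mL
#' stroke_work(c(0, 100, 100, 0), c(50, 50, 70, 70))
stroke_work <- function(p, v) {
  if (length(p) != length(v)) stop("p and v must have the same length")
  if (length(p) < 3) stop("need at least 3 samples")
  pn <- c(p[-1], p[1])
  vn <- c(v[-1], v[1])
  abs(sum(v * pn - vn * p)) / 2
}

#' Ejection fraction
#'
#' `EF = (EDV - ESV) / EDV`.
#'
#' @param edv End-diastolic volume, mL (positive).
#' @param esv End-systolic volume, mL (non-negative, at most `edv`).
#' @return Fraction in \[0, 1\].
#' @export
ejection_fraction <- function(edv, esv) {
  if (any(edv <= 0)) stop("edv must be positive")
  if (any(esv < 0)) stop("esv must be non-negative")
  if (any(esv > edv)) stop("esv must not exceed edv")
  (edv - esv) / edv
}

# cyclic trapezoid mean of a periodic signal sampled over [0, T)
.cycle_mean <- function(t, x, bcl) {
  tt <- c(t, t[1] + bcl)
  xx <- c(x, x[1])
  sum(diff(tt) * (xx[-length(xx)] + xx[-1]) / 2) / bcl
}

# cyclic trapezoid integral of the positive/negative part of a flow
.cycle_volume <- function(t, q, bcl, part = c("forward", "backward")) {
  part <- match.arg(part)
  q <- if (part == "forward") pmax(q, 0) else pmax(-q, 0)
  .cycle_mean(t, q, bcl) * bcl
}

#' Per-cycle scalar metric panel
#'
#' Computes the full metric panel from one extracted steady-state cycle:
#' peak left-atrial pressure (LAPP), peak left-ventricular pressure
#' (LVPP), peak and time-averaged aortic (systemic arterial) pressure,
#' end-diastolic/end-systolic LV volume, stroke volume, ejection fraction,
#' PV-loop stroke work, mean cross-bridge ATP consumption rate, and the
#' per-cycle regurgitant fractions of the mitral and aortic valves
#' (backward over forward volume; 0 when the valve is competent). The
#' aortic forward volume and the outflow-based ejection fraction
#' (aortic forward volume over EDV) are included as a cross-check on the
#' volume-extrema EF.
#'
#' @param cycle A `cv_cycle` from [extract_cycle()].
#' @return An object of class `cycle_metrics` (a named list of scalars).
#' @export
cycle_metrics <- function(cycle) {
  stopifnot(inherits(cycle, "cv_cycle"))
  if (nrow(cycle) == 0) stop("empty cycle")
  bcl <- attr(cycle, "bcl")
  t <- cycle$time
  edv <- max(cycle$v_lv)
  esv <- min(cycle$v_lv)
  fwd_mi <- .cycle_volume(t, cycle$q_mi, bcl, "forward")
  bwd_mi <- .cycle_volume(t, cycle$q_mi, bcl, "backward")
  fwd_ao <- .cycle_volume(t, cycle$q_ao, bcl, "forward")
  bwd_ao <- .cycle_volume(t, cycle$q_ao, bcl, "backward")
  m <- list(
    lapp = max(cycle$p_la),
    lvpp = max(cycle$p_lv),
    ao_peak = max(cycle$p_sa),
    ao_mean = .cycle_mean(t, cycle$p_sa, bcl),
    edv = edv,
    esv = esv,
    sv = edv - esv,
    ef = ejection_fraction(edv, esv),
    stroke_work = stroke_work(cycle$p_lv, cycle$v_lv),
    atp_mean = .cycle_mean(t, cycle$atp_lv, bcl),
    rf_mi = if (fwd_mi > 0) bwd_mi / fwd_mi else 0,
    rf_ao = if (fwd_ao > 0) bwd_ao / fwd_ao else 0,
    ao_forward_vol = fwd_ao,
    ef_outflow = fwd_ao / edv,
    pump_mean = .cycle_mean(t, cycle$q_pump, bcl),
    max_plv_minus_pao = max(cycle$p_lv - cycle$p_sa)
  )
  class(m) <- "cycle_metrics"
  m
}

#' @export
print.cycle_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("LAPP %.1f  LVPP %.1f  AoP peak/mean %.1f/%.1f mmHg\n",
           "EDV %.1f  ESV %.1f  SV %.1f mL  EF %.1f%%\n",
           "stroke work %.1f mmHg.mL  mean ATP rate %.3f 1/s\n",
           "regurgitant fraction MI %.3f  AO %.3f\n"),
    x$lapp, x$lvpp, x$ao_peak, x$ao_mean, x$edv, x$esv, x$sv, 100 * x$ef,
    x$stroke_work, x$atp_mean, x$rf_mi, x$rf_ao))
  invisible(x)
}

#' @export
as.data.frame.cycle_metrics <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Simulate, extract the steady-state cycle and measure it
#'
#' Convenience wrapper: run [simulate_circulation()] for `duration`
#' seconds, extract the cycle starting at `window_start`, and return its
#' [cycle_metrics()].
#'
#' @inheritParams simulate_circulation
#' @inheritParams extract_cycle
#' @return A `cycle_metrics` object with the simulation attached as
#'   attribute `sim`.
#' @export
measure_model <- function(model, duration = 20, window_start = 18.6, ...) {
  sim <- simulate_circulation(model, duration = duration, ...)
  m <- cycle_metrics(extract_cycle(sim, window_start))
  attr(m, "sim") <- sim
  m
}
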