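#' Regurgitation condition
#'
#' The three study conditions: `normal` (heart failure without valvular
#' regurgitation, no leak), `ar` (5% aortic regurgitation) and `mr`
#' (5% mitral regurgitation).
#'
#' @param label One of `"normal"`, `"ar"`, `"mr"`.
#' @param sf Leak scale factor applied to the leaky valve, percent
#'   (default 5).
#' @return A list with `label`, `sf_mi`, `sf_ao` (class `cv_condition`).
#' @export
condition <- function(label = c("normal", "ar", "mr"), sf = 5) {
  label <- match.arg(label)
  if (sf < 0 || sf > 100) stop("sf must lie in [0, 100] percent")
  structure(list(label = label,
                 sf_mi = if (label == "mr") sf else 0,
                 sf_ao = if (label == "ar") sf else 0),
            class = "cv_condition")
}

#' LVAD support group
#'
#' The three study groups: `control` (no device), `laao` (pump inlet at
#' the left atrium) and `lvao` (pump inlet at the left ventricle), the
#' assisted groups running at a constant 40 mL/s.
#'
#' @param label One of `"control"`, `"laao"`, `"lvao"`.
#' @param flow Pump flux for the assisted groups, mL/s (default 40).
#' @return A list with `label` and an [lvad_config()] (class `cv_group`).
#' @export
study_group <- function(label = c("control", "laao", "lvao"), flow = 40) {
  label <- match.arg(label)
  structure(list(label = label,
                 lvad = if (label == "control") lvad_config("none")
                        else lvad_config(label, flow)),
            class = "cv_group")
}

#' Apply a condition and group to a model
#'
#' @param model A [cv_model()].
#' @param cond A [condition()].
#' @param group A [study_group()].
#' @return The modified model.
#' @export
apply_cell <- function(model, cond, group) {
  stopifnot(inherits(model, "cv_model"), inherits(cond, "cv_condition"),
            inherits(group, "cv_group"))
  model$circulation$sf_mi <- cond$sf_mi
  model$circulation$sf_ao <- cond$sf_ao
  model$lvad <- group$lvad
  model
}

#' Calibrate the failing-heart baseline
#'
#' Adjusts the LV active-pressure gain and the total blood volume so that
#' the unassisted, non-regurgitant failing heart reproduces the target
#' baseline phenotype: stroke volume 20 mL at end-diastolic volume 100 mL
#' (hence 20% ejection fraction), measured on the steady-state cycle
#' (18.6--19.2 s of a 20 s run). A damped Broyden iteration with a
#' finite-difference initial Jacobian; fully deterministic from the
#' starting model.
#'
#' @param model Starting [cv_model()]; its `normal`/`control` cell is
#'   simulated regardless of the leak/LVAD settings it carries.
#' @param sv_target,edv_target Targets, mL.
#' @param tol_sv,tol_edv Convergence tolerances, mL.
#' @param max_iter Maximum Broyden steps.
#' @param damping Step damping factor in (0, 1].
#' @param verbose Print per-iteration residuals.
#' @return The calibrated model (leak/LVAD reset to `normal`/`control`
#'   values of the input preserved), with a `calibration` attribute
#'   holding residuals and iteration count. If the starting model already
#'   meets both tolerances it is returned unchanged (fixed point).
#' @export
calibrate_baseline <- function(model, sv_target = 20, edv_target = 100,
                               tol_sv = 0.5, tol_edv = 2, max_iter = 12,
                               damping = 0.7, verbose = FALSE) {
  stopifnot(inherits(model, "cv_model"))

  eval_cell <- function(x) {
    m <- model
    m$lv$p_act_gain <- x[1]
    m$v_total <- x[2]
    m <- apply_cell(m, condition("normal"), study_group("control"))
    met <- measure_model(m)
    c(met$sv - sv_target, met$edv - edv_target)
  }
  converged <- function(r) abs(r[1]) <= tol_sv && abs(r[2]) <= tol_edv

  x <- c(model$lv$p_act_gain, model$v_total)
  r <- eval_cell(x)
  if (verbose)
    message(sprintf("start: SV resid %.3f, EDV resid %.3f", r[1], r[2]))
  it <- 0L
  if (!converged(r)) {
    # finite-difference Jacobian at the start point
    hx <- c(0.05 * x[1], 0.02 * x[2])
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + hx[j]
      J[, j] <- (eval_cell(xp) - r) / hx[j]
    }
    repeat {
      it <- it + 1L
      if (it > max_iter)
        stop(sprintf(
          "calibration did not converge in %d iterations (SV resid %.3f mL, EDV resid %.3f mL)",
          max_iter, r[1], r[2]))
      step <- tryCatch(solve(J, -r), error = function(e)
        stop("singular calibration Jacobian"))
      x_new <- x + damping * step
      x_new[1] <- max(x_new[1], 0.05)
      x_new[2] <- max(x_new[2], 100)
      r_new <- eval_cell(x_new)
      if (verbose)
        message(sprintf("iter %d: gain %.4f, volume %.1f, SV resid %.3f, EDV resid %.3f",
                        it, x_new[1], x_new[2], r_new[1], r_new[2]))
      dx <- x_new - x
      J <- J + ((r_new - r - J %*% dx) %*% t(dx)) / sum(dx^2)
      x <- x_new
      r <- r_new
      if (converged(r)) break
    }
  }
  model$lv$p_act_gain <- x[1]
  model$v_total <- x[2]
  attr(model, "calibration") <- list(
    p_act_gain = x[1], v_total = x[2],
    residual_sv = r[1], residual_edv = r[2], iterations = it)
  model
}

#' Run the full 3 x 3 experiment grid
#'
#' Simulates every combination of condition (`normal`, `ar`, `mr`) and
#' group (`control`, `laao`, `lvao`) for `duration` seconds and measures
#' the steady-state cycle of each. Cells are independent; the grid is
#' deterministic given the model and solver settings.
#'
#' @param model A calibrated [cv_model()].
#' @param duration Per-cell simulated time, s.
#' @param window_start Measurement cycle start, s.
#' @param sf Leak severity for the regurgitant conditions, percent.
#' @return An object of class `cv_grid`: a data.frame with `condition`,
#'   `group` and one column per [cycle_metrics()] field, plus the
#'   per-cell diagnostics in attribute `diagnostics`.
#' @export
run_grid <- function(model, duration = 20, window_start = 18.6, sf = 5) {
  stopifnot(inherits(model, "cv_model"))
  conds <- c("normal", "ar", "mr")
  groups <- c("control", "laao", "lvao")
  rows <- list()
  diags <- list()
  for (cd in conds) for (g in groups) {
    m <- apply_cell(model, condition(cd, sf), study_group(g))
    met <- measure_model(m, duration = duration, window_start = window_start)
    sim <- attr(met, "sim")
    key <- paste(cd, g, sep = ".")
    rows[[key]] <- cbind(data.frame(condition = cd, group = g,
                                    stringsAsFactors = FALSE),
                         as.data.frame(met))
    diags[[key]] <- sim$diagnostics
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  attr(grid, "diagnostics") <- diags
  class(grid) <- c("cv_grid", class(grid))
  grid
}

# fetch one metric of one grid cell
.cell <- function(grid, cond, group, metric) {
  i <- grid$condition == cond & grid$group == group
  if (!any(i)) stop("grid cell (", cond, ", ", group, ") missing")
  grid[[metric]][i]
}

#' Qualitative trend report
#'
#' Evaluates the panel of directional hemodynamic findings on a completed
#' experiment grid: the isovolumic-contraction (zero-EF, zero stroke
#' work) outcome of atrial cannulation in the non-regurgitant failing
#' heart; the loading shifts of untreated aortic and mitral
#' regurgitation; the overloading of the AR heart by atrial cannulation
#' versus its tolerance of ventricular cannulation; the recovery of the
#' MR heart by either cannulation; the rise of aortic pressure under
#' support; and the unloading of the pump's inlet chamber. Each check
#' compares named metrics of named grid cells and reports the two numbers
#' with a pass flag.
#'
#' @param grid A `cv_grid` from [run_grid()].
#' @return An object of class `cv_trends`: a data.frame with `id`,
#'   `description`, `value_a`, `value_b`, `pass`.
#' @export
trend_report <- function(grid) {
  stopifnot(inherits(grid, "cv_grid"))
  g <- function(cond, grp, met) .cell(grid, cond, grp, met)
  checks <- list()
  add <- function(id, description, a, b, pass) {
    checks[[length(checks) + 1]] <<- data.frame(
      id = id, description = description, value_a = a, value_b = b,
      pass = pass, stringsAsFactors = FALSE)
  }

  add("laao_normal_zero_ef",
      "LAAO in the non-regurgitant failing heart: no ejection (EF ~ 0, stroke work ~ 0)",
      100 * g("normal", "laao", "ef"), g("normal", "laao", "stroke_work"),
      100 * g("normal", "laao", "ef") < 1 &&
        g("normal", "laao", "stroke_work") < 1)
  add("laao_normal_isovolumic",
      "LAAO in the non-regurgitant heart: LV pressure never exceeds aortic pressure",
      g("normal", "laao", "max_plv_minus_pao"),
      g("normal", "laao", "ao_forward_vol"),
      g("normal", "laao", "max_plv_minus_pao") < 0 &&
        g("normal", "laao", "ao_forward_vol") < 0.5)
  add("ar_control_lv_unloaded",
      "Untreated AR: LV peak pressure below the non-regurgitant control",
      g("ar", "control", "lvpp"), g("normal", "control", "lvpp"),
      g("ar", "control", "lvpp") < g("normal", "control", "lvpp"))
  add("ar_control_la_loaded",
      "Untreated AR: LA peak pressure above the non-regurgitant control",
      g("ar", "control", "lapp"), g("normal", "control", "lapp"),
      g("ar", "control", "lapp") > g("normal", "control", "lapp"))
  add("mr_control_la_loaded",
      "Untreated MR: LA peak pressure above the non-regurgitant control",
      g("mr", "control", "lapp"), g("normal", "control", "lapp"),
      g("mr", "control", "lapp") > g("normal", "control", "lapp"))
  add("ar_laao_overload",
      "LAAO in AR: LV peak pressure and ATP rate above the AR control, stroke work above the normal-condition value (worsening)",
      g("ar", "laao", "lvpp"), g("ar", "control", "lvpp"),
      g("ar", "laao", "lvpp") > g("ar", "control", "lvpp") &&
        g("ar", "laao", "atp_mean") > g("ar", "control", "atp_mean") &&
        g("ar", "laao", "stroke_work") > g("normal", "control", "stroke_work"))
  add("ar_lvao_atp",
      "LVAO in AR: mean ATP consumption rate not above the AR control",
      g("ar", "lvao", "atp_mean"), g("ar", "control", "atp_mean"),
      g("ar", "lvao", "atp_mean") <= g("ar", "control", "atp_mean"))
  add("mr_lvad_recovery",
      "Either cannulation in MR: lower ATP consumption and higher mean aortic pressure than the MR control",
      min(g("mr", "laao", "atp_mean"), g("mr", "lvao", "atp_mean")),
      g("mr", "control", "atp_mean"),
      g("mr", "laao", "atp_mean") < g("mr", "control", "atp_mean") &&
        g("mr", "lvao", "atp_mean") < g("mr", "control", "atp_mean") &&
        g("mr", "laao", "ao_mean") > g("mr", "control", "ao_mean") &&
        g("mr", "lvao", "ao_mean") > g("mr", "control", "ao_mean"))
  add("normal_lvad_aortic_rise",
      "Either cannulation in the non-regurgitant heart: peak aortic pressure above control",
      min(g("normal", "laao", "ao_peak"), g("normal", "lvao", "ao_peak")),
      g("normal", "control", "ao_peak"),
      g("normal", "laao", "ao_peak") > g("normal", "control", "ao_peak") &&
        g("normal", "lvao", "ao_peak") > g("normal", "control", "ao_peak"))
  add("normal_inlet_unloading",
      "Non-regurgitant heart: the pump's inlet chamber peak pressure falls (LA under LAAO, LV under LVAO)",
      g("normal", "laao", "lapp"), g("normal", "control", "lapp"),
      g("normal", "laao", "lapp") < g("normal", "control", "lapp") &&
        g("normal", "lvao", "lvpp") < g("normal", "control", "lvpp"))

  out <- do.call(rbind, checks)
  class(out) <- c("cv_trends", class(out))
  out
}

#' @export
print.cv_trends <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("[%s] %-28s %8.3f vs %8.3f  %s\n",
                if (x$pass[i]) "PASS" else "FAIL", x$id[i],
                x$value_a[i], x$value_b[i], x$description[i]))
  }
  invisible(x)
}

#' Write grid metrics to CSV
#' @param grid A `cv_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "cv_grid"))
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' Write a trend report to JSON
#' @param trends A `cv_trends`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trends_json <- function(trends, path) {
  stopifnot(inherits(trends, "cv_trends"))
  jsonlite::write_json(as.data.frame(trends), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
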