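#' Write a model configuration to YAML
#'
#' Serializes a [cv_model()] into a YAML file with blocks `calcium` (in
#' ms/uM, as accepted by [ca_params()]), `myofilament`, `lv`, `rv`,
#' `circulation`, `leak`, `lvad` and `blood`. The file round-trips through
#' [load_model_yaml()].
#'
#' @param model A [cv_model()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_yaml <- function(model, path) {
  stopifnot(inherits(model, "cv_model"))
  ca <- model$calcium
  ci <- model$circulation
  cfg <- list(
    calcium = list(bcl_ms = ca$bcl * 1000,
                   ca_diastolic_uM = ca$ca_diastolic,
                   ca_amplitude_uM = ca$ca_amplitude,
                   tau_rise_ms = ca$tau_rise * 1000,
                   tau_decay_ms = ca$tau_decay * 1000,
                   hf_amplitude_factor = ca$hf_amplitude_factor),
    myofilament = unclass(model$myofilament),
    lv = unclass(model$lv),
    rv = unclass(model$rv),
    circulation = unclass(ci)[setdiff(names(ci), c("sf_mi", "sf_ao"))],
    leak = list(sf_mi = ci$sf_mi, sf_ao = ci$sf_ao),
    lvad = list(mode = model$lvad$mode, flow_ml_s = model$lvad$flow),
    blood = list(v_total = model$v_total)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Load a model configuration from YAML
#'
#' Reads a configuration written by [write_model_yaml()] (or edited by
#' hand). Any omitted block or field falls back to the package default;
#' all invariants are re-validated by the constructors.
#'
#' @param path YAML file path.
#' @return A [cv_model()] object.
#' @export
load_model_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  fill <- function(args, fn) do.call(fn, args[names(args) %in%
                                                names(formals(fn))])
  calcium <- if (is.null(cfg$calcium)) ca_params()
             else fill(cfg$calcium, ca_params)
  myo <- if (is.null(cfg$myofilament)) myo_params()
         else fill(cfg$myofilament, myo_params)
  lv <- if (is.null(cfg$lv)) ventricle_params()
        else fill(cfg$lv, ventricle_params)
  rv_default <- formals(cv_model)$rv
  rv <- if (is.null(cfg$rv)) eval(rv_default) else fill(cfg$rv, ventricle_params)
  circ_args <- c(cfg$circulation, cfg$leak)
  circ <- if (length(circ_args) == 0) circ_params()
          else fill(circ_args, circ_params)
  lvad <- if (is.null(cfg$lvad)) lvad_config()
          else lvad_config(mode = cfg$lvad$mode %||% "none",
                           flow = cfg$lvad$flow_ml_s %||% 40)
  v_total <- cfg$blood$v_total %||% 550
  cv_model(calcium = calcium, myofilament = myo, lv = lv, rv = rv,
           circulation = circ, lvad = lvad, v_total = v_total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
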