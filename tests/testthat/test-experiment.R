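test_that("conditions and groups encode the study design", {
  expect_equal(condition("normal")[c("sf_mi", "sf_ao")],
               list(sf_mi = 0, sf_ao = 0))
  expect_equal(condition("ar")[c("sf_mi", "sf_ao")],
               list(sf_mi = 0, sf_ao = 5))
  expect_equal(condition("mr")[c("sf_mi", "sf_ao")],
               list(sf_mi = 5, sf_ao = 0))
  expect_identical(study_group("control")$lvad$mode, "none")
  expect_identical(study_group("control")$lvad$flow, 0)
  expect_identical(study_group("laao")$lvad$flow, 40)
  expect_identical(study_group("lvao")$lvad$mode, "lvao")
  expect_error(condition("tr"))
})

test_that("an already-calibrated model is a fixed point of calibration", {
  cal <- calibrated_model()
  again <- calibrate_baseline(cal)
  expect_identical(attr(again, "calibration")$iterations, 0L)
  expect_equal(again$lv$p_act_gain, cal$lv$p_act_gain)
  expect_equal(again$v_total, cal$v_total)
})

test_that("calibration recovers the targets after an afterload perturbation", {
  m <- calibrated_model()
  m$circulation$r_sa <- m$circulation$r_sa * 1.2
  recal <- calibrate_baseline(m)
  info <- attr(recal, "calibration")
  expect_lte(abs(info$residual_sv), 0.5)
  expect_lte(abs(info$residual_edv), 2)
  # the free parameters moved to compensate
  expect_gt(recal$lv$p_act_gain, calibrated_model()$lv$p_act_gain)
})

test_that("grid cells match standalone runs and carry their labels", {
  grid <- study_grid()
  expect_equal(nrow(grid), 9)
  expect_setequal(unique(grid$condition), c("normal", "ar", "mr"))
  expect_setequal(unique(grid$group), c("control", "laao", "lvao"))
  single <- measure_model(apply_cell(calibrated_model(),
                                     condition("normal"),
                                     study_group("control")))
  expect_equal(grid_cell(grid, "normal", "control", "sv"), single$sv,
               tolerance = 1e-12)
  expect_equal(grid_cell(grid, "normal", "control", "stroke_work"),
               single$stroke_work, tolerance = 1e-12)
})

test_that("trend predicates fail on a degenerate all-equal grid", {
  grid <- study_grid()
  flat <- grid
  for (col in setdiff(names(flat), c("condition", "group")))
    flat[[col]] <- rep(flat[[col]][1], nrow(flat))
  tr <- trend_report(flat)
  strict <- !tr$id %in% c("laao_normal_zero_ef", "laao_normal_isovolumic",
                          "ar_lvao_atp")
  expect_false(any(tr$pass[strict]))
})

test_that("repeated runs are bit-identical (deterministic pipeline)", {
  m <- apply_cell(calibrated_model(), condition("mr"), study_group("laao"))
  m1 <- measure_model(m, duration = 5, window_start = 4.2)
  m2 <- measure_model(m, duration = 5, window_start = 4.2)
  expect_identical(unclass(m1)[names(unclass(m1))],
                   unclass(m2)[names(unclass(m2))])
})

test_that("model configurations round-trip through YAML", {
  cal <- calibrated_model()
  cal$lvad <- lvad_config("lvao", 40)
  cal$circulation$sf_ao <- 5
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  write_model_yaml(cal, path)
  back <- load_model_yaml(path)
  expect_equal(back$lv$p_act_gain, cal$lv$p_act_gain, tolerance = 1e-9)
  expect_equal(back$v_total, cal$v_total, tolerance = 1e-9)
  expect_identical(back$lvad$mode, "lvao")
  expect_equal(back$circulation$sf_ao, 5)
  expect_equal(back$calcium$bcl, cal$calcium$bcl)
  # loading an edited file re-validates invariants
  cfg <- yaml::read_yaml(path)
  cfg$leak$sf_ao <- 150
  yaml::write_yaml(cfg, path)
  expect_error(load_model_yaml(path), "\\[0, 100\\]")
})
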