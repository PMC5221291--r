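test_that("cycle extraction returns exactly one cycle and validates its window", {
  sim <- simulate_circulation(cv_model(), duration = 20)
  cyc <- extract_cycle(sim, 18.6)
  expect_s3_class(cyc, "cv_cycle")
  expect_true(all(cyc$time >= 18.6 - 1e-9 & cyc$time < 19.2 - 1e-9))
  # bookkeeping: cycle length times sampling rate gives the sample count
  expect_equal(nrow(cyc), 600)
  expect_error(extract_cycle(sim, 19.9), "outside")
  expect_error(extract_cycle(sim, -1), "outside")
})

test_that("stroke work matches the shoelace oracle on synthetic polygons", {
  # rectangle: 100 mmHg x 20 mL
  expect_equal(stroke_work(c(0, 100, 100, 0), c(50, 50, 70, 70)), 2000)
  # isovolumic trajectory has zero enclosed area
  expect_equal(stroke_work(c(0, 40, 90, 40), rep(60, 4)), 0)
  # random closed polygons against an independent shoelace implementation
  shoelace <- function(x, y) {
    n <- length(x)
    j <- c(n, seq_len(n - 1))
    abs(sum(x[j] * y - x * y[j])) / 2
  }
  set.seed(7)
  for (k in 1:10) {
    n <- sample(5:40, 1)
    p <- runif(n, 0, 120)
    v <- runif(n, 20, 140)
    expect_equal(stroke_work(p, v), shoelace(v, p), tolerance = 1e-9)
    # cyclic rotation and reversal leave the area unchanged
    r <- sample(n, 1)
    p_rot <- c(p[r:n], p[seq_len(r - 1)])
    v_rot <- c(v[r:n], v[seq_len(r - 1)])
    expect_equal(stroke_work(p_rot, v_rot), stroke_work(p, v),
                 tolerance = 1e-9)
    expect_equal(stroke_work(rev(p), rev(v)), stroke_work(p, v),
                 tolerance = 1e-9)
  }
  expect_error(stroke_work(1:4, 1:5), "length")
  expect_error(stroke_work(1:2, 1:2), "3 samples")
})

test_that("ejection fraction follows its definition and rejects bad input", {
  expect_equal(ejection_fraction(100, 80), 0.20)
  expect_equal(ejection_fraction(120, 90), 0.25)
  expect_equal(ejection_fraction(75, 75), 0)
  expect_error(ejection_fraction(0, 0), "positive")
  expect_error(ejection_fraction(50, 60), "exceed")
})

# build a synthetic one-cycle series with known analytic properties
synthetic_cycle <- function(n = 600, bcl = 0.6, p_la_fun, atp_const = 5) {
  t <- seq(0, bcl - bcl / n, length.out = n)
  cyc <- data.frame(time = t,
                    v_lv = 80 + 20 * sin(2 * pi * t / bcl),
                    p_lv = 40 - 40 * cos(2 * pi * t / bcl),
                    p_la = p_la_fun(t), p_sa = 70 + 10 * sin(2 * pi * t / bcl),
                    q_mi = pmax(sin(2 * pi * t / bcl), 0),
                    q_ao = sin(2 * pi * t / bcl),
                    q_pump = 0, atp_lv = atp_const)
  attr(cyc, "bcl") <- bcl
  class(cyc) <- c("cv_cycle", class(cyc))
  cyc
}

test_that("metric panel recovers analytic values on a synthetic cycle", {
  cyc <- synthetic_cycle(p_la_fun = function(t) 5 + 10 * sin(2 * pi * t / 0.6))
  m <- cycle_metrics(cyc)
  expect_equal(m$lapp, 15, tolerance = 1e-4)
  expect_equal(m$edv, 100, tolerance = 1e-4)
  expect_equal(m$esv, 60, tolerance = 1e-4)
  expect_equal(m$sv, 40, tolerance = 1e-4)
  expect_equal(m$ef, 0.4, tolerance = 1e-4)
  # ellipse area pi*a*b traced by the sin/cos pair
  expect_equal(m$stroke_work, pi * 20 * 40, tolerance = 1e-3)
  expect_equal(m$atp_mean, 5)
  # forward and backward aortic volumes are equal half-sine lobes
  expect_equal(m$rf_ao, 1, tolerance = 1e-3)
  expect_equal(m$rf_mi, 0)
})

test_that("constant signals give degenerate metrics", {
  cyc <- synthetic_cycle(p_la_fun = function(t) rep(7, length(t)))
  cyc$v_lv <- rep(80, nrow(cyc))
  cyc$p_lv <- rep(30, nrow(cyc))
  cyc$q_ao <- rep(0, nrow(cyc))
  cyc$q_mi <- rep(0, nrow(cyc))
  m <- cycle_metrics(cyc)
  expect_equal(m$sv, 0)
  expect_equal(m$ef, 0)
  expect_equal(m$stroke_work, 0)
  expect_equal(m$lapp, 7)
  expect_equal(m$rf_mi, 0)   # no forward volume: fraction defined as 0
})

test_that("mean ATP rate is invariant to resampling density", {
  f <- function(n) {
    cyc <- synthetic_cycle(n = n,
                           p_la_fun = function(t) 5 + sin(2 * pi * t / 0.6))
    cyc$atp_lv <- 2 + sin(2 * pi * cyc$time / 0.6)^2
    cycle_metrics(cyc)$atp_mean
  }
  expect_equal(f(300), f(3000), tolerance = 1e-3)
})
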