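# forward tissue models and the exponential-kernel convolution

test_that("convolution degenerates to the cumulative integral at kep = 0", {
  t <- seq(0, 100, by = 1.55)
  x <- sin(t / 20)^2
  y <- exp_convolution(t, x, kep = 0)
  seg <- diff(t) * (x[-1] + x[-length(x)]) / 2
  expect_equal(y, c(0, cumsum(seg)), tolerance = 1e-12)
  expect_identical(y[1], 0)
})

test_that("convolution matches the constant-input closed form", {
  t <- seq(0, 120, by = 0.1)
  c_in <- rep(1, length(t))      # constant unit input from t = 0
  for (kep in c(6, 0.6)) {       # 0.1 and 0.01 s^-1
    k <- kep / 60
    y <- exp_convolution(t, c_in, kep)
    ref <- (1 / k) * (1 - exp(-k * t))
    expect_lt(max(abs(y[-1] - ref[-1]) / ref[-1]), 1e-6)
  }
})

test_that("convolution agrees with fine-grid quadrature of the interpolant", {
  # independent oracle: trapezoid on a 64x refined grid aligned to the knots
  oracle <- function(times, values, kep) {
    k <- kep / 60
    tf <- seq(times[1], times[length(times)],
              by = (times[2] - times[1]) / 64)
    cf <- approx(times, values, xout = tf)$y
    vapply(times, function(tt) {
      keep <- tf <= tt + 1e-12
      integrand <- exp(-k * (tt - tf[keep])) * cf[keep]
      sum(diff(tf[keep]) * (integrand[-1] + integrand[-sum(keep)]) / 2)
    }, numeric(1))
  }
  set.seed(7)
  t <- seq(0, 300, by = 1.55)
  for (i in 1:50) {
    arr <- runif(1, 5, 60)
    shape <- population_aif(t, arrival = arr, alpha = runif(1, 2, 4),
                            t_peak = runif(1, 3, 8))
    kep <- runif(1, 0.02, 2)
    y <- exp_convolution(t, shape, kep)
    ref <- oracle(t, shape, kep)
    scale <- max(abs(ref))
    expect_lt(max(abs(y - ref)) / scale, 1e-4)
  }
})

test_that("convolution is causal and rejects bad input", {
  t <- seq(0, 50, by = 1.55)
  x <- population_aif(t, arrival = 10)
  y1 <- exp_convolution(t, x, 0.5)
  x2 <- x; x2[t > 30] <- x2[t > 30] + 5
  y2 <- exp_convolution(t, x2, 0.5)
  expect_equal(y1[t <= 30], y2[t <= 30])
  expect_error(exp_convolution(t, x, -1), "nonnegative")
  expect_error(exp_convolution(rev(t), x, 1), "increasing")
})

test_that("nested models collapse onto each other at boundary parameters", {
  aif <- default_aif()
  p3 <- pk_params(vp = 0.03, ktrans = 0.02, kep = 0)
  p2 <- pk_params(vp = 0.03, ktrans = 0.02)
  expect_equal(ctissue(aif, p3, 3), ctissue(aif, p2, 2), tolerance = 1e-15)
  p2z <- pk_params(vp = 0.03, ktrans = 0)
  p1 <- pk_params(vp = 0.03)
  expect_equal(ctissue(aif, p2z, 2), ctissue(aif, p1, 1), tolerance = 1e-15)
})

test_that("tissue models are linear in vp, ktrans and the AIF", {
  aif <- default_aif()
  y1 <- ctissue(aif, pk_params(0.01, 0.01, 0.2), 3)
  y2 <- ctissue(aif, pk_params(0.02, 0.01, 0.2), 3)
  y3 <- ctissue(aif, pk_params(0.01, 0.02, 0.2), 3)
  base_vp <- ctissue(aif, pk_params(0.01), 1)
  expect_equal(y2 - y1, base_vp, tolerance = 1e-12)
  expect_equal(y3 - y1, y1 - base_vp, tolerance = 1e-12)
  aif2 <- aif_trace(aif$times, 2 * aif$c_aif, hct = aif$hct)
  expect_equal(ctissue(aif2, pk_params(0.01, 0.01, 0.2), 3), 2 * y1,
               tolerance = 1e-12)
})

test_that("model 2 with a constant input matches the closed form", {
  t <- seq(0, 120, by = 0.5)
  aif <- aif_trace(t, rep(1, length(t)), hct = 0.45)
  y <- ctissue(aif, pk_params(vp = 0.02, ktrans = 0.01), 2)
  # at t = 120 s: (vp * 1 + ktrans[1/min] * 2 min) / (1 - hct)
  expect_equal(y[length(t)], (0.02 + 0.01 * 2) / 0.55, tolerance = 1e-10)
})

test_that("parameter container enforces the ve = ktrans/kep identity", {
  p <- pk_params(0.02, 0.03, 0.15)
  expect_equal(p$ve, 0.2)
  expect_true(attr(p, "physical"))
  expect_true(is.na(pk_params(0.02, 0.03)$ve))
  expect_false(attr(pk_params(1.4), "physical"))  # flagged, not clipped
  expect_equal(pk_params(1.4)$vp, 1.4)
})

test_that("ctissue validates parameters and hematocrit", {
  aif <- default_aif()
  expect_error(ctissue(aif, pk_params(0.02), 2), "requires")
  expect_error(ctissue(aif, pk_params(0.02, 0.01), 3), "requires")
  bad <- aif; bad$hct <- 1
  expect_error(ctissue(bad, pk_params(0.02), 1), "hct")
})
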