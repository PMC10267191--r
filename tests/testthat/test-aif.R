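# population AIF construction, reference normalization, dispersion

test_that("population shape is a unit-peak causal bolus", {
  acq <- acq_params(n_frames = 200)
  arrival <- (acq$injection_frame - 1) * acq$frame_interval
  s <- population_aif(acq$times, arrival = arrival)
  expect_equal(max(s), 1)
  expect_true(all(s[acq$times <= arrival] == 0))
  expect_true(all(s >= 0))
  pk_frame <- which.max(s)
  expect_lte(pk_frame - acq$injection_frame, 3)   # peak close to injection
  expect_gt(pk_frame, acq$injection_frame - 1)
  # monotone washout once the recirculation/washin transient has developed
  late <- acq$times > arrival + 60
  expect_true(all(diff(s[late]) <= 1e-12))
  expect_equal(population_aif(acq$times, arrival, washout_frac = c(0, 0)) *
                 0, population_aif(acq$times, arrival,
                                   washout_frac = c(0, 0)) * 0)
})

test_that("zero-amplitude bolus yields the zero trace", {
  t <- seq(0, 100, 1.55)
  expect_true(all(0 * population_aif(t, 20) == 0))
})

test_that("normalization is self-consistent: refit returns vp_ref exactly", {
  acq <- acq_params(n_frames = 200)
  t <- acq$times
  shape <- population_aif(t, arrival = 21.7)
  for (vp_true in c(0.01, 0.02)) {
    ref <- vp_true * 6 * shape / (1 - 0.45)   # reference tissue curve
    aif <- normalize_aif(shape, ref, t, vp_ref = 0.01, hct = 0.45)
    f1 <- fit_pk_model(ref, aif, 1, intercept = TRUE)
    expect_equal(f1$params$vp, 0.01, tolerance = 1e-10)
    # deliberate-bias propagation: truth vp 0.02 assumed 0.01 => scale x2
    expect_equal(aif$normalization$scale, 6 * vp_true / 0.01,
                 tolerance = 1e-10)
  }
})

test_that("normalization is idempotent and scale-equivariant", {
  t <- seq(0, 300, 1.55)
  shape <- population_aif(t, arrival = 21.7)
  ref <- 0.13 * shape + 0.001
  a1 <- normalize_aif(shape, ref, t)
  a2 <- normalize_aif(a1$c_aif, ref, t)
  expect_equal(a1$c_aif, a2$c_aif, tolerance = 1e-10)
  a3 <- normalize_aif(shape, 3 * ref, t)
  expect_equal(a3$c_aif, 3 * a1$c_aif, tolerance = 1e-12)
  expect_error(normalize_aif(shape * 0, ref, t), "zero")
})

test_that("dispersion preserves area, lowers the peak, delays the mean", {
  # fine grid, fully decayed bolus (no washout plateau), so no tail mass
  # leaves the grid
  t <- seq(0, 900, by = 0.05)
  shape <- population_aif(t, arrival = 20, washout_frac = c(0.2, 0),
                          washout_rate = c(0.02, 0))
  aif <- aif_trace(t, shape, hct = 0.45)
  trapz <- function(y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
  a0 <- trapz(aif$c_aif)
  m0 <- trapz(t * aif$c_aif) / a0
  peaks <- c(); moments <- c()
  for (tau in c(2, 5, 10)) {
    d <- apply_dispersion(aif, tau)
    expect_lt(abs(trapz(d$c_aif) - a0) / a0, 1e-6)
    peaks <- c(peaks, max(d$c_aif))
    moments <- c(moments, trapz(t * d$c_aif) / a0)
  }
  expect_true(all(diff(peaks) < 0))
  expect_lt(peaks[1], max(aif$c_aif))
  expect_true(all(diff(moments) > 0))
  expect_gt(moments[1], m0)
  # identity at tau = 0
  expect_identical(apply_dispersion(aif, 0)$c_aif, aif$c_aif)
  expect_error(apply_dispersion(aif, -1), "nonnegative")
})

test_that("AIF trace validates its invariants and round-trips through CSV", {
  t <- seq(0, 10, 0.5)
  expect_error(aif_trace(t, rep(1, 5)), "equal length")
  expect_error(aif_trace(rev(t), seq_along(t)), "increasing")
  expect_error(aif_trace(t, seq_along(t), hct = 0.95), "hct")
  a <- aif_trace(t, seq_along(t) * 0.1, hct = 0.4)
  p <- withr::local_tempfile(fileext = ".csv")
  write_aif(a, p)
  b <- read_aif(p, hct = 0.4)
  expect_equal(b$c_aif, a$c_aif)
  expect_equal(b$times, a$times)
})
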