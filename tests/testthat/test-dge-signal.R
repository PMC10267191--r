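# dual-echo SPGR synthesis and inversion (tip angle, dR1)

test_that("spgr_echo matches a hand evaluation and its limits", {
  acq <- acq_params()
  th <- 18 * pi / 180
  f <- spgr_echo(1000, 1.5, 0.04, acq, 1, th)
  e <- exp(-acq$tr / 1.5)
  ref <- 1000 * sin(th) * (1 - e) * exp(-acq$te1 / 0.04) / (1 - cos(th) * e)
  expect_equal(f, ref, tolerance = 1e-12)
  expect_equal(round(f, 1), 72.9)
  # theta -> 0 kills the signal; infinite T2* equalizes the echoes
  expect_lt(spgr_echo(1000, 1.5, 0.04, acq, 1, 1e-9), 1e-5)
  expect_equal(spgr_echo(1000, 1.5, 1e12, acq, 1, th),
               spgr_echo(1000, 1.5, 1e12, acq, 2, th), tolerance = 1e-9)
  expect_error(spgr_echo(1000, -1, 0.04, acq, 1, th), "positive")
})

test_that("window means follow their definitions", {
  acq <- acq_params(n_frames = 120)
  win <- baseline_windows(acq, m = 5, n = 14)
  f <- rep(3, 120); s <- rep(2, 120)
  w <- window_means(f, s, win)
  expect_equal(c(w$f_pre, w$f_sat, w$s_pre, w$s_sat), c(3, 3, 2, 2))
  f2 <- seq_len(120)
  w2 <- window_means(f2, s, win)
  expect_equal(w2$f_pre, 9.5)            # mean of 5..14
  expect_equal(w2$f_pre_sum, sum(5:14))
  expect_equal(w2$f_sat, mean(111:120))
  expect_false(window_means(replace(f, 6, NA), s, win)$ok)
})

test_that("baseline windows enforce their invariants", {
  acq <- acq_params(n_frames = 120)
  w <- baseline_windows(acq)
  expect_equal(c(w$m, w$n, w$o, w$p), c(5, 14, 111, 120))
  expect_equal(w$p - w$o, w$n - w$m)
  expect_error(baseline_windows(acq, m = 5, n = 15), "injection")
  expect_error(baseline_windows(acq, m = 5, n = 14, o = 100, p = 120),
               "equal length")
})

test_that("noise-free forward synthesis round-trips theta and dR1 exactly", {
  # programmed dR1 reaching an exact plateau, nonzero common dR2* dynamics
  acq <- acq_params(n_frames = 120)
  win <- baseline_windows(acq)
  t <- acq$times
  up <- pmin(pmax(t - 21.7, 0) / 30, 1)
  dr1_true <- 0.4 * up             # plateau 0.4 s^-1 from ~52 s on
  dr2s_true <- 3 * up              # arbitrary common T2* dynamics
  th_values <- seq(10, 30, by = 2) * pi / 180
  for (th in th_values) {
    t1 <- 1 / (1 / 1.6 + dr1_true)
    t2s <- 1 / (1 / 0.035 + dr2s_true)
    f <- spgr_echo(900, t1, t2s, acq, 1, th)
    s <- spgr_echo(900, t1, t2s, acq, 2, th)
    e_pre <- exp(-acq$tr / 1.6)
    e_post <- exp(-acq$tr * (1 / 1.6 + 0.4))
    est <- estimate_tip_angle(f, s, e_pre, e_post, acq, win)
    expect_true(est$valid)
    expect_lt(abs(est$theta - th), 1e-10)
    dr1 <- estimate_delta_r1(f, s, est$theta, e_pre, acq, win)
    expect_equal(dr1$n_invalid, 0)
    expect_lt(max(abs(dr1$dr1 - dr1_true)), 1e-10)
  }
})

test_that("dR1 estimation is invariant to echo rescaling and T2* dynamics", {
  acq <- acq_params(n_frames = 120)
  win <- baseline_windows(acq)
  t <- acq$times
  dr1_true <- 0.3 * pmin(pmax(t - 21.7, 0) / 40, 1)
  th <- 18 * pi / 180
  e_pre <- exp(-acq$tr / 1.5)
  make <- function(dr2s, m0) {
    t1 <- 1 / (1 / 1.5 + dr1_true)
    t2s <- 1 / (1 / 0.04 + dr2s)
    list(f = spgr_echo(m0, t1, t2s, acq, 1, th),
         s = spgr_echo(m0, t1, t2s, acq, 2, th))
  }
  base <- make(0, 1000)
  ref <- estimate_delta_r1(base$f, base$s, th, e_pre, acq, win)$dr1
  # (a) global rescaling of both echoes (M0 change)
  scaled <- estimate_delta_r1(5 * base$f, 5 * base$s, th, e_pre, acq, win)$dr1
  expect_lt(max(abs(scaled - ref)), 1e-12)
  # (b) arbitrary common post-injection T2* dynamics at mu = 2
  # (dR2* is contrast-driven, so it is zero before the bolus arrives)
  wob <- make(2 * sin((t - 21.7) / 15)^2 * (t > 21.7), 1000)
  wobbled <- estimate_delta_r1(wob$f, wob$s, th, e_pre, acq, win)$dr1
  expect_lt(max(abs(wobbled - ref)), 1e-9)
})

test_that("frames at the baseline level give dR1 = 0 exactly", {
  acq <- acq_params(n_frames = 120)
  win <- baseline_windows(acq)
  f <- rep(80, 120); s <- rep(60, 120)
  out <- estimate_delta_r1(f, s, 18 * pi / 180, exp(-0.016), acq, win)
  expect_lt(max(abs(out$dr1)), 1e-12)
})

test_that("larger first-echo signal at fixed second echo raises dR1", {
  acq <- acq_params(n_frames = 120)
  win <- baseline_windows(acq)
  f <- rep(80, 120); s <- rep(60, 120)
  f2 <- f; f2[60] <- 85
  out <- estimate_delta_r1(f2, s, 18 * pi / 180, exp(-0.016), acq, win)
  expect_gt(out$dr1[60], 0)
  f3 <- f; f3[60] <- 75
  out2 <- estimate_delta_r1(f3, s, 18 * pi / 180, exp(-0.016), acq, win)
  expect_lt(out2$dr1[60], 0)
})

test_that("degenerate and out-of-domain voxels are flagged, not clamped", {
  acq <- acq_params(n_frames = 120)
  win <- baseline_windows(acq)
  f <- rep(80, 120); s <- rep(60, 120)
  ep <- exp(-0.016)
  # no enhancement and equal pre/post factors: no angle information
  est <- estimate_tip_angle(f, s, ep, ep * (1 + 1e-16), acq, win)
  expect_false(est$valid)
  # noise-driven arccos excursion
  set.seed(1)
  fz <- f + rnorm(120, sd = 8); sz <- s + rnorm(120, sd = 8)
  est2 <- estimate_tip_angle(fz, sz, ep, exp(-acq$tr * (1 / 1.5 + 0.001)),
                             acq, win)
  if (!est2$valid) expect_true(est2$reason %in% c("acos_domain", "degenerate"))
  est3 <- estimate_tip_angle(fz, sz, ep, exp(-acq$tr * (1 / 1.5 + 0.001)),
                             acq, win, clamp = TRUE)
  expect_true(est3$valid)
})

test_that("study-level driver recovers the phantom maps noise-free", {
  st <- tiny_study()
  fit <- estimate_dr1_study(st)
  m <- st$mask
  expect_true(all(fit$flags[m] == 0))
  expect_true(all(fit$flags[!m] == -1))
  expect_lt(max(abs(fit$theta[m] - st$truth$theta[m])), 1e-9)
  err <- abs(fit$dr1 - st$truth$dr1)
  expect_lt(max(err[is.finite(err)]), 1e-9)
})

test_that("theta policies agree noise-free and differ under noise", {
  st <- tiny_study()
  auto <- estimate_dr1_study(st, theta = "auto")
  est <- estimate_dr1_study(st, theta = "estimate")
  m <- st$mask
  expect_equal(auto$theta[m], est$theta[m])
  stn <- tiny_study_noisy()
  nom <- estimate_dr1_study(stn, theta = "nominal")
  expect_true(all(nom$theta[stn$mask & nom$flags == 0] ==
                    stn$acq$theta_nominal))
})
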