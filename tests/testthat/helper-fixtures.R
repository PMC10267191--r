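# Shared fixtures, built lazily and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small fast phantom spec: 16 x 12 x 1 grid, 120 frames
tiny_spec <- function(snr = Inf, ...) {
  phantom_spec(nx = 16, ny = 12, nz = 1,
               acq = acq_params(n_frames = 120), snr = snr, ...)
}

tiny_study <- function() {
  fixture("tiny_study_nf", function() make_phantom_study(tiny_spec(), seed = 42))
}

tiny_study_noisy <- function() {
  fixture("tiny_study_sn20",
          function() make_phantom_study(tiny_spec(snr = 20), seed = 42))
}

# a default-protocol AIF trace (400 frames) used across fitting tests
default_aif <- function() {
  fixture("default_aif", function() {
    acq <- acq_params()
    arrival <- (acq$injection_frame - 1) * acq$frame_interval
    aif_trace(acq$times, 6 * population_aif(acq$times, arrival = arrival),
              hct = 0.45)
  })
}

# matrix view of a study's voxel time series
voxel_series <- function(study, voxel) {
  dims <- dim(study$f)
  nvox <- prod(dims[1:3])
  list(f = matrix(study$f, nvox, dims[4])[voxel, ],
       s = matrix(study$s, nvox, dims[4])[voxel, ])
}

# six-study noisy cohort with NMS targets, used by the CV and negative-
# control tests
make_small_cohort_table <- function() {
  fixture("small_cohort_table", function() {
    spec <- tiny_spec(snr = 20)
    coh <- make_cohort(spec, 6, seed = 19)
    g <- feature_grid(spec$acq$n_frames, l1 = 10, step = 5)
    tabs <- lapply(seq_along(coh$studies), function(i) {
      an <- analyze_study(coh$studies[[i]])
      build_training_table(coh$studies[[i]], an$nms, study_id = i, grid = g)
    })
    dplyr::bind_rows(tabs)
  })
}

# vectorized closed-form Model-1/2 fits used by the F-test calibration
# simulations (linear algebra only, independent of the package's fitters)
sim_f_rates <- function(n_rep, sigma, aif, vp = 0.01, alpha = 0.05,
                        seed = 1) {
  set.seed(seed)
  b1 <- aif$c_aif / (1 - aif$hct)
  b2 <- exp_convolution(aif$times, aif$c_aif, 0) / (60 * (1 - aif$hct))
  n <- length(b1)
  Y <- vp * b1 + matrix(rnorm(n * n_rep, sd = sigma), n, n_rep)
  g1 <- as.numeric(crossprod(b1, Y))
  vp1 <- g1 / sum(b1^2)
  rss1 <- colSums(Y^2) - vp1 * g1
  a11 <- sum(b1^2); a12 <- sum(b1 * b2); a22 <- sum(b2^2)
  g2 <- as.numeric(crossprod(b2, Y))
  det <- a11 * a22 - a12^2
  c1 <- (a22 * g1 - a12 * g2) / det
  c2 <- (a11 * g2 - a12 * g1) / det
  rss2 <- colSums(Y^2) - c1 * g1 - c2 * g2
  f12 <- pmax(0, rss1 - rss2) / (rss2 / (n - 2))
  mean(f12 > qf(1 - alpha, 1, n - 2))
}
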