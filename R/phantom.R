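#' Specification of a digital dual-echo DCE-MRI phantom
#'
#' Describes a rat-brain-like digital reference object: an elliptical brain
#' (Model 1 region, intact vasculature), a circular tumor whose rim leaks
#' without measurable back-flux (Model 2) and whose core leaks with back-flux
#' (Model 3), and a small reference region of normal tissue (caudate-putamen
#' analog) with plasma volume fraction fixed at `vp_ref` for AIF calibration.
#' Defaults emulate the acquisition the package targets: 128 x 64 in-plane
#' matrix, 3 slices, 400 frames at ~1.55 s, bolus at frame 15.
#'
#' @param nx,ny,nz Grid dimensions (defaults 128, 64, 3).
#' @param acq An [acq_params()] object.
#' @param vp_range,ktrans_range,kep_range Per-region parameter draw ranges:
#'   `vp` (all tissue), `ktrans` min^-1 (Model >= 2), `kep` min^-1 (Model 3).
#' @param vp_ref Plasma volume fraction assigned to the reference region.
#' @param hct Hematocrit fraction.
#' @param aif_peak Peak whole-blood dR1 of the true AIF, s^-1.
#' @param r2s_factor Vascular-weighted T2* coupling: the simulated
#'   `dR2*(t) = r2s_factor * vp * c_aif(t)`. 0 disables T2* dynamics.
#' @param snr Baseline first-echo signal-to-noise ratio; `Inf` disables noise.
#' @param noise `"gaussian"` (default) or `"rician"`.
#' @param b1_jitter Half-width of the relative per-voxel flip-angle variation
#'   (uniform); 0 gives the nominal angle everywhere.
#' @param t1_range,t2s_range Baseline T1 and T2* draw ranges, seconds.
#' @param m0_range Equilibrium magnetization draw range (arbitrary units).
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(nx = 128, ny = 64, nz = 3,
                         acq = acq_params(),
                         vp_range = c(0.005, 0.05),
                         ktrans_range = c(0.005, 0.05),
                         kep_range = c(0.05, 0.5),
                         vp_ref = 0.01, hct = 0.45,
                         aif_peak = 6, r2s_factor = 20,
                         snr = 20, noise = c("gaussian", "rician"),
                         b1_jitter = 0.1,
                         t1_range = c(1.4, 1.9),
                         t2s_range = c(0.025, 0.045),
                         m0_range = c(800, 1200)) {
  noise <- match.arg(noise)
  stopifnot(nx >= 8, ny >= 8, nz >= 1, snr > 0,
            all(vp_range > 0), all(ktrans_range > 0), all(kep_range > 0),
            vp_ref > 0, hct >= 0, hct < 1, aif_peak > 0, r2s_factor >= 0,
            b1_jitter >= 0, all(t1_range > 0), all(t2s_range > 0),
            all(m0_range > 0))
  structure(list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
                 acq = acq, vp_range = vp_range, ktrans_range = ktrans_range,
                 kep_range = kep_range, vp_ref = vp_ref, hct = hct,
                 aif_peak = aif_peak, r2s_factor = r2s_factor, snr = snr,
                 noise = noise, b1_jitter = b1_jitter,
                 t1_range = t1_range, t2s_range = t2s_range,
                 m0_range = m0_range),
            class = "phantom_spec")
}

#' Compact phantom preset for desk-scale validation
#'
#' A scaled-down study condition used throughout the package's own validation:
#' 24 x 16 x 1 grid and 300 frames at 1.55 s (7.75 min), keeping the injection
#' frame, parameter ranges, SNR and all physics identical to the full-size
#' default. Feature extraction on this grid uses 24 retained samples per echo
#' (see [feature_grid()]).
#'
#' @param n_frames Number of frames (default 300).
#' @param nx,ny,nz Grid dimensions (defaults 24, 16, 1).
#' @param ... Overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
compact_phantom_spec <- function(n_frames = 300, nx = 24, ny = 16, nz = 1,
                                 ...) {
  phantom_spec(nx = nx, ny = ny, nz = nz,
               acq = acq_params(n_frames = n_frames), ...)
}

# region labels on the grid: 0 outside brain, 1 normal, 2 rim, 3 core;
# attribute "reference" marks the reference-ROI voxels (subset of label 1)
.phantom_geometry <- function(spec) {
  nx <- spec$nx; ny <- spec$ny; nz <- spec$nz
  x <- matrix(rep(seq_len(nx), ny), nx, ny)
  y <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  brain <- ((x - cx) / (0.45 * nx))^2 + ((y - cy) / (0.42 * ny))^2 <= 1
  tx <- 0.70 * nx; ty <- 0.50 * ny
  rt <- 0.22 * min(nx, ny)
  d2 <- (x - tx)^2 + (y - ty)^2
  tumor <- d2 <= rt^2
  core <- d2 <= (0.6 * rt)^2
  lab <- matrix(0L, nx, ny)
  lab[brain] <- 1L
  lab[brain & tumor] <- 2L
  lab[brain & core] <- 3L
  # reference region (caudate-putamen analog): a box in normal tissue whose
  # extent scales with the grid (~13 x 13 voxels at the full 128 x 64 matrix)
  rx <- round(0.30 * nx); ry <- round(0.50 * ny)
  hw <- max(1L, round(0.1 * min(nx, ny)))
  ref <- matrix(FALSE, nx, ny)
  ref[(rx - hw):(rx + hw), (ry - hw):(ry + hw)] <- TRUE
  ref <- ref & lab == 1L
  labels <- array(rep(lab, nz), dim = c(nx, ny, nz))
  reference <- array(rep(ref, nz), dim = c(nx, ny, nz))
  list(labels = labels, reference = reference)
}

#' Simulate one dual-echo DCE-MRI study with full ground truth
#'
#' Draws per-voxel vascular parameters within the region ranges, builds tissue
#' dR1(t) through the nested forward models, couples a vascular-weighted
#' dR2*(t), converts to dynamic T1/T2*, synthesizes both spoiled gradient-echo
#' signals at a per-voxel flip angle, and adds signal-domain noise. Every
#' intermediate quantity a downstream consumer could need (labels, parameter
#' maps, tip angles, noise-free dR1, AIF, pre/post longitudinal factors) is
#' recorded as truth rather than recomputed from the noisy data. The
#' post-contrast factor `e_post` is the effective value implied by the
#' saturation-window signal level — the quantity a post-contrast T1 map
#' measures.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; the study is bit-reproducible given the seed.
#' @param aif Optional [aif_trace()] to drive the simulation (e.g. a dispersed
#'   or delayed trace); default builds the population shape scaled to
#'   `spec$aif_peak`.
#'
#' @return An object of class `dge_study`: list with signal arrays `f`, `s`
#'   (x, y, z, t), `mask`, `e_pre`, `e_post`, `acq`, and a `truth` list
#'   (labels, reference mask, vp/ktrans/kep/ve/theta maps, `dr1` array, `aif`,
#'   noise sigma, baseline maps).
#' @export
make_phantom_study <- function(spec, seed = 1L, aif = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  acq <- spec$acq
  geo <- .phantom_geometry(spec)
  labels <- geo$labels
  dims <- c(spec$nx, spec$ny, spec$nz)
  nvox <- prod(dims)
  nt <- acq$n_frames
  times <- acq$times

  if (is.null(aif)) {
    arrival <- (acq$injection_frame - 1) * acq$frame_interval
    shape <- population_aif(times, arrival = arrival)
    aif <- aif_trace(times, spec$aif_peak * shape, hct = spec$hct)
  }
  stopifnot(length(aif$times) == nt)

  lab <- as.integer(labels)
  inb <- lab > 0L
  vp <- rep(NA_real_, nvox)
  kt <- rep(NA_real_, nvox)
  kp <- rep(NA_real_, nvox)
  vp[inb] <- runif(sum(inb), spec$vp_range[1], spec$vp_range[2])
  vp[geo$reference] <- spec$vp_ref
  i2 <- lab >= 2L
  kt[i2] <- runif(sum(i2), spec$ktrans_range[1], spec$ktrans_range[2])
  i3 <- lab == 3L
  kp[i3] <- runif(sum(i3), spec$kep_range[1], spec$kep_range[2])
  ve <- ifelse(!is.na(kp) & kp > 0, kt / kp, NA_real_)

  # forward tissue concentration (dR1 surrogate), V x T
  cp <- aif$c_aif / (1 - aif$hct)
  cum_int <- exp_convolution(times, aif$c_aif, kep = 0) / (1 - aif$hct)
  dr1 <- matrix(0, nvox, nt)
  dr1[inb, ] <- outer(vp[inb], cp)
  idx2 <- which(lab == 2L)
  if (length(idx2))
    dr1[idx2, ] <- dr1[idx2, ] + outer(kt[idx2] / 60, cum_int)
  idx3 <- which(i3)
  for (v in idx3) {
    conv <- exp_convolution(times, aif$c_aif, kep = kp[v]) / (1 - aif$hct)
    dr1[v, ] <- dr1[v, ] + (kt[v] / 60) * conv
  }

  dr2s <- matrix(0, nvox, nt)
  if (spec$r2s_factor > 0)
    dr2s[inb, ] <- spec$r2s_factor * outer(vp[inb], aif$c_aif)

  t1b <- runif(nvox, spec$t1_range[1], spec$t1_range[2])
  t2sb <- runif(nvox, spec$t2s_range[1], spec$t2s_range[2])
  m0 <- runif(nvox, spec$m0_range[1], spec$m0_range[2])
  theta <- acq$theta_nominal *
    (1 + spec$b1_jitter * runif(nvox, -1, 1))

  r1 <- 1 / t1b + dr1
  r2s <- 1 / t2sb + dr2s
  e1 <- exp(-acq$tr * r1)
  amp <- m0 * sin(theta) * (1 - e1) / (1 - cos(theta) * e1)
  f0 <- amp * exp(-acq$te1 * r2s)
  s0 <- amp * exp(-acq$te2 * r2s)

  e_pre <- exp(-acq$tr / t1b)
  # effective post-contrast factor from the saturation-window amplitude
  win <- baseline_windows(acq)
  ex <- .dge_exponents(acq$mu)
  pre <- win$m:win$n; sat <- win$o:win$p
  p_meas <- (rowSums(s0[, pre, drop = FALSE])^ex$a /
             rowSums(f0[, pre, drop = FALSE])^ex$b) *
            (rowSums(f0[, sat, drop = FALSE])^ex$b /
             rowSums(s0[, sat, drop = FALSE])^ex$a)
  cth <- cos(theta)
  gam <- p_meas * (1 - e_pre) / (1 - cth * e_pre)
  e_post <- (1 - gam) / (1 - cth * gam)

  if (is.finite(spec$snr)) {
    sigma <- mean(f0[inb, pre]) / spec$snr
    if (spec$noise == "gaussian") {
      f <- f0 + matrix(rnorm(nvox * nt, sd = sigma), nvox, nt)
      s <- s0 + matrix(rnorm(nvox * nt, sd = sigma), nvox, nt)
    } else {
      f <- sqrt((f0 + matrix(rnorm(nvox * nt, sd = sigma), nvox, nt))^2 +
                matrix(rnorm(nvox * nt, sd = sigma), nvox, nt)^2)
      s <- sqrt((s0 + matrix(rnorm(nvox * nt, sd = sigma), nvox, nt))^2 +
                matrix(rnorm(nvox * nt, sd = sigma), nvox, nt)^2)
    }
  } else {
    sigma <- 0
    f <- f0; s <- s0
  }

  shape3 <- function(v) array(v, dims)
  structure(list(
    f = array(f, c(dims, nt)), s = array(s, c(dims, nt)),
    mask = shape3(inb), acq = acq,
    e_pre = shape3(e_pre), e_post = shape3(e_post),
    truth = list(labels = labels, reference = geo$reference,
                 vp = shape3(vp), ktrans = shape3(kt), kep = shape3(kp),
                 ve = shape3(ve), theta = shape3(theta),
                 dr1 = array(dr1, c(dims, nt)), aif = aif, sigma = sigma,
                 t1_base = shape3(t1b), t2s_base = shape3(t2sb),
                 m0 = shape3(m0), windows = win, seed = seed),
    spec = spec),
    class = "dge_study")
}

#' @export
print.dge_study <- function(x, ...) {
  d <- dim(x$f)
  cat(sprintf("<dge_study> %d x %d x %d grid, %d frames, %s voxels in mask\n",
              d[1], d[2], d[3], d[4], format(sum(x$mask), big.mark = ",")))
  invisible(x)
}

#' Simulate a cohort of phantom studies
#'
#' Generates `n_studies` independent studies from one spec, each with its own
#' derived seed, optionally jittering the AIF per study with a bolus-dispersion
#' time constant drawn uniformly from `tau_range` (emulating between-animal
#' variation in bolus sharpness).
#'
#' @param spec A [phantom_spec()].
#' @param n_studies Number of studies (>= 1).
#' @param seed Cohort master seed; per-study seeds are derived from it.
#' @param tau_range Length-2 range (s) for the per-study dispersion constant,
#'   or `NULL` (default) for no jitter.
#'
#' @return A list with `studies` (list of `dge_study`) and `manifest`
#'   (tibble: study id, seed, dispersion tau).
#' @export
make_cohort <- function(spec, n_studies, seed = 1L, tau_range = NULL) {
  stopifnot(n_studies >= 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max / 2, n_studies)
  taus <- if (is.null(tau_range)) rep(0, n_studies) else
    runif(n_studies, tau_range[1], tau_range[2])
  acq <- spec$acq
  arrival <- (acq$injection_frame - 1) * acq$frame_interval
  shape <- population_aif(acq$times, arrival = arrival)
  base_aif <- aif_trace(acq$times, spec$aif_peak * shape, hct = spec$hct)
  studies <- vector("list", n_studies)
  for (i in seq_len(n_studies)) {
    aif_i <- if (taus[i] > 0) apply_dispersion(base_aif, taus[i]) else base_aif
    studies[[i]] <- make_phantom_study(spec, seed = seeds[i], aif = aif_i)
  }
  list(studies = studies,
       manifest = tibble::tibble(study = seq_len(n_studies),
                                 seed = seeds, tau = taus))
}
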