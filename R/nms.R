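# --- internal fitting machinery -------------------------------------------

# precompute the design vectors shared by every voxel of a study
.nms_precomp <- function(aif) {
  times <- aif$times
  b1 <- aif$c_aif / (1 - aif$hct)
  b2 <- exp_convolution(times, aif$c_aif, kep = 0) / (60 * (1 - aif$hct))
  basis3 <- function(kep)
    exp_convolution(times, aif$c_aif, kep = kep) / (60 * (1 - aif$hct))
  list(times = times, b1 = b1, b2 = b2, basis3 = basis3)
}

.lin2 <- function(y, c1, c2, intercept = FALSE) {
  # exact linear least squares of y on (c1, c2) with optional nuisance
  # intercept (handled by mean-centering); returns coefficients of c1, c2
  if (intercept) {
    y <- y - mean(y); c1 <- c1 - mean(c1); c2 <- c2 - mean(c2)
  }
  a11 <- sum(c1 * c1); a12 <- sum(c1 * c2); a22 <- sum(c2 * c2)
  g1 <- sum(c1 * y); g2 <- sum(c2 * y)
  det <- a11 * a22 - a12 * a12
  if (det <= .Machine$double.eps * a11 * a22) {
    cf <- c(if (a11 > 0) g1 / a11 else 0, 0)
  } else {
    cf <- c((a22 * g1 - a12 * g2) / det, (a11 * g2 - a12 * g1) / det)
  }
  list(coef = cf, rss = max(0, sum(y * y) - cf[1] * g1 - cf[2] * g2))
}

.lin1 <- function(y, c1, intercept = FALSE) {
  if (intercept) {
    y <- y - mean(y); c1 <- c1 - mean(c1)
  }
  ss <- sum(c1 * c1)
  cf <- if (ss > 0) sum(y * c1) / ss else 0
  list(coef = cf, rss = max(0, sum(y * y) - cf^2 * ss))
}

.fit_model3 <- function(y, keep, pre, kep_grid, n_restarts, control,
                        intercept = FALSE) {
  b1 <- pre$b1[keep]
  if (intercept) {
    y <- y - mean(y); b1 <- b1 - mean(b1)
  }
  bas3 <- function(kep) {
    b <- pre$basis3(kep)[keep]
    if (intercept) b - mean(b) else b
  }
  best <- NULL
  for (kep in kep_grid) {
    lf <- .lin2(y, b1, bas3(kep))
    if (is.null(best) || lf$rss < best$rss)
      best <- list(par = c(lf$coef, kep), rss = lf$rss)
  }
  # profile the only nonlinear parameter, then polish all three by simplex
  prss <- function(kep) .lin2(y, b1, bas3(kep))$rss
  i0 <- which(kep_grid == best$par[3])
  lo <- if (i0 > 1) kep_grid[i0 - 1] else 0
  hi <- if (i0 < length(kep_grid)) kep_grid[i0 + 1] else 2 * kep_grid[i0]
  op <- stats::optimize(prss, c(lo, hi), tol = 1e-7)
  kep0 <- op$minimum
  lf0 <- .lin2(y, b1, bas3(kep0))
  start0 <- c(lf0$coef, kep0)
  obj <- function(p) {
    if (p[3] < 0) return(1e30 * (1 - p[3]))
    sum((y - p[1] * b1 - p[2] * bas3(p[3]))^2)
  }
  starts <- list(start0)
  if (n_restarts > 0)
    for (j in seq_len(n_restarts))
      starts[[j + 1]] <- start0 * (1 + c(0.2, -0.2, 0.3) * j) + 1e-9
  out <- NULL
  for (st in starts) {
    o <- optim(st, obj, method = "Nelder-Mead", control = control)
    if (is.null(out) || o$value < out$value) out <- o
  }
  if (lf0$rss < out$value) out <- list(par = start0, value = lf0$rss,
                                       convergence = 0)
  # the nested kep = 0 (Patlak) solution caps the rss from above
  lf2 <- .lin2(y, b1, if (intercept) pre$b2[keep] - mean(pre$b2[keep])
                      else pre$b2[keep])
  if (lf2$rss <= out$value)
    return(list(par = c(lf2$coef, 0), rss = lf2$rss,
                converged = out$convergence == 0))
  list(par = out$par, rss = out$value, converged = out$convergence == 0)
}

#' Fit one nested pharmacokinetic model to a concentration curve
#'
#' Least-squares fit of Model 1, 2 or 3 (see [ctissue()]) to a voxel dR1
#' curve. Models 1 and 2 are linear in their parameters, so their exact
#' optima come from closed-form linear least squares; Model 3 is minimized
#' over `(vp, ktrans, kep)` by profiling the only nonlinear parameter
#' (`kep`, golden-section over a bracketing grid with a closed-form linear
#' solve at each candidate) followed by a Nelder-Mead simplex polish of all
#' three parameters, with optional jittered restarts. Because Model 3 nests
#' Model 2 which nests Model 1, the returned residual sums of squares are
#' monotone non-increasing with model order by construction (the nested
#' `kep = 0` solution caps the Model-3 rss). `method = "simplex"` forces a
#' pure simplex fit for every model and is used as a cross-check of the
#' closed-form solutions.
#'
#' @param curve Numeric vector: tissue dR1 on the AIF grid (s^-1). `NA`
#'   frames are dropped from the fit.
#' @param aif An [aif_trace()].
#' @param model Integer 1, 2 or 3.
#' @param method `"auto"` (closed-form where linear) or `"simplex"`.
#' @param kep_grid Candidate back-flux rates (min^-1) bracketing the
#'   Model-3 profile search.
#' @param n_restarts Jittered simplex restarts for Model 3 (default 1).
#' @param control Passed to [stats::optim()].
#'
#' @return A list with `params` ([pk_params()]), `rss`, `n_points`,
#'   `converged`.
#' @export
fit_pk_model <- function(curve, aif, model, method = c("auto", "simplex"),
                         kep_grid = c(0.02, 0.05, 0.1, 0.2, 0.5, 1),
                         n_restarts = 1, intercept = FALSE,
                         control = list(reltol = 1e-10, maxit = 400)) {
  method <- match.arg(method)
  stopifnot(inherits(aif, "aif_trace"), model %in% 1:3)
  keep <- is.finite(curve)
  y <- curve[keep]
  n <- length(y)
  if (n < 4) stop("need at least 4 finite points to fit")
  pre <- .nms_precomp(aif)
  b1 <- pre$b1[keep]

  if (model == 1) {
    if (all(b1 == 0)) stop("AIF is identically zero")
    lf <- .lin1(y, b1, intercept = intercept)
    if (method == "simplex") {
      obj <- function(p) {
        r <- y - p * b1
        if (intercept) r <- r - mean(r)
        sum(r^2)
      }
      o <- optim(lf$coef * 1.2 + 1e-6, obj, method = "Nelder-Mead",
                 control = c(control, warn.1d.NelderMead = FALSE))
      return(list(params = pk_params(o$par), rss = o$value, n_points = n,
                  converged = o$convergence == 0))
    }
    return(list(params = pk_params(lf$coef), rss = lf$rss, n_points = n,
                converged = TRUE))
  }

  if (model == 2) {
    lf <- .lin2(y, b1, pre$b2[keep], intercept = intercept)
    if (method == "simplex") {
      b2 <- pre$b2[keep]
      obj <- function(p) {
        r <- y - p[1] * b1 - p[2] * b2
        if (intercept) r <- r - mean(r)
        sum(r^2)
      }
      o <- optim(lf$coef * 1.1 + 1e-6, obj,
                 method = "Nelder-Mead", control = control)
      return(list(params = pk_params(o$par[1], o$par[2]), rss = o$value,
                  n_points = n, converged = o$convergence == 0))
    }
    return(list(params = pk_params(lf$coef[1], lf$coef[2]), rss = lf$rss,
                n_points = n, converged = TRUE))
  }

  f3 <- .fit_model3(y, keep, pre, kep_grid, n_restarts, control,
                    intercept = intercept)
  list(params = pk_params(f3$par[1], f3$par[2], f3$par[3]), rss = f3$rss,
       n_points = n, converged = f3$converged)
}

#' Sequential F-test nested model selection
#'
#' Forward sequential F-tests at confidence `1 - alpha`: Model 2 is accepted
#' over Model 1 iff `F = (rss1 - rss2) / (rss2 / (n - 2))` exceeds the upper
#' `1 - alpha` quantile of `F(1, n - 2)`; if accepted, Model 3 vs Model 2 is
#' tested analogously with `F(1, n - 3)`. Negative rss differences
#' (optimizer noise) are clipped to zero. An improvement smaller than
#' `rss_tol` times the curve's total sum of squares (`tss`) is treated as no
#' evidence of the richer model — this guards the noise-free 0/0 case, where
#' both residuals are numerically zero and the voxel belongs with the
#' reduced model.
#'
#' @param rss1,rss2,rss3 Residual sums of squares of the three fits.
#' @param n_points Number of fitted frames.
#' @param alpha Test size (default 0.05).
#' @param rss_tol Relative degenerate-fit guard (default 1e-9).
#' @param tss Scale for the guard: total sum of squares of the fitted curve
#'   (defaults to `rss1`, the Model-1 residual, when not supplied).
#' @param extra_params Number of nuisance parameters shared by all three
#'   fits (e.g. 1 when each model carries a fitted intercept); shifts the
#'   denominator degrees of freedom accordingly.
#'
#' @return Integer model label 1, 2 or 3.
#' @export
f_test_select <- function(rss1, rss2, rss3, n_points, alpha = 0.05,
                          rss_tol = 1e-9, tss = NULL, extra_params = 0) {
  stopifnot(n_points > 3 + extra_params, is.finite(rss1), is.finite(rss2),
            is.finite(rss3), rss1 >= 0, rss2 >= 0, rss3 >= 0)
  scale <- (tss %||% rss1) + .Machine$double.xmin
  df2 <- n_points - 2 - extra_params
  df3 <- n_points - 3 - extra_params
  d12 <- max(0, rss1 - rss2)
  if (d12 <= rss_tol * scale) return(1L)
  f12 <- d12 / (rss2 / df2)    # Inf (perfect full fit) escalates
  if (is.nan(f12) || f12 <= qf(1 - alpha, 1, df2)) return(1L)
  d23 <- max(0, rss2 - rss3)
  if (d23 <= rss_tol * scale) return(2L)
  f23 <- d23 / (rss3 / df3)
  if (is.nan(f23) || f23 <= qf(1 - alpha, 1, df3)) return(2L)
  3L
}

#' Voxel-wise nested model selection over a dR1 study
#'
#' Conventional analysis arm: fits Models 1-3 to every unflagged voxel,
#' selects the model by sequential F-tests, and assembles the model-choice
#' map and parametric maps. Models 1 and 2 are solved in closed form
#' (vectorized across voxels); Model 3 runs the profiled-simplex fit of
#' [fit_pk_model()] per voxel. Parameters are masked by estimability:
#' `ktrans` is reported only where the label is >= 2 and `ve` only where the
#' label is 3; non-estimable parameters are absent (`NA`), not zero. Voxels
#' flagged upstream are labeled 0 (outside the model set).
#'
#' @param dr1 Either a `dr1_fit` from [estimate_dr1_study()] or a 4D array
#'   of dR1 values.
#' @param aif An [aif_trace()].
#' @param mask Logical array of voxels to fit (default: unflagged voxels of
#'   the `dr1_fit`, or voxels with < 20% invalid frames for a bare array).
#' @param alpha F-test size.
#' @param intercept Fit a shared nuisance DC offset in every model (default
#'   `TRUE`). Measured dR1 curves carry a small voxel-wise DC error from the
#'   noisy baseline-window sums inside the dual-echo estimator; absorbing it
#'   as an intercept keeps it out of the vascular parameters. The F-test
#'   degrees of freedom are adjusted accordingly.
#' @param kep_grid,n_restarts,control Passed to the Model-3 fitter.
#'
#' @return An object of class `nms_fit`: list with `results` (tibble: voxel
#'   index, coordinates, label, vp, ktrans, kep, ve, rss1-3, n_points,
#'   converged), maps (`label`, `vp`, `ktrans`, `ve`, `kep` arrays),
#'   `alpha`, and `aif`.
#' @export
fit_nms <- function(dr1, aif, mask = NULL, alpha = 0.05, intercept = TRUE,
                    kep_grid = c(0.02, 0.05, 0.1, 0.2, 0.5, 1),
                    n_restarts = 1,
                    control = list(reltol = 1e-10, maxit = 400)) {
  flags <- NULL
  if (inherits(dr1, "dr1_fit")) {
    flags <- dr1$flags
    dr1 <- dr1$dr1
  }
  dims <- dim(dr1)
  stopifnot(length(dims) == 4)
  nvox <- prod(dims[1:3]); nt <- dims[4]
  dm <- matrix(dr1, nvox, nt)
  if (is.null(mask)) {
    mask <- if (!is.null(flags)) flags == 0L else
      array(rowSums(!is.finite(dm)) < 0.2 * nt, dims[1:3])
  }
  idx <- which(as.logical(mask))
  if (!length(idx)) stop("mask is empty")
  co <- arrayInd(idx, dims[1:3])
  pre <- .nms_precomp(aif)

  n <- length(idx)
  lab <- integer(n); vp <- numeric(n); kt <- rep(NA_real_, n)
  kp <- rep(NA_real_, n); ve <- rep(NA_real_, n)
  rss <- matrix(NA_real_, n, 3); npts <- integer(n); conv <- logical(n)
  Y <- dm[idx, , drop = FALSE]
  allfin <- rowSums(!is.finite(Y)) == 0

  for (i in seq_len(n)) {
    yfull <- Y[i, ]
    keep <- if (allfin[i]) rep(TRUE, nt) else is.finite(yfull)
    y <- yfull[keep]
    b1 <- pre$b1[keep]
    npts[i] <- length(y)
    lf1 <- .lin1(y, b1, intercept = intercept)
    vp1 <- lf1$coef
    r1 <- lf1$rss
    lf2 <- .lin2(y, b1, pre$b2[keep], intercept = intercept)
    r2 <- min(lf2$rss, r1)
    f3 <- .fit_model3(y, keep, pre, kep_grid, n_restarts, control,
                      intercept = intercept)
    r3 <- min(f3$rss, r2)
    tss <- if (intercept) sum((y - mean(y))^2) else sum(y * y)
    l <- f_test_select(r1, r2, r3, npts[i], alpha = alpha, tss = tss,
                       extra_params = as.integer(intercept))
    lab[i] <- l
    vp[i] <- switch(l, vp1, lf2$coef[1], f3$par[1])
    if (l >= 2) kt[i] <- if (l == 2) lf2$coef[2] else f3$par[2]
    if (l == 3) {
      kp[i] <- f3$par[3]
      ve[i] <- if (f3$par[3] > 0) f3$par[2] / f3$par[3] else NA_real_
    }
    rss[i, ] <- c(r1, r2, r3)
    conv[i] <- f3$converged
  }

  mk <- function(v) { a <- array(NA_real_, dims[1:3]); a[idx] <- v; a }
  label_map <- array(0L, dims[1:3]); label_map[idx] <- lab
  results <- tibble::tibble(
    voxel = idx, x = co[, 1], y = co[, 2], z = co[, 3],
    label = lab, vp = vp, ktrans = kt, kep = kp, ve = ve,
    rss1 = rss[, 1], rss2 = rss[, 2], rss3 = rss[, 3],
    n_points = npts, converged = conv)
  structure(list(results = results, label = label_map, vp = mk(vp),
                 ktrans = mk(kt), kep = mk(kp), ve = mk(ve),
                 alpha = alpha, aif = aif, dims = dims[1:3]),
            class = "nms_fit")
}

#' @export
print.nms_fit <- function(x, ...) {
  tb <- table(factor(x$results$label, levels = 1:3))
  cat(sprintf("<nms_fit> %d voxels: Model 1 %d | Model 2 %d | Model 3 %d (alpha = %g)\n",
              nrow(x$results), tb[1], tb[2], tb[3], x$alpha))
  invisible(x)
}

#' @rdname fit_nms
#' @param x An `nms_fit`.
#' @param ... Unused.
#' @export
tidy.nms_fit <- function(x, ...) x$results

#' @rdname fit_nms
#' @export
glance.nms_fit <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    n_voxels = nrow(r),
    n_model1 = sum(r$label == 1), n_model2 = sum(r$label == 2),
    n_model3 = sum(r$label == 3),
    median_vp = median(r$vp, na.rm = TRUE),
    median_ktrans = median(r$ktrans, na.rm = TRUE),
    median_ve = median(r$ve, na.rm = TRUE),
    alpha = x$alpha)
}

#' @rdname fit_nms
#' @param object An `nms_fit`.
#' @param slice Slice index to display.
#' @export
autoplot.nms_fit <- function(object, slice = 1, ...) {
  r <- dplyr::filter(object$results, .data$z == slice)
  long <- tidyr::pivot_longer(
    dplyr::select(r, "x", "y", "label", "vp", "ktrans", "ve"),
    cols = c("label", "vp", "ktrans", "ve"),
    names_to = "map", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~map, scales = "free") +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Nested model selection maps (slice %d)", slice))
}
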