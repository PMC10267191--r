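#' Train a single-hidden-layer perceptron by Levenberg-Marquardt
#'
#' Fits a shallow feed-forward network (tanh hidden units, linear output) to
#' a regression target by damped Gauss-Newton on the full residual Jacobian
#' (batch Levenberg-Marquardt). Each epoch solves
#' `(J'J + lambda diag(J'J) + eps I) delta = -J'r` and accepts the step only
#' if the batch MSE decreases, dividing the damping by 10 on acceptance and
#' multiplying by 10 on rejection; accepted steps therefore never increase
#' the training MSE. Targets are standardized internally for conditioning
#' and predictions are returned on the original scale. Training is
#' deterministic given the seed.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Numeric target vector.
#' @param hidden Number of hidden units (>= 1).
#' @param epochs Maximum number of LM epochs.
#' @param seed Seed for the weight initialization.
#' @param classes If `TRUE`, `y` is an ordinal class label (1/2/3 style) and
#'   a per-epoch correct-classification-fraction (CCF) curve is recorded by
#'   rounding predictions to the nearest label; otherwise the score curve is
#'   the training Pearson correlation.
#' @param max_samples Jacobian memory guard: if `nrow(x)` exceeds this, the
#'   training set is subsampled (deterministically from `seed`) with a
#'   warning.
#' @param lambda0 Initial damping.
#' @param stop_epoch Optional early-stop epoch (e.g. from
#'   [ccf_stopping_epoch()] on a previous run); training halts after it.
#' @param tol Stop when the relative MSE improvement over an epoch falls
#'   below this.
#' @param n_init Number of random initializations (derived deterministically
#'   from `seed`); the fit with the lowest final training MSE is kept.
#'   Damped Gauss-Newton descends into the nearest basin, so a handful of
#'   restarts guards against poor initializations on hard targets.
#' @param warn_subsample Warn when the memory guard subsamples (default
#'   `TRUE`; callers that set the cap deliberately pass `FALSE`).
#'
#' @return An object of class `dce_mlp`: weights (`w1`, `b1`, `w2`, `b2`),
#'   target scaling, and `trace` (tibble: epoch, mse, score, lambda,
#'   accepted).
#' @export
train_mlp_lm <- function(x, y, hidden = 10, epochs = 60, seed = 1L,
                         classes = FALSE, max_samples = 4000,
                         lambda0 = 1e-2, stop_epoch = NULL, tol = 1e-10,
                         n_init = 1, warn_subsample = TRUE) {
  if (n_init > 1) {
    fits <- lapply(seq_len(n_init) - 1L, function(k)
      train_mlp_lm(x, y, hidden = hidden, epochs = epochs,
                   seed = seed + 7919L * k, classes = classes,
                   max_samples = max_samples, lambda0 = lambda0,
                   stop_epoch = stop_epoch, tol = tol, n_init = 1,
                   warn_subsample = warn_subsample))
    best <- which.min(vapply(fits, function(f) tail(f$trace$mse, 1),
                             numeric(1)))
    return(fits[[best]])
  }
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), hidden >= 1, all(is.finite(y)),
            all(is.finite(x)))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  if (nrow(x) > max_samples) {
    keep <- sort(sample.int(nrow(x), max_samples))
    if (warn_subsample)
      warning(sprintf("training set subsampled from %d to %d rows", nrow(x),
                      max_samples))
    x <- x[keep, , drop = FALSE]; y <- y[keep]
  }
  n <- nrow(x); d <- ncol(x); h <- as.integer(hidden)
  y_center <- mean(y); y_scale <- sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  ys <- (y - y_center) / y_scale

  w1 <- matrix(runif(h * d, -0.5, 0.5) / sqrt(d), h, d)
  b1 <- runif(h, -0.5, 0.5)
  w2 <- runif(h, -0.5, 0.5) / sqrt(h)
  b2 <- 0
  np <- h * d + h + h + 1

  pack <- function() c(as.numeric(w1), b1, w2, b2)
  unpack <- function(p) {
    w1 <<- matrix(p[1:(h * d)], h, d)
    b1 <<- p[h * d + 1:h]
    w2 <<- p[h * d + h + 1:h]
    b2 <<- p[np]
  }
  fwd <- function(p) {
    W1 <- matrix(p[1:(h * d)], h, d)
    B1 <- p[h * d + 1:h]
    W2 <- p[h * d + h + 1:h]
    B2 <- p[np]
    z <- tanh(sweep(x %*% t(W1), 2, B1, "+"))
    list(z = z, yhat = as.numeric(z %*% W2 + B2))
  }

  p <- pack()
  f <- fwd(p)
  r <- f$yhat - ys
  mse <- mean(r^2)
  lambda <- lambda0
  score_of <- function(yhat_s) {
    yhat <- yhat_s * y_scale + y_center
    if (classes) {
      lv <- sort(unique(y))
      pred <- lv[pmax(1, pmin(length(lv), round(yhat - min(lv)) + 1))]
      mean(pred == y)
    } else {
      if (sd(yhat) == 0 || sd(y) == 0) 0 else cor(yhat, y)
    }
  }
  trace <- vector("list", epochs)
  max_ep <- if (is.null(stop_epoch)) epochs else min(epochs, stop_epoch)

  for (ep in seq_len(max_ep)) {
    z <- f$z
    dz <- (1 - z^2)
    g <- sweep(dz, 2, p[h * d + h + 1:h], "*")   # N x h: w2_j (1 - z_j^2)
    # w1 is packed column-major (h x d), so column m = (k-1)*h + j of the
    # Jacobian is dyhat/dw1[j,k] = w2_j (1 - z_j^2) x_k
    jw1 <- g[, rep(seq_len(h), d), drop = FALSE] *
      x[, rep(seq_len(d), each = h), drop = FALSE]
    J <- cbind(jw1, g, z, rep(1, n))
    A <- crossprod(J)
    gvec <- crossprod(J, r)
    accepted <- FALSE
    for (try in 1:30) {
      M <- A
      diag(M) <- diag(A) * (1 + lambda) + 1e-12
      delta <- tryCatch(solve(M, -gvec), error = function(e) NULL)
      if (!is.null(delta)) {
        p_new <- p + as.numeric(delta)
        f_new <- fwd(p_new)
        r_new <- f_new$yhat - ys
        mse_new <- mean(r_new^2)
        if (is.finite(mse_new) && mse_new < mse) {
          p <- p_new; f <- f_new; r <- r_new
          improve <- (mse - mse_new) / max(mse, .Machine$double.xmin)
          mse <- mse_new
          lambda <- max(lambda / 10, 1e-13)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    trace[[ep]] <- tibble::tibble(epoch = ep, mse = mse * y_scale^2,
                                  score = score_of(f$yhat),
                                  lambda = lambda, accepted = accepted)
    if (!accepted) break
    if (accepted && improve < tol) break
  }
  unpack(p)
  structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2,
                 y_center = y_center, y_scale = y_scale,
                 hidden = h, d = d, classes = classes, seed = seed,
                 trace = dplyr::bind_rows(trace[!vapply(trace, is.null,
                                                        logical(1))])),
            class = "dce_mlp")
}

#' @export
predict.dce_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  stopifnot(ncol(x) == object$d)
  z <- tanh(sweep(x %*% t(object$w1), 2, object$b1, "+"))
  as.numeric(z %*% object$w2 + object$b2) * object$y_scale + object$y_center
}

#' @export
print.dce_mlp <- function(x, ...) {
  cat(sprintf("<dce_mlp> %d-%d-1 tanh/linear, %d LM epochs, final MSE %.3g\n",
              x$d, x$hidden, nrow(x$trace), tail(x$trace$mse, 1)))
  invisible(x)
}

#' @rdname train_mlp_lm
#' @param x A `dce_mlp`.
#' @param ... Unused.
#' @export
tidy.dce_mlp <- function(x, ...) x$trace

#' @rdname train_mlp_lm
#' @export
glance.dce_mlp <- function(x, ...) {
  tibble::tibble(hidden = x$hidden, n_inputs = x$d,
                 n_weights = x$hidden * (x$d + 2) + 1,
                 epochs = nrow(x$trace),
                 final_mse = tail(x$trace$mse, 1),
                 final_score = tail(x$trace$score, 1))
}

#' Stopping epoch from a saturating score curve
#'
#' Finds the epoch at which a per-epoch score curve (e.g. the correct
#' classification fraction) first comes within 10% of its plateau, after
#' moving-average smoothing. The plateau is the mean of the final 10% of
#' epochs. This reads the "10% of plateau" rule as *within 10% of the
#' plateau value* (i.e. first epoch with smoothed score >= 0.9 x plateau);
#' `rule = "fraction_of_plateau"` gives the alternative literal reading
#' (first epoch >= 0.1 x plateau).
#'
#' @param score Numeric per-epoch curve (length >= 5 for a meaningful
#'   plateau; shorter curves return their last epoch).
#' @param window Moving-average smoothing window (default 3).
#' @param rule `"within_10pct"` (default) or `"fraction_of_plateau"`.
#' @return The stopping epoch (integer).
#' @export
ccf_stopping_epoch <- function(score, window = 3,
                               rule = c("within_10pct", "fraction_of_plateau")) {
  rule <- match.arg(rule)
  n <- length(score)
  if (n < 5) return(n)
  sm <- as.numeric(stats::filter(score, rep(1 / window, window), sides = 2))
  sm[is.na(sm)] <- score[is.na(sm)]
  plateau <- mean(score[max(1, ceiling(0.9 * n)):n])
  thr <- if (rule == "within_10pct") 0.9 * plateau else 0.1 * plateau
  hit <- which(sm >= thr)
  if (!length(hit)) n else hit[1]
}
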