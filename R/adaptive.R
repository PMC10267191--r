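#' Evaluation metrics for regression and classification
#'
#' Standard metric set used to validate the adaptive models: Pearson
#' correlation, adjusted R-squared computed for the single-predictor relation
#' between predictions and truth (`adj R2 = 1 - (1 - R2)(n - 1)/(n - 2)`),
#' rank-based (Mann-Whitney) ROC area with ties averaged, and correct
#' classification fraction `(TP + TN) / total`.
#'
#' @param y_true Numeric truth vector.
#' @param y_pred Numeric predictions (regression metrics).
#' @param scores Numeric scores for the ROC (higher = more positive class).
#' @param labels Logical or two-level vector defining the positive class for
#'   the ROC / CCF.
#' @return `pearson_r()` and `adjusted_r2()` return scalars (`NA` with a
#'   warning when either vector has zero variance); `auc_rank()` the ROC
#'   area; `ccf()` the correct classification fraction.
#' @export
pearson_r <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 3)
  if (sd(y_true) == 0 || sd(y_pred) == 0) {
    warning("zero variance: Pearson r undefined")
    return(NA_real_)
  }
  cor(y_true, y_pred)
}

#' @rdname pearson_r
#' @export
adjusted_r2 <- function(y_true, y_pred) {
  r <- pearson_r(y_true, y_pred)
  n <- length(y_true)
  1 - (1 - r^2) * (n - 1) / (n - 2)
}

#' @rdname pearson_r
#' @export
auc_rank <- function(scores, labels) {
  pos <- as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for AUC")
  rk <- rank(scores)          # ties averaged
  (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname pearson_r
#' @param pred_labels Predicted class labels.
#' @param true_labels True class labels.
#' @export
ccf <- function(pred_labels, true_labels) {
  stopifnot(length(pred_labels) == length(true_labels))
  mean(pred_labels == true_labels)
}

#' Knowledge-based class-separation thresholds
#'
#' For each pair of nested classes, scans every candidate cut point (the
#' midpoints of the sorted unique responses) and picks the cut that maximizes
#' balanced correct classification subject to each class's misclassification
#' rate staying within `tolerance` (default 5%). When no cut satisfies the
#' tolerance, the cut minimizing the larger per-class error is returned and
#' the pair is flagged infeasible. Responses at or above a cut are assigned
#' to the upper class (right-closed convention). Because the pairs are
#' optimized independently, heavily overlapping response distributions can
#' yield cuts violating the nesting order `theta_12 <= theta_13 <=
#' theta_23`; when that happens the cut values are reassigned to the pairs
#' in ascending order (per-class errors recomputed) and the result carries
#' `attr(, "reordered") = TRUE`.
#'
#' @param responses Numeric network responses.
#' @param labels True model labels (1/2/3).
#' @param tolerance Per-class misclassification tolerance.
#' @param pairs Class pairs to separate (default all of 1-2, 1-3, 2-3).
#'
#' @return A tibble with one row per pair: `pair`, `lower`, `upper`,
#'   `theta`, `err_lower`, `err_upper`, `feasible`.
#' @export
optimize_thresholds <- function(responses, labels, tolerance = 0.05,
                                pairs = list(c(1, 2), c(1, 3), c(2, 3))) {
  stopifnot(length(responses) == length(labels), all(is.finite(responses)))
  rows <- lapply(pairs, function(pr) {
    lo <- responses[labels == pr[1]]
    hi <- responses[labels == pr[2]]
    if (!length(lo) || !length(hi))
      stop(sprintf("class pair %d-%d: both classes must be represented",
                   pr[1], pr[2]))
    u <- sort(unique(c(lo, hi)))
    cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
    # right-closed: response >= cut -> upper class
    err_lo <- vapply(cand, function(ct) mean(lo >= ct), numeric(1))
    err_hi <- vapply(cand, function(ct) mean(hi < ct), numeric(1))
    bal <- 1 - (err_lo + err_hi) / 2
    ok <- err_lo <= tolerance & err_hi <= tolerance
    if (any(ok)) {
      i_ok <- which(ok)
      i <- i_ok[which.max(bal[i_ok])]
      feasible <- TRUE
    } else {
      i <- which.min(pmax(err_lo, err_hi))
      feasible <- FALSE
    }
    tibble::tibble(pair = sprintf("%d-%d", pr[1], pr[2]),
                   lower = pr[1], upper = pr[2], theta = cand[i],
                   err_lower = err_lo[i], err_upper = err_hi[i],
                   feasible = feasible)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 1 && is.unsorted(out$theta)) {
    sorted <- sort(out$theta)
    for (i in seq_len(nrow(out))) {
      ct <- sorted[i]
      lo <- responses[labels == out$lower[i]]
      hi <- responses[labels == out$upper[i]]
      out$theta[i] <- ct
      out$err_lower[i] <- mean(lo >= ct)
      out$err_upper[i] <- mean(hi < ct)
      out$feasible[i] <- out$err_lower[i] <= tolerance &&
        out$err_upper[i] <= tolerance
    }
    attr(out, "reordered") <- TRUE
  }
  out
}

#' Classify a network response into a nested model label
#'
#' Decision rule over the continuous model-selection response: label 1 below
#' the 1-2 threshold, label 3 at or above the 2-3 threshold, label 2 in
#' between (intervals right-closed: a response exactly at a threshold takes
#' the upper class). The 1-3 threshold is carried in the threshold table for
#' the optional pairwise scheme but does not enter this default rule.
#'
#' @param response Numeric response(s).
#' @param thresholds Either the tibble from [optimize_thresholds()] or a
#'   named numeric vector with `t12` and `t23`.
#' @return Integer label(s) 1, 2 or 3.
#' @export
classify_nms <- function(response, thresholds) {
  if (is.data.frame(thresholds)) {
    t12 <- thresholds$theta[thresholds$pair == "1-2"]
    t23 <- thresholds$theta[thresholds$pair == "2-3"]
  } else {
    t12 <- thresholds[["t12"]]; t23 <- thresholds[["t23"]]
  }
  # a class absent from training leaves its cut undefined: the decision
  # rule then simply never assigns the missing side
  if (!length(t12) || is.na(t12)) t12 <- -Inf
  if (!length(t23) || is.na(t23)) t23 <- Inf
  stopifnot(length(t12) == 1, length(t23) == 1, t12 <= t23)
  ifelse(response < t12, 1L, ifelse(response < t23, 2L, 3L))
}

#' Train the four-network adaptive bundle
#'
#' Trains the adaptive-model bundle on a voxel table: one shallow network
#' regressing the nested-model label (1/2/3) on the raw-signal features,
#' whose response distribution is then cut by knowledge-based thresholds;
#' and three networks regressing plasma volume, forward transfer constant
#' and extravascular-extracellular fraction. The conventional
#' nested-model-selection results serve as the source of truth. The
#' transfer-constant net trains on voxels whose (by default *predicted*)
#' label is >= 2 and the `ve` net on predicted label 3; empty strata leave
#' that net absent with a flag.
#'
#' @param data Tibble with matrix column `mu` (features), `label` (truth
#'   labels 1/2/3), `vp`, `ktrans`, `ve` (training targets; `NA` where not
#'   estimable).
#' @param hidden_nms,hidden_pk Hidden-layer sizes (defaults 10 and 7).
#' @param epochs Maximum LM epochs per net.
#' @param tolerance Threshold-optimization tolerance.
#' @param mask_source `"predicted"` (default) or `"truth"`: which labels
#'   gate the parameter nets' training strata.
#' @param seed Master seed (per-net seeds derived deterministically).
#' @param max_samples Per-net training-sample cap.
#'
#' @return An object of class `am_bundle`: `nms_net`, `thresholds`,
#'   `pk_nets` (list `vp`, `ktrans`, `ve`; possibly `NULL` with
#'   `missing_nets` naming them), and training provenance.
#' @export
train_adaptive_bundle <- function(data, hidden_nms = 10, hidden_pk = 7,
                                  epochs = 40, tolerance = 0.05,
                                  mask_source = c("predicted", "truth"),
                                  seed = 1L, max_samples = 4000) {
  mask_source <- match.arg(mask_source)
  stopifnot(is.data.frame(data), !is.null(data$mu), !is.null(data$label))
  X <- as.matrix(data$mu)
  lab <- data$label
  nms_net <- train_mlp_lm(X, lab, hidden = hidden_nms, epochs = epochs,
                          seed = seed, classes = TRUE,
                          max_samples = max_samples, warn_subsample = FALSE)
  resp <- predict(nms_net, X)
  pairs <- Filter(function(pr) any(lab == pr[1]) && any(lab == pr[2]),
                  list(c(1, 2), c(1, 3), c(2, 3)))
  if (!length(pairs))
    stop("training labels contain a single class; cannot optimize thresholds")
  thresholds <- optimize_thresholds(resp, lab, tolerance = tolerance,
                                    pairs = pairs)
  pred_lab <- classify_nms(resp, thresholds)
  gate <- if (mask_source == "predicted") pred_lab else lab

  train_param <- function(target, strat, sd_offset) {
    keep <- strat & is.finite(target)
    if (sum(keep) < 20) return(NULL)
    train_mlp_lm(X[keep, , drop = FALSE], target[keep], hidden = hidden_pk,
                 epochs = epochs, seed = seed + sd_offset,
                 max_samples = max_samples, warn_subsample = FALSE)
  }
  pk_nets <- list(
    vp = train_param(data$vp, rep(TRUE, nrow(data)), 1L),
    ktrans = train_param(data$ktrans, gate >= 2, 2L),
    ve = train_param(data$ve, gate == 3, 3L))
  missing <- names(pk_nets)[vapply(pk_nets, is.null, logical(1))]
  structure(list(nms_net = nms_net, thresholds = thresholds,
                 pk_nets = pk_nets, missing_nets = missing,
                 mask_source = mask_source, seed = seed,
                 hidden = c(nms = hidden_nms, pk = hidden_pk)),
            class = "am_bundle")
}

#' @export
print.am_bundle <- function(x, ...) {
  cat(sprintf("<am_bundle> NMS net %d hidden, PK nets %d hidden; thresholds %s\n",
              x$hidden["nms"], x$hidden["pk"],
              paste(sprintf("%s=%.3f", x$thresholds$pair, x$thresholds$theta),
                    collapse = ", ")))
  if (length(x$missing_nets))
    cat("  missing nets:", paste(x$missing_nets, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname train_adaptive_bundle
#' @param x An `am_bundle`.
#' @param ... Unused.
#' @export
tidy.am_bundle <- function(x, ...) x$thresholds

#' Apply an adaptive bundle to feature vectors
#'
#' Predicts the model-choice label and the vascular parameters directly from
#' raw-signal features — no arterial input function is needed at prediction
#' time. Parameters are masked by the predicted label exactly as in the
#' conventional maps: `ktrans` only where the label is >= 2, `ve` only where
#' it is 3.
#'
#' @param bundle An `am_bundle`.
#' @param data Tibble with matrix column `mu` (e.g. from
#'   [featurize_study()]), or a bare feature matrix.
#' @return The input tibble with added columns `response`, `pred_label`,
#'   `pred_vp`, `pred_ktrans`, `pred_ve`.
#' @export
predict_adaptive <- function(bundle, data) {
  stopifnot(inherits(bundle, "am_bundle"))
  X <- if (is.data.frame(data)) as.matrix(data$mu) else as.matrix(data)
  out <- if (is.data.frame(data)) data else tibble::tibble(.rows = nrow(X))
  resp <- predict(bundle$nms_net, X)
  labp <- classify_nms(resp, bundle$thresholds)
  pr <- function(net) if (is.null(net)) rep(NA_real_, nrow(X)) else
    predict(net, X)
  out$response <- resp
  out$pred_label <- labp
  out$pred_vp <- pr(bundle$pk_nets$vp)
  out$pred_ktrans <- ifelse(labp >= 2, pr(bundle$pk_nets$ktrans), NA_real_)
  out$pred_ve <- ifelse(labp == 3, pr(bundle$pk_nets$ve), NA_real_)
  out
}
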