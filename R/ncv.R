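#' Study-level nested cross-validation of the adaptive models
#'
#' Estimates the generalization performance of the adaptive bundle with two
#' independent loops. The outer loop splits the *studies* (never voxels —
#' voxel-level splits leak within-animal structure) into `k_outer` disjoint
#' folds; for each fold the remaining studies form the train+validation
#' cohort. The inner loop runs repeated random-permutation-sampled k-fold
#' cross-validation over that cohort to choose the hidden-layer sizes from
#' the grids and the stopping epoch (from the correct-classification-fraction
#' curve), after which the tuned bundle is retrained on the full
#' train+validation cohort and evaluated once on the held-out fold.
#'
#' @param data Voxel table with columns `study`, matrix column `mu`, training
#'   targets `label`, `vp`, `ktrans`, `ve`, and (optionally) ground-truth
#'   columns `true_label`, `true_vp`, `true_ktrans`, `true_ve` used for an
#'   additional evaluation against simulation truth.
#' @param k_outer Number of outer folds (requires at least that many
#'   studies).
#' @param hidden_grid_nms,hidden_grid_pk Hidden-size candidate grids.
#' @param inner_k,inner_reps Inner-loop folds and random-permutation repeats.
#' @param epochs Maximum LM epochs.
#' @param tolerance Threshold-optimization tolerance.
#' @param max_samples Per-net training cap (voxel subsampling).
#' @param seed Seed controlling fold assignment, permutations and training.
#'
#' @return An object of class `ncv_report`: `folds` (tibble of per-fold
#'   outer metrics), `inner` (chosen hyperparameters per fold),
#'   `predictions` (per-voxel outer-fold predictions), and the fold
#'   assignment (`assignment`).
#' @export
nested_cv <- function(data, k_outer = 10,
                      hidden_grid_nms = c(5, 7, 10, 15),
                      hidden_grid_pk = c(5, 7, 10, 15),
                      inner_k = 5, inner_reps = 3,
                      epochs = 40, tolerance = 0.05,
                      max_samples = 4000, seed = 1L) {
  stopifnot(is.data.frame(data), !is.null(data$study), !is.null(data$mu))
  studies <- sort(unique(data$study))
  if (length(studies) < k_outer)
    stop(sprintf(paste("nested CV needs at least as many studies (%d) as outer",
                       "folds (%d); reduce k_outer or enlarge the cohort"),
                 length(studies), k_outer))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(k_outer), length(studies)))
  assignment <- tibble::tibble(study = studies, fold = fold_of)

  has_truth <- all(c("true_vp", "true_ktrans", "true_ve") %in% names(data))
  fold_rows <- list(); inner_rows <- list(); pred_rows <- list()

  for (fold in seq_len(k_outer)) {
    test_studies <- studies[fold_of == fold]
    train_studies <- setdiff(studies, test_studies)
    stopifnot(length(intersect(train_studies, test_studies)) == 0)
    tr <- data[data$study %in% train_studies, ]
    te <- data[data$study %in% test_studies, ]

    # ---- inner loop: RPS k-fold over the train+validation studies --------
    inner_eval <- function(h, net = c("nms", "vp")) {
      net <- match.arg(net)
      scores <- c(); curves <- list()
      for (rep in seq_len(inner_reps)) {
        perm <- sample(train_studies)
        grp <- rep_len(seq_len(inner_k), length(perm))
        for (kk in seq_len(inner_k)) {
          va_st <- perm[grp == kk]
          tr_st <- setdiff(train_studies, va_st)
          itr <- tr[tr$study %in% tr_st, ]
          iva <- tr[tr$study %in% va_st, ]
          if (!nrow(itr) || !nrow(iva)) next
          if (net == "nms") {
            m <- train_mlp_lm(as.matrix(itr$mu), itr$label, hidden = h,
                              epochs = epochs, seed = seed + fold,
                              classes = TRUE, max_samples = max_samples,
                              warn_subsample = FALSE)
            thr <- optimize_thresholds(predict(m, as.matrix(itr$mu)),
                                       itr$label, tolerance = tolerance)
            pl <- classify_nms(predict(m, as.matrix(iva$mu)), thr)
            scores <- c(scores, ccf(pl, iva$label))
          } else {
            keep <- is.finite(itr$vp)
            m <- train_mlp_lm(as.matrix(itr$mu)[keep, , drop = FALSE],
                              itr$vp[keep], hidden = h, epochs = epochs,
                              seed = seed + fold, max_samples = max_samples,
                              warn_subsample = FALSE)
            kv <- is.finite(iva$vp)
            scores <- c(scores,
                        pearson_r(iva$vp[kv],
                                  predict(m, as.matrix(iva$mu)[kv, , drop = FALSE])))
          }
          curves[[length(curves) + 1]] <- m$trace$score
        }
      }
      nmax <- max(lengths(curves))
      cm <- vapply(curves, function(cv) {
        c(cv, rep(tail(cv, 1), nmax - length(cv)))
      }, numeric(nmax))
      list(score = mean(scores, na.rm = TRUE),
           curve = if (is.matrix(cm)) rowMeans(cm) else cm)
    }

    nms_evals <- lapply(hidden_grid_nms, inner_eval, net = "nms")
    i_nms <- which.max(vapply(nms_evals, `[[`, numeric(1), "score"))
    pk_evals <- lapply(hidden_grid_pk, inner_eval, net = "vp")
    i_pk <- which.max(vapply(pk_evals, `[[`, numeric(1), "score"))
    h_nms <- hidden_grid_nms[i_nms]
    h_pk <- hidden_grid_pk[i_pk]
    stop_ep <- ccf_stopping_epoch(nms_evals[[i_nms]]$curve)

    inner_rows[[fold]] <- tibble::tibble(
      fold = fold, hidden_nms = h_nms, hidden_pk = h_pk,
      stop_epoch = stop_ep,
      inner_ccf = nms_evals[[i_nms]]$score,
      inner_r_vp = pk_evals[[i_pk]]$score)

    # ---- retrain tuned bundle on the full train+validation cohort --------
    bundle <- train_adaptive_bundle(tr, hidden_nms = h_nms, hidden_pk = h_pk,
                                    epochs = epochs, tolerance = tolerance,
                                    seed = seed + 1000L + fold,
                                    max_samples = max_samples)
    pred <- predict_adaptive(bundle, te)
    pred$fold <- fold
    pred_rows[[fold]] <- dplyr::select(pred, -"mu")

    eval_param <- function(truth, est) {
      k <- is.finite(truth) & is.finite(est)
      if (sum(k) < 3 || sd(truth[k]) == 0) return(c(NA_real_, NA_real_))
      c(pearson_r(truth[k], est[k]), adjusted_r2(truth[k], est[k]))
    }
    net_pred <- function(net)
      if (is.null(net)) rep(NA_real_, nrow(te)) else predict(net, as.matrix(te$mu))
    # parameter nets evaluated on the voxels where the target is estimable
    pk_t <- rbind(eval_param(te$vp, pred$pred_vp),
                  eval_param(te$ktrans, net_pred(bundle$pk_nets$ktrans)),
                  eval_param(te$ve, net_pred(bundle$pk_nets$ve)))
    row <- tibble::tibble(
      fold = fold, n_test_voxels = nrow(te),
      n_test_studies = length(test_studies),
      ccf_label = ccf(pred$pred_label, te$label),
      r_label = pearson_r(te$label, pred$response),
      adj_r2_label = adjusted_r2(te$label, pred$response),
      auc_1_v_23 = auc_rank(pred$response, te$label >= 2),
      auc_2_v_3 = if (any(te$label == 2) && any(te$label == 3))
        auc_rank(pred$response[te$label >= 2],
                 te$label[te$label >= 2] == 3) else NA_real_,
      r_vp = pk_t[1, 1], adj_r2_vp = pk_t[1, 2],
      r_ktrans = pk_t[2, 1], adj_r2_ktrans = pk_t[2, 2],
      r_ve = pk_t[3, 1], adj_r2_ve = pk_t[3, 2])
    if (has_truth) {
      row$ccf_true_label <- ccf(pred$pred_label, te$true_label)
      row$r_true_vp <- eval_param(te$true_vp, pred$pred_vp)[1]
      row$r_true_ktrans <- eval_param(te$true_ktrans,
                                      net_pred(bundle$pk_nets$ktrans))[1]
      row$r_true_ve <- eval_param(te$true_ve, net_pred(bundle$pk_nets$ve))[1]
    }
    fold_rows[[fold]] <- row
  }

  structure(list(folds = dplyr::bind_rows(fold_rows),
                 inner = dplyr::bind_rows(inner_rows),
                 predictions = dplyr::bind_rows(pred_rows),
                 assignment = assignment,
                 k_outer = k_outer, seed = seed),
            class = "ncv_report")
}

#' @export
print.ncv_report <- function(x, ...) {
  g <- glance.ncv_report(x)
  cat(sprintf("<ncv_report> %d outer folds; mean outer CCF %.3f, r(vp) %.3f, r(ktrans) %.3f, r(ve) %.3f\n",
              x$k_outer, g$ccf_label, g$r_vp, g$r_ktrans, g$r_ve))
  invisible(x)
}

#' @rdname nested_cv
#' @param x,object An `ncv_report`.
#' @param ... Unused.
#' @export
tidy.ncv_report <- function(x, ...) x$folds

#' @rdname nested_cv
#' @export
glance.ncv_report <- function(x, ...) {
  num <- x$folds[vapply(x$folds, is.numeric, logical(1))]
  num$fold <- NULL
  tibble::as_tibble(as.list(colMeans(num, na.rm = TRUE)))
}

#' @rdname nested_cv
#' @export
autoplot.ncv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$folds, "fold", dplyr::starts_with("r_"),
                  "ccf_label"),
    cols = -"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "outer-fold metric",
                  title = "Nested cross-validation, outer-loop metrics") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
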