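# thresholds, classification, metrics, bundle training

test_that("threshold optimizer equals exhaustive search on random instances", {
  # independent oracle: double loop over candidates and explicit error counts
  oracle <- function(lo, hi, tol) {
    u <- sort(unique(c(lo, hi)))
    cand <- (u[-1] + u[-length(u)]) / 2
    best <- NULL
    for (ct in cand) {
      e_lo <- sum(lo >= ct) / length(lo)
      e_hi <- sum(hi < ct) / length(hi)
      bal <- 1 - (e_lo + e_hi) / 2
      ok <- e_lo <= tol && e_hi <= tol
      if (is.null(best) ||
          (ok && !best$ok) ||
          (ok == best$ok && ok && bal > best$bal) ||
          (!ok && !best$ok && max(e_lo, e_hi) < max(best$e_lo, best$e_hi)))
        best <- list(ct = ct, bal = bal, ok = ok, e_lo = e_lo, e_hi = e_hi)
    }
    best
  }
  set.seed(21)
  for (i in 1:100) {
    n1 <- sample(10:60, 1); n2 <- sample(10:60, 1)
    lo <- rnorm(n1, 1, 0.4); hi <- rnorm(n2, 1 + runif(1, 0.3, 2), 0.4)
    tol <- sample(c(0.05, 0.2, 0.5), 1)
    got <- optimize_thresholds(c(lo, hi), rep(1:2, c(n1, n2)),
                               tolerance = tol, pairs = list(c(1, 2)))
    ref <- oracle(lo, hi, tol)
    expect_equal(got$feasible, ref$ok)
    expect_equal(1 - (got$err_lower + got$err_upper) / 2, ref$bal,
                 tolerance = 1e-12)
  }
})

test_that("perfectly separated classes give the gap midpoint with zero error", {
  lo <- runif(40, 0, 1.4); hi <- runif(40, 1.6, 3)
  got <- optimize_thresholds(c(lo, hi), rep(1:2, each = 40),
                             pairs = list(c(1, 2)))
  expect_true(got$theta > max(lo) && got$theta < min(hi))
  expect_equal(got$err_lower + got$err_upper, 0)
  expect_true(got$feasible)
  expect_error(optimize_thresholds(lo, rep(1, 40), pairs = list(c(1, 2))),
               "represented")
})

test_that("a slack tolerance reduces to the balanced-accuracy cut", {
  set.seed(3)
  lo <- rnorm(80, 1); hi <- rnorm(80, 1.8)
  strict <- optimize_thresholds(c(lo, hi), rep(1:2, each = 80),
                                tolerance = 0.5, pairs = list(c(1, 2)))
  u <- sort(unique(c(lo, hi)))
  cand <- (u[-1] + u[-length(u)]) / 2
  bal <- vapply(cand, function(ct)
    1 - (mean(lo >= ct) + mean(hi < ct)) / 2, numeric(1))
  expect_equal(1 - (strict$err_lower + strict$err_upper) / 2, max(bal),
               tolerance = 1e-12)
})

test_that("the label rule uses right-closed intervals on ordered cuts", {
  thr <- tibble::tibble(pair = c("1-2", "1-3", "2-3"),
                        theta = c(1.73, 1.92, 2.44))
  expect_equal(classify_nms(1.0, thr), 1L)
  expect_equal(classify_nms(2.0, thr), 2L)
  expect_equal(classify_nms(3.0, thr), 3L)
  expect_equal(classify_nms(1.73, thr), 2L)   # boundary takes upper class
  expect_equal(classify_nms(2.44, thr), 3L)
  expect_equal(classify_nms(c(0, 5), thr), c(1L, 3L))
})

test_that("metrics match their definitions and oracles", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(y, y), 1)
  expect_equal(adjusted_r2(y, y), 1)
  n <- length(y)
  r <- pearson_r(y, y + c(0.1, -0.2, 0.05, 0, 0.1))
  expect_equal(adjusted_r2(y, y + c(0.1, -0.2, 0.05, 0, 0.1)),
               1 - (1 - r^2) * (n - 1) / (n - 2))
  expect_warning(pearson_r(rep(1, 5), y), "zero variance")
  expect_equal(auc_rank(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(ccf(c(1, 2, 2), c(1, 2, 3)), 2 / 3)
})

test_that("rank AUC equals the brute-force pair count, ties averaged", {
  set.seed(13)
  scores <- round(rnorm(200), 1)           # forces ties
  labels <- runif(200) > 0.5
  pos <- scores[labels]; neg <- scores[!labels]
  brute <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
  expect_equal(auc_rank(scores, labels), brute, tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(auc_rank(exp(scores), labels), brute, tolerance = 1e-12)
  expect_equal(auc_rank(atan(scores), labels), brute, tolerance = 1e-12)
})

test_that("bundle training is deterministic and masks parameters by label", {
  st <- tiny_study()
  an <- analyze_study(st)
  g <- feature_grid(st$acq$n_frames, l1 = 10, step = 5)
  tab <- build_training_table(st, an$nms, study_id = 1, grid = g)
  b1 <- train_adaptive_bundle(tab, hidden_nms = 4, hidden_pk = 3,
                              epochs = 10, seed = 5, max_samples = 1000)
  b2 <- train_adaptive_bundle(tab, hidden_nms = 4, hidden_pk = 3,
                              epochs = 10, seed = 5, max_samples = 1000)
  expect_identical(b1$nms_net$w1, b2$nms_net$w1)
  expect_identical(b1$thresholds$theta, b2$thresholds$theta)
  expect_true(all(b1$thresholds$theta == sort(b1$thresholds$theta)))
  pred <- predict_adaptive(b1, tab)
  expect_true(all(is.na(pred$pred_ve[pred$pred_label != 3])))
  expect_true(all(is.na(pred$pred_ktrans[pred$pred_label < 2])))
  expect_true(all(is.finite(pred$pred_vp)))
  # prediction needs no AIF: only the feature matrix enters
  pred2 <- predict_adaptive(b1, as.matrix(tab$mu))
  expect_equal(pred2$response, pred$response)
})

test_that("an empty training stratum leaves that net absent and flagged", {
  st <- tiny_study()
  an <- analyze_study(st)
  g <- feature_grid(st$acq$n_frames, l1 = 10, step = 5)
  tab <- build_training_table(st, an$nms, study_id = 1, grid = g)
  tab2 <- tab[tab$label <= 2, ]          # no label-3 voxels at all
  b <- train_adaptive_bundle(tab2, hidden_nms = 3, hidden_pk = 3,
                             epochs = 5, seed = 1,
                             mask_source = "truth")
  expect_true("ve" %in% b$missing_nets)
  p <- predict_adaptive(b, tab2)
  expect_true(all(is.na(p$pred_ve)))
})

test_that("shuffled labels drive held-out discrimination toward chance", {
  # permuted-label negative control at study level: train on five studies
  # with labels shuffled across voxels, evaluate on a held-out study
  dat <- make_small_cohort_table()
  tr <- dat[dat$study <= 5, ]; te <- dat[dat$study == 6, ]
  aucs <- vapply(1:3, function(rep) {
    set.seed(100 + rep)
    trp <- tr
    trp$label <- sample(trp$label)
    net <- train_mlp_lm(as.matrix(trp$mu), trp$label, hidden = 4,
                        epochs = 12, seed = rep, classes = TRUE,
                        max_samples = 1500)
    auc_rank(predict(net, as.matrix(te$mu)), te$label >= 2)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})
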