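test_that("the session-rotation plan is disjoint, exhaustive and balanced", {
  for (k in c(1, 4, 9)) {
    plan <- cross_test_plan(k, 10)
    expect_length(plan, 10L)
    cover <- integer(10)
    for (f in plan) {
      expect_length(f$train, k)
      expect_length(f$test, 10 - k)
      expect_length(intersect(f$train, f$test), 0L)
      expect_setequal(c(f$train, f$test), 1:10)
      cover[f$test] <- cover[f$test] + 1L
    }
    expect_true(all(cover == 10 - k))
  }
  expect_error(cross_test_plan(10, 10), "1\\.\\.9")
  expect_error(cross_test_plan(0, 10), "1\\.\\.9")
})

test_that("confusion matrices are row-normalised tallies", {
  lv <- posture_vocabulary()
  perfect <- confusion_matrix(lv, lv)
  expect_equal(unname(diag(perfect)), rep(100, 12))
  expect_true(all(abs(rowSums(perfect) - 100) < 1e-6))
  # degenerate predictor puts all mass in one column
  degen <- confusion_matrix(rep(lv, 3), rep(lv[1], 36))
  expect_true(all(degen[, 1] == 100))
  expect_true(all(degen[, -1] == 0))
  # random labels against a hand-rolled tally loop
  set.seed(9)
  tr <- sample(lv, 200, replace = TRUE)
  pr <- sample(lv, 200, replace = TRUE)
  got <- confusion_matrix(tr, pr)
  want <- matrix(0, 12, 12, dimnames = list(lv, lv))
  for (i in seq_along(tr)) want[tr[i], pr[i]] <- want[tr[i], pr[i]] + 1
  for (r in seq_len(12)) {
    if (sum(want[r, ]) > 0) want[r, ] <- 100 * want[r, ] / sum(want[r, ])
  }
  expect_equal(unname(got), unname(want), ignore_attr = TRUE)
  # empty true classes are flagged
  part <- confusion_matrix(rep(lv[1:2], 5), rep(lv[1:2], 5))
  expect_setequal(attr(part, "empty_classes"), lv[3:12])
  expect_error(confusion_matrix("fist", "rest"), "unknown labels")
  expect_error(confusion_matrix(lv, lv[1:3]), "length")
})

test_that("training is deterministic and learns separable toy data", {
  set.seed(12)
  x <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 6), 50))
  f <- structure(list(x = cbind(a = x[, 1], b = x[, 2]),
                      posture = rep(c("rest", "spread"), each = 50),
                      session_id = rep(1L, 100), day_id = rep(1L, 100),
                      channel_names = c("a", "b"), feature_set = "mav",
                      R = 0), class = "semg_features")
  m1 <- train_classifier(f, fast_classifier(4L), seed = 42)
  m2 <- train_classifier(f, fast_classifier(4L), seed = 42)
  probe <- matrix(rnorm(40, 3), 20)
  expect_identical(predict(m1, probe), predict(m2, probe))
  expect_identical(m1$net$wts, m2$net$wts)
  expect_equal(mean(predict(m1, f) == f$posture), 1)
  # single-class input is rejected
  f1 <- structure(c(f[-2], list(posture = rep("rest", 100))),
                  class = "semg_features")
  expect_error(train_classifier(f1, fast_classifier(4L)), "2 posture classes")
  expect_error(classifier_spec(hidden_layers = c(8, 8)), "one hidden layer")
  expect_error(classifier_spec(validation_fraction = 0.6), "0, 0.5")
})

test_that("cross-testing aggregates folds without leaking test sessions", {
  set.seed(14)
  sim <- generate_dataset(tiny_config(seed = 15))
  day1 <- Filter(function(r) r$day_id == 1, sim$recordings)
  ev <- cross_test(day1, k = 3, feature_set = "hudgins", R = 2,
                   classifier_spec = fast_classifier(),
                   window_spec = tiny_window_spec(), seed = 2L,
                   n_sessions = 4L)
  expect_s3_class(ev, "semg_eval")
  expect_length(ev$fold_accuracy, 4L)
  expect_equal(ev$mean, mean(ev$fold_accuracy))
  expect_true(all(abs(rowSums(ev$confusion) - 100) < 1e-6))
  # accuracy recomputed from pooled counts equals the reported fold mean
  # only in expectation; the exact identity is per fold and checked via the
  # pooled diagonal against total mass
  expect_equal(100 * sum(diag(ev$pooled_counts)) / sum(ev$pooled_counts),
               mean(ev$fold_accuracy), tolerance = 1e-9)
  # no leakage: training artifacts are bit-identical after corrupting the
  # sessions outside the training fold
  tr_sessions <- c(1, 2)
  train_model <- function(recs) {
    sp <- split_rest(Filter(function(r) r$session_id %in% tr_sessions, recs))
    thr <- calibrate_threshold(sp$rest, 2)
    ftr <- extract_features(segment_dataset(sp$posture, tiny_window_spec()),
                            feature_config("hudgins", R = 2, thresholds = thr))
    train_classifier(ftr, fast_classifier(), seed = 7L)
  }
  corrupted <- lapply(day1, function(r) {
    if (!r$session_id %in% tr_sessions) {
      r$samples[] <- rnorm(length(r$samples), sd = 100)
    }
    r
  })
  m_clean <- train_model(day1)
  m_corr <- train_model(corrupted)
  expect_identical(m_clean$net$wts, m_corr$net$wts)
  expect_identical(m_clean$center, m_corr$center)
  # session-count validation
  expect_error(cross_test(day1, 3, n_sessions = 10L), "exactly 10 sessions")
})

test_that("an oracle classifier yields perfect plumbing metrics", {
  lv <- posture_vocabulary()[1:4]
  truth <- rep(lv, each = 25)
  cm <- confusion_matrix(truth, truth, labels = lv)
  expect_equal(unname(cm), diag(4) * 100, ignore_attr = TRUE)
  acc_direct <- 100 * mean(truth == truth)
  acc_conf <- sum(diag(cm) * as.numeric(table(factor(truth, lv)))) /
    length(truth)
  expect_equal(acc_direct, acc_conf, tolerance = 1e-9)
})

test_that("trial-level majority voting returns one verdict per trial", {
  set.seed(16)
  sim <- generate_dataset(tiny_config(seed = 17))
  day1 <- Filter(function(r) r$day_id == 1, sim$recordings)
  ev <- cross_test(day1, k = 3, feature_set = "mav",
                   classifier_spec = fast_classifier(),
                   window_spec = tiny_window_spec(), seed = 2L,
                   vote = "trial", n_sessions = 4L)
  # one test session per fold x 4 postures = 4 verdicts per fold
  expect_equal(sum(ev$pooled_counts), 16)
})

test_that("accuracy_trend produces one tidy row per evaluation", {
  expect_identical(nrow(accuracy_trend(list())), 0L)
  fake <- structure(list(fold_accuracy = c(90, 96), mean = 93, sd = sqrt(18),
                         confusion = NULL, feature_set = "mav", R = 0,
                         day = 2L, trn_level = 5L, vote = "window"),
                    class = "semg_eval")
  tr <- accuracy_trend(fake)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$day, 2L)
  expect_identical(tr$trn_level, 5L)
  expect_equal(tr$mean, 93)
})
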