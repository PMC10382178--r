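# Evaluation metrics, voting, cross-validation, significance testing

test_that("Brier score, MCR and FDR match hand-computed values", {
  # perfect confident predictions: all three metrics vanish
  truth <- c("healthy", "healthy", "compensatory", "compensatory")
  p <- c(1 - 1e-9, 1 - 1e-9, 1e-9, 1e-9)
  pred <- truth
  m <- classification_metrics(truth, p, pred)
  expect_equal(m$bs, 0, tolerance = 1e-8)
  expect_equal(m$mcr, 0)
  expect_equal(m$fdr, 0)
  expect_equal(m$balanced_accuracy, 1)
  # BS by direct formula: labels (1, 0), confidences (0.8, 0.4) -> 0.10
  m2 <- classification_metrics(c("healthy", "compensatory"), c(0.8, 0.4),
                               c("healthy", "compensatory"))
  # healthy class: (1 - 0.8)^2 = 0.04; compensatory: (1 - 0.6)^2 = 0.16
  expect_equal(m2$per_class$healthy$bs, 0.04)
  expect_equal(m2$per_class$compensatory$bs, 0.16)
  expect_equal(m2$bs, 0.10)
})

test_that("MCR and FDR are the recall and precision complements", {
  # confusion for healthy: TP = 8, FN = 2, FP = 2 -> MCR = FDR = 0.2
  truth <- c(rep("healthy", 10), rep("compensatory", 10))
  pred <- c(rep("healthy", 8), rep("compensatory", 2),
            rep("compensatory", 8), rep("healthy", 2))
  p <- ifelse(pred == "healthy", 0.9, 0.1)
  m <- classification_metrics(truth, p, pred)
  expect_equal(m$per_class$healthy$mcr, 0.2)
  expect_equal(m$per_class$healthy$fdr, 0.2)
  # symmetric confusion: balanced values equal the per-class ones
  expect_equal(m$mcr, 0.2)
  expect_equal(m$fdr, 0.2)
  # MCR + recall = 1 and FDR + precision = 1 on random confusions
  set.seed(17)
  truth_r <- sample(c("healthy", "compensatory"), 200, replace = TRUE)
  pred_r <- sample(c("healthy", "compensatory"), 200, replace = TRUE)
  mr <- classification_metrics(truth_r, runif(200, 0.01, 0.99), pred_r)
  recall_h <- mean(pred_r[truth_r == "healthy"] == "healthy")
  prec_h <- mean(truth_r[pred_r == "healthy"] == "healthy")
  expect_equal(mr$per_class$healthy$mcr + recall_h, 1)
  expect_equal(mr$per_class$healthy$fdr + prec_h, 1)
  # balanced mode requires both classes
  expect_error(classification_metrics(rep("healthy", 5), runif(5, 0.4, 0.6),
                                      rep("healthy", 5)), "compensatory")
})

test_that("trajectory voting takes the majority with compensatory ties", {
  pr <- data.frame(
    trajectory = c("a", "a", "a", "b", "b", "c"),
    label = c("compensatory", "compensatory", "healthy",
              "compensatory", "healthy", "healthy"),
    p = c(0.2, 0.3, 0.6, 0.4, 0.6, 0.9),
    truth = c(rep("compensatory", 5), "healthy"))
  v <- trajectory_vote(pr)
  expect_identical(as.character(v$vote[v$trajectory == "a"]), "compensatory")
  expect_identical(as.character(v$vote[v$trajectory == "b"]), "compensatory") # tie
  expect_identical(as.character(v$vote[v$trajectory == "c"]), "healthy")
  expect_equal(v$p[v$trajectory == "a"], mean(c(0.2, 0.3, 0.6)))
})

test_that("quartile balanced accuracy bins by elapsed fraction", {
  truth <- rep(c("healthy", "compensatory"), 8)
  pred <- truth
  frac <- rep(c(0.1, 0.3, 0.6, 1.0), each = 4)
  q <- quartile_balanced_accuracy(truth, pred, frac)
  expect_equal(q$balanced_accuracy, rep(1, 4))    # all correct, all bins
  expect_identical(q$n, rep(4L, 4))
  # healthy accuracy 1.0, compensatory 0.5 -> BA 0.75
  truth2 <- c("healthy", "healthy", "compensatory", "compensatory")
  pred2 <- c("healthy", "healthy", "compensatory", "healthy")
  q2 <- quartile_balanced_accuracy(truth2, pred2, rep(0.1, 4))
  expect_equal(q2$balanced_accuracy[1], 0.75)
  # fraction exactly 1 falls in the right-closed last bin
  q3 <- quartile_balanced_accuracy(c("healthy", "compensatory"),
                                   c("healthy", "compensatory"), c(1, 1))
  expect_identical(q3$n[4], 2L)
  # a bin missing one class is flagged undefined, not dropped
  q4 <- quartile_balanced_accuracy("healthy", "healthy", 0.1)
  expect_false(q4$defined[1])
  expect_true(is.na(q4$balanced_accuracy[1]))
  expect_identical(nrow(q4), 4L)
})

test_that("McNemar statistic and Holm adjustment match hand computation", {
  # b = 10, c = 0: chi^2 = (10 - 1)^2 / 10 = 8.1
  a <- c(rep(TRUE, 10), rep(TRUE, 20))
  b <- c(rep(FALSE, 10), rep(TRUE, 20))
  r <- mcnemar_test(a, b, exact = FALSE)
  expect_equal(r$statistic, 8.1)
  expect_equal(r$b, 10L)
  # b = c = 5: chi^2 = (0 - 1)^2 / 10 = 0.1
  a2 <- c(rep(TRUE, 5), rep(FALSE, 5))
  b2 <- c(rep(FALSE, 5), rep(TRUE, 5))
  r2 <- mcnemar_test(a2, b2, exact = FALSE)
  expect_equal(r2$statistic, 0.1)
  # symmetric under swapping the models (b and c exchange)
  r2s <- mcnemar_test(b2, a2, exact = FALSE)
  expect_equal(r2s$statistic, r2$statistic)
  expect_identical(r2s$b, r2$c)
  # agreement with the stats implementation
  tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
  ref <- stats::mcnemar.test(tab, correct = TRUE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, unname(ref$p.value))
  # no discordant pairs: undefined, reported as such
  r0 <- mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_false(r0$defined)
  # Holm on raw p-values (0.01, 0.04) in a family of 2 -> (0.02, 0.04)
  expect_equal(stats::p.adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  fam <- mcnemar_holm(list(one = list(a, b), two = list(a2, b2)), exact = FALSE)
  expect_equal(fam$p_holm, stats::p.adjust(fam$p_value, "holm"))
  expect_true(all(fam$p_holm >= fam$p_value))
})

test_that("calibration curves recover calibrated classifiers", {
  # all confidences 0.5, half the labels positive: one bin on the ideal line
  c1 <- calibration_curve(rep(c(1, 0), 50), rep(0.5, 100))
  expect_identical(nrow(c1), 1L)
  expect_equal(c1$mean_predicted, 0.5)
  expect_equal(c1$empirical_frequency, 0.5)
  # n_bins = 1 collapses to overall mean confidence and positive rate
  set.seed(18)
  p <- runif(500, 0.01, 0.99)
  y <- rbinom(500, 1, p)
  cb1 <- calibration_curve(y, p, n_bins = 1)
  expect_equal(cb1$mean_predicted, mean(p))
  expect_equal(cb1$empirical_frequency, mean(y))
  # perfectly calibrated draws converge to the identity line
  set.seed(19)
  p2 <- runif(1e5, 0.01, 0.99)
  y2 <- rbinom(1e5, 1, p2)
  cb <- calibration_curve(y2, p2, n_bins = 10)
  expect_lt(max(abs(cb$mean_predicted - cb$empirical_frequency)), 0.02)
})

test_that("LOOCV folds partition trajectories by participant without leakage", {
  d <- generate_dataset(small_design(n_participants = 3, n_repetitions = 1),
                        seed = 22)
  fd <- build_frame_dataset(d)
  folds <- loocv_folds(fd$participant)
  expect_length(folds, 3)
  all_test <- unlist(lapply(folds, `[[`, "test_idx"))
  expect_identical(sort(all_test), seq_along(fd$participant))  # disjoint cover
  cv <- loocv_train_predict(fd, method = "lr")
  # every trajectory predicted exactly once
  expect_setequal(unique(cv$predictions$trajectory), d$manifest$id)
  by_traj <- table(unique(cv$predictions[c("trajectory", "fold")])$trajectory)
  expect_true(all(by_traj == 1))
  # fold-local scalers differ across heterogeneous participants
  mins <- sapply(cv$models, function(m) m$scaler$min)
  expect_gt(max(apply(mins, 1, function(r) diff(range(r)))), 0)
  expect_error(loocv_folds(rep(1, 5)), "2 participants")
})
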