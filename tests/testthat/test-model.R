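# Linear compensation classifiers

test_that("both methods separate well-separated clusters perfectly", {
  cl <- fixture_clusters(n = 50, seed = 2)
  for (m in c("lr", "svm")) {
    fit <- fit_compensation_model(cl$x, cl$y, method = m)
    pr <- predict(fit, cl$x)
    expect_identical(as.character(pr$label), cl$y)
    # margin check: decision values carry the correct sign on every point
    expect_true(all(pr$decision[cl$y == "healthy"] >= 0))
    expect_true(all(pr$decision[cl$y == "compensatory"] < 0))
  }
})

test_that("the decision rule follows the sign convention with healthy ties", {
  cl <- fixture_clusters(n = 30, seed = 3)
  fit <- fit_compensation_model(cl$x, cl$y, method = "lr")
  # construct feature vectors giving exact decision values
  fit0 <- fit
  fit0$w[] <- 0
  fit0$b <- -0.5
  pr <- predict(fit0, cl$x[1, ])
  expect_identical(as.character(pr$label), "compensatory")  # d < 0
  fit0$b <- 0
  pr0 <- predict(fit0, cl$x[1, ])
  expect_identical(as.character(pr0$label), "healthy")      # tie d = 0
  expect_equal(pr0$p, 0.5)                                  # plogis(0)
  # label from sign of d always agrees with thresholding p at 0.5 (LR)
  prs <- predict(fit, cl$x)
  expect_identical(prs$label == "healthy", prs$p >= 0.5)
})

test_that("overwhelming regularization shrinks the weights to zero", {
  cl <- fixture_clusters(n = 40, seed = 4)
  fit <- fit_compensation_model(cl$x, cl$y, method = "lr", lambda = 1e6)
  expect_lt(sqrt(sum(fit$w^2)), 1e-3)
})

test_that("duplicating every record leaves the boundary essentially unchanged", {
  set.seed(9)
  n <- 80
  # overlapping clusters so the fit is regularization-stable
  X <- matrix(runif(2 * n * 40, 0, 0.3), 2 * n, 40,
              dimnames = list(NULL, feature_names()))
  X[seq_len(n), 1] <- runif(n, 0, 0.45)
  X[n + seq_len(n), 1] <- runif(n, 0.35, 0.8)
  y <- rep(c("healthy", "compensatory"), each = n)
  for (m in c("lr", "svm")) {
    f1 <- fit_compensation_model(X, y, method = m)
    f2 <- fit_compensation_model(rbind(X, X), c(y, y), method = m)
    dir1 <- c(f1$w, f1$b) / sqrt(sum(f1$w^2))
    dir2 <- c(f2$w, f2$b) / sqrt(sum(f2$w^2))
    expect_lt(max(abs(dir1 - dir2)), 0.05)
    # predicted labels agree except possibly right at the boundary
    expect_gte(mean(predict(f1, X)$label == predict(f2, X)$label), 0.97)
  }
})

test_that("LR agrees with an independent ridge-logistic fit", {
  skip_if_not_installed("glmnet")
  cl <- fixture_clusters(n = 60, seed = 5, sep = 0.3)
  fit <- fit_compensation_model(cl$x, cl$y, method = "lr", lambda = 2)
  Xn <- transform_minmax(fit$scaler, cl$x)
  # same objective in glmnet parameterization: sum CE + (lambda/2)||w||^2
  # equals N * (mean CE + (lambda/N) * (1/2)||w||^2)
  g <- glmnet::glmnet(Xn, factor(cl$y == "healthy"), family = "binomial",
                      alpha = 0, lambda = 2 / nrow(Xn), standardize = FALSE,
                      thresh = 1e-12)
  expect_equal(unname(fit$w), unname(as.vector(g$beta)), tolerance = 5e-3)
  expect_equal(fit$b, unname(g$a0), tolerance = 5e-3)
})

test_that("normalization absorbs per-feature scale changes", {
  cl <- fixture_clusters(n = 40, seed = 6)
  fit <- fit_compensation_model(cl$x, cl$y, method = "lr")
  scaled <- cl$x
  scaled[, 3] <- scaled[, 3] * 1000
  fit2 <- fit_compensation_model(scaled, cl$y, method = "lr")
  test <- cl$x[c(1, 45, 70), ]
  test2 <- test
  test2[, 3] <- test2[, 3] * 1000
  expect_equal(predict(fit, test)$decision, predict(fit2, test2)$decision,
               tolerance = 1e-5)
})

test_that("degenerate inputs are rejected with clear errors", {
  cl <- fixture_clusters(n = 10, seed = 7)
  expect_error(fit_compensation_model(cl$x[1:10, ], cl$y[1:10]), "both classes")
  bad <- cl$x; bad[1, 1] <- NA
  expect_error(fit_compensation_model(bad, cl$y), "NA")
  fit <- fit_compensation_model(cl$x, cl$y)
  expect_error(predict(fit, cl$x[, 1:10]), "mismatch")
})

test_that("SVM confidences are calibrated into (0, 1)", {
  cl <- fixture_clusters(n = 50, seed = 8, sep = 0.4)
  fit <- fit_compensation_model(cl$x, cl$y, method = "svm")
  expect_false(is.null(fit$calibration))
  pr <- predict(fit, cl$x)
  expect_true(all(pr$p > 0 & pr$p < 1))
  # calibrated probabilities track the class: healthy higher than compensatory
  expect_gt(mean(pr$p[cl$y == "healthy"]), mean(pr$p[cl$y == "compensatory"]))
})

test_that("models serialize to JSON and back", {
  cl <- fixture_clusters(n = 30, seed = 9)
  fit <- fit_compensation_model(cl$x, cl$y, method = "svm")
  path <- tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$w, fit$w, tolerance = 1e-12)
  expect_equal(predict(back, cl$x), predict(fit, cl$x), tolerance = 1e-10)
})

test_that("streaming prediction emits one prediction per frame", {
  d <- generate_dataset(small_design(n_participants = 2, n_repetitions = 1),
                        seed = 15)
  fd <- build_frame_dataset(d)
  fit <- fit_compensation_model(fd)
  tr <- d$trajectories[[1]]
  pr <- predict_stream(fit, tr)
  expect_identical(nrow(pr), nrow(tr$q))
  expect_true(all(!is.na(pr$p)))
  expect_true(all(diff(pr$start) >= 0))
})

test_that("streaming predictions agree with the offline pipeline", {
  d <- generate_dataset(small_design(n_participants = 2, n_repetitions = 2),
                        seed = 16)
  fd <- build_frame_dataset(d)
  fit <- fit_compensation_model(fd)
  # stream a held-in trajectory and compare execution-frame labels with the
  # offline pipeline's
  tr <- d$trajectories[[3]]
  stream <- predict_stream(fit, tr)
  tf <- trajectory_features(tr)
  offline <- predict(fit, as.matrix(tf[, feature_names()]))
  agree <- as.character(stream$label[tf$frame]) == as.character(offline$label)
  # allow disagreement only during the early-segment transient
  expect_gt(mean(agree[tf$frac > 0.25]), 0.95)
})
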