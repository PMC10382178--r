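# Class-balanced evaluation. Per class k: Brier score = mean squared
# difference between the class indicator and the predicted probability of
# k over the samples whose true class is k; MCR = 1 - recall(k);
# FDR = 1 - precision(k). Class-balanced values average the two per-class
# values, counterbalancing the healthy/compensatory imbalance of the
# study design. Balanced accuracy is the mean of the two class accuracies.

#' Classification metrics (Brier score, MCR, FDR)
#'
#' @param truth true labels (factor/character, `"healthy"` /
#'   `"compensatory"`).
#' @param p_healthy predicted probability that each sample is healthy,
#'   in (0, 1).
#' @param pred predicted labels.
#' @param balanced compute per-class values and their mean (default);
#'   errors if a class is absent from `truth`.
#' @return list with per-class `bs`, `mcr`, `fdr` and balanced `bs`,
#'   `mcr`, `fdr`, `balanced_accuracy`.
#' @export
classification_metrics <- function(truth, p_healthy, pred, balanced = TRUE) {
  lv <- c("healthy", "compensatory")
  truth <- factor(as.character(truth), levels = lv)
  pred <- factor(as.character(pred), levels = lv)
  stopifnot(length(truth) == length(p_healthy), length(truth) == length(pred),
            length(truth) > 0)
  if (any(p_healthy <= 0 | p_healthy >= 1))
    stop("confidences must lie strictly in (0, 1)")
  per_class <- lapply(lv, function(k) {
    in_k <- truth == k
    pred_k <- pred == k
    if (balanced && !any(in_k))
      stop("class '", k, "' is absent from the true labels")
    p_k <- if (k == "healthy") p_healthy else 1 - p_healthy
    list(bs = if (any(in_k)) mean((1 - p_k[in_k])^2) else NA_real_,
         mcr = if (any(in_k)) mean(pred[in_k] != k) else NA_real_,
         fdr = if (any(pred_k)) mean(truth[pred_k] != k) else 0,
         acc = if (any(in_k)) mean(pred[in_k] == k) else NA_real_)
  })
  names(per_class) <- lv
  bal <- function(m) mean(c(per_class$healthy[[m]], per_class$compensatory[[m]]))
  list(per_class = per_class,
       bs = bal("bs"), mcr = bal("mcr"), fdr = bal("fdr"),
       balanced_accuracy = bal("acc"))
}

#' Aggregate per-frame predictions to per-trajectory votes
#'
#' Majority vote over each trajectory's frames; an exact tie counts as
#' `"compensatory"` (the cautious call in a screening context). The
#' trajectory confidence is the mean per-frame healthy probability.
#'
#' @param predictions data.frame with columns `trajectory`, `label`
#'   (per-frame prediction), `p` (per-frame healthy probability) and,
#'   optionally, `truth`.
#' @return data.frame with one row per trajectory: `trajectory`, `vote`,
#'   `p` and (if supplied) `truth`.
#' @export
trajectory_vote <- function(predictions) {
  stopifnot(all(c("trajectory", "label", "p") %in% names(predictions)))
  sp <- split(predictions, predictions$trajectory)
  out <- lapply(sp, function(g) {
    n_comp <- sum(g$label == "compensatory")
    vote <- if (n_comp >= nrow(g) - n_comp) "compensatory" else "healthy"
    r <- data.frame(trajectory = g$trajectory[1], vote = vote, p = mean(g$p),
                    stringsAsFactors = FALSE)
    if ("truth" %in% names(g)) r$truth <- as.character(g$truth[1])
    r
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out$vote <- factor(out$vote, levels = c("healthy", "compensatory"))
  if ("truth" %in% names(out))
    out$truth <- factor(out$truth, levels = c("healthy", "compensatory"))
  out
}

#' Balanced accuracy per temporal quartile
#'
#' Frames are binned by the fraction of their segment elapsed so far into
#' \[0,.25), \[.25,.5), \[.5,.75), \[.75,1\] (the last bin is
#' right-closed). Per bin, balanced accuracy is the mean of the healthy
#' and the compensatory frame accuracies; a bin missing one class is
#' flagged undefined (`NA` with `defined = FALSE`) rather than dropped.
#'
#' @param truth,pred per-frame true and predicted labels.
#' @param frac per-frame elapsed segment fraction in \[0, 1\].
#' @return data.frame with `quartile`, `balanced_accuracy`, `n`,
#'   `defined`.
#' @export
quartile_balanced_accuracy <- function(truth, pred, frac) {
  stopifnot(all(frac >= 0 & frac <= 1))
  lv <- c("healthy", "compensatory")
  truth <- factor(as.character(truth), levels = lv)
  pred <- factor(as.character(pred), levels = lv)
  bin <- pmin(floor(frac * 4) + 1L, 4L)
  labs <- c("[0,0.25)", "[0.25,0.5)", "[0.5,0.75)", "[0.75,1]")
  out <- lapply(1:4, function(b) {
    idx <- bin == b
    if (!any(idx))
      return(data.frame(quartile = labs[b], balanced_accuracy = NA_real_,
                        n = 0L, defined = FALSE))
    acc <- vapply(lv, function(k) {
      in_k <- idx & truth == k
      if (!any(in_k)) NA_real_ else mean(pred[in_k] == k)
    }, numeric(1))
    data.frame(quartile = labs[b],
               balanced_accuracy = if (anyNA(acc)) NA_real_ else mean(acc),
               n = sum(idx), defined = !anyNA(acc))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Leave-one-participant-out fold assignments
#'
#' @param participants vector of participant ids (one per frame or
#'   trajectory).
#' @return list of folds, each with `test_participant`, `train_idx`,
#'   `test_idx`.
#' @export
loocv_folds <- function(participants) {
  ps <- sort(unique(participants))
  if (length(ps) < 2L) stop("leave-one-participant-out needs at least 2 participants")
  lapply(ps, function(p)
    list(test_participant = p,
         train_idx = which(participants != p),
         test_idx = which(participants == p)))
}

#' Leave-one-participant-out cross-validated training and prediction
#'
#' One fold per participant. Within each fold the min-max scaler and the
#' model are fitted on the remaining participants only (feature
#' normalization is fold-local, so no test information leaks into it),
#' then every frame of the held-out participant is predicted. Across the
#' folds, every trajectory is predicted exactly once.
#'
#' @param fd a [build_frame_dataset()] result.
#' @param method `"lr"` or `"svm"`.
#' @param ... passed to [fit_compensation_model()].
#' @return object of class `"comp_cv"`: list with `predictions` (frame
#'   data.frame: fold, trajectory, participant, task, condition, truth,
#'   frac, true_dofs, decision, label, p), `models` (per-fold fits),
#'   `fold_metrics` (frame-level balanced metrics per fold), `method`.
#' @export
loocv_train_predict <- function(fd, method = "lr", ...) {
  stopifnot(inherits(fd, "frame_dataset"))
  folds <- loocv_folds(fd$participant)
  preds <- vector("list", length(folds))
  models <- vector("list", length(folds))
  fold_metrics <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    model <- tryCatch(
      fit_compensation_model(fd$features[f$train_idx, , drop = FALSE],
                             fd$label[f$train_idx], method = method, ...),
      error = function(e) stop("fold for participant ", f$test_participant,
                               ": ", conditionMessage(e)))
    models[[i]] <- model
    pr <- predict(model, fd$features[f$test_idx, , drop = FALSE])
    preds[[i]] <- data.frame(
      fold = i, trajectory = fd$trajectory[f$test_idx],
      participant = fd$participant[f$test_idx], task = fd$task[f$test_idx],
      condition = fd$condition[f$test_idx],
      truth = fd$label[f$test_idx], frac = fd$frac[f$test_idx],
      true_dofs = fd$true_dofs[f$test_idx],
      decision = pr$decision, label = pr$label, p = pr$p,
      stringsAsFactors = FALSE)
    m <- classification_metrics(preds[[i]]$truth, preds[[i]]$p, preds[[i]]$label)
    fold_metrics[[i]] <- data.frame(fold = i, participant = f$test_participant,
                                    bs = m$bs, mcr = m$mcr, fdr = m$fdr,
                                    balanced_accuracy = m$balanced_accuracy)
  }
  structure(list(predictions = do.call(rbind, preds),
                 models = models,
                 fold_metrics = do.call(rbind, fold_metrics),
                 method = method),
            class = "comp_cv")
}

#' @export
print.comp_cv <- function(x, ...) {
  cat(sprintf("LOOCV (%s): %d folds, %d frames, frame-level balanced metrics (mean +/- sd):\n",
              toupper(x$method), nrow(x$fold_metrics), nrow(x$predictions)))
  for (m in c("bs", "mcr", "fdr"))
    cat(sprintf("  %s: %.3f +/- %.3f\n", toupper(m), mean(x$fold_metrics[[m]]),
                sd(x$fold_metrics[[m]])))
  invisible(x)
}

#' McNemar's test on paired per-trajectory predictions
#'
#' Discordant counts: `b` = model A correct and model B wrong, `c` = the
#' converse. The continuity-corrected chi-squared statistic
#' `(|b - c| - 1)^2 / (b + c)` (df = 1) is used; when `b + c < 25` the
#' exact binomial form is available. `b + c = 0` leaves the test
#' undefined.
#'
#' @param correct_a,correct_b logical vectors: whether each trajectory was
#'   predicted correctly by models A and B.
#' @param exact use the exact binomial test (`NULL` = automatic: exact
#'   when `b + c < 25`).
#' @param label comparison label carried into the result.
#' @return object of class `"mcnemar_result"`: list with `b`, `c`,
#'   `statistic`, `df`, `p_value`, `method`, `label`, `defined`.
#' @export
mcnemar_test <- function(correct_a, correct_b, exact = NULL, label = "A vs B") {
  stopifnot(length(correct_a) == length(correct_b))
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0L)
    return(structure(list(b = b, c = cc, statistic = NA_real_, df = 1L,
                          p_value = NA_real_, method = "undefined (no discordant pairs)",
                          label = label, defined = FALSE),
                     class = "mcnemar_result"))
  if (is.null(exact)) exact <- (b + cc) < 25L
  if (exact) {
    p <- stats::binom.test(b, b + cc, 0.5)$p.value
    stat <- NA_real_
    method <- "exact binomial"
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "continuity-corrected chi-squared"
  }
  structure(list(b = b, c = cc, statistic = stat, df = 1L, p_value = p,
                 method = method, label = label, defined = TRUE),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("McNemar [%s]: undefined (b = c = 0)\n", x$label))
  } else if (is.na(x$statistic)) {
    cat(sprintf("McNemar [%s]: exact, b = %d, c = %d, p = %.4g\n",
                x$label, x$b, x$c, x$p_value))
  } else {
    cat(sprintf("McNemar [%s]: chi^2(1) = %.3f, b = %d, c = %d, p = %.4g\n",
                x$label, x$statistic, x$b, x$c, x$p_value))
  }
  invisible(x)
}

#' Family of McNemar comparisons with Holm-Bonferroni correction
#'
#' @param comparisons named list; each element is a list/vector pair of
#'   logical correctness vectors `(a, b)`.
#' @param exact passed to [mcnemar_test()].
#' @param alpha significance level (default 0.05).
#' @return data.frame: `label`, `b`, `c`, `statistic`, `p_value`,
#'   `p_holm`, `significant`.
#' @export
mcnemar_holm <- function(comparisons, exact = FALSE, alpha = 0.05) {
  res <- lapply(names(comparisons), function(nm) {
    pair <- comparisons[[nm]]
    mcnemar_test(pair[[1]], pair[[2]], exact = exact, label = nm)
  })
  df <- data.frame(
    label = vapply(res, `[[`, character(1), "label"),
    b = vapply(res, `[[`, integer(1), "b"),
    c = vapply(res, `[[`, integer(1), "c"),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  df$p_holm <- p.adjust(df$p_value, method = "holm")
  df$significant <- !is.na(df$p_holm) & df$p_holm < alpha
  df
}

#' Calibration curve
#'
#' Equal-width probability bins on \[0, 1\]; per bin, the mean predicted
#' probability against the empirical positive frequency. Empty bins are
#' omitted; an ideally calibrated classifier lies on the identity line.
#'
#' @param truth binary outcomes (0/1, logical, or `"healthy"` /
#'   `"compensatory"` labels -- healthy maps to 1 to match the healthy
#'   probability).
#' @param confidence predicted probabilities in (0, 1).
#' @param n_bins number of bins (default 10).
#' @return data.frame: `bin`, `mean_predicted`, `empirical_frequency`,
#'   `n`.
#' @export
calibration_curve <- function(truth, confidence, n_bins = 10) {
  if (is.factor(truth) || is.character(truth))
    truth <- as.numeric(as.character(truth) == "healthy")
  truth <- as.numeric(truth)
  stopifnot(all(truth %in% c(0, 1)), all(confidence > 0 & confidence < 1))
  bin <- pmin(floor(confidence * n_bins) + 1L, n_bins)
  out <- lapply(sort(unique(bin)), function(b) {
    idx <- bin == b
    data.frame(bin = b, mean_predicted = mean(confidence[idx]),
               empirical_frequency = mean(truth[idx]), n = sum(idx))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Plot a calibration curve against the ideal classifier
#'
#' @param curve a [calibration_curve()] result.
#' @param ... passed to [plot()].
#' @export
plot_calibration <- function(curve, ...) {
  plot(curve$mean_predicted, curve$empirical_frequency, type = "b", pch = 19,
       xlim = c(0, 1), ylim = c(0, 1),
       xlab = "mean predicted probability", ylab = "empirical frequency", ...)
  abline(0, 1, lty = 2, col = "grey50")
  legend("topleft", legend = c("model", "ideal classifier"),
         lty = c(1, 2), pch = c(19, NA), col = c("black", "grey50"), bty = "n")
  invisible(curve)
}
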