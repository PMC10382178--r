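# Linear compensation classifiers. Both methods learn the hyperplane
# w . phi + b = 0 over min-max-normalized CAE features, with the decision
# rule
#   w . phi + b <  0  =>  Compensation
#   w . phi + b >= 0  =>  No Compensation (healthy),
# i.e. healthy is the positive class. Logistic regression minimizes the
# L2-penalized cross-entropy (sum over frames + (lambda/2)||w||^2,
# intercept unpenalized) with a quasi-Newton optimizer; the linear SVM
# minimizes 0.5||w||^2 + C * sum of squared hinge losses. Both are capped
# at 5000 iterations. SVM confidences come from a Platt-style sigmoid
# fitted on the training decision values.

#' Build a labeled frame dataset from trajectories
#'
#' Computes execution-phase features for every trajectory and replicates
#' each trajectory's class label onto all of its frames (frames inherit
#' the sparse per-trajectory label). The dataset size is the total number
#' of execution frames.
#'
#' @param dataset a [generate_dataset()] result (or list with
#'   `trajectories` + `manifest`).
#' @param seg_config a [segmentation_config()].
#' @param agg_config an [aggregation_config()].
#' @param cutoff low-pass cutoff, Hz.
#' @return object of class `"frame_dataset"`: list with `features`
#'   (N x 40 matrix, unnormalized), `label` (factor healthy/compensatory),
#'   `trajectory`, `participant`, `task`, `condition`, `frac`,
#'   `true_dofs` (per-frame character of recruited DoFs).
#' @export
build_frame_dataset <- function(dataset, seg_config = segmentation_config(),
                                agg_config = aggregation_config(), cutoff = 6) {
  feats <- vector("list", length(dataset$trajectories))
  meta <- vector("list", length(dataset$trajectories))
  for (i in seq_along(dataset$trajectories)) {
    tr <- dataset$trajectories[[i]]
    tf <- trajectory_features(tr, seg_config, agg_config, cutoff)
    fx <- as.matrix(tf[, feature_names(), drop = FALSE])
    feats[[i]] <- fx
    meta[[i]] <- data.frame(
      trajectory = tr$id %||% names(dataset$trajectories)[i],
      participant = tr$participant, task = tr$task, condition = tr$condition,
      label = tr$y, frac = tf$frac,
      true_dofs = paste(tr$true_compensating_dofs, collapse = ","),
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  structure(
    list(features = do.call(rbind, feats),
         label = factor(meta$label, levels = c("healthy", "compensatory")),
         trajectory = meta$trajectory, participant = meta$participant,
         task = meta$task, condition = meta$condition, frac = meta$frac,
         true_dofs = meta$true_dofs),
    class = "frame_dataset")
}

#' @export
print.frame_dataset <- function(x, ...) {
  cat(sprintf("Labeled frame dataset: %d frames from %d trajectories, %d features\n",
              nrow(x$features), length(unique(x$trajectory)), ncol(x$features)))
  invisible(x)
}

# y in {+1 healthy, -1 compensatory}; X already normalized.
fit_lr <- function(X, y01, lambda, max_iter) {
  n <- nrow(X); p <- ncol(X)
  obj <- function(th) {
    w <- th[-1L]; b <- th[1L]
    eta <- drop(X %*% w) + b
    # log(1+exp(-|eta|)) form for numerical stability
    ll <- sum(pmax(eta, 0) - y01 * eta + log1p(exp(-abs(eta))))
    ll + lambda / 2 * sum(w^2)
  }
  grad <- function(th) {
    w <- th[-1L]; b <- th[1L]
    mu <- plogis(drop(X %*% w) + b)
    r <- mu - y01
    c(sum(r), drop(crossprod(X, r)) + lambda * w)
  }
  fit <- optim(numeric(p + 1L), obj, grad, method = "L-BFGS-B",
               control = list(maxit = max_iter))
  list(w = fit$par[-1L], b = fit$par[1L], value = fit$value,
       converged = fit$convergence == 0L)
}

fit_svm <- function(X, ypm, cost, max_iter) {
  p <- ncol(X)
  obj <- function(th) {
    w <- th[-1L]; b <- th[1L]
    m <- pmax(0, 1 - ypm * (drop(X %*% w) + b))
    0.5 * sum(w^2) + cost * sum(m^2)
  }
  grad <- function(th) {
    w <- th[-1L]; b <- th[1L]
    m <- pmax(0, 1 - ypm * (drop(X %*% w) + b))
    gy <- -2 * cost * m * ypm
    c(sum(gy), w + drop(crossprod(X, gy)))
  }
  fit <- optim(numeric(p + 1L), obj, grad, method = "L-BFGS-B",
               control = list(maxit = max_iter))
  list(w = fit$par[-1L], b = fit$par[1L], value = fit$value,
       converged = fit$convergence == 0L)
}

# Platt-style sigmoid p = plogis(a * d + c) fitted on training decision
# values against the binary labels.
fit_platt <- function(d, y01, max_iter = 200L) {
  obj <- function(th) {
    eta <- th[1L] * d + th[2L]
    sum(pmax(eta, 0) - y01 * eta + log1p(exp(-abs(eta))))
  }
  fit <- optim(c(1, 0), obj, method = "BFGS", control = list(maxit = max_iter))
  list(a = fit$par[1L], c = fit$par[2L])
}

#' Fit a linear compensation classifier
#'
#' The central model-fitting function. Features are min-max normalized:
#' either pass raw features and let the function fit the scaler
#' (`scaler = NULL`), or pass a prefitted scaler (as cross-validation
#' folds must, to avoid leaking test information into the normalization).
#'
#' @param x feature matrix (rows = frames) or a `"frame_dataset"`.
#' @param y class labels (`"healthy"`/`"compensatory"` factor or
#'   character); ignored when `x` is a `"frame_dataset"`.
#' @param method `"lr"` (L2-penalized logistic regression) or `"svm"`
#'   (linear squared-hinge SVM).
#' @param lambda L2 penalty strength for `"lr"`.
#' @param cost data-term weight C for `"svm"`.
#' @param max_iter optimizer iteration cap.
#' @param scaler optional prefitted [fit_minmax()] scaler; fitted on `x`
#'   when `NULL`.
#' @param calibrate fit a Platt sigmoid for SVM confidences (default
#'   `TRUE`; LR probabilities are already `plogis(d)`).
#' @return object of class `"comp_model"` with elements `w` (named weight
#'   vector in [feature_names()] order), `b` (intercept), `method`,
#'   `scaler`, `calibration`, `converged` and the training configuration.
#' @export
fit_compensation_model <- function(x, y = NULL, method = c("lr", "svm"),
                                   lambda = 1, cost = 1, max_iter = 5000L,
                                   scaler = NULL, calibrate = TRUE) {
  method <- match.arg(method)
  if (inherits(x, "frame_dataset")) { y <- x$label; x <- x$features }
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("healthy", "compensatory"))
  if (anyNA(y)) stop("labels must be 'healthy' or 'compensatory'")
  if (nlevels(droplevels(y)) < 2L)
    stop("training data must contain both classes")
  if (anyNA(x) || any(!is.finite(x))) stop("features contain NA or non-finite values")
  if (is.null(scaler)) scaler <- fit_minmax(x)
  X <- transform_minmax(scaler, x)
  y01 <- as.numeric(y == "healthy")       # healthy = positive class
  fit <- if (method == "lr") fit_lr(X, y01, lambda, max_iter)
         else fit_svm(X, 2 * y01 - 1, cost, max_iter)
  w <- setNames(fit$w, colnames(x) %||% feature_names())
  calibration <- NULL
  if (method == "svm" && calibrate) {
    d <- drop(X %*% fit$w) + fit$b
    calibration <- fit_platt(d, y01)
  }
  structure(
    list(w = w, b = fit$b, method = method, lambda = lambda, cost = cost,
         max_iter = max_iter, scaler = scaler, calibration = calibration,
         converged = fit$converged, loss = fit$value,
         n_train = nrow(x)),
    class = "comp_model")
}

#' @export
print.comp_model <- function(x, ...) {
  cat(sprintf("Linear compensation model (%s): %d features, intercept %.4f%s\n",
              toupper(x$method), length(x$w), x$b,
              if (isTRUE(x$converged)) "" else " [optimizer hit iteration cap]"))
  cat("Decision rule: w.phi + b < 0 => Compensation; >= 0 => No Compensation\n")
  invisible(x)
}

#' @export
coef.comp_model <- function(object, ...) c("(Intercept)" = object$b, object$w)

#' @export
summary.comp_model <- function(object, ...) {
  psi_w <- rowSums(matrix(object$w, ncol = 4L, byrow = TRUE))
  names(psi_w) <- comp_dofs()
  out <- list(model = object, per_dof_weight_sum = sort(psi_w))
  class(out) <- "summary.comp_model"
  out
}

#' @export
print.summary.comp_model <- function(x, ...) {
  print(x$model)
  cat("\nPer-DoF weight sums (most negative = most compensation-indicative):\n")
  print(round(x$per_dof_weight_sum, 4))
  invisible(x)
}

#' Predict from a fitted compensation model
#'
#' @param object a [fit_compensation_model()] fit.
#' @param newdata feature matrix (rows = frames) or single feature vector,
#'   in the model's feature order.
#' @param normalized set `TRUE` if `newdata` is already normalized with
#'   the model's scaler; by default the stored scaler is applied.
#' @param ... unused.
#' @return data.frame with `decision` (w.phi + b), `label`
#'   (`"compensatory"` iff decision < 0; the tie decision = 0 is
#'   `"healthy"`), and `p` -- the confidence that the frame is healthy
#'   (`plogis(decision)` for LR, calibrated sigmoid for SVM), in (0, 1).
#' @export
predict.comp_model <- function(object, newdata, normalized = FALSE, ...) {
  one_row <- is.null(dim(newdata))
  X <- if (one_row) matrix(newdata, 1L, dimnames = list(NULL, names(newdata)))
       else as.matrix(newdata)
  if (ncol(X) != length(object$w))
    stop(sprintf("feature count mismatch: model has %d, input has %d",
                 length(object$w), ncol(X)))
  if (!normalized) X <- transform_minmax(object$scaler, X)
  if (is.null(dim(X))) X <- matrix(X, 1L)
  d <- drop(X %*% object$w) + object$b
  p <- if (object$method == "lr" || is.null(object$calibration)) plogis(d)
       else plogis(object$calibration$a * d + object$calibration$c)
  data.frame(decision = d,
             label = factor(ifelse(d < 0, "compensatory", "healthy"),
                            levels = c("healthy", "compensatory")),
             p = pmin(pmax(p, 1e-12), 1 - 1e-12))
}

#' Streaming per-frame prediction
#'
#' Processes a trajectory frame-by-frame: the streaming segmenter tracks
#' the current primitive start; at every recomputation interval the
#' buffered kinematics/dynamics are low-pass filtered, raw metrics are
#' computed over the current segment and aggregated (CAE from the running
#' start), normalized with the training scaler and classified. One
#' prediction is emitted per input frame; between recomputations the most
#' recent feature matrix is reused, matching the periodic-update design of
#' the online segmenter.
#'
#' @param model a [fit_compensation_model()] fit.
#' @param traj a `"motion_trajectory"` streamed frame-by-frame.
#' @param seg_config a [segmentation_config()].
#' @param agg_config an [aggregation_config()].
#' @param cutoff low-pass cutoff, Hz.
#' @param attribution also return the two most-negative-psi DoFs per frame.
#' @return data.frame with one row per frame: `frame`, `start` (current
#'   primitive start), `decision`, `label`, `p`, and (optionally)
#'   `top_dof1`, `top_dof2`.
#' @export
predict_stream <- function(model, traj, seg_config = segmentation_config(),
                           agg_config = aggregation_config(), cutoff = 6,
                           attribution = FALSE) {
  T <- nrow(traj$markers)
  fs <- traj$sample_rate
  seg <- online_segmenter(seg_config, fs)
  cap <- seg$cap
  out <- data.frame(frame = seq_len(T), start = NA_integer_,
                    decision = NA_real_, label = NA_character_, p = NA_real_)
  if (attribution) { out$top_dof1 <- NA_character_; out$top_dof2 <- NA_character_ }
  last_pred <- NULL
  last_attr <- c(NA_character_, NA_character_)
  w_frames <- sg_window_frames(seg_config, fs)
  for (t in seq_len(T)) {
    start <- online_segment_update(seg, traj$markers[t, ])
    due <- t %% seg_config$update_interval == 0L || t == w_frames || t == T
    if (due && t >= max(2L, start + 1L)) {
      lo <- max(start, t - cap + 1L)
      rows <- lo:t
      if (length(rows) >= 2L) {
        filt <- function(m) {
          m <- m[rows, , drop = FALSE]
          if (length(rows) > 3L * 8L) lowpass(m, fs, cutoff = cutoff) else m
        }
        raw <- compute_raw_metrics(filt(traj$q), filt(traj$qd), filt(traj$qdd),
                                   filt(traj$tau), fs)
        agg <- aggregate_features(raw, agg_config, fs)
        phi <- agg[nrow(agg), ]
        last_pred <- predict(model, phi)
        if (attribution) {
          at <- attribute_joints(model, phi)
          last_attr <- at$ranking[1:2]
        }
      }
    }
    out$start[t] <- start
    if (!is.null(last_pred)) {
      out$decision[t] <- last_pred$decision
      out$label[t] <- as.character(last_pred$label)
      out$p[t] <- last_pred$p
    } else {
      # too little history for features yet: undecided, reported healthy-side
      out$decision[t] <- 0; out$label[t] <- "healthy"; out$p[t] <- 0.5
    }
    if (attribution) { out$top_dof1[t] <- last_attr[1]; out$top_dof2[t] <- last_attr[2] }
  }
  out$label <- factor(out$label, levels = c("healthy", "compensatory"))
  out
}

#' Serialize / restore a fitted model as JSON
#'
#' Weights are keyed by feature name so the file is self-describing.
#'
#' @param model a `"comp_model"`.
#' @param path JSON file path.
#' @return `path` (write) / the restored model (read).
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(method = model$method, w = as.list(model$w), b = model$b,
         lambda = model$lambda, cost = model$cost, max_iter = model$max_iter,
         scaler = list(min = as.list(setNames(model$scaler$min, model$scaler$names)),
                       max = as.list(setNames(model$scaler$max, model$scaler$names))),
         calibration = model$calibration, converged = model$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- structure(list(min = unlist(j$scaler$min), max = unlist(j$scaler$max),
                           names = names(j$scaler$min)), class = "minmax_scaler")
  structure(list(w = unlist(j$w), b = j$b, method = j$method, lambda = j$lambda,
                 cost = j$cost, max_iter = j$max_iter, scaler = scaler,
                 calibration = j$calibration, converged = j$converged),
            class = "comp_model")
}
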