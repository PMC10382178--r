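# End-to-end experiments: generate (or load) the dataset, segment,
# extract features, train/predict per LOOCV fold, vote per trajectory,
# evaluate, attribute. Everything is a pure function of (config, seed).

#' Experiment configuration
#'
#' @param design a [study_design()].
#' @param seg a [segmentation_config()].
#' @param agg an [aggregation_config()].
#' @param methods classifier methods to run (subset of `c("lr", "svm")`).
#' @param lambda,cost,max_iter training hyper-parameters, see
#'   [fit_compensation_model()].
#' @param cutoff low-pass cutoff, Hz.
#' @param seed global experiment seed.
#' @return object of class `"experiment_config"` (a plain, serializable
#'   list).
#' @export
experiment_config <- function(design = study_design(),
                              seg = segmentation_config(),
                              agg = aggregation_config(),
                              methods = c("lr", "svm"),
                              lambda = 1, cost = 1, max_iter = 5000L,
                              cutoff = 6, seed = 1) {
  structure(list(design = design, seg = seg, agg = agg, methods = methods,
                 lambda = lambda, cost = cost, max_iter = max_iter,
                 cutoff = cutoff, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the offline experiment
#'
#' Pipeline: generate dataset -> auto-segment -> execution-phase CAE
#' features -> per-fold scaler + classifier (LOOCV by participant) ->
#' per-frame prediction -> per-trajectory vote -> class-balanced metrics
#' and final-frame attribution of compensating DoFs. Reruns with the same
#' config reproduce the report exactly.
#'
#' @param config an [experiment_config()].
#' @param dataset optional pregenerated dataset (skips generation).
#' @param frame_data optional precomputed [build_frame_dataset()] result.
#' @param out_dir optional directory; when given, the manifest, per-fold
#'   models, predictions and the report are written there as JSON/CSV.
#' @return object of class `"comp_experiment"`: list with `config`,
#'   `manifest`, `cv` (per-method `"comp_cv"`), `votes` (per-method
#'   trajectory votes), `metrics` (per-method data.frame of fold-mean
#'   trajectory-level balanced BS/MCR/FDR/balanced accuracy),
#'   `quartile_ba`, `attribution` (per-method top-2 recovery summary).
#' @export
run_offline_experiment <- function(config = experiment_config(), dataset = NULL,
                                   frame_data = NULL, out_dir = NULL) {
  if (is.null(dataset) && is.null(frame_data))
    dataset <- generate_dataset(config$design, config$seed)
  if (is.null(frame_data))
    frame_data <- build_frame_dataset(dataset, config$seg, config$agg, config$cutoff)
  manifest <- if (!is.null(dataset)) dataset$manifest else NULL

  cv <- list(); votes <- list(); metrics <- list(); attribution <- list()
  quart <- list()
  for (m in config$methods) {
    cv[[m]] <- loocv_train_predict(frame_data, method = m, lambda = config$lambda,
                                   cost = config$cost, max_iter = config$max_iter)
    votes[[m]] <- trajectory_vote(cv[[m]]$predictions)
    metrics[[m]] <- fold_vote_metrics(cv[[m]])
    quart[[m]] <- quartile_balanced_accuracy(cv[[m]]$predictions$truth,
                                             cv[[m]]$predictions$label,
                                             cv[[m]]$predictions$frac)
    attribution[[m]] <- attribution_recovery(cv[[m]], frame_data)
  }
  out <- structure(list(config = config, manifest = manifest, cv = cv,
                        votes = votes, metrics = metrics, quartile_ba = quart,
                        attribution = attribution),
                   class = "comp_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

# Trajectory-vote metrics per fold, then mean +/- sd across folds.
fold_vote_metrics <- function(cv) {
  per_fold <- lapply(sort(unique(cv$predictions$fold)), function(f) {
    v <- trajectory_vote(cv$predictions[cv$predictions$fold == f, ])
    m <- classification_metrics(v$truth, v$p, v$vote)
    data.frame(fold = f, bs = m$bs, mcr = m$mcr, fdr = m$fdr,
               balanced_accuracy = m$balanced_accuracy)
  })
  per_fold <- do.call(rbind, per_fold)
  summary <- data.frame(
    metric = c("bs", "mcr", "fdr", "balanced_accuracy"),
    mean = vapply(c("bs", "mcr", "fdr", "balanced_accuracy"),
                  function(k) mean(per_fold[[k]]), numeric(1)),
    sd = vapply(c("bs", "mcr", "fdr", "balanced_accuracy"),
                function(k) sd(per_fold[[k]]), numeric(1)))
  list(per_fold = per_fold, summary = summary)
}

# Share of correctly-classified compensatory trajectories whose injected
# recruited DoF ranks among the two most negative psi at the final
# execution frame (fold-local model and scaler).
attribution_recovery <- function(cv, frame_data) {
  pr <- cv$predictions
  votes <- trajectory_vote(pr)
  comp_ok <- votes$trajectory[votes$truth == "compensatory" &
                                votes$vote == "compensatory"]
  if (!length(comp_ok))
    return(list(rate = NA_real_, n = 0L, hits = 0L))
  hits <- 0L
  for (tid in comp_ok) {
    rows <- which(pr$trajectory == tid)
    last <- rows[which.max(pr$frac[rows])]
    model <- cv$models[[pr$fold[last]]]
    fi <- which(frame_data$trajectory == tid)
    fi_last <- fi[which.max(frame_data$frac[fi])]
    at <- attribute_joints(model, frame_data$features[fi_last, ])
    true_dofs <- strsplit(pr$true_dofs[last], ",", fixed = TRUE)[[1]]
    if (length(intersect(true_dofs, at$ranking[1:2]))) hits <- hits + 1L
  }
  list(rate = hits / length(comp_ok), n = length(comp_ok), hits = hits)
}

#' @export
print.comp_experiment <- function(x, ...) {
  cat("Offline compensation-detection experiment\n")
  if (!is.null(x$manifest))
    cat(sprintf("  dataset: %d trajectories, %d participants\n",
                nrow(x$manifest), length(unique(x$manifest$participant))))
  for (m in names(x$metrics)) {
    s <- x$metrics[[m]]$summary
    cat(sprintf("  %s (trajectory vote, fold mean +/- sd): BS %.3f+/-%.3f, MCR %.3f+/-%.3f, FDR %.3f+/-%.3f, BA %.3f\n",
                toupper(m),
                s$mean[s$metric == "bs"], s$sd[s$metric == "bs"],
                s$mean[s$metric == "mcr"], s$sd[s$metric == "mcr"],
                s$mean[s$metric == "fdr"], s$sd[s$metric == "fdr"],
                s$mean[s$metric == "balanced_accuracy"]))
    a <- x$attribution[[m]]
    if (!is.na(a$rate))
      cat(sprintf("  %s attribution: recruited DoF in top-2 psi for %d/%d (%.0f%%) of correctly classified compensatory trajectories\n",
                  toupper(m), a$hits, a$n, 100 * a$rate))
  }
  invisible(x)
}

write_experiment <- function(exp, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(exp$manifest))
    jsonlite::write_json(exp$manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (m in names(exp$cv)) {
    write.csv(exp$cv[[m]]$predictions,
              file.path(out_dir, paste0("predictions_", m, ".csv")),
              row.names = FALSE)
    jsonlite::write_json(
      list(fold_vote_metrics = exp$metrics[[m]]$per_fold,
           summary = exp$metrics[[m]]$summary,
           attribution = exp$attribution[[m]],
           quartile_ba = exp$quartile_ba[[m]]),
      file.path(out_dir, paste0("report_", m, ".json")),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    for (i in seq_along(exp$cv[[m]]$models))
      write_model(exp$cv[[m]]$models[[i]],
                  file.path(out_dir, sprintf("model_%s_fold%d.json", m, i)))
  }
  invisible(out_dir)
}

#' Run the streaming (online) experiment
#'
#' For each LOOCV fold, the held-out participant's repetitions of each
#' (task, condition) cell are concatenated into one continuous recording
#' and processed frame-by-frame with [predict_stream()], using the
#' fold's trained model. Metrics are computed over execution-phase frames
#' only (participants follow no protocol while returning to the start, so
#' those frames are excluded). `mode = "fixed"` replaces zero-crossing
#' segmentation with contiguous 1-second segments.
#'
#' @param offline a [run_offline_experiment()] result providing the
#'   per-fold models and the dataset design/seed.
#' @param dataset the dataset the offline experiment ran on.
#' @param method classifier to stream (`"lr"` or `"svm"`).
#' @param mode `"auto"` (zero-crossing online segmentation) or `"fixed"`.
#' @param participants subset of participants to stream (default: all).
#' @return object of class `"comp_online"`: list with `predictions`
#'   (execution-frame predictions with truth), `metrics` (balanced
#'   frame-level BS/MCR/FDR), `mode`, `method`.
#' @export
run_online_experiment <- function(offline, dataset, method = "lr",
                                  mode = c("auto", "fixed"),
                                  participants = NULL) {
  mode <- match.arg(mode)
  cfg <- offline$config
  seg <- cfg$seg
  seg$mode <- if (mode == "fixed") "fixed" else "auto"
  man <- dataset$manifest
  ps <- participants %||% sort(unique(man$participant))
  fold_ps <- sort(unique(man$participant))
  out <- list()
  for (p in ps) {
    model <- offline$cv[[method]]$models[[match(p, fold_ps)]]
    cells <- unique(man[man$participant == p, c("task", "condition")])
    for (i in seq_len(nrow(cells))) {
      ids <- man$id[man$participant == p & man$task == cells$task[i] &
                      man$condition == cells$condition[i]]
      stream <- concat_trajectories(dataset$trajectories[ids])
      pr <- predict_stream(model, stream, seg, cfg$agg, cfg$cutoff)
      keep <- stream$phase == "execution"
      out[[length(out) + 1L]] <- data.frame(
        participant = p, task = cells$task[i], condition = cells$condition[i],
        trajectory = stream$frame_trajectory[keep],
        truth = stream$y, frame = pr$frame[keep],
        label = as.character(pr$label[keep]), p = pr$p[keep],
        stringsAsFactors = FALSE)
    }
  }
  preds <- do.call(rbind, out)
  m <- classification_metrics(preds$truth, preds$p, preds$label)
  structure(list(predictions = preds,
                 metrics = data.frame(bs = m$bs, mcr = m$mcr, fdr = m$fdr,
                                      balanced_accuracy = m$balanced_accuracy),
                 mode = mode, method = method),
            class = "comp_online")
}

#' @export
print.comp_online <- function(x, ...) {
  cat(sprintf("Online experiment (%s, %s-seg): %d execution frames\n",
              toupper(x$method), x$mode, nrow(x$predictions)))
  cat(sprintf("  balanced BS %.3f, MCR %.3f, FDR %.3f, BA %.3f\n",
              x$metrics$bs, x$metrics$mcr, x$metrics$fdr,
              x$metrics$balanced_accuracy))
  invisible(x)
}

# Concatenate single-repetition trajectories of one (participant, task,
# condition) cell into a continuous multi-repetition recording. All
# repetitions start and end at the baseline pose, so the joined series
# stays rest-to-rest continuous.
concat_trajectories <- function(trajs) {
  stopifnot(length(trajs) >= 1L)
  t1 <- trajs[[1]]
  bind <- function(f) do.call(rbind, lapply(trajs, `[[`, f))
  Ts <- vapply(trajs, function(tr) nrow(tr$q), integer(1))
  out <- t1
  out$q <- bind("q"); out$qd <- bind("qd"); out$qdd <- bind("qdd")
  out$tau <- bind("tau"); out$markers <- bind("markers")
  out$phase <- unlist(lapply(trajs, `[[`, "phase"), use.names = FALSE)
  out$time <- (seq_len(sum(Ts)) - 1) / t1$sample_rate
  offs <- cumsum(c(0L, Ts[-length(Ts)]))
  out$rest_frames <- unlist(lapply(seq_along(trajs), function(i)
    trajs[[i]]$rest_frames + offs[i]), use.names = FALSE)
  out$frame_trajectory <- unlist(lapply(seq_along(trajs), function(i)
    rep(trajs[[i]]$id %||% i, Ts[i])), use.names = FALSE)
  out$id <- paste0(t1$id %||% "traj", "_stream")
  out
}
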