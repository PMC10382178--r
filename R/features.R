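# Energy-based per-joint features. For each analyzed DoF and frame:
#   jerk = |d3 q / dt3|   (movement smoothness, joint space)
#   pow  = |qd * tau|     (mechanical power)
#   eff  = |d2 tau / dt2| (effort)
#   tr   = |d tau / dt|   (torque rate)
# Metrics are computed per frame, then aggregated over the elapsed
# primitive (cumulative averaging -> CAE features, or a centered window,
# or not at all) and min-max normalized against the training data.

#' Low-pass filter the kinematic and dynamic series of a trajectory
#'
#' Zero-phase Butterworth (order 4) at the given cutoff, applied to `q`,
#' `qd`, `qdd` and `tau` columnwise. Applied once per trajectory before
#' feature extraction; 6 Hz retains voluntary upper-limb movement while
#' suppressing measurement jitter that the double differentiation in the
#' effort/jerk metrics would otherwise amplify.
#'
#' @param traj a `"motion_trajectory"`.
#' @param cutoff cutoff frequency, Hz.
#' @return the trajectory with filtered `q`, `qd`, `qdd`, `tau`.
#' @export
filter_trajectory <- function(traj, cutoff = 6) {
  for (f in c("q", "qd", "qdd", "tau"))
    traj[[f]] <- lowpass(traj[[f]], traj$sample_rate, cutoff = cutoff)
  traj
}

#' Per-frame raw energy metrics
#'
#' Derivatives use the package-wide central-difference scheme
#' ([finite_diff()]): jerk is the derivative of `qdd`, torque rate the
#' derivative of `tau`, effort its second derivative. Alternative
#' definitions (`jerk = |qdd|`, `eff = |tau|`) are selectable for
#' sensitivity analyses.
#'
#' @param q,qd,qdd,tau T x J matrices with matching DoF column names.
#' @param sample_rate sampling rate, Hz.
#' @param jerk `"d3q"` (third angle derivative, default) or `"qdd"`.
#' @param effort `"d2tau"` (second torque derivative, default) or `"tau"`.
#' @return T x (4 J) matrix of non-negative metric values, columns in
#'   [feature_names()] order (DoF-major, metric-minor).
#' @export
compute_raw_metrics <- function(q, qd, qdd, tau, sample_rate,
                                jerk = c("d3q", "qdd"),
                                effort = c("d2tau", "tau")) {
  jerk <- match.arg(jerk); effort <- match.arg(effort)
  q <- as.matrix(q); qd <- as.matrix(qd); qdd <- as.matrix(qdd); tau <- as.matrix(tau)
  if (!identical(dim(q), dim(qd)) || !identical(dim(q), dim(qdd)) ||
      !identical(dim(q), dim(tau)))
    stop("q, qd, qdd, tau must share their shape")
  if (nrow(q) < 2L) stop("need at least 2 frames")
  dofs <- colnames(q)
  if (is.null(dofs)) stop("q must carry DoF column names")
  jm <- abs(if (jerk == "d3q") finite_diff(qdd, sample_rate) else qdd)
  pm <- abs(qd * tau)
  trm <- abs(finite_diff(tau, sample_rate))
  em <- abs(if (effort == "d2tau") finite_diff(finite_diff(tau, sample_rate),
                                               sample_rate) else tau)
  out <- matrix(0, nrow(q), 4L * length(dofs),
                dimnames = list(NULL, feature_names(dofs)))
  for (j in seq_along(dofs)) {
    base <- (j - 1L) * 4L
    out[, base + 1L] <- jm[, j]
    out[, base + 2L] <- pm[, j]
    out[, base + 3L] <- em[, j]
    out[, base + 4L] <- trm[, j]
  }
  out
}

#' Aggregation configuration
#'
#' @param mode `"cae"` (cumulative average from the segment start, the
#'   default), `"windowed"` (mean over a centered window, truncated at the
#'   series boundaries) or `"none"` (per-frame values unchanged).
#' @param window window length in seconds for `"windowed"` mode (0.2 and
#'   1.0 are the standard comparison points).
#' @return object of class `"aggregation_config"`.
#' @export
aggregation_config <- function(mode = c("cae", "windowed", "none"), window = 1.0) {
  mode <- match.arg(mode)
  if (mode == "windowed" && window <= 0) stop("window must be positive")
  structure(list(mode = mode, window = window), class = "aggregation_config")
}

#' Aggregate raw metric series over the elapsed primitive
#'
#' In `"cae"` mode the value at frame `t` is the mean of the raw values
#' from the segment start through `t` (Cumulative Averaged Energy); the
#' value at the final frame equals the whole-segment mean. `"windowed"`
#' averages over a window centered at `t`, shrunk at the boundaries;
#' `"none"` returns the input.
#'
#' @param raw T x F matrix of per-frame raw metrics for one segment
#'   (row 1 = segment start).
#' @param config an [aggregation_config()].
#' @param sample_rate sampling rate, Hz (needed for `"windowed"`).
#' @return matrix of the same shape.
#' @export
aggregate_features <- function(raw, config = aggregation_config(), sample_rate = 100) {
  raw <- as.matrix(raw)
  if (!nrow(raw)) stop("raw series is empty")
  switch(config$mode,
    none = raw,
    cae = {
      cs <- apply(raw, 2, cumsum)
      if (is.null(dim(cs))) cs <- matrix(cs, 1L, dimnames = list(NULL, colnames(raw)))
      cs / seq_len(nrow(raw))
    },
    windowed = {
      half <- max(0L, as.integer(floor(round(config$window * sample_rate) / 2)))
      T <- nrow(raw)
      cs <- apply(raw, 2, function(v) cumsum(c(0, v)))  # (T+1) x F
      lo <- pmax(1L, seq_len(T) - half)
      hi <- pmin(T, seq_len(T) + half)
      (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
    })
}

#' Fit a min-max scaler on training features
#'
#' Per-feature minimum and maximum over every frame of every training
#' trajectory in the fold. Fitting must use training data only; at test
#' time the training min/max are reused, so test values may fall outside
#' \[0, 1\] (no clipping).
#'
#' @param x numeric matrix (rows = frames) or list of such matrices.
#' @return object of class `"minmax_scaler"`.
#' @export
fit_minmax <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (!nrow(x)) stop("cannot fit a scaler on an empty collection")
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max),
                 names = colnames(x)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Per-feature affine map `(x - min) / (max - min)`. A degenerate feature
#' (training `min == max`) maps to 0 for any input -- the feature carries
#' no training information, so it is neutralized rather than divided by
#' zero.
#'
#' @param scaler a [fit_minmax()] result.
#' @param x matrix (or vector treated as one row) with the same feature
#'   columns the scaler was fitted on.
#' @return normalized matrix of the same shape.
#' @export
transform_minmax <- function(scaler, x) {
  one_row <- is.null(dim(x))
  x <- if (one_row) matrix(x, 1L, dimnames = list(NULL, names(x))) else as.matrix(x)
  if (ncol(x) != length(scaler$min))
    stop(sprintf("feature count mismatch: scaler has %d, input has %d",
                 length(scaler$min), ncol(x)))
  if (!is.null(scaler$names) && !is.null(colnames(x)) &&
      !identical(colnames(x), scaler$names))
    stop("feature names do not match the scaler's")
  rng <- scaler$max - scaler$min
  out <- sweep(x, 2, scaler$min) %*% diag(ifelse(rng > 0, 1 / rng, 0), ncol(x))
  out[, rng == 0] <- 0
  colnames(out) <- colnames(x)
  if (one_row) out[1L, ] else out
}

#' Extract aggregated features for the execution segments of a trajectory
#'
#' Full offline per-trajectory pipeline stage: low-pass filter the
#' kinematic/dynamic series, compute raw metrics over the whole
#' trajectory, slice per segment and aggregate from each segment's start.
#' Return-phase segments are excluded from analysis.
#'
#' @param traj a `"motion_trajectory"`.
#' @param seg_config a [segmentation_config()].
#' @param agg_config an [aggregation_config()].
#' @param cutoff low-pass cutoff, Hz.
#' @param segments optional precomputed segment table (from
#'   [segment_offline()]); segmentation is run when omitted.
#' @return data.frame with one row per execution frame: the feature
#'   columns, plus `frame` (absolute), `segment`, `frac` (elapsed fraction
#'   of its segment in \[0,1\]).
#' @export
trajectory_features <- function(traj, seg_config = segmentation_config(),
                                agg_config = aggregation_config(), cutoff = 6,
                                segments = NULL) {
  if (is.null(segments)) segments <- segment_offline(traj, seg_config)
  ft <- filter_trajectory(traj, cutoff = cutoff)
  raw <- compute_raw_metrics(ft$q, ft$qd, ft$qdd, ft$tau, ft$sample_rate)
  ex <- segments[segments$phase == "execution", , drop = FALSE]
  out <- vector("list", nrow(ex))
  for (i in seq_len(nrow(ex))) {
    rows <- ex$start[i]:(ex$end[i] - 1L)
    agg <- aggregate_features(raw[rows, , drop = FALSE], agg_config, traj$sample_rate)
    out[[i]] <- data.frame(agg, frame = rows, segment = i,
                           frac = (rows - ex$start[i]) / max(1L, length(rows) - 1L),
                           check.names = FALSE)
  }
  do.call(rbind, out)
}
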