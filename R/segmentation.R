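# Motion-primitive segmentation by end-effector velocity zero-crossings:
# smooth the marker trajectory (Savitzky-Golay), differentiate, and take
# the frames where speed is (near) zero on all three axes as primitive
# boundaries. Offline over a full trajectory, or streaming over a bounded
# history buffer with periodic recomputation. A fixed-length fallback
# partitions the trajectory into contiguous equal segments.

#' Segmentation configuration
#'
#' @param savgol_window Savitzky-Golay smoothing window in seconds
#'   (default 0.2 s).
#' @param savgol_order Savitzky-Golay polynomial order (default 3,
#'   preserving cubic kinematics).
#' @param rest_tol rest speed tolerance `eps_v` in m/s: a frame qualifies
#'   as a rest point iff the largest per-axis |velocity| is below it.
#'   Sampled, noisy velocities never hit exactly zero, so the zero-crossing
#'   condition is operationalized as this tolerance.
#' @param refractory minimum spacing between detected rest points,
#'   seconds; qualifying frames closer than this collapse to the single
#'   frame of minimum speed.
#' @param t_hist seconds of history retained by the streaming segmenter.
#' @param update_interval frames between streaming recomputations.
#' @param mode `"auto"` (zero-crossing segmentation) or `"fixed"`
#'   (contiguous fixed-length segments).
#' @param fixed_length segment length in seconds for `"fixed"` mode.
#' @return object of class `"segmentation_config"`.
#' @export
segmentation_config <- function(savgol_window = 0.2, savgol_order = 3,
                                rest_tol = 0.02, refractory = 0.15,
                                t_hist = 5, update_interval = 10L,
                                mode = c("auto", "fixed"), fixed_length = 1.0) {
  mode <- match.arg(mode)
  if (rest_tol <= 0) stop("rest_tol must be positive")
  if (t_hist < fixed_length) stop("t_hist must cover at least one fixed-length segment")
  structure(list(savgol_window = savgol_window, savgol_order = savgol_order,
                 rest_tol = rest_tol, refractory = refractory, t_hist = t_hist,
                 update_interval = as.integer(update_interval), mode = mode,
                 fixed_length = fixed_length),
            class = "segmentation_config")
}

sg_window_frames <- function(config, sample_rate) {
  w <- max(3L, as.integer(round(config$savgol_window * sample_rate)))
  if (w %% 2L == 0L) w <- w + 1L
  if (config$savgol_order >= w) stop("savgol_order must be below the window length in samples")
  w
}

#' Smooth marker positions and compute end-effector velocity
#'
#' Savitzky-Golay smoothing with the configured window and order, then
#' per-axis velocity by central differences at the sample rate (one-sided
#' at the series ends).
#'
#' @param markers T x 3 marker position matrix (meters).
#' @param sample_rate sampling rate, Hz.
#' @param config a [segmentation_config()].
#' @return list with `positions` (smoothed T x 3) and `velocity` (T x 3,
#'   m/s).
#' @export
preprocess_markers <- function(markers, sample_rate, config = segmentation_config()) {
  markers <- as.matrix(markers)
  w <- sg_window_frames(config, sample_rate)
  if (nrow(markers) < w)
    stop(sprintf("need at least %d samples for the %g s smoothing window", w,
                 config$savgol_window))
  sm <- apply(markers, 2, function(v)
    signal::sgolayfilt(v, p = config$savgol_order, n = w))
  list(positions = sm, velocity = finite_diff(sm, sample_rate))
}

#' Find rest points in an end-effector velocity series
#'
#' A frame qualifies iff `max_axis |v| < rest_tol`; runs of qualifying
#' frames whose gaps are within the refractory interval collapse to the
#' single frame of minimum speed. Returned indices are 1-based and
#' strictly increasing.
#'
#' @param velocity T x 3 velocity matrix (m/s).
#' @param sample_rate sampling rate, Hz.
#' @param config a [segmentation_config()].
#' @return integer vector of rest-point frames.
#' @export
find_rest_points <- function(velocity, sample_rate, config = segmentation_config()) {
  velocity <- as.matrix(velocity)
  if (!nrow(velocity)) stop("velocity series is empty")
  speed <- apply(abs(velocity), 1, max)
  qual <- which(speed < config$rest_tol)
  if (!length(qual)) return(integer(0))
  gap <- max(1L, as.integer(round(config$refractory * sample_rate)))
  grp <- cumsum(c(1L, diff(qual) > gap))
  vapply(split(qual, grp), function(idx) idx[which.min(speed[idx])], integer(1),
         USE.NAMES = FALSE)
}

#' Offline motion-primitive segmentation
#'
#' In `"auto"` mode, consecutive rest points of the smoothed end-effector
#' velocity delimit segments; phases alternate starting with
#' `"execution"` (the first motion leaves the start pose). In `"fixed"`
#' mode, contiguous segments of the configured length partition the whole
#' trajectory from frame 1 (the trailing partial segment is retained).
#'
#' @param traj a `"motion_trajectory"` (or any list with `markers` and
#'   `sample_rate`).
#' @param config a [segmentation_config()].
#' @return data.frame with columns `start`, `end` (1-based, half-open
#'   `[start, end)`), `phase`.
#' @export
segment_offline <- function(traj, config = segmentation_config()) {
  T <- nrow(traj$markers)
  if (config$mode == "fixed") {
    len <- max(1L, as.integer(round(config$fixed_length * traj$sample_rate)))
    starts <- seq(1L, T, by = len)
    return(data.frame(start = starts, end = pmin(starts + len, T + 1L),
                      phase = rep(c("execution", "return"), length.out = length(starts)),
                      stringsAsFactors = FALSE))
  }
  pre <- preprocess_markers(traj$markers, traj$sample_rate, config)
  rp <- find_rest_points(pre$velocity, traj$sample_rate, config)
  if (length(rp) < 2L)
    stop("fewer than 2 rest points found; the trajectory is not rest-bounded ",
         "under the current tolerance -- consider mode = \"fixed\"")
  n <- length(rp) - 1L
  data.frame(start = rp[-length(rp)], end = rp[-1L],
             phase = rep(c("execution", "return"), length.out = n),
             stringsAsFactors = FALSE)
}

#' Streaming segmenter over a bounded history buffer
#'
#' Maintains up to `t_hist` seconds of marker (and optionally kinematic/
#' dynamic) history. Every `update_interval` frames the rest points are
#' recomputed from the buffered markers and the segment start is set to
#' the most recent rest point (buffer start if none); between
#' recomputations the previous start is reused.
#'
#' @param config a [segmentation_config()].
#' @param sample_rate sampling rate, Hz.
#' @return an `"online_segmenter"` object (an environment); feed it with
#'   [online_segment_update()].
#' @export
online_segmenter <- function(config = segmentation_config(), sample_rate = 100) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$sample_rate <- sample_rate
  st$cap <- max(3L, as.integer(round(config$t_hist * sample_rate)))
  st$markers <- NULL          # buffer, rows = frames
  st$buf_first <- 1L          # absolute frame index of buffer row 1
  st$n_seen <- 0L
  st$start <- 1L              # current primitive start, absolute frames
  class(st) <- "online_segmenter"
  st
}

#' Advance the streaming segmenter by one frame
#'
#' @param state an [online_segmenter()].
#' @param marker_row length-3 marker position of the new frame.
#' @return current primitive start (absolute 1-based frame index).
#' @export
online_segment_update <- function(state, marker_row) {
  state$markers <- rbind(state$markers, matrix(marker_row, 1L))
  state$n_seen <- state$n_seen + 1L
  if (nrow(state$markers) > state$cap) {
    drop <- nrow(state$markers) - state$cap
    state$markers <- state$markers[-seq_len(drop), , drop = FALSE]
    state$buf_first <- state$buf_first + drop
  }
  cfg <- state$config
  w <- sg_window_frames(cfg, state$sample_rate)
  due <- state$n_seen %% cfg$update_interval == 0L || state$n_seen == w
  if (due && nrow(state$markers) >= w) {
    pre <- preprocess_markers(state$markers, state$sample_rate, cfg)
    rp <- find_rest_points(pre$velocity, state$sample_rate, cfg)
    new_start <- if (length(rp)) state$buf_first + rp[length(rp)] - 1L else state$buf_first
    # starts never move backwards over a stream
    state$start <- max(state$start, new_start)
  }
  state$start <- max(state$start, state$buf_first)
  state$start
}
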