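# Synthetic motion generator: seeded stand-in for a motion-capture +
# musculoskeletal-model pipeline. Produces rest-bounded goal-directed
# primitives (execution then return-to-start), healthy or with acted
# compensation realised as attenuation of task-primary DoFs plus
# recruitment of normally quiet torso DoFs.

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Study design for synthetic dataset generation
#'
#' The default replicates a 6-participant study: 5 tasks (bimanual tray
#' lift, eye-level reach, chest-level reach, reach with pronation, reach
#' with supination), each recorded healthy and under 3 acted-compensation
#' conditions, 5 repetitions each, sampled at 100 Hz -- 5 x (3+1) x 5 x 6 =
#' 600 trajectories, 100 per participant.
#'
#' @param n_participants number of participants (>= 1).
#' @param tasks character vector of task identifiers; must name entries of
#'   the built-in task templates.
#' @param conditions named list of [compensation_spec()] objects; must
#'   include exactly one healthy condition.
#' @param n_repetitions repetitions per (participant, task, condition) cell.
#' @param sample_rate sampling rate, Hz.
#' @return object of class `"study_design"`.
#' @export
study_design <- function(n_participants = 6,
                         tasks = names(task_amplitudes()),
                         conditions = default_conditions(),
                         n_repetitions = 5,
                         sample_rate = 100) {
  if (n_participants < 1 || n_repetitions < 1 || length(tasks) < 1)
    stop("participants, tasks and repetitions must all be >= 1")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  unknown <- setdiff(tasks, names(task_amplitudes()))
  if (length(unknown)) stop("unknown task(s): ", paste(unknown, collapse = ", "))
  healthy <- vapply(conditions, function(cs) length(cs$recruited) == 0L, logical(1))
  if (sum(healthy) != 1L) stop("conditions must include exactly one healthy condition")
  structure(
    list(n_participants = as.integer(n_participants), tasks = tasks,
         conditions = conditions, n_repetitions = as.integer(n_repetitions),
         sample_rate = sample_rate),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  n_cond <- length(x$conditions)
  cat("Study design:", x$n_participants, "participants x", length(x$tasks),
      "tasks x", n_cond, "conditions x", x$n_repetitions, "repetitions =",
      x$n_participants * length(x$tasks) * n_cond * x$n_repetitions,
      "trajectories @", x$sample_rate, "Hz\n")
  invisible(x)
}

#' Specification of one acted-compensation condition
#'
#' @param condition condition identifier (character scalar).
#' @param impaired named numeric vector of attenuation factors `rho` in
#'   (0,1) applied to the task amplitude of the impaired DoFs.
#' @param recruited named numeric vector of recruitment amplitudes `delta`
#'   (radians, > 0) added to normally quiet DoFs. Empty for the healthy
#'   condition; must be disjoint from `impaired`.
#' @return object of class `"compensation_spec"`.
#' @export
compensation_spec <- function(condition, impaired = numeric(0), recruited = numeric(0)) {
  if (length(intersect(names(impaired), names(recruited))))
    stop("recruited and impaired DoF sets must be disjoint")
  if (any(impaired <= 0) || any(impaired >= 1))
    stop("attenuation factors rho must lie in (0, 1)")
  if (any(recruited <= 0)) stop("recruitment amplitudes delta must be positive")
  bad <- setdiff(c(names(impaired), names(recruited)), comp_dofs())
  if (length(bad)) stop("not a model DoF: ", paste(bad, collapse = ", "))
  structure(list(condition = condition, impaired = impaired, recruited = recruited),
            class = "compensation_spec")
}

#' Per-participant surrogate body model
#'
#' Draws, deterministically from the participant seed, the per-DoF
#' inertia-like (`I`, kg m^2 scale), damping (`b`) and gravity (`g`, N m
#' scale) coefficients of the surrogate dynamics, the baseline joint pose
#' `q0` (radians; elbow flexed near 90 degrees), the primitive duration
#' range (seconds), an overall amplitude scale and the noise scale.
#'
#' @param participant participant index (1-based).
#' @param seed dataset-level seed the participant substream is derived from.
#' @return object of class `"participant_profile"`.
#' @export
participant_profile <- function(participant, seed) {
  dofs <- comp_dofs()
  nj <- length(dofs)
  pseed <- derive_seed(seed, 101L, participant)
  with_seed(pseed, {
    inertia <- runif(nj, 0.6, 1.8)
    inertia[1:3] <- inertia[1:3] * 3   # torso segments are heavier
    damping <- runif(nj, 0.3, 0.9)
    gravity <- runif(nj, 1.0, 4.0)
    q0 <- runif(nj, -0.08, 0.08)
    names(q0) <- dofs
    q0["elbow_flexion"] <- 1.2 + runif(1, -0.1, 0.1)
    dur_scale <- runif(1, 0.9, 1.1)
    structure(
      list(participant = as.integer(participant),
           I = setNames(inertia, dofs), b = setNames(damping, dofs),
           g = setNames(gravity, dofs), q0 = q0,
           duration_range = c(1.2, 1.8) * dur_scale,
           amplitude_scale = runif(1, 0.85, 1.15),
           noise_scale = 8e-4 * runif(1, 0.8, 1.2),
           seed = pseed),
      class = "participant_profile")
  })
}

#' Minimum-jerk rest-to-rest profile
#'
#' The classic smooth point-to-point profile `10 s^3 - 15 s^4 + 6 s^5`:
#' monotone from 0 to 1 on normalized time with zero velocity and
#' acceleration at both ends, the standard model of unconstrained reaching
#' in motor control.
#'
#' @param s normalized time in \[0, 1\] (vectorized).
#' @return profile values in \[0, 1\].
#' @export
minimum_jerk_profile <- function(s) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("s must lie in [0, 1]")
  s^3 * (10 - 15 * s + 6 * s^2)
}

#' Surrogate inverse dynamics
#'
#' Maps joint kinematics to joint torques with a decoupled per-DoF
#' second-order model `tau_j = I_j qdd_j + b_j qd_j + g_j sin(q_j)`,
#' preserving the kinematics-to-torque dependency the energy features need
#' in place of a full musculoskeletal inverse-dynamics solve.
#'
#' @param q,qd,qdd angle / velocity / acceleration matrices (rows = time,
#'   named columns = DoFs), radians and derived units.
#' @param profile a [participant_profile()] supplying `I`, `b`, `g`.
#' @return torque matrix (N m) of the same shape as `q`.
#' @export
surrogate_inverse_dynamics <- function(q, qd, qdd, profile) {
  q <- as.matrix(q); qd <- as.matrix(qd); qdd <- as.matrix(qdd)
  if (!identical(dim(q), dim(qd)) || !identical(dim(q), dim(qdd)))
    stop("q, qd, qdd must share their shape")
  dofs <- colnames(q)
  if (is.null(dofs)) stop("q must carry DoF column names")
  missing_c <- setdiff(dofs, intersect(names(profile$I),
                                       intersect(names(profile$b), names(profile$g))))
  if (length(missing_c))
    stop("profile lacks coefficients for DoF(s): ", paste(missing_c, collapse = ", "))
  tau <- qdd * rep(profile$I[dofs], each = nrow(q)) +
    qd * rep(profile$b[dofs], each = nrow(q)) +
    sin(q) * rep(profile$g[dofs], each = nrow(q))
  dimnames(tau) <- dimnames(q)
  tau
}

#' Synthesize one motion trajectory
#'
#' Generates `n_repetitions` rest-bounded repetitions of a goal-directed
#' primitive: an execution phase driving every DoF along a minimum-jerk
#' joint-space profile toward its task amplitude, then a return phase back
#' to the start pose. Compensation scales impaired-DoF amplitudes by `rho`
#' and adds recruitment amplitude `delta` on the recruited DoFs; all
#' trajectories start from the healthy baseline pose. Smooth band-limited
#' noise (sums of sub-6 Hz sinusoids) is superimposed; torques come from
#' [surrogate_inverse_dynamics()]; wrist-marker positions from a fixed
#' affine forward map, so marker velocity vanishes exactly at joint rests.
#'
#' Random draws (durations, per-repetition amplitude jitter, noise) are
#' consumed in a spec-independent order, so a healthy and a compensatory
#' trajectory generated from the same seed differ only by the deterministic
#' amplitude changes.
#'
#' @param task task identifier (a name of the built-in task templates).
#' @param comp_spec a [compensation_spec()].
#' @param profile a [participant_profile()].
#' @param n_repetitions number of repetitions (>= 1).
#' @param seed integer seed; the trajectory is a pure function of
#'   (task, comp_spec, profile, n_repetitions, seed).
#' @param sample_rate sampling rate in Hz.
#' @return object of class `"motion_trajectory"`: list with `time`, `q`,
#'   `qd`, `qdd`, `tau`, `markers`, `phase` (`"execution"`/`"return"` per
#'   frame), `rest_frames` (ground-truth phase-boundary frames, 1-based),
#'   `y` (`"healthy"`/`"compensatory"`), `true_compensating_dofs`,
#'   `participant`, `task`, `condition`, `sample_rate`, `seed`.
#' @export
synthesize_trajectory <- function(task, comp_spec, profile, n_repetitions = 1,
                                  seed = 1, sample_rate = 100) {
  stopifnot(inherits(comp_spec, "compensation_spec"),
            inherits(profile, "participant_profile"), n_repetitions >= 1)
  dofs <- comp_dofs()
  nj <- length(dofs)
  amp <- task_amplitudes()[[task]]
  if (is.null(amp)) stop("unknown task: ", task)
  amp <- amp * profile$amplitude_scale
  if (length(comp_spec$impaired))
    amp[names(comp_spec$impaired)] <- amp[names(comp_spec$impaired)] * comp_spec$impaired
  if (length(comp_spec$recruited))
    amp[names(comp_spec$recruited)] <- amp[names(comp_spec$recruited)] + comp_spec$recruited

  with_seed(seed, {
    exec_dur <- runif(n_repetitions, profile$duration_range[1], profile$duration_range[2])
    ret_dur <- exec_dur * runif(n_repetitions, 0.75, 0.95)
    rep_jitter <- runif(n_repetitions, 0.92, 1.08)
    n_sin <- 3L
    noise_amp <- matrix(profile$noise_scale * runif(nj * n_sin, 0.3, 1), nj, n_sin)
    noise_freq <- matrix(runif(nj * n_sin, 0.3, 2.0), nj, n_sin)
    noise_phase <- matrix(runif(nj * n_sin, 0, 2 * pi), nj, n_sin)
  })

  phase_frames <- as.integer(round(rbind(exec_dur, ret_dur) * sample_rate))
  phase_frames <- pmax(phase_frames, 2L)
  n_phases <- 2L * n_repetitions
  starts <- cumsum(c(1L, as.vector(phase_frames)))   # length n_phases + 1
  T <- starts[n_phases + 1L]                         # final frame sits at last rest
  time <- (seq_len(T) - 1) / sample_rate

  q <- matrix(rep(profile$q0, each = T), T, nj, dimnames = list(NULL, dofs))
  phase <- character(T)
  envelope <- numeric(T)
  for (p in seq_len(n_phases)) {
    rng <- starts[p]:(starts[p + 1L] - 1L)
    s <- (rng - starts[p]) / (starts[p + 1L] - starts[p])
    r <- ceiling(p / 2)
    h <- if (p %% 2L == 1L) minimum_jerk_profile(s) else 1 - minimum_jerk_profile(s)
    q[rng, ] <- q[rng, ] + outer(h, amp * rep_jitter[r])
    phase[rng] <- if (p %% 2L == 1L) "execution" else "return"
    # normalized minimum-jerk speed profile (peak 1 at mid-phase)
    envelope[rng] <- 30 * s^2 * (1 - s)^2 / 1.875
  }
  phase[T] <- "return"

  # Signal-dependent motor noise: variability scales with movement speed
  # (large mid-primitive, small residual tremor when settled at rest),
  # realized as band-limited sinusoids modulated by the phase's speed
  # profile over a small resting floor. The modulation keeps rests sharply
  # localized while leaving mid-movement variability at the noise scale.
  noise_floor <- 0.1
  env <- noise_floor + (1 - noise_floor) * envelope
  noise <- matrix(0, T, nj)
  for (k in seq_len(n_sin))
    noise <- noise + t(noise_amp[, k] * sin(outer(2 * pi * noise_freq[, k], time) +
                                              noise_phase[, k]))
  q <- q + noise * env

  qd <- finite_diff(q, sample_rate)
  qdd <- finite_diff(qd, sample_rate)
  tau <- surrogate_inverse_dynamics(q, qd, qdd, profile)
  markers <- q %*% t(marker_map()) +
    matrix(rep(marker_origin(), each = T), T, 3, dimnames = list(NULL, c("x", "y", "z")))

  structure(
    list(time = time, q = q, qd = qd, qdd = qdd, tau = tau, markers = markers,
         phase = phase, rest_frames = starts,
         y = if (length(comp_spec$recruited)) "compensatory" else "healthy",
         true_compensating_dofs = names(comp_spec$recruited) %||% character(0),
         participant = profile$participant, task = task,
         condition = comp_spec$condition, sample_rate = sample_rate,
         seed = as.integer(seed)),
    class = "motion_trajectory")
}

#' @export
print.motion_trajectory <- function(x, ...) {
  cat(sprintf("Motion trajectory: %s / %s / participant %d, %d frames @ %g Hz, label %s\n",
              x$task, x$condition, x$participant, nrow(x$q), x$sample_rate, x$y))
  if (length(x$true_compensating_dofs))
    cat("  recruited DoFs:", paste(x$true_compensating_dofs, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a full synthetic dataset
#'
#' One single-repetition trajectory per (participant, task, condition,
#' repetition) cell of the design, with hierarchical seeding (dataset seed
#' -> participant seed -> trajectory seed) so any subset is reproducible in
#' isolation. Repetitions of one (participant, task, condition) cell all
#' start and end at the participant's baseline pose, so they can be
#' concatenated into the continuous multi-repetition recording used for
#' streaming experiments.
#'
#' @param design a [study_design()].
#' @param seed integer dataset seed.
#' @return object of class `"comp_dataset"`: list with `trajectories`
#'   (named list of [synthesize_trajectory()] outputs), `manifest`
#'   (data.frame: id, participant, task, condition, repetition, label,
#'   true_compensating_dofs, seed, n_frames), `design`, `seed`.
#' @export
generate_dataset <- function(design = study_design(), seed = 1) {
  stopifnot(inherits(design, "study_design"))
  profiles <- lapply(seq_len(design$n_participants), participant_profile, seed = seed)
  trajs <- list()
  rows <- list()
  for (p in seq_len(design$n_participants)) {
    for (ti in seq_along(design$tasks)) {
      for (ci in seq_along(design$conditions)) {
        for (r in seq_len(design$n_repetitions)) {
          tseed <- derive_seed(seed, p, ti, ci, r)
          tr <- synthesize_trajectory(design$tasks[ti], design$conditions[[ci]],
                                      profiles[[p]], n_repetitions = 1,
                                      seed = tseed, sample_rate = design$sample_rate)
          id <- sprintf("p%02d_%s_%s_r%d", p, design$tasks[ti],
                        tr$condition, r)
          tr$id <- id
          trajs[[id]] <- tr
          rows[[id]] <- data.frame(
            id = id, participant = p, task = design$tasks[ti],
            condition = tr$condition, repetition = r, label = tr$y,
            true_compensating_dofs = paste(tr$true_compensating_dofs, collapse = ","),
            seed = tseed, n_frames = nrow(tr$q), stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(trajectories = trajs,
                 manifest = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 design = design, seed = as.integer(seed)),
            class = "comp_dataset")
}

#' @export
print.comp_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Synthetic compensation dataset: %d trajectories (%d healthy, %d compensatory), %d participants, seed %d\n",
              nrow(m), sum(m$label == "healthy"), sum(m$label == "compensatory"),
              length(unique(m$participant)), x$seed))
  invisible(x)
}
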