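# Synthetic motion generator

test_that("minimum-jerk profile is a smooth rest-to-rest ramp", {
  expect_equal(minimum_jerk_profile(0), 0)
  expect_equal(minimum_jerk_profile(1), 1)
  expect_equal(minimum_jerk_profile(0.5), 0.5)  # odd symmetry about midpoint
  s <- seq(0, 1, by = 1e-4)
  h <- minimum_jerk_profile(s)
  expect_true(all(diff(h) >= 0))                # monotone non-decreasing
  # zero velocity and acceleration at both ends (finite-difference check)
  d1 <- diff(h) / 1e-4
  d2 <- diff(d1) / 1e-4
  expect_lt(abs(d1[1]), 1e-4)
  expect_lt(abs(d1[length(d1)]), 1e-4)
  expect_lt(abs(d2[1]), 1e-2)
  expect_lt(abs(d2[length(d2)]), 1e-2)
  expect_error(minimum_jerk_profile(1.2), "0, 1")
  expect_error(minimum_jerk_profile(-0.1), "0, 1")
})

test_that("surrogate inverse dynamics evaluates its closed form", {
  prof <- fixture_profile()
  nj <- length(comp_dofs())
  zero <- matrix(0, 5, nj, dimnames = list(NULL, comp_dofs()))
  # static pose at q = 0: all three terms vanish
  expect_equal(surrogate_inverse_dynamics(zero, zero, zero, prof), zero)
  # single-term product I * qdd with b = g = 0
  prof2 <- prof
  prof2$I[] <- 1.5; prof2$b[] <- 0; prof2$g[] <- 0
  qdd <- zero + 2
  expect_equal(unname(surrogate_inverse_dynamics(zero, zero, qdd, prof2)[1, 1]), 3)
  # full closed form: I qdd + b qd + g sin(q) = 1 + 0.5 + 2 = 3.5
  prof3 <- prof
  prof3$I[] <- 1; prof3$b[] <- 0.5; prof3$g[] <- 2
  q <- zero + pi / 2; qd <- zero + 1; qdd1 <- zero + 1
  expect_equal(unname(surrogate_inverse_dynamics(q, qd, qdd1, prof3)[1, 1]), 3.5)
  # missing coefficient is a configuration error
  prof4 <- prof
  prof4$I <- prof4$I[-1]
  expect_error(surrogate_inverse_dynamics(zero, zero, zero, prof4), "coefficients")
})

test_that("trajectories are rest-bounded with alternating phases", {
  tr <- fixture_trajectory(n_repetitions = 3)
  # 3 executions + 3 returns in the phase labels
  r <- rle(tr$phase)
  expect_identical(r$values, rep(c("execution", "return"), 3))
  expect_length(tr$rest_frames, 7)
  # every series shares the frame count
  T <- nrow(tr$q)
  for (f in list(tr$qd, tr$qdd, tr$tau, tr$markers))
    expect_identical(nrow(f), T)
  expect_length(tr$phase, T)
  # marker speed below the rest tolerance at every ground-truth boundary
  pre <- preprocess_markers(tr$markers, tr$sample_rate)
  speed <- apply(abs(pre$velocity), 1, max)
  expect_true(all(speed[tr$rest_frames] < segmentation_config()$rest_tol))
  # velocity/acceleration consistent with q under the package scheme
  expect_equal(tr$qd, finite_diff(tr$q, tr$sample_rate))
  expect_equal(tr$qdd, finite_diff(tr$qd, tr$sample_rate))
})

test_that("compensation recruits the specified DoF from a healthy start", {
  comp <- fixture_trajectory("trunk_lean", seed = 7)
  heal <- fixture_trajectory("healthy", seed = 7)
  # recruited torso flexion exceeds the same-seed healthy excursion
  excess <- max(comp$q[, "torso_flexion"]) - max(heal$q[, "torso_flexion"])
  expect_gte(excess, 0.2)
  # trajectories begin in the healthy pose: zero recruitment displacement
  expect_lt(abs(comp$q[1, "torso_flexion"] - heal$q[1, "torso_flexion"]), 0.01)
  expect_identical(comp$y, "compensatory")
  expect_identical(comp$true_compensating_dofs, "torso_flexion")
  expect_identical(heal$y, "healthy")
  expect_length(heal$true_compensating_dofs, 0)
})

test_that("generation is deterministic and hierarchically seeded", {
  a <- fixture_trajectory(seed = 13)
  b <- fixture_trajectory(seed = 13)
  expect_identical(a, b)
  d1 <- generate_dataset(small_design(), seed = 5)
  d2 <- generate_dataset(small_design(), seed = 5)
  expect_identical(d1, d2)
  # a single trajectory regenerated in isolation from its manifest seed
  row <- d1$manifest[9, ]
  prof <- participant_profile(row$participant, 5)
  cond <- default_conditions()[[row$condition]]
  solo <- synthesize_trajectory(row$task, cond, prof, 1, row$seed)
  expect_equal(solo$q, d1$trajectories[[row$id]]$q)
})

test_that("dataset structure follows the study design", {
  d <- generate_dataset(small_design(n_participants = 2, n_repetitions = 2), seed = 3)
  expect_identical(nrow(d$manifest), 2L * 2L * 2L * 2L)
  expect_true(all(table(d$manifest$participant) == 8))
  # degenerate design: one healthy-only trajectory
  deg <- study_design(n_participants = 1, tasks = "reach_eye",
                      conditions = default_conditions()["healthy"],
                      n_repetitions = 1)
  dd <- generate_dataset(deg, seed = 1)
  expect_identical(nrow(dd$manifest), 1L)
  expect_identical(dd$manifest$label, "healthy")
})

test_that("invalid specifications are rejected", {
  expect_error(compensation_spec("x", impaired = c(torso_tilt = 0.5),
                                 recruited = c(torso_tilt = 0.3)), "disjoint")
  expect_error(compensation_spec("x", impaired = c(torso_tilt = 1.2)), "rho")
  expect_error(compensation_spec("x", recruited = c(not_a_dof = 0.3)), "DoF")
  expect_error(study_design(n_participants = 0), ">= 1")
  expect_error(study_design(sample_rate = -1), "positive")
  prof <- fixture_profile()
  expect_error(synthesize_trajectory("no_such_task",
                                     default_conditions()$healthy, prof),
               "unknown task")
})

test_that("recruited DoFs move more in compensatory than healthy data", {
  # separability sanity under the default rho / delta
  d <- generate_dataset(small_design(n_participants = 2, n_repetitions = 2), seed = 9)
  peak <- function(tr, dof) max(abs(tr$q[, dof] - tr$q[1, dof]))
  comp <- d$manifest$id[d$manifest$label == "compensatory"]
  heal <- d$manifest$id[d$manifest$label == "healthy"]
  m_comp <- mean(vapply(d$trajectories[comp], peak, numeric(1), dof = "torso_flexion"))
  m_heal <- mean(vapply(d$trajectories[heal], peak, numeric(1), dof = "torso_flexion"))
  expect_gt(m_comp, m_heal)
})
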