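test_that("solver settings are validated", {
  expect_error_class(ik_settings(weights = c(1, 2)), "invalid_parameter")
  expect_error_class(ik_settings(ftol = 0), "invalid_parameter")
  s <- ik_settings(weights = c(th1 = 2), multi_start = 0)
  expect_equal(s$multi_start, 1L)
})

test_that("scale factors recover identity, uniform and per-segment scales", {
  fx <- gait_fixture()
  sc <- compute_scale_factors(fx$model, fx$trial)
  expect_lt(max(abs(sc - 1)), 1e-9)

  # uniformly scaled subject
  m12 <- make_synthetic_hexapod(scale = 1.2)
  tr12 <- render_marker_trial(
    m12, make_gait_trajectories(m12, synthetic_gait_spec()))
  sc12 <- compute_scale_factors(fx$model, tr12)
  expect_lt(max(abs(sc12 - 1.2)), 1e-6)

  # per-segment scales on femur and tibia
  true_sc <- c(fr_fe = 1.1, fr_ti = 0.9)
  ms <- apply_scaling(fx$model, true_sc)
  trs <- render_marker_trial(
    ms, make_gait_trajectories(ms, synthetic_gait_spec()))
  rec <- compute_scale_factors(fx$model, trs)
  expect_equal(unname(rec["fr_fe"]), 1.1, tolerance = 1e-6)
  expect_equal(unname(rec["fr_ti"]), 0.9, tolerance = 1e-6)
  expect_equal(unname(rec["rl_mt"]), 1.0, tolerance = 1e-6)
})

test_that("scaling a model scales marker distances and commutes with FK", {
  fx <- gait_fixture()
  m <- fx$model
  # identity leaves the model unchanged
  m1 <- apply_scaling(m, setNames(rep(1, length(m$segments)),
                                  names(m$segments)))
  expect_equal(m1$cpp$marker_loc, m$cpp$marker_loc)
  expect_equal(m1$cpp$pp, m$cpp$pp)

  # factor 2 on one segment doubles its inter-marker distance under FK
  m2 <- apply_scaling(m, c(rr_fe = 2))
  fk <- forward_kinematics(m2, neutral_pose(m2))$markers
  fk0 <- forward_kinematics(m, neutral_pose(m))$markers
  d2 <- sqrt(sum((fk["fl_fe1", ] - fk["fl_fe2", ])^2))  # other legs untouched
  expect_equal(d2, sqrt(sum((fk0["fl_fe1", ] - fk0["fl_fe2", ])^2)),
               tolerance = 1e-12)
  dr <- sqrt(sum((fk["rr_fe1", ] - fk["rr_fe2", ])^2))
  expect_equal(dr, 2 * sqrt(sum((fk0["rr_fe1", ] - fk0["rr_fe2", ])^2)),
               tolerance = 1e-12)

  # single-segment model: scale-then-FK equals FK-then-scale
  single <- assemble_model(list(segment_spec(
    "s", "ground", joint_spec("h", "hinge1", identity_frame()),
    markers = list(a = c(1, 0.2, 0), b = c(0.3, -0.1, 0.5)))))
  q <- 0.7
  scaled <- apply_scaling(single, c(s = 1.7))
  expect_equal(forward_kinematics(scaled, q)$markers,
               1.7 * forward_kinematics(single, q)$markers,
               tolerance = 1e-12)

  expect_error_class(apply_scaling(m, c(rr_fe = -1)), "invalid_parameter")
})

test_that("single-frame IK recovers a noiseless pose from a nearby start", {
  fx <- gait_fixture()
  q_true <- fx$gait$q[, 40]
  obs <- forward_kinematics(fx$model, q_true)$markers
  sol <- solve_ik_frame(fx$model, obs, ik_settings(multi_start = 1),
                        q_init = q_true + 0.02)
  expect_true(sol$status$converged)
  expect_lt(max(abs(sol$q - q_true)), 1e-6)
  expect_lt(sol$rmse, 1e-8)
  expect_lte(sol$status$cost, sol$status$init_cost)
})

test_that("rigidly translating the marker cloud only shifts the base", {
  fx <- gait_fixture()
  q_true <- fx$gait$q[, 10]
  obs <- forward_kinematics(fx$model, q_true)$markers
  delta <- c(3.1, -2.4, 0.9)
  obs2 <- sweep(obs, 2, delta, `+`)
  s <- ik_settings(multi_start = 1)
  sol1 <- solve_ik_frame(fx$model, obs, s, q_init = q_true)
  sol2 <- solve_ik_frame(fx$model, obs2, s,
                         q_init = antkin:::centroid_init(
                           fx$model, q_true,
                           antkin:::align_observations(fx$model, obs2),
                           rep(1, length(fx$model$marker_names))))
  dt <- dof_table(fx$model)
  tr_rows <- dt[dt$kind == "translation", ]
  rot_rows <- dt[dt$kind == "rotation" & !dt$locked, ]
  expect_lt(max(abs(sol2$q[rot_rows$q_index] - sol1$q[rot_rows$q_index])),
            1e-8)
  # the base shift, mapped through the base frame, equals the translation
  Rp <- fx$model$segments$thorax$joint$frame_in_parent$rotation
  shift <- as.numeric(Rp %*% (sol2$q[tr_rows$q_index] -
                                sol1$q[tr_rows$q_index]))
  expect_equal(shift, delta, tolerance = 1e-8)
})

test_that("IK refuses under-determined frames", {
  fx <- gait_fixture()
  obs <- forward_kinematics(fx$model, fx$gait$q[, 1])$markers
  expect_error_class(
    solve_ik_frame(fx$model, obs[1:10, ], ik_settings()), "invalid_input")
})

test_that("a static pose yields zero range of motion", {
  m <- hexapod_fixture()
  g <- make_gait_trajectories(
    m, synthetic_gait_spec(duration = 0.2, rate = 50, amplitude_frac = 0,
                           trunk_amplitude_deg = 0, base_amplitude_deg = 0,
                           speed_mm_s = 0))
  tr <- render_marker_trial(m, g)
  res <- solve_ik_trial(m, tr, ik_settings(multi_start = 2))
  rom <- range_of_motion(res)
  expect_true(all(is.na(rom$rom[rom$locked])))
  expect_lt(max(rom$rom[!rom$locked]), 1e-6)
})

test_that("range of motion of a sinusoidal DOF is twice its amplitude", {
  # drive one hinge with a 20-degree-amplitude sinusoid directly
  m <- planar_two_link()
  nfr <- 60
  q <- rbind(20 * pi / 180 * sin(2 * pi * (0:(nfr - 1)) / nfr), 0)
  tr <- render_marker_trial(m, list(q = q, time = (0:(nfr - 1)) / 50),
                            rate = 50)
  res <- solve_ik_trial(m, tr, ik_settings(multi_start = 4))
  rom <- range_of_motion(res)
  expect_equal(rom$rom[rom$segment == "link1"], 40, tolerance = 0.1)
})

test_that("marker RMSE grows monotonically with isotropic marker noise", {
  m <- hexapod_fixture()
  g <- make_gait_trajectories(
    m, synthetic_gait_spec(duration = 1.39, rate = 10))
  s <- ik_settings(multi_start = 2)
  sds <- c(0.01, 0.05, 0.15)
  rmse <- vapply(sds, function(sd) {
    mean(vapply(1:3, function(seed) {
      tr <- render_marker_trial(m, g, noise = "gaussian", noise_mm = sd,
                                seed = seed)
      solve_ik_trial(m, tr, s)$avg_rmse
    }, 0))
  }, 0)
  expect_true(all(diff(rmse) > 0))
})

test_that("IK results export to CSV with one angle column per coordinate", {
  fx <- gait_fixture()
  sub <- crop_cycle(fx$trial, gait_cycle(0, 5))
  res <- solve_ik_trial(fx$model, sub, ik_settings(multi_start = 2),
                        body_length_mm = 6.6)
  path <- tempfile(fileext = ".csv")
  write_ik_csv(res, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 5L)
  expect_equal(ncol(df), 2 + n_dof(fx$model))
  expect_true(all(is.finite(df$marker_rmse)))
})
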