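test_that("uniform-ball samples have the closed-form mean norm and support", {
  expect_equal(sample_uniform_ball(0, 5), matrix(0, 5, 3))
  expect_error_class(sample_uniform_ball(-1), "invalid_parameter")

  set.seed(99)
  x <- sample_uniform_ball(0.4, 1e5)
  nrm <- sqrt(rowSums(x^2))
  expect_lte(max(nrm), 0.4)
  # E||x|| = 3R/4, within 3 standard errors
  se <- sd(nrm) / sqrt(length(nrm))
  expect_lt(abs(mean(nrm) - 0.3), 3 * se)
  # E||x||^2 = 3R^2/5
  se2 <- sd(nrm^2) / sqrt(length(nrm))
  expect_lt(abs(mean(nrm^2) - 0.6 * 0.4^2), 4 * se2)
})

test_that("marker perturbation is bounded, seeded and radius-0 exact", {
  m <- hexapod_fixture()
  expect_identical(perturb_marker_set(m, 0), m)

  set.seed(7)
  pm <- perturb_marker_set(m, 0.4)
  d <- sqrt(colSums((pm$cpp$marker_loc - m$cpp$marker_loc)^2))
  expect_lte(max(d), 0.4)
  expect_gt(min(d), 0)          # every marker moved
  # same seed reproduces the same perturbed model
  set.seed(7)
  pm2 <- perturb_marker_set(m, 0.4)
  expect_identical(pm$cpp$marker_loc, pm2$cpp$marker_loc)

  # support bound over many draws
  set.seed(8)
  for (k in 1:50) {
    p <- perturb_marker_set(m, 0.1)
    expect_lte(max(sqrt(colSums((p$cpp$marker_loc - m$cpp$marker_loc)^2))),
               0.1)
  }
})

test_that("joint perturbation respects the cylindrical zone and tilt bound", {
  m <- hexapod_fixture()
  expect_identical(perturb_joint_parameters(m, 0), m)

  radius <- 0.2
  set.seed(11)
  for (k in 1:40) {
    pm <- perturb_joint_parameters(m, radius)
    for (s in names(m$segments)) {
      g0 <- m$segments[[s]]$joint$geom
      g1 <- pm$segments[[s]]$joint$geom
      if (is.null(g0) || g0$kind != "hinge") next
      # both defining points stay within the zone radius of their nominal
      # position, hence within the stated cylinder around the nominal axis
      expect_lte(sqrt(sum((g1$point_a - g0$point_a)^2)), radius + 1e-12)
      expect_lte(sqrt(sum((g1$point_b - g0$point_b)^2)), radius + 1e-12)
      # induced tilt is at most asin(2r/L)
      L <- sqrt(sum((g0$point_b - g0$point_a)^2))
      a0 <- (g0$point_b - g0$point_a) / L
      a1 <- g1$point_b - g1$point_a
      a1 <- a1 / sqrt(sum(a1^2))
      tilt <- acos(min(1, abs(sum(a0 * a1))))
      expect_lte(tilt, asin(min(1, 2 * radius / L)) + 1e-9)
    }
  }
  # ball joints move their center within the zone and keep unit frames
  set.seed(12)
  pm <- perturb_joint_parameters(m, radius)
  for (s in names(m$segments)) {
    g0 <- m$segments[[s]]$joint$geom
    if (is.null(g0) || g0$kind != "ball") next
    g1 <- pm$segments[[s]]$joint$geom
    expect_lte(sqrt(sum((g1$center - g0$center)^2)), radius + 1e-12)
    R <- pm$segments[[s]]$joint$frame_in_parent$rotation
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
  }
})

test_that("Monte Carlo at radius zero is exact and seeding is bit-stable", {
  fx <- short_gait_fixture()
  s <- ik_settings(multi_start = 2, max_iter = 600)
  spec0 <- perturbation_spec("model_markers", radius = 0,
                             n_iterations = 20, seed = 123)
  mc0 <- run_monte_carlo(fx$model, fx$trial, s, spec0)
  expect_equal(mc0$n_success, 20L)
  expect_true(all(mc0$sd == 0))
  expect_true(all(mc0$coverage == 0))

  spec <- perturbation_spec("model_markers", radius = 0.2,
                            n_iterations = 20, seed = 123)
  mc1 <- run_monte_carlo(fx$model, fx$trial, s, spec)
  mc2 <- run_monte_carlo(fx$model, fx$trial, s, spec)
  expect_identical(mc1$mean, mc2$mean)
  expect_identical(mc1$sd, mc2$sd)
  expect_identical(mc1$failed_iterations, mc2$failed_iterations)
  # coverage is exactly the multiplier times the sd
  expect_identical(mc1$coverage, 2 * mc1$sd)
})

test_that("the Monte Carlo mean converges to the baseline as radius -> 0", {
  fx <- short_gait_fixture()
  s <- ik_settings(multi_start = 2, max_iter = 600)
  baseline <- solve_ik_trial(fx$model, fx$trial, s)
  mc <- run_monte_carlo(fx$model, fx$trial, s,
                        perturbation_spec("model_markers", radius = 1e-6,
                                          n_iterations = 5, seed = 3))
  expect_lt(max(abs(mc$mean - baseline$angles)), 1e-3)
})

test_that("SNR follows its closed form and is invariant to offsets", {
  # synthesize an mc_result-like object directly: one ball DOF with a
  # 10-degree sinusoidal mean and constant 5-degree coverage
  m <- assemble_model(list(segment_spec(
    "s", "ground", joint_spec("j", "ball3", identity_frame()),
    markers = list(a = c(1, 0, 0), b = c(0, 1, 0.5)))))
  t <- seq(0, 1, length.out = 101)  # grid hits the sinusoid extrema exactly
  mean_mat <- matrix(0, 3, 101)
  mean_mat[3, ] <- 10 * sin(2 * pi * t)
  cov_mat <- matrix(5, 3, 101)
  mc <- structure(
    list(mean = mean_mat, sd = cov_mat / 2, coverage = cov_mat,
         n_success = 10L, n_failed = 0L, coverage_multiplier = 2,
         spec = perturbation_spec("model_markers", 0.1, 10),
         time = t, dof_table = dof_table(m)),
    class = "mc_result")
  rep_ <- compute_snr(mc)
  flex <- rep_[rep_$dof == "flexion", ]
  expect_equal(flex$Ps, 20)
  expect_equal(flex$Pn, 5)
  expect_equal(flex$snr, 4)

  # adding a constant offset to the mean trajectory leaves SNR unchanged
  mc2 <- mc
  mc2$mean <- mc$mean + 37
  expect_equal(compute_snr(mc2)$snr, rep_$snr)

  # zero coverage yields an undefined (NA) SNR, not infinity
  mc3 <- mc
  mc3$coverage[] <- 0
  expect_true(all(is.na(compute_snr(mc3)$snr)))
})

test_that("SNR group summaries average over the standard groups", {
  m <- hexapod_fixture()
  dt <- dof_table(m)
  free <- dt[!dt$locked, ]
  free <- free[order(free$q_index), ]
  nf <- 20
  mean_mat <- matrix(0, nrow(free), nf)
  cov_mat <- matrix(1, nrow(free), nf)
  # constant SNR 3 everywhere: Ps = 3, Pn = 1
  mean_mat[, nf] <- 3
  mc <- structure(
    list(mean = mean_mat, sd = cov_mat / 2, coverage = cov_mat,
         n_success = 10L, n_failed = 0L, coverage_multiplier = 2,
         spec = perturbation_spec("model_markers", 0.1, 10),
         time = seq_len(nf), dof_table = dt),
    class = "mc_result")
  rep_ <- compute_snr(mc)
  tab <- summarize_snr(rep_)
  expect_true(all(abs(tab$snr - 3) < 1e-12))
  # 6 standard groups + 9 joint rows (8 anatomical joints + petiole)
  expect_equal(nrow(tab), 15L)
  expect_setequal(
    tab$group[7:15],
    c("thorax/head", "thorax/petiole", "thorax/abdomen", "thorax/cox",
      "cox/tro", "tro/fe", "fe/ti", "ti/mt", "mt/ta"))
  # a two-element group averages arithmetically
  rep2 <- rep_[rep_$joint_label == "fe/ti" & rep_$side == "right", ]
  rep2$snr <- c(2, 4, 2)[seq_len(nrow(rep2))]
  class(rep2) <- c("snr_report", "data.frame")
  tab2 <- summarize_snr(rep2, grouping = list(
    pair = function(r) seq_len(nrow(r)) <= 2))
  expect_equal(tab2$snr, 3)
})

test_that("base coordinates and locked DOFs never enter the SNR report", {
  fx <- short_gait_fixture()
  s <- ik_settings(multi_start = 2, max_iter = 600)
  mc <- run_monte_carlo(fx$model, fx$trial, s,
                        perturbation_spec("model_markers", radius = 0.1,
                                          n_iterations = 5, seed = 2))
  rep_ <- compute_snr(mc)
  expect_false("thorax" %in% rep_$segment)
  expect_false(any(rep_$dof %in% c("tx", "ty", "tz")))
  # 59 reportable DOFs: 65 free minus the 6 base coordinates
  expect_equal(nrow(rep_), 59L)
  # diagnostic emitted for judging stabilization
  expect_true(nrow(mc$diagnostic) >= 1)
})
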