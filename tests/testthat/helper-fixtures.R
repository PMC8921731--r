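# Shared fixtures, memoized so the synthetic hexapod and its reference
# trials are built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

hexapod_fixture <- function() memo("hexapod", make_synthetic_hexapod)

# noiseless reference gait trial at the default conditions (1.39 s at 100 Hz)
gait_fixture <- function() {
  memo("gait100", function() {
    m <- hexapod_fixture()
    g <- make_gait_trajectories(m, synthetic_gait_spec())
    list(model = m, gait = g,
         trial = render_marker_trial(m, g))
  })
}

# short trial for Monte Carlo tests: same 1.39 s cycle sampled at 10 Hz
short_gait_fixture <- function() {
  memo("gait10", function() {
    m <- hexapod_fixture()
    g <- make_gait_trajectories(m, synthetic_gait_spec(rate = 10))
    list(model = m, gait = g,
         trial = render_marker_trial(m, g))
  })
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# independent forward-kinematics oracle: homogeneous 4x4 composition built
# straight from the segment specifications, no shared code with the
# compiled path
fk_oracle <- function(model, q) {
  hom <- function(R, p) rbind(cbind(R, p), c(0, 0, 0, 1))
  joint_hom <- function(joint, qloc) {
    R <- diag(3); p <- c(0, 0, 0)
    if (joint$type == "free6") {
      p <- qloc[1:3]
      R <- rot_x_ref(qloc[4]) %*% rot_y_ref(qloc[5]) %*% rot_z_ref(qloc[6])
    } else if (joint$type == "ball3") {
      R <- rot_x_ref(qloc[1]) %*% rot_y_ref(qloc[2]) %*% rot_z_ref(qloc[3])
    } else if (joint$type == "hinge1") {
      R <- rot_z_ref(qloc[1])
    }
    hom(R, p)
  }
  dt <- dof_table(model)
  poses <- list(ground = diag(4))
  markers <- list()
  for (seg in model$segments) {
    rows <- dt[dt$segment == seg$name, , drop = FALSE]
    qloc <- numeric(max(1, nrow(rows)))
    if (nrow(rows)) {
      for (i in seq_len(nrow(rows))) {
        qloc[i] <- if (rows$locked[i]) 0 else q[rows$q_index[i]]
      }
    }
    Tp <- hom(seg$joint$frame_in_parent$rotation,
              seg$joint$frame_in_parent$origin)
    Tc <- hom(seg$joint$frame_in_child$rotation,
              seg$joint$frame_in_child$origin)
    poses[[seg$name]] <- poses[[seg$parent]] %*% Tp %*%
      joint_hom(seg$joint, qloc) %*% solve(Tc)
    for (mn in names(seg$markers)) {
      markers[[mn]] <- as.numeric(
        (poses[[seg$name]] %*% c(seg$markers[[mn]], 1))[1:3])
    }
  }
  list(poses = poses, markers = markers)
}

rot_x_ref <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                                  0, -sin(a), cos(a)), 3, 3)
rot_y_ref <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                                  sin(a), 0, cos(a)), 3, 3)
rot_z_ref <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                                  0, 0, 1), 3, 3)

# minimal planar two-link arm: two z-hinges in the xy-plane, markers at
# the elbow and the tip
planar_two_link <- function(L1 = 1, L2 = 0.8, rom = 180) {
  link1 <- segment_spec(
    "link1", "ground",
    joint_spec("shoulder", "hinge1", identity_frame(), rom = rom),
    markers = list(elbow = c(L1, 0, 0)))
  link2 <- segment_spec(
    "link2", "link1",
    joint_spec("elbow", "hinge1", identity_frame(c(L1, 0, 0)), rom = rom),
    markers = list(tip = c(L2, 0, 0)))
  assemble_model(list(link1, link2))
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = paste0("antkin_", class))
}
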