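# Fully known synthetic inputs: a hexapod whole-body model in the ant's
# topology, smooth periodic gait trajectories, rendered marker trials and
# articular-surface point clouds.  Every generator is a pure function of
# (configuration, seed), so each pipeline stage can be tested against
# ground truth without any downloads.

# rotate v about unit axis u by angle a (Rodrigues)
rotate_about <- function(v, u, a) {
  u <- normalize(u)
  v * cos(a) + cross3(u, v) * sin(a) + u * sum(u * v) * (1 - cos(a))
}

to_local <- function(frame, p_global) {
  as.numeric(t(frame$rotation) %*% (p_global - frame$origin))
}

frame_in_parent_of <- function(parent_frame, child_frame) {
  R <- t(parent_frame$rotation) %*% child_frame$rotation
  p <- to_local(parent_frame, child_frame$origin)
  frame_def(p, R)
}

# Maximum allowable ranges of motion (degrees) used by the reference
# topology: trunk joints, then leg joints by anterior-posterior position.
# Leg values are identical for left and right.  NA marks blocked DOFs.
ROM_TRUNK <- list(
  head = c(abduction = 75, internal_rotation = 40, flexion = 120),
  abdomen = c(abduction = 25, internal_rotation = 60, flexion = 100)
)
ROM_LEGS <- list(
  front = list(th_cox = c(70, 40, 80), cox_tro = c(120, 165, 180),
               tro_fe = 130, fe_ti = 160, ti_mt = 190, mt_ta = 200),
  middle = list(th_cox = c(80, 55, 100), cox_tro = c(NA, NA, 120),
                tro_fe = 180, fe_ti = 165, ti_mt = 200, mt_ta = 200),
  rear = list(th_cox = c(110, 105, 105), cox_tro = c(NA, NA, 130),
              tro_fe = 120, fe_ti = 190, ti_mt = 175, mt_ta = 240)
)

#' Synthetic hexapod whole-body model
#'
#' Builds a floating-base model in the ant's topology: thorax (free
#' 6-DOF base), head and abdomen on ball joints, a petiole hinge, and six
#' legs of coxa / trochanter / femur / tibia / metatarsus / tarsus.
#' Thorax/coxa joints are ball-and-socket; coxa/trochanter is
#' ball-and-socket on the front legs and has abduction and internal
#' rotation locked on the middle and rear legs; the remaining leg joints
#' are hinges.  Range-of-motion limits default to the reference maximum
#' allowable spans, centered on the neutral pose.  Each segment carries
#' two markers named by the `<f|m|r><l|r>_<anatomy><1|2>` grammar
#' (trunk markers omit the leg prefix).  Default segment lengths give a
#' body of about 6.6 mm.
#'
#' Every ball and hinge joint stores its generating geometry (sphere
#' center or condyle endpoints, plus the sagittal plane) in parent
#' coordinates, so [perturb_joint_parameters()] can rebuild frames from
#' perturbed geometry.
#'
#' @param petiole_rom_deg span of the petiole hinge (degrees; its
#'   allowable range is not part of the reference tables).
#' @param scale overall geometric scale factor (1 = ~6.6 mm body).
#' @return a [assemble_model()] result with 40 segments, 65 free DOF and
#'   80 markers.
#' @export
make_synthetic_hexapod <- function(petiole_rom_deg = 40, scale = 1) {
  sagittal <- plane_def(c(1, 0, 0), c(0, 0, 1.2) * scale)
  segs <- list()
  frames <- list()   # global frame per segment, reference pose
  marker_sets <- list()

  add_segment <- function(name, parent, joint, frame, markers_global,
                          meta = list()) {
    frames[[name]] <<- frame
    local_markers <- lapply(markers_global, to_local, frame = frame)
    segs[[name]] <<- segment_spec(name, parent, joint,
                                  markers = local_markers, meta = meta)
  }

  ball_joint <- function(name, center, parent_frame, rom = NULL,
                         locked = NULL) {
    frame <- build_ball_frame(center, parent_frame$origin, sagittal)
    j <- joint_spec(name, "ball3",
                    frame_in_parent = frame_in_parent_of(parent_frame, frame),
                    rom = rom, locked = locked)
    j$geom <- list(kind = "ball",
                   center = to_local(parent_frame, center),
                   normal = as.numeric(t(parent_frame$rotation) %*%
                                         sagittal$unit_normal),
                   plane_point = to_local(parent_frame,
                                          sagittal$point_on_plane))
    list(joint = j, frame = frame)
  }

  hinge_joint <- function(name, point_a, point_b, parent_frame, rom = NULL) {
    axis <- hinge_axis_from_centers(point_a, point_b)
    frame <- build_hinge_frame(axis, parent_frame$origin, sagittal)
    j <- joint_spec(name, "hinge1",
                    frame_in_parent = frame_in_parent_of(parent_frame, frame),
                    rom = rom)
    j$geom <- list(kind = "hinge",
                   point_a = to_local(parent_frame, point_a),
                   point_b = to_local(parent_frame, point_b),
                   normal = as.numeric(t(parent_frame$rotation) %*%
                                         sagittal$unit_normal),
                   plane_point = to_local(parent_frame,
                                          sagittal$point_on_plane))
    list(joint = j, frame = frame)
  }

  # ---- trunk -------------------------------------------------------------
  # body coordinates: y anterior, z up, x to the ant's right; the ant
  # stands with the thorax midline 1.2 mm above ground
  P_h <- c(0, 1.0, 1.4) * scale    # thorax/head joint center
  P_a <- c(0, -1.0, 1.3) * scale   # thorax/petiole joint center
  thorax_frame <- build_thorax_frame(P_h, P_a, sagittal)
  base_joint <- joint_spec("base", "free6", frame_in_parent = thorax_frame)
  thorax_markers <- list(
    th1 = c(0.35, 0.55, 1.75) * scale,
    th2 = c(-0.3, -0.6, 1.7) * scale
  )
  segs[["thorax"]] <- segment_spec(
    "thorax", "ground", base_joint,
    markers = lapply(thorax_markers, to_local, frame = thorax_frame),
    meta = list(joint_label = "base"))
  frames[["thorax"]] <- thorax_frame

  hd <- ball_joint("thorax_head", P_h, thorax_frame,
                   rom = unname(ROM_TRUNK$head))
  add_segment("head", "thorax", hd$joint, hd$frame,
              list(hd1 = c(0, 1.55, 1.75) * scale,
                   hd2 = c(0.35, 1.95, 1.35) * scale),
              meta = list(joint_label = "thorax/head"))

  pt <- hinge_joint("thorax_petiole",
                    c(0.2, -1.15, 1.3) * scale, c(-0.2, -1.15, 1.3) * scale,
                    thorax_frame, rom = petiole_rom_deg)
  add_segment("petiole", "thorax", pt$joint, pt$frame,
              list(pet1 = c(0.1, -1.25, 1.45) * scale,
                   pet2 = c(-0.08, -1.45, 1.25) * scale),
              meta = list(joint_label = "thorax/petiole"))

  ab <- ball_joint("petiole_abdomen", c(0, -1.55, 1.25) * scale,
                   frames[["petiole"]], rom = unname(ROM_TRUNK$abdomen))
  add_segment("abdomen", "petiole", ab$joint, ab$frame,
              list(abd1 = c(0, -2.2, 1.7) * scale,
                   abd2 = c(0.4, -2.85, 1.3) * scale),
              meta = list(joint_label = "thorax/abdomen"))

  # ---- legs --------------------------------------------------------------
  # legs splay outward slightly downward; the femur rises (insect knees sit
  # above the body line), the tibia and metatarsus descend to the ground
  # and the tarsus runs roughly flat on it
  leg_defs <- list(
    front = list(root = c(0.45, 0.75, 1.05), dir = c(0.85, 0.45, -0.12)),
    middle = list(root = c(0.5, 0.0, 1.05), dir = c(0.98, 0.0, -0.12)),
    rear = list(root = c(0.45, -0.75, 1.05), dir = c(0.85, -0.45, -0.12))
  )
  lengths <- c(cox = 0.45, tro = 0.35, fe = 1.55, ti = 1.45,
               mt = 0.9, ta = 0.55) * scale
  pitch <- c(fe = 25, ti = -52, mt = -8, ta = 42) * DEG
  rom_key <- c(cox = "th_cox", tro = "cox_tro", fe = "tro_fe",
               ti = "fe_ti", mt = "ti_mt", ta = "mt_ta")
  joint_lbl <- c(cox = "thorax/cox", tro = "cox/tro", fe = "tro/fe",
                 ti = "fe/ti", mt = "ti/mt", ta = "mt/ta")

  for (pos in names(leg_defs)) {
    for (side in c("right", "left")) {
      pre <- paste0(substr(pos, 1, 1), substr(side, 1, 1))
      mir <- function(p) if (side == "left") p * c(-1, 1, 1) else p
      root <- mir(leg_defs[[pos]]$root * scale)
      d <- normalize(mir(leg_defs[[pos]]$dir))
      # hinge axes: horizontal, perpendicular to the leg direction
      axis_dir <- normalize(cross3(c(0, 0, 1), d))
      rom_set <- ROM_LEGS[[pos]]
      meta <- list(side = side, leg = pos)

      # joint centers along the leg, with per-segment downward pitch
      centers <- list(cox = root)
      dirs <- list(cox = d)
      prev <- root; dcur <- d
      seg_order <- c("cox", "tro", "fe", "ti", "mt", "ta")
      for (i in seq_along(seg_order)[-1]) {
        nm <- seg_order[i]
        prev <- prev + dirs[[seg_order[i - 1]]] * lengths[[seg_order[i - 1]]]
        dcur <- if (nm %in% names(pitch)) {
          rotate_about(dcur, axis_dir * (if (side == "left") -1 else 1),
                       pitch[[nm]])
        } else dcur
        centers[[nm]] <- prev
        dirs[[nm]] <- dcur
      }
      tip <- centers$ta + dirs$ta * lengths[["ta"]]

      parent <- "thorax"
      for (i in seq_along(seg_order)) {
        nm <- seg_order[i]
        seg_name <- paste0(pre, "_", nm)
        parent_frame <- frames[[parent]]
        jname <- paste0(pre, "_", joint_lbl[[nm]])
        rom <- rom_set[[rom_key[[nm]]]]
        if (nm == "cox") {
          jt <- ball_joint(jname, centers[[nm]], parent_frame,
                           rom = unname(rom))
        } else if (nm == "tro") {
          locked <- is.na(rom)
          jt <- ball_joint(jname, centers[[nm]], parent_frame,
                           rom = unname(rom), locked = unname(locked))
        } else {
          pa <- centers[[nm]] + axis_dir * 0.22 * scale
          pb <- centers[[nm]] - axis_dir * 0.22 * scale
          jt <- hinge_joint(jname, pa, pb, parent_frame, rom = unname(rom))
        }
        a <- centers[[nm]]
        b <- if (i < length(seg_order)) centers[[seg_order[i + 1]]] else tip
        u <- axis_dir
        v <- normalize(cross3(axis_dir, dirs[[nm]]))
        mks <- list(a + 0.3 * (b - a) + 0.1 * scale * u,
                    a + 0.92 * (b - a) - 0.07 * scale * v)
        names(mks) <- paste0(pre, "_", nm, 1:2)
        add_segment(seg_name, parent, jt$joint, jt$frame, mks,
                    meta = c(meta, list(joint_label = joint_lbl[[nm]])))
        parent <- seg_name
      }
    }
  }
  assemble_model(unname(segs))
}

#' Synthetic gait specification
#'
#' Conditions of the emulated recording: a gait cycle of 1.39 s sampled at
#' 100 Hz, smooth periodic joint-angle oscillations bounded by the
#' range-of-motion limits, tripod phasing (opposite tripods in antiphase)
#' and a mean forward speed of 3.4 mm/s.
#'
#' @param duration cycle duration (s).
#' @param rate sampling rate (Hz).
#' @param amplitude_frac leg-joint oscillation amplitude as a fraction of
#'   each DOF's half-span (fundamental plus a 30 % second harmonic stays
#'   within the limits for values up to ~0.7).
#' @param trunk_amplitude_deg oscillation amplitude of trunk joints
#'   (capped at 45 % of each half-span).
#' @param base_amplitude_deg oscillation amplitude of the floating-base
#'   rotations.
#' @param speed_mm_s mean forward walking speed.
#' @param noise marker noise model: `"none"`, `"gaussian"` (isotropic,
#'   `noise_mm` = sd) or `"uniform_ball"` (`noise_mm` = radius).
#' @param noise_mm noise magnitude (mm).
#' @param seed seed for trial rendering.
#' @return Object of class `synthetic_gait_spec`.
#' @export
synthetic_gait_spec <- function(duration = 1.39, rate = 100,
                                amplitude_frac = 0.3,
                                trunk_amplitude_deg = 6,
                                base_amplitude_deg = 1.5,
                                speed_mm_s = 3.4,
                                noise = c("none", "gaussian", "uniform_ball"),
                                noise_mm = 0, seed = 1L) {
  noise <- match.arg(noise)
  if (duration * rate < 2) {
    stop_antkin("duration x rate must give at least 2 samples",
                "invalid_parameter")
  }
  if (amplitude_frac < 0 || amplitude_frac > 0.7) {
    stop_antkin("amplitude_frac must lie in [0, 0.7] to respect the limits",
                "invalid_parameter")
  }
  structure(
    list(duration = duration, rate = rate, amplitude_frac = amplitude_frac,
         trunk_amplitude_deg = trunk_amplitude_deg,
         base_amplitude_deg = base_amplitude_deg,
         speed_mm_s = speed_mm_s, noise = noise, noise_mm = noise_mm,
         seed = as.integer(seed)),
    class = "synthetic_gait_spec"
  )
}

# tripod membership: right front + left middle + right rear move in phase;
# the opposite tripod is shifted by pi
tripod_phase <- function(side, leg) {
  first <- (side == "right" & leg %in% c("front", "rear")) |
    (side == "left" & leg == "middle")
  ifelse(first, 0, pi)
}

#' Ground-truth gait trajectories
#'
#' Smooth sum-of-sines trajectories for every free DOF: leg and trunk
#' rotations oscillate at the cycle fundamental (plus a 30 % second
#' harmonic for the legs) with tripod phase offsets; the base translates
#' forward at constant mean speed with a small vertical bounce.  The
#' generated series is validated against the range-of-motion limits.
#'
#' @param model a [make_synthetic_hexapod()] (or compatible) model.
#' @param spec a [synthetic_gait_spec()].
#' @return list with `q` (`n_dof x frames` pose matrix, radians / mm),
#'   `time` (s) and `spec`.
#' @export
make_gait_trajectories <- function(model, spec = synthetic_gait_spec()) {
  stopifnot(inherits(model, "kinematic_model"),
            inherits(spec, "synthetic_gait_spec"))
  nf <- floor(spec$duration * spec$rate)
  t <- (seq_len(nf) - 1) / spec$rate
  f <- 1 / spec$duration
  dt <- model$dof_table
  free <- dt[!dt$locked, ]
  free <- free[order(free$q_index), ]
  stagger_keys <- sort(unique(paste(free$joint_label, free$dof)))
  q <- matrix(0, model$n_dof, nf)
  for (i in seq_len(nrow(free))) {
    row <- free[i, ]
    if (row$kind == "translation") {
      q[row$q_index, ] <- switch(row$dof,
        ty = spec$speed_mm_s * t,
        # small vertical bounce at twice the cycle frequency, scaled with
        # the overall oscillation amplitude so a zero-amplitude spec is
        # exactly static
        tz = 0.1 * spec$amplitude_frac * sin(2 * pi * 2 * f * t),
        0)
      next
    }
    half <- min(abs(row$rom_min), abs(row$rom_max))
    # deterministic phase stagger shared by homologous DOFs of left and
    # right legs, so mirrored legs of opposite tripods are in exact
    # antiphase
    stagger <- 0.7 * (match(paste(row$joint_label, row$dof),
                            stagger_keys) %% 5)
    if (row$joint_type == "free6") {
      amp <- deg2rad(min(spec$base_amplitude_deg, 0.45 * half))
      q[row$q_index, ] <- amp * sin(2 * pi * f * t + stagger)
    } else if (is.na(row$leg)) {
      amp <- deg2rad(min(spec$trunk_amplitude_deg, 0.45 * half))
      q[row$q_index, ] <- amp * sin(2 * pi * f * t + stagger)
    } else {
      amp <- deg2rad(spec$amplitude_frac * half)
      ph <- tripod_phase(row$side, row$leg) + stagger
      q[row$q_index, ] <- amp * (sin(2 * pi * f * t + ph) +
                                   0.3 * sin(4 * pi * f * t + 2 * ph))
    }
  }
  for (i in seq_len(nf)) {
    viol <- check_rom(model, q[, i])
    if (nrow(viol) > 0) {
      stop_antkin(sprintf(
        "generated trajectory violates range of motion at frame %d (%s %s)",
        i, viol$segment[1], viol$dof[1]), "invalid_parameter")
    }
  }
  list(q = q, time = t, spec = spec)
}

#' Render a marker trial from ground-truth poses
#'
#' Runs forward kinematics at each pose and applies the configured marker
#' noise.  The generating poses are retained in the `ground_truth`
#' attribute so recovery tests never re-derive them.
#'
#' @param model a [assemble_model()] result.
#' @param pose_series a [make_gait_trajectories()] result (or a list with
#'   `q` and `time`).
#' @param noise,noise_mm,seed override the noise model of the pose
#'   series' spec (defaults taken from it when present).
#' @param rate sampling rate (Hz); default from the pose series.
#' @return a [marker_trial()] with attribute `ground_truth`
#'   (list of `q` and `time`).
#' @export
render_marker_trial <- function(model, pose_series, noise = NULL,
                                noise_mm = NULL, seed = NULL, rate = NULL) {
  stopifnot(inherits(model, "kinematic_model"))
  spec <- pose_series$spec
  if (is.null(noise)) noise <- if (is.null(spec)) "none" else spec$noise
  if (is.null(noise_mm)) noise_mm <- if (is.null(spec)) 0 else spec$noise_mm
  if (is.null(seed)) seed <- if (is.null(spec)) 1L else spec$seed
  if (is.null(rate)) {
    rate <- if (is.null(spec)) 1 / diff(pose_series$time[1:2]) else spec$rate
  }
  q <- pose_series$q
  nf <- ncol(q)
  nm <- length(model$marker_names)
  data <- array(0, c(nf, nm, 3))
  for (i in seq_len(nf)) {
    data[i, , ] <- fk_markers_cpp(model$cpp, q[, i])
  }
  if (noise != "none" && noise_mm > 0) {
    set.seed(seed)
    if (noise == "gaussian") {
      data <- data + array(rnorm(length(data), sd = noise_mm), dim(data))
    } else {
      off <- sample_uniform_ball(noise_mm, nf * nm)
      data <- data + array(off, c(nf, nm, 3))
    }
  }
  out <- marker_trial(data, model$marker_names, rate,
                      time = pose_series$time)
  attr(out, "ground_truth") <- list(q = q, time = pose_series$time)
  out
}

#' Synthetic articular-surface point cloud
#'
#' Points uniformly distributed on a spherical cap, with optional radial
#' Gaussian noise — a stand-in for an operator-selected articular surface
#' patch.  The generator parameters are returned as attributes (ground
#' truth for fitting tests).
#'
#' @param center sphere center (mm).
#' @param radius sphere radius (mm), > 0.
#' @param cap_half_angle_deg cap half-angle in (0, 90].
#' @param n number of points (>= 4).
#' @param noise_sd radial Gaussian noise sd (mm).
#' @param axis cap symmetry axis (default +z).
#' @param seed optional seed.
#' @return `n x 3` matrix with attributes `center`, `radius`,
#'   `cap_half_angle_deg` and `axis`.
#' @export
make_articular_surface <- function(center = c(0, 0, 0), radius = 0.3,
                                   cap_half_angle_deg = 60, n = 200,
                                   noise_sd = 0, axis = c(0, 0, 1),
                                   seed = NULL) {
  if (radius <= 0) stop_antkin("radius must be > 0", "invalid_parameter")
  if (cap_half_angle_deg <= 0 || cap_half_angle_deg > 90) {
    stop_antkin("cap half-angle must lie in (0, 90]", "invalid_parameter")
  }
  if (n < 4) stop_antkin("need at least 4 points", "invalid_parameter")
  if (!is.null(seed)) set.seed(seed)
  center <- as_point3(center); axis <- normalize(as_point3(axis))
  # uniform on the cap: cos(theta) uniform in [cos(alpha), 1]
  u <- runif(n, cos(deg2rad(cap_half_angle_deg)), 1)
  phi <- runif(n, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - u^2))
  local <- cbind(st * cos(phi), st * sin(phi), u)
  r <- radius + if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
  # rotate +z onto the requested axis
  z <- c(0, 0, 1)
  if (vnorm(axis - z) < 1e-12) {
    R <- diag(3)
  } else if (vnorm(axis + z) < 1e-12) {
    R <- diag(c(1, -1, -1))
  } else {
    v <- cross3(z, axis)
    s <- vnorm(v); cth <- sum(z * axis)
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  pts <- (local * r) %*% t(R)
  pts <- sweep(pts, 2, center, `+`)
  structure(pts, center = center, radius = radius,
            cap_half_angle_deg = cap_half_angle_deg, axis = axis)
}
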