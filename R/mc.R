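#' Perturbation specification for Monte Carlo uncertainty propagation
#'
#' Uncertainty zones are uniform: spherical (solid ball) for model marker
#' positions and ball-and-socket joint centers, cylindrical for hinge axes
#' (realized by independently displacing the two axis-defining condyle
#' points inside balls of the zone radius, which keeps the perturbed axis
#' inside the stated cylinder).  Default radii: 0.4 mm for markers (a
#' common camera-calibration residual at this scale) and 0.2 mm for joint
#' geometrical parameters (operator variability of articular-surface
#' identification).
#'
#' @param target `"model_markers"` or `"joint_parameters"`.
#' @param radius uncertainty-zone radius in mm (defaults 0.4 / 0.2 by
#'   target).
#' @param n_iterations Monte Carlo iterations (default 1000).
#' @param seed master seed; per-iteration substream seeds are derived from
#'   it.
#' @param coverage_multiplier coverage-interval width as a multiple of the
#'   per-time-step standard deviation (default 2: width = 2 sd).
#' @return Object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(target = c("model_markers", "joint_parameters"),
                              radius = NULL, n_iterations = 1000L,
                              seed = 1L, coverage_multiplier = 2) {
  target <- match.arg(target)
  if (is.null(radius)) {
    radius <- if (target == "model_markers") 0.4 else 0.2
  }
  if (radius < 0) stop_antkin("radius must be >= 0", "invalid_parameter")
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1L) {
    stop_antkin("n_iterations must be >= 1", "invalid_parameter")
  }
  structure(
    list(target = target, radius = radius, n_iterations = n_iterations,
         seed = as.integer(seed), coverage_multiplier = coverage_multiplier),
    class = "perturbation_spec"
  )
}

#' Uniform samples inside a ball
#'
#' Draws offsets uniformly distributed in the closed ball of the given
#' radius (uniform over the solid zone, not its surface), using R's
#' current random-number stream.  The mean offset norm is `3 R / 4`.
#'
#' @param radius ball radius (mm), >= 0.
#' @param n number of draws.
#' @return `n x 3` matrix of offsets (mm).
#' @export
sample_uniform_ball <- function(radius, n = 1L) {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) ||
      radius < 0) {
    stop_antkin("radius must be a non-negative scalar", "invalid_parameter")
  }
  n <- as.integer(n)
  if (radius == 0) return(matrix(0, n, 3))
  g <- matrix(rnorm(3 * n), n, 3)
  nrm <- sqrt(rowSums(g^2))
  nrm[nrm < 1e-300] <- 1
  r <- radius * runif(n)^(1 / 3)
  g / nrm * r
}

#' Perturb model marker placements
#'
#' Offsets every model marker's segment-local position by an independent
#' uniform-ball sample of the given radius — one draw per marker, held
#' fixed over the trial, modeling marker placement/identification error
#' rather than per-frame tracking noise.  Topology and joints are
#' untouched.
#'
#' @param model a [assemble_model()] result.
#' @param radius uncertainty-zone radius (mm).
#' @return a perturbed [assemble_model()] result.
#' @export
perturb_marker_set <- function(model, radius) {
  stopifnot(inherits(model, "kinematic_model"))
  if (radius < 0) stop_antkin("radius must be >= 0", "invalid_parameter")
  if (radius == 0) return(model)
  segments <- model$segments
  for (s in names(segments)) {
    mk <- segments[[s]]$markers
    if (!length(mk)) next
    off <- sample_uniform_ball(radius, length(mk))
    segments[[s]]$markers <- lapply(seq_along(mk), function(k)
      mk[[k]] + off[k, ])
    names(segments[[s]]$markers) <- names(mk)
  }
  assemble_model(unname(segments))
}

#' Perturb joint geometrical parameters
#'
#' Ball-and-socket joint centers are displaced by uniform-ball samples;
#' hinge joints have their two axis-defining condyle points displaced by
#' independent uniform-ball samples (axis stays within a cylinder of the
#' zone radius around the nominal axis).  Joint frames are rebuilt from
#' the perturbed geometry, so both the location and the orientation of
#' each joint change.  Joints without stored geometry (the floating base,
#' locked attachments) are untouched.  A perturbation that collapses the
#' two hinge points (< 1e-9 mm apart) is resampled internally and counted
#' in the `resampled` attribute.
#'
#' @param model a [assemble_model()] result whose joints carry geometry
#'   metadata (as built by [make_synthetic_hexapod()]).
#' @param radius uncertainty-zone radius (mm).
#' @return a perturbed [assemble_model()] result.
#' @export
perturb_joint_parameters <- function(model, radius) {
  stopifnot(inherits(model, "kinematic_model"))
  if (radius < 0) stop_antkin("radius must be >= 0", "invalid_parameter")
  if (radius == 0) return(model)
  segments <- model$segments
  resampled <- 0L
  for (s in names(segments)) {
    g <- segments[[s]]$joint$geom
    if (is.null(g)) next
    sag <- plane_def(g$normal, g$plane_point)
    if (g$kind == "ball") {
      center <- g$center + drop(sample_uniform_ball(radius, 1L))
      frame <- build_ball_frame(center, c(0, 0, 0), sag,
                                flip_x = isTRUE(g$flip_x))
      segments[[s]]$joint$geom$center <- center
    } else if (g$kind == "hinge") {
      repeat {
        pa <- g$point_a + drop(sample_uniform_ball(radius, 1L))
        pb <- g$point_b + drop(sample_uniform_ball(radius, 1L))
        if (vnorm(pb - pa) >= 1e-9) break
        resampled <- resampled + 1L
      }
      axis <- hinge_axis_from_centers(pa, pb)
      frame <- build_hinge_frame(axis, c(0, 0, 0), sag)
      segments[[s]]$joint$geom$point_a <- pa
      segments[[s]]$joint$geom$point_b <- pb
    } else {
      next
    }
    segments[[s]]$joint$frame_in_parent <- frame
  }
  out <- assemble_model(unname(segments))
  attr(out, "resampled") <- resampled
  out
}

#' Monte Carlo propagation of model parameter uncertainties
#'
#' Repeatedly perturbs the model (markers or joint geometry per
#' `spec$target`), re-solves inverse kinematics over the whole trial, and
#' summarizes per-DOF joint-angle trajectories across iterations: mean,
#' standard deviation and coverage-interval width (default twice the
#' standard deviation).  Iterations whose IK fails on any frame are
#' dropped and logged, never imputed.  Per-iteration substream seeds are
#' derived from the master seed, so a given (seed, inputs) pair yields
#' bit-identical results.
#'
#' Each iteration's frames are warm-started from the baseline
#' (unperturbed) IK solution, which is appropriate for the small
#' perturbation radii of interest.
#'
#' @param model a scaled [assemble_model()] result.
#' @param trial a preprocessed [marker_trial()].
#' @param settings an [ik_settings()].
#' @param spec a [perturbation_spec()].
#' @return Object of class `mc_result` with `mean`, `sd` and `coverage`
#'   matrices (free DOF x frames; degrees for rotations, mm for base
#'   translations), iteration bookkeeping and a running group-mean SNR
#'   diagnostic for judging stabilization of the averages.
#' @export
run_monte_carlo <- function(model, trial, settings = ik_settings(),
                            spec = perturbation_spec("model_markers")) {
  stopifnot(inherits(model, "kinematic_model"),
            inherits(trial, "marker_trial"),
            inherits(spec, "perturbation_spec"))
  baseline <- solve_ik_trial(model, trial, settings)
  if (!all(baseline$convergence)) {
    stop_antkin("baseline IK did not converge on every frame",
                "invalid_input")
  }
  nd <- model$n_dof; nf <- n_frames(trial)
  set.seed(spec$seed)
  iter_seeds <- sample.int(2147483646L, spec$n_iterations)
  perturb <- switch(spec$target,
    model_markers = function() perturb_marker_set(model, spec$radius),
    joint_parameters = function() perturb_joint_parameters(model, spec$radius))

  # Welford accumulators over iterations, per (dof, frame)
  count <- 0L
  mean_acc <- matrix(0, nd, nf)
  m2_acc <- matrix(0, nd, nf)
  failed <- integer(0)
  diag_at <- unique(pmax(1L, round(seq_len(20L) / 20 * spec$n_iterations)))
  diagnostic <- data.frame(iteration = integer(0), group_mean_snr = numeric(0))
  rot <- rotation_dof_mask(model)

  for (i in seq_len(spec$n_iterations)) {
    set.seed(iter_seeds[i])
    pm <- perturb()
    res <- tryCatch(
      solve_ik_trial(pm, trial, settings, init = baseline$q),
      error = function(e) NULL)
    if (is.null(res) || !all(res$convergence) || any(res$flagged)) {
      failed <- c(failed, i)
      next
    }
    count <- count + 1L
    delta <- res$angles - mean_acc
    mean_acc <- mean_acc + delta / count
    m2_acc <- m2_acc + delta * (res$angles - mean_acc)
    if (i %in% diag_at && count >= 2L) {
      sd_run <- sqrt(m2_acc / (count - 1L))
      cov_run <- spec$coverage_multiplier * sd_run
      snr_run <- snr_from_matrices(model, mean_acc, cov_run, rot)
      diagnostic <- rbind(diagnostic, data.frame(
        iteration = i, group_mean_snr = mean(snr_run, na.rm = TRUE)))
    }
  }
  if (count == 0L) {
    stop_antkin("every Monte Carlo iteration failed", "invalid_input")
  }
  sd_mat <- if (count >= 2L) sqrt(m2_acc / (count - 1L)) else
    matrix(0, nd, nf)
  structure(
    list(mean = mean_acc, sd = sd_mat,
         coverage = spec$coverage_multiplier * sd_mat,
         n_success = count, n_failed = length(failed),
         failed_iterations = failed, seed = spec$seed,
         coverage_multiplier = spec$coverage_multiplier,
         spec = spec, time = trial$time, dof_table = model$dof_table,
         baseline = baseline, diagnostic = diagnostic),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> %s perturbation, radius %g mm: %d successful iterations (%d failed)\n",
    x$spec$target, x$spec$radius, x$n_success, x$n_failed))
  cat(sprintf("  coverage width = %g x sd; max coverage %.3f deg\n",
              x$coverage_multiplier, max(x$coverage)))
  invisible(x)
}

# SNR per reportable DOF from mean/coverage matrices (vector along the
# reportable subset of free coordinates)
snr_from_matrices <- function(model, mean_mat, cov_mat, rot_mask) {
  dt <- model$dof_table
  free <- dt[!dt$locked, ]
  free <- free[order(free$q_index), ]
  rep_dof <- free$joint_type %in% c("ball3", "hinge1") & free$kind == "rotation"
  ps <- apply(mean_mat[rep_dof, , drop = FALSE], 1, function(v)
    max(v) - min(v))
  pn <- apply(cov_mat[rep_dof, , drop = FALSE], 1, max)
  ifelse(pn > 0, ps / pn, NA_real_)
}

#' Signal-to-noise ratio of joint-angle trajectories
#'
#' Per degree of freedom: the signal power `Ps` is the peak-to-peak
#' amplitude of the Monte Carlo mean trajectory over the gait cycle, the
#' noise power `Pn` the maximum coverage-interval width, and `SNR =
#' Ps / Pn`.  Locked DOFs and floating-base coordinates are excluded; a
#' DOF with `Pn = 0` is reported with `SNR = NA` (undefined, noted), not
#' infinity.
#'
#' @param mc a [run_monte_carlo()] result.
#' @return Object of class `snr_report`: a data frame with one row per
#'   reported DOF (`Ps`, `Pn` in degrees, dimensionless `snr`, plus the
#'   joint/side/leg annotations used by [summarize_snr()]).
#' @export
compute_snr <- function(mc) {
  stopifnot(inherits(mc, "mc_result"))
  dt <- mc$dof_table
  free <- dt[!dt$locked, ]
  free <- free[order(free$q_index), ]
  keep <- free$joint_type %in% c("ball3", "hinge1") & free$kind == "rotation"
  rows <- free[keep, c("segment", "joint", "joint_label", "dof",
                       "side", "leg")]
  idx <- free$q_index[keep]
  rows$Ps <- apply(mc$mean[idx, , drop = FALSE], 1, function(v)
    max(v) - min(v))
  rows$Pn <- apply(mc$coverage[idx, , drop = FALSE], 1, max)
  rows$snr <- ifelse(rows$Pn > 0, rows$Ps / rows$Pn, NA_real_)
  rownames(rows) <- NULL
  n_undef <- sum(rows$Pn == 0)
  structure(rows, class = c("snr_report", "data.frame"),
            note = if (n_undef > 0)
              sprintf("%d DOF with zero noise power excluded (SNR undefined)",
                      n_undef) else NULL)
}

#' Group averages of the signal-to-noise ratio
#'
#' Arithmetic means of the per-DOF SNR over standard reporting groups:
#' all joints, right- and left-hand side joints, front/middle/rear leg
#' joints, and one row per anatomical joint (leg joints averaged over the
#' six legs).  Empty groups are omitted with a warning.
#'
#' @param report a [compute_snr()] result.
#' @param grouping optional named list of row-selector functions
#'   `function(report) logical`; defaults to the standard groups.
#' @return data frame with `group`, `n_dof` and mean `snr`.
#' @export
summarize_snr <- function(report, grouping = NULL) {
  stopifnot(inherits(report, "snr_report"))
  if (is.null(grouping)) {
    grouping <- c(
      list(
        "all joints" = function(r) rep(TRUE, nrow(r)),
        "right-hand side joints" = function(r) !is.na(r$side) &
          r$side == "right",
        "left-hand side joints" = function(r) !is.na(r$side) &
          r$side == "left",
        "front legs joints" = function(r) !is.na(r$leg) & r$leg == "front",
        "middle legs joints" = function(r) !is.na(r$leg) & r$leg == "middle",
        "rear legs joints" = function(r) !is.na(r$leg) & r$leg == "rear"
      ),
      local({
        labels <- unique(report$joint_label)
        g <- lapply(labels, function(lb) {
          force(lb)
          function(r) r$joint_label == lb
        })
        names(g) <- labels
        g
      })
    )
  }
  rows <- lapply(names(grouping), function(g) {
    sel <- grouping[[g]](report)
    vals <- report$snr[sel]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) {
      warning(sprintf("SNR group '%s' is empty; omitted", g))
      return(NULL)
    }
    data.frame(group = g, n_dof = length(vals), snr = mean(vals),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a Monte Carlo joint-angle trajectory with its coverage band
#'
#' @param x a [run_monte_carlo()] result.
#' @param segment,dof selects the coordinate (segment name and DOF name).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted mean and coverage vectors.
#' @export
plot.mc_result <- function(x, segment, dof = "flexion", ...) {
  dt <- x$dof_table
  row <- which(dt$segment == segment & dt$dof == dof & !dt$locked)
  if (length(row) != 1L) {
    stop_antkin("no unique free DOF matches the segment/dof selection",
                "invalid_input")
  }
  i <- dt$q_index[row]
  m <- x$mean[i, ]; h <- x$coverage[i, ] / 2
  graphics::plot(x$time, m, type = "n", xlab = "time (s)",
                 ylab = sprintf("%s %s (deg)", segment, dof),
                 ylim = range(m - h, m + h), ...)
  graphics::polygon(c(x$time, rev(x$time)), c(m - h, rev(m + h)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$time, m, lwd = 2, col = "steelblue4")
  invisible(list(mean = m, coverage = 2 * h))
}
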