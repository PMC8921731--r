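#' Inverse-kinematics solver settings
#'
#' @param weights named numeric vector of per-marker weights (default 1 for
#'   every marker; weight 0 excludes a marker).
#' @param enforce_rom apply range-of-motion bounds during optimization.
#' @param ftol relative cost-reduction tolerance of the bounded
#'   Levenberg-Marquardt solver.
#' @param max_iter maximum solver iterations per frame.
#' @param warm_start initialize each frame from the previous frame's
#'   solution.
#' @param multi_start number of starts for the first frame (neutral pose
#'   plus `multi_start - 1` random ROM-respecting offsets, seeded).
#' @param seed seed for the multi-start offsets.
#' @return Object of class `ik_settings`.
#' @export
ik_settings <- function(weights = NULL, enforce_rom = TRUE, ftol = 1e-10,
                        max_iter = 200L, warm_start = TRUE, multi_start = 8L,
                        seed = 1L) {
  if (!is.null(weights) && (is.null(names(weights)) || any(weights < 0))) {
    stop_antkin("weights must be a named vector of non-negative values",
                "invalid_parameter")
  }
  if (ftol <= 0) stop_antkin("ftol must be positive", "invalid_parameter")
  structure(
    list(weights = weights, enforce_rom = isTRUE(enforce_rom), ftol = ftol,
         max_iter = as.integer(max_iter), warm_start = isTRUE(warm_start),
         multi_start = max(1L, as.integer(multi_start)),
         seed = as.integer(seed)),
    class = "ik_settings"
  )
}

#' Per-segment scale factors from inter-marker distances
#'
#' For each segment carrying at least one pair of markers observed in the
#' trial, the scale factor is the mean over frames (and marker pairs) of
#' the experimental inter-marker distance divided by the model's reference
#' distance.  Segments without measurable pairs inherit the parent's
#' factor (the root defaults to 1).
#'
#' @param model a [assemble_model()] result.
#' @param trial a [marker_trial()].
#' @param marker_pairs optional named list: segment name -> 2-column
#'   matrix of marker-name pairs.  Defaults to all within-segment pairs
#'   present in both model and trial.
#' @return named numeric vector of class `scale_set`.
#' @export
compute_scale_factors <- function(model, trial, marker_pairs = NULL) {
  stopifnot(inherits(model, "kinematic_model"), inherits(trial, "marker_trial"))
  mk <- model_markers(model)
  seg_names <- names(model$segments)
  if (is.null(marker_pairs)) {
    marker_pairs <- lapply(seg_names, function(s) {
      nm <- intersect(mk$name[mk$segment == s], trial$marker_names)
      if (length(nm) < 2) return(NULL)
      t(utils::combn(nm, 2))
    })
    names(marker_pairs) <- seg_names
  }
  loc <- t(model$cpp$marker_loc)
  rownames(loc) <- model$marker_names
  factors <- rep(NA_real_, length(seg_names))
  names(factors) <- seg_names
  any_pair <- FALSE
  for (s in seg_names) {
    pairs <- marker_pairs[[s]]
    if (is.null(pairs) || nrow(pairs) == 0) next
    ratios <- numeric(0)
    for (p in seq_len(nrow(pairs))) {
      a <- pairs[p, 1]; b <- pairs[p, 2]
      if (!all(c(a, b) %in% trial$marker_names)) next
      dref <- vnorm(loc[a, ] - loc[b, ])
      if (dref < 1e-12) {
        stop_antkin(sprintf(
          "model markers '%s'/'%s' coincide: scale undefined", a, b),
          "degenerate_geometry")
      }
      ok <- !trial$missing[, a] & !trial$missing[, b]
      if (!any(ok)) next
      dexp <- sqrt(rowSums((trial$data[ok, a, , drop = FALSE] -
                            trial$data[ok, b, , drop = FALSE])^2))
      ratios <- c(ratios, mean(dexp) / dref)
    }
    if (length(ratios)) {
      factors[s] <- mean(ratios)
      any_pair <- TRUE
    }
  }
  if (!any_pair) {
    stop_antkin("no measurable marker pairs in any segment", "invalid_input")
  }
  # inherit parent's factor down the tree (segments are in pre-order)
  for (s in seg_names) {
    if (is.na(factors[s])) {
      par <- model$segments[[s]]$parent
      factors[s] <- if (par == "ground") 1 else factors[par]
    }
  }
  structure(factors, class = "scale_set")
}

#' Apply per-segment scale factors to a model
#'
#' Marker local positions and the joint placement translations are scaled
#' by the owning segment's factor (a joint's placement in its parent is a
#' length of the parent, so it uses the parent's factor; the floating-base
#' placement is left unscaled).  Rotations and range-of-motion limits are
#' unchanged.
#'
#' @param model a [assemble_model()] result.
#' @param scales a [compute_scale_factors()] result (or named positive
#'   vector; missing segments default to 1).
#' @return a scaled [assemble_model()] result.
#' @export
apply_scaling <- function(model, scales) {
  stopifnot(inherits(model, "kinematic_model"))
  scales <- unclass(scales)
  if (any(scales <= 0)) {
    stop_antkin("scale factors must be positive", "invalid_parameter")
  }
  fac <- function(s) if (s %in% names(scales)) scales[[s]] else 1
  segments <- model$segments
  for (s in names(segments)) {
    seg <- segments[[s]]
    fs <- fac(s)
    fp <- if (seg$parent == "ground") 1 else fac(seg$parent)
    seg$markers <- lapply(seg$markers, function(m) m * fs)
    seg$joint$frame_in_parent$origin <- seg$joint$frame_in_parent$origin * fp
    seg$joint$frame_in_child$origin <- seg$joint$frame_in_child$origin * fs
    if (!is.null(seg$joint$geom)) {
      g <- seg$joint$geom
      for (f in intersect(names(g), c("center", "point_a", "point_b",
                                      "plane_point"))) {
        g[[f]] <- g[[f]] * fp
      }
      seg$joint$geom <- g
    }
    segments[[s]] <- seg
  }
  out <- assemble_model(unname(segments))
  out
}

# align observed markers with the model ordering; NA rows for absent markers
align_observations <- function(model, observed_markers) {
  obs <- matrix(NA_real_, length(model$marker_names), 3,
                dimnames = list(model$marker_names, c("x", "y", "z")))
  if (is.null(rownames(observed_markers))) {
    stop_antkin("observed markers must have marker names as row names",
                "invalid_input")
  }
  common <- intersect(rownames(observed_markers), model$marker_names)
  obs[common, ] <- as.matrix(observed_markers)[common, , drop = FALSE]
  obs
}

sqrt_weights <- function(model, settings) {
  w <- rep(1, length(model$marker_names))
  names(w) <- model$marker_names
  if (!is.null(settings$weights)) {
    common <- intersect(names(settings$weights), names(w))
    w[common] <- settings$weights[common]
  }
  sqrt(w)
}

# translate the base so model marker centroid matches the observed centroid
centroid_init <- function(model, q, obs, sw) {
  dt <- model$dof_table
  tr <- dt[!dt$locked & dt$kind == "translation", ]
  if (nrow(tr) == 0) return(q)
  use <- is.finite(obs[, 1]) & sw > 0
  if (!any(use)) return(q)
  mk <- fk_markers_cpp(model$cpp, q)
  delta <- colMeans(obs[use, , drop = FALSE]) -
    colMeans(mk[use, , drop = FALSE])
  seg <- model$segments[[tr$segment[1]]]
  Rp <- seg$joint$frame_in_parent$rotation
  tq <- as.numeric(t(Rp) %*% delta)
  idx <- tr$q_index[match(c("tx", "ty", "tz"), tr$dof)]
  ok <- !is.na(idx)
  q[idx[ok]] <- q[idx[ok]] + tq[ok]
  q
}

# Projected Levenberg-Marquardt for box-bounded nonlinear least squares.
# Steps solve (J'J + lambda diag(J'J)) dq = -J'r and are projected onto the
# bounds; rejected steps raise the damping.  Accept/reject makes the cost
# non-increasing by construction.  Convergence reasons:
#   zero_cost - residual numerically zero (noiseless data);
#   gradient  - projected gradient vanishes (at bounds where active);
#   ftol      - relative cost reduction below ftol on 2 successive steps;
#   plateau   - mean relative reduction over the last 10 iterations below
#               plateau_tol: the solver is creeping along a near-degenerate
#               valley of the cost (marginally identifiable DOFs; see the
#               observability warning) and the fit is stationary at
#               measurement resolution;
#   stalled   - no damping level yields a descent step;
#   max_iter  - iteration budget exhausted while still improving (not
#               converged).
lm_box <- function(costfn, ngfun, q0, lower, upper, ftol, max_iter,
                   plateau_tol = 1e-5) {
  q <- pmin(pmax(q0, lower), upper)
  ng <- ngfun(q)
  cost <- ng$cost
  init_cost <- cost
  lambda <- 1e-3
  n_small <- 0L
  cost_hist <- rep(NA_real_, max_iter)
  converged <- FALSE
  reason <- "max_iter"
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (cost < 1e-280) { converged <- TRUE; reason <- "zero_cost"; break }
    g <- as.numeric(ng$g)
    at_lo <- q <= lower + 1e-12
    at_hi <- q >= upper - 1e-12
    gp <- g
    gp[(at_lo & g > 0) | (at_hi & g < 0)] <- 0
    if (max(abs(gp)) < 1e-11 * max(1, sqrt(cost))) {
      converged <- TRUE; reason <- "gradient"; break
    }
    # active set: coordinates pinned at a bound with the gradient pushing
    # outward are frozen, and the LM subproblem is solved in the free
    # subspace (plain clipping of full steps stalls at active bounds)
    free <- !((at_lo & g > 0) | (at_hi & g < 0))
    H <- ng$H[free, free, drop = FALSE]
    gf <- g[free]
    dH <- pmax(diag(H), 1e-12)
    accepted <- FALSE
    while (!accepted) {
      A <- H
      diag(A) <- diag(H) + lambda * dH
      step_f <- tryCatch(solve(A, -gf), error = function(e) NULL)
      if (!is.null(step_f)) {
        step <- numeric(length(q))
        step[free] <- step_f
        q_new <- pmin(pmax(q + step, lower), upper)
        cost_new <- costfn(q_new)
        if (is.finite(cost_new) && cost_new <= cost) {
          rel <- (cost - cost_new) / max(cost, 1e-300)
          q <- q_new; cost <- cost_new
          lambda <- max(lambda * 0.35, 1e-12)
          accepted <- TRUE
          if (rel < ftol) {
            n_small <- n_small + 1L
            if (n_small >= 2L) { converged <- TRUE; reason <- "ftol" }
          } else n_small <- 0L
        }
      }
      if (!accepted) {
        lambda <- lambda * 4
        if (lambda > 1e14) {
          converged <- TRUE; reason <- "stalled"
          accepted <- TRUE  # leave the inner loop; q unchanged
        }
      }
    }
    cost_hist[it] <- cost
    if (!converged && it > 10L &&
        (cost_hist[it - 10L] - cost) / max(cost, 1e-300) <
          10 * plateau_tol) {
      converged <- TRUE; reason <- "plateau"
    }
    if (converged) break
    ng <- ngfun(q)
  }
  if (it >= max_iter && !converged) reason <- "max_iter"
  list(par = q, cost = cost, init_cost = init_cost, niter = it,
       converged = converged, reason = reason)
}

solve_ik_once <- function(model, obs, sw, settings, q_init) {
  bounds <- if (settings$enforce_rom) rom_bounds(model) else
    list(lower = rep(-Inf, model$n_dof), upper = rep(Inf, model$n_dof))
  fit <- lm_box(
    costfn = function(q) ik_cost_cpp(model$cpp, q, obs, sw),
    ngfun = function(q) ik_normal_cpp(model$cpp, q, obs, sw),
    q0 = q_init, lower = bounds$lower, upper = bounds$upper,
    ftol = settings$ftol, max_iter = settings$max_iter
  )
  list(q = fit$par, cost = fit$cost, init_cost = fit$init_cost,
       info = fit$reason, message = fit$reason, niter = fit$niter,
       converged = fit$converged)
}

#' Solve inverse kinematics for one frame
#'
#' Minimizes the weighted least-squares distance between observed markers
#' and the corresponding model markers, subject to range-of-motion bounds,
#' with a bounded Levenberg-Marquardt solver.
#'
#' @param model a [assemble_model()] result.
#' @param observed_markers named `markers x 3` matrix (mm); `NA` rows or
#'   entries are treated as missing.
#' @param settings an [ik_settings()].
#' @param q_init initial pose (radians / mm); defaults to the neutral pose
#'   with the base translated to align marker centroids.
#' @return list with `q` (pose, radians / mm), `rmse` (mm, weighted RMS
#'   over non-missing markers) and `status` (convergence info, costs and an
#'   observability flag raised when the Gauss-Newton approximate Hessian is
#'   near-singular).
#' @export
solve_ik_frame <- function(model, observed_markers, settings = ik_settings(),
                           q_init = NULL) {
  stopifnot(inherits(model, "kinematic_model"))
  obs <- align_observations(model, observed_markers)
  sw <- sqrt_weights(model, settings)
  used <- is.finite(obs[, 1]) & is.finite(obs[, 2]) & is.finite(obs[, 3]) &
    sw > 0
  if (3 * sum(used) < model$n_dof) {
    stop_antkin(sprintf(
      "insufficient markers: %d observed, %d DOF to determine",
      sum(used), model$n_dof), "invalid_input")
  }
  if (is.null(q_init)) {
    q_init <- centroid_init(model, neutral_pose(model), obs, sw)
  }
  sol <- solve_ik_once(model, obs, sw, settings, q_init)
  ev <- eigen(ik_normal_cpp(model$cpp, sol$q, obs, sw)$H,
              symmetric = TRUE, only.values = TRUE)$values
  obs_warn <- ev[length(ev)] < 1e-8 * ev[1]
  wsum <- sum(sw[used]^2)
  list(
    q = sol$q,
    rmse = sqrt(sol$cost / wsum),
    status = list(info = sol$info, message = sol$message,
                  converged = sol$converged, cost = sol$cost,
                  init_cost = sol$init_cost,
                  observability_warning = obs_warn)
  )
}

#' Solve inverse kinematics over a whole trial
#'
#' The first frame is solved with multi-start from the neutral pose (plus
#' seeded random ROM-respecting offsets); subsequent frames are
#' warm-started from the previous solution.  Frames with insufficient
#' markers are flagged and excluded from the averages.
#'
#' @param model a [assemble_model()] result (scaled to the specimen).
#' @param trial a preprocessed [marker_trial()] (filtered / resampled /
#'   cropped).
#' @param settings an [ik_settings()].
#' @param init optional `n_dof x frames` matrix of initial poses (radians);
#'   when given it replaces both the multi-start and the warm start.
#' @param body_length_mm specimen body length used for the normalized RMSE
#'   (`NA` to skip).
#' @return Object of class `ik_result`: coordinate trajectories in internal
#'   units (`q`, radians / mm) and reporting units (`angles`, degrees for
#'   rotations), per-frame marker RMSE (mm) and convergence status, the
#'   average RMSE, and the normalized RMSE in % of body length.
#' @export
solve_ik_trial <- function(model, trial, settings = ik_settings(),
                           init = NULL, body_length_mm = NA_real_) {
  stopifnot(inherits(model, "kinematic_model"), inherits(trial, "marker_trial"))
  nf <- n_frames(trial)
  nd <- model$n_dof
  sw <- sqrt_weights(model, settings)
  bounds <- rom_bounds(model)
  qmat <- matrix(NA_real_, nd, nf)
  rmse <- rep(NA_real_, nf)
  conv <- rep(FALSE, nf)
  flagged <- logical(nf)
  obs_warns <- 0L
  q_prev <- NULL
  for (i in seq_len(nf)) {
    obs <- align_observations(model, trial_frame(trial, i))
    used <- rowSums(is.finite(obs)) == 3 & sw > 0
    if (3 * sum(used) < nd) {
      flagged[i] <- TRUE
      next
    }
    wsum <- sum(sw[used]^2)
    if (!is.null(init)) {
      sol <- solve_ik_once(model, obs, sw, settings, init[, i])
    } else if (i == 1L || !settings$warm_start || is.null(q_prev)) {
      # multi-start around neutral
      starts <- list(centroid_init(model, neutral_pose(model), obs, sw))
      if (settings$multi_start > 1L) {
        set.seed(settings$seed)
        lo <- pmax(bounds$lower, -pi); hi <- pmin(bounds$upper, pi)
        for (k in seq_len(settings$multi_start - 1L)) {
          qr0 <- neutral_pose(model) +
            runif(nd, 0.5 * lo, 0.5 * hi)
          starts[[k + 1L]] <- centroid_init(model, qr0, obs, sw)
        }
      }
      sols <- lapply(starts, function(q0)
        solve_ik_once(model, obs, sw, settings, q0))
      sol <- sols[[which.min(vapply(sols, `[[`, 0, "cost"))]]
    } else {
      sol <- solve_ik_once(model, obs, sw, settings, q_prev)
    }
    qmat[, i] <- sol$q
    rmse[i] <- sqrt(sol$cost / wsum)
    conv[i] <- sol$converged
    q_prev <- sol$q
  }
  ok <- !flagged & conv
  angles <- qmat
  rot <- rotation_dof_mask(model)
  angles[rot, ] <- rad2deg(angles[rot, ])
  avg_rmse <- mean(rmse[ok])
  structure(
    list(q = qmat, angles = angles, time = trial$time,
         rmse_per_frame = rmse, convergence = conv, flagged = flagged,
         avg_rmse = avg_rmse,
         normalized_rmse = 100 * avg_rmse / body_length_mm,
         dof_table = model$dof_table, settings = settings),
    class = "ik_result"
  )
}

#' @export
print.ik_result <- function(x, ...) {
  cat(sprintf(
    "<ik_result> %d DOF x %d frames; %d converged, %d flagged; average marker RMSE %.4g mm\n",
    nrow(x$q), ncol(x$q), sum(x$convergence), sum(x$flagged), x$avg_rmse))
  if (is.finite(x$normalized_rmse)) {
    cat(sprintf("  normalized RMSE: %.2f %% of body length\n",
                x$normalized_rmse))
  }
  invisible(x)
}

#' Range of motion of solved joint angles
#'
#' Max minus min of each DOF trajectory over the converged frames of the
#' gait cycle, in degrees (mm for base translations).  Locked DOFs are
#' reported as `NA`.
#'
#' @param result an [solve_ik_trial()] result.
#' @return data frame: one row per DOF of the model description with the
#'   observed span in the `rom` column.
#' @export
range_of_motion <- function(result) {
  stopifnot(inherits(result, "ik_result"))
  ok <- result$convergence & !result$flagged
  if (!any(ok)) {
    stop_antkin("no converged frames: range of motion undefined",
                "invalid_input")
  }
  dt <- result$dof_table
  dt$rom <- NA_real_
  for (i in seq_len(nrow(dt))) {
    if (dt$locked[i]) next
    traj <- result$angles[dt$q_index[i], ok]
    dt$rom[i] <- max(traj) - min(traj)
  }
  dt[, c("segment", "joint", "joint_label", "dof", "kind", "side", "leg",
         "locked", "rom")]
}

#' Export an IK result as CSV
#'
#' One row per frame: time, every coordinate (degrees for rotations, mm
#' for translations) and the per-frame marker RMSE.
#'
#' @param result an [solve_ik_trial()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ik_csv <- function(result, path) {
  stopifnot(inherits(result, "ik_result"))
  dt <- result$dof_table
  free <- dt[!dt$locked, ]
  free <- free[order(free$q_index), ]
  df <- data.frame(time = result$time, t(result$angles))
  names(df) <- c("time", paste(free$segment, free$dof, sep = "."))
  df$marker_rmse <- result$rmse_per_frame
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
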