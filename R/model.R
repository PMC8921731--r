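JOINT_TYPES <- c(free6 = 6L, ball3 = 3L, hinge1 = 1L, locked0 = 0L)
JOINT_CODE <- c(free6 = 0L, ball3 = 1L, hinge1 = 2L, locked0 = 3L)

default_dof_names <- function(type) {
  switch(type,
    free6 = c("tx", "ty", "tz", "rx", "ry", "rz"),
    ball3 = c("abduction", "internal_rotation", "flexion"),
    hinge1 = "flexion",
    locked0 = character(0)
  )
}

#' Joint specification
#'
#' Describes a joint connecting a segment to its parent.  Supported types:
#' `free6` (floating base: 3 translations in mm + 3 rotations), `ball3`
#' (ball-and-socket, intrinsic x-y-z rotations named abduction, internal
#' rotation, flexion), `hinge1` (single rotation about the joint z-axis,
#' named flexion) and `locked0` (rigid attachment).
#'
#' Sign conventions follow the anatomical definition used throughout:
#' abduction is a positive rotation about x, internal rotation positive
#' about y, extension positive (and flexion negative) about z.
#'
#' @param name joint name.
#' @param type one of `"free6"`, `"ball3"`, `"hinge1"`, `"locked0"`.
#' @param frame_in_parent a [frame_def()] placing the joint frame in the
#'   parent segment's coordinates.
#' @param frame_in_child a [frame_def()] placing the joint frame in the
#'   child segment's coordinates (identity by default: the child frame is
#'   the joint frame at the reference pose).
#' @param rom range-of-motion limits: `ndof x 2` matrix of (min, max),
#'   degrees for rotations, mm for base translations.  A single-column
#'   vector of spans `R` is interpreted as neutral-centered limits
#'   `[-R/2, +R/2]`.  Defaults: rotations (-180, 180) deg, translations
#'   unbounded.
#' @param locked logical vector, one per DOF; locked DOFs exist in the
#'   model description but contribute no optimization variables and are
#'   held at zero.
#' @return Object of class `joint_spec`.
#' @export
joint_spec <- function(name, type, frame_in_parent,
                       frame_in_child = identity_frame(),
                       rom = NULL, locked = NULL) {
  type <- match.arg(type, names(JOINT_TYPES))
  ndof <- JOINT_TYPES[[type]]
  stopifnot(inherits(frame_in_parent, "frame_def"),
            inherits(frame_in_child, "frame_def"))
  dof_names <- default_dof_names(type)
  is_trans <- if (type == "free6") c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
              else rep(FALSE, ndof)

  rom_mat <- matrix(rep(c(-180, 180), each = ndof), ndof, 2)
  if (any(is_trans)) rom_mat[is_trans, ] <- c(-Inf, Inf)[col(rom_mat[is_trans, , drop = FALSE])]
  if (!is.null(rom)) {
    if (is.null(dim(rom))) {
      if (length(rom) != ndof) {
        stop_antkin(sprintf("joint '%s': rom span vector must have %d entries",
                            name, ndof), "invalid_input")
      }
      given <- is.finite(rom)
      rom_mat[given, 1] <- -rom[given] / 2
      rom_mat[given, 2] <- rom[given] / 2
    } else {
      rom <- as.matrix(rom)
      if (!all(dim(rom) == c(ndof, 2L))) {
        stop_antkin(sprintf("joint '%s': rom must be %d x 2", name, ndof),
                    "invalid_input")
      }
      rom_mat <- rom
    }
  }
  if (ndof > 0 && any(rom_mat[, 1] >= rom_mat[, 2])) {
    stop_antkin(sprintf("joint '%s': rom min must be < max for every DOF",
                        name), "invalid_input")
  }
  if (is.null(locked)) locked <- rep(FALSE, ndof)
  if (length(locked) != ndof || !is.logical(locked)) {
    stop_antkin(sprintf("joint '%s': locked must be logical length %d",
                        name, ndof), "invalid_input")
  }
  dimnames(rom_mat) <- list(dof_names, c("min", "max"))
  structure(
    list(name = name, type = type, frame_in_parent = frame_in_parent,
         frame_in_child = frame_in_child, dof_names = dof_names,
         rom = rom_mat, locked = locked, is_translation = is_trans,
         geom = NULL),
    class = "joint_spec"
  )
}

#' Segment specification
#'
#' A rigid body attached to a parent segment (or `"ground"`) through a
#' joint, carrying virtual markers given in segment-local coordinates (mm).
#'
#' @param name unique segment name.
#' @param parent parent segment name, or `"ground"` for the base segment.
#' @param joint a [joint_spec()].
#' @param markers named list of 3-vectors (mm, segment-local).
#' @param meta optional list of annotations used for reporting, e.g.
#'   `side` (`"left"`/`"right"`), `leg` (`"front"`/`"middle"`/`"rear"`)
#'   and `joint_label` (anatomical joint name such as `"fe/ti"`).
#' @return Object of class `segment_spec`.
#' @export
segment_spec <- function(name, parent, joint, markers = list(), meta = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(parent), length(parent) == 1L,
            inherits(joint, "joint_spec"))
  if (length(markers)) {
    if (is.null(names(markers)) || anyDuplicated(names(markers))) {
      stop_antkin(sprintf("segment '%s': markers must be uniquely named",
                          name), "invalid_input")
    }
    markers <- lapply(markers, as_point3, name = "marker position")
  }
  structure(
    list(name = name, parent = parent, joint = joint,
         markers = markers, meta = meta),
    class = "segment_spec"
  )
}

#' Assemble a kinematic model from segment specifications
#'
#' Validates the topology (a tree with exactly one segment attached to
#' ground, no cycles or orphans, unique segment and marker names) and fixes
#' a deterministic coordinate layout: segments in pre-order traversal
#' (children in input order), each joint's DOFs in translation-then-
#' abduction/internal-rotation/flexion order.  Locked DOFs are part of the
#' model description but receive no coordinate index.
#'
#' @param segments list of [segment_spec()] objects.
#' @return Object of class `kinematic_model`.
#' @export
assemble_model <- function(segments) {
  if (!length(segments) || !all(vapply(segments, inherits, TRUE, "segment_spec"))) {
    stop_antkin("segments must be a non-empty list of segment_spec objects",
                "invalid_input")
  }
  nm <- vapply(segments, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop_antkin("duplicate segment names", "invalid_input")
  }
  names(segments) <- nm
  parents <- vapply(segments, `[[`, "", "parent")
  roots <- nm[parents == "ground"]
  if (length(roots) != 1L) {
    stop_antkin(sprintf(
      "exactly one segment must attach to ground (found %d)", length(roots)),
      "invalid_topology")
  }
  unknown <- setdiff(parents, c("ground", nm))
  if (length(unknown)) {
    stop_antkin(sprintf("unknown parent segment(s): %s",
                        paste(unknown, collapse = ", ")), "invalid_topology")
  }
  children <- split(nm, factor(parents, levels = c("ground", nm)))
  order <- character(0)
  visit <- function(s) {
    order <<- c(order, s)
    for (ch in children[[s]]) visit(ch)
  }
  visit(roots)
  if (length(order) != length(nm)) {
    stop_antkin(sprintf(
      "segment(s) unreachable from the root (cycle or orphan): %s",
      paste(setdiff(nm, order), collapse = ", ")), "invalid_topology")
  }
  segments <- segments[order]

  all_markers <- unlist(lapply(segments, function(s) names(s$markers)))
  if (anyDuplicated(all_markers)) {
    stop_antkin("marker names must be unique across the model", "invalid_input")
  }

  # coordinate layout + flat arrays for the compiled FK core
  nseg <- length(segments)
  parent_idx <- integer(nseg)
  jtype <- integer(nseg)
  Rp <- matrix(0, 9, nseg); pp <- matrix(0, 3, nseg)
  Rci <- matrix(0, 9, nseg); pci <- matrix(0, 3, nseg)
  dofmap <- matrix(-1L, 6, nseg)
  rows <- list()
  qi <- 0L
  for (s in seq_len(nseg)) {
    seg <- segments[[s]]
    parent_idx[s] <- if (seg$parent == "ground") -1L else
      match(seg$parent, names(segments)) - 1L
    j <- seg$joint
    jtype[s] <- JOINT_CODE[[j$type]]
    Rp[, s] <- as.numeric(j$frame_in_parent$rotation)
    pp[, s] <- j$frame_in_parent$origin
    Rc <- j$frame_in_child$rotation
    Rci[, s] <- as.numeric(t(Rc))
    pci[, s] <- as.numeric(-t(Rc) %*% j$frame_in_child$origin)
    ndof <- JOINT_TYPES[[j$type]]
    if (ndof > 0) {
      for (k in seq_len(ndof)) {
        idx <- NA_integer_
        if (!j$locked[k]) {
          qi <- qi + 1L
          idx <- qi
          dofmap[k, s] <- qi - 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          segment = seg$name, joint = j$name, joint_type = j$type,
          dof = j$dof_names[k],
          kind = if (j$is_translation[k]) "translation" else "rotation",
          rom_min = j$rom[k, 1], rom_max = j$rom[k, 2],
          locked = j$locked[k], q_index = idx,
          side = if (is.null(seg$meta$side)) NA_character_ else seg$meta$side,
          leg = if (is.null(seg$meta$leg)) NA_character_ else seg$meta$leg,
          joint_label = if (is.null(seg$meta$joint_label)) j$name else
            seg$meta$joint_label,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  dof_table <- do.call(rbind, rows)
  rownames(dof_table) <- NULL

  marker_seg <- integer(0); marker_loc <- NULL; marker_names <- character(0)
  for (s in seq_len(nseg)) {
    mk <- segments[[s]]$markers
    if (length(mk)) {
      marker_seg <- c(marker_seg, rep(s - 1L, length(mk)))
      marker_loc <- cbind(marker_loc, vapply(mk, identity, numeric(3)))
      marker_names <- c(marker_names, names(mk))
    }
  }
  if (is.null(marker_loc)) marker_loc <- matrix(0, 3, 0)

  cpp <- list(parent = parent_idx, jtype = jtype, Rp = Rp, pp = pp,
              Rci = Rci, pci = pci, dofmap = dofmap,
              marker_seg = marker_seg, marker_loc = marker_loc,
              n_free = qi)
  structure(
    list(segments = segments, dof_table = dof_table, n_dof = qi,
         marker_names = marker_names, cpp = cpp),
    class = "kinematic_model"
  )
}

#' @export
print.kinematic_model <- function(x, ...) {
  cat(sprintf(
    "<kinematic_model> %d segments, %d free DOF (%d locked), %d markers\n",
    length(x$segments), x$n_dof, sum(x$dof_table$locked),
    length(x$marker_names)))
  invisible(x)
}

#' Number of free degrees of freedom
#' @param model a [assemble_model()] result.
#' @return integer count of coordinates (locked DOFs excluded).
#' @export
n_dof <- function(model) {
  stopifnot(inherits(model, "kinematic_model"))
  model$n_dof
}

#' Coordinate layout of a model
#'
#' One row per DOF (including locked ones) in the deterministic model
#' order, with range-of-motion limits in degrees (mm for base
#' translations), the coordinate index (`NA` for locked DOFs) and the
#' reporting annotations carried by the segments.
#'
#' @param model a [assemble_model()] result.
#' @return data frame.
#' @export
dof_table <- function(model) {
  stopifnot(inherits(model, "kinematic_model"))
  model$dof_table
}

#' Neutral pose
#' @param model a [assemble_model()] result.
#' @return numeric vector of zeros, one per free DOF (radians / mm).
#' @export
neutral_pose <- function(model) rep(0, n_dof(model))

check_pose <- function(model, q) {
  q <- as.numeric(q)
  if (length(q) != model$n_dof || any(!is.finite(q))) {
    stop_antkin(sprintf("pose vector must be finite with length %d",
                        model$n_dof), "invalid_input")
  }
  q
}

#' Forward kinematics
#'
#' Computes global segment poses and marker positions for a pose vector.
#' Each segment's pose is its parent's pose composed with the joint
#' placement and the joint rotation (and base translation).  Rotational
#' coordinates are radians unless `degrees = TRUE`.
#'
#' @param model a [assemble_model()] result.
#' @param q pose vector, one value per free DOF in [dof_table()] order.
#' @param degrees interpret rotational entries of `q` as degrees.
#' @return list with `markers` (named n x 3 matrix, mm, global frame) and
#'   `segment_frames` (named list of [frame_def()] in the global frame).
#' @export
forward_kinematics <- function(model, q, degrees = FALSE) {
  stopifnot(inherits(model, "kinematic_model"))
  q <- check_pose(model, q)
  if (degrees) q <- pose_to_internal(model, q)
  seg <- fk_segments_cpp(model$cpp, q)
  frames <- lapply(seq_along(model$segments), function(s) {
    frame_def(seg$p[, s], matrix(seg$R[, s], 3, 3))
  })
  names(frames) <- names(model$segments)
  mk <- fk_markers_cpp(model$cpp, q)
  dimnames(mk) <- list(model$marker_names, c("x", "y", "z"))
  list(markers = mk, segment_frames = frames)
}

# degree-facing pose -> internal radians (translations untouched)
pose_to_internal <- function(model, q) {
  rot <- rotation_dof_mask(model)
  q[rot] <- deg2rad(q[rot])
  q
}

pose_to_degrees <- function(model, q) {
  rot <- rotation_dof_mask(model)
  q[rot] <- rad2deg(q[rot])
  q
}

rotation_dof_mask <- function(model) {
  dt <- model$dof_table
  idx <- dt$q_index[!dt$locked]
  (dt$kind[!dt$locked] == "rotation")[order(idx)]
}

# lower/upper bounds in internal units (radians / mm)
rom_bounds <- function(model) {
  dt <- model$dof_table[!model$dof_table$locked, ]
  dt <- dt[order(dt$q_index), ]
  lo <- ifelse(dt$kind == "rotation", deg2rad(dt$rom_min), dt$rom_min)
  hi <- ifelse(dt$kind == "rotation", deg2rad(dt$rom_max), dt$rom_max)
  list(lower = lo, upper = hi)
}

#' Check a pose against range-of-motion limits
#'
#' @param model a [assemble_model()] result.
#' @param q pose vector (radians internally, see `degrees`).
#' @param degrees interpret rotational entries of `q` as degrees.
#' @return data frame of violations (zero rows if the pose is feasible):
#'   segment, joint, dof, value and limits in degrees, and the signed
#'   exceedance in degrees.  Limits are treated as a closed interval.
#' @export
check_rom <- function(model, q, degrees = FALSE) {
  stopifnot(inherits(model, "kinematic_model"))
  q <- check_pose(model, q)
  if (degrees) q <- pose_to_internal(model, q)
  dt <- model$dof_table
  dt <- dt[!dt$locked & dt$kind == "rotation", ]
  out <- dt[0, c("segment", "joint", "dof")]
  out$value <- numeric(0); out$rom_min <- numeric(0)
  out$rom_max <- numeric(0); out$exceedance <- numeric(0)
  tol <- 1e-12
  for (i in seq_len(nrow(dt))) {
    val <- rad2deg(q[dt$q_index[i]])
    lo <- dt$rom_min[i]; hi <- dt$rom_max[i]
    if (val < lo - tol || val > hi + tol) {
      out <- rbind(out, data.frame(
        segment = dt$segment[i], joint = dt$joint[i], dof = dt$dof[i],
        value = val, rom_min = lo, rom_max = hi,
        exceedance = if (val < lo) val - lo else val - hi,
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(out) <- NULL
  out
}

#' Marker table of a model
#' @param model a [assemble_model()] result.
#' @return data frame with marker name, owning segment and local mm
#'   coordinates.
#' @export
model_markers <- function(model) {
  stopifnot(inherits(model, "kinematic_model"))
  cpp <- model$cpp
  data.frame(
    name = model$marker_names,
    segment = names(model$segments)[cpp$marker_seg + 1L],
    x = cpp$marker_loc[1, ], y = cpp$marker_loc[2, ], z = cpp$marker_loc[3, ],
    stringsAsFactors = FALSE
  )
}

# Rebuild the flat arrays after in-place edits of segments (scaling,
# perturbation).  Topology is untouched, so validation is skipped.
rebuild_model <- function(model) {
  assemble_model(unname(model$segments))
}
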