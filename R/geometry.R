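#' Least-squares sphere fit to an articular surface
#'
#' Estimates the center and radius of a sphere from a point cloud sampled on
#' an articular surface.  The center of such a sphere serves as the center
#' of rotation of a ball-and-socket joint; pairs of fitted condyle spheres
#' define hinge axes (see [fit_hinge_axis()]).
#'
#' The fit is algebraic linear least squares (Coope formulation), which is
#' deterministic and closed-form, optionally followed by Gauss-Newton
#' refinement of the geometric (orthogonal-distance) criterion.  For exact
#' spheres both stages recover the parameters to machine precision.
#'
#' @param points n x 3 matrix (or list of 3-vectors) of surface points, mm.
#' @param refine logical; run Gauss-Newton geometric refinement (default
#'   `TRUE`).  The algebraic solution is the starting point.
#' @return Object of class `sphere_fit` with fields `center` (mm),
#'   `radius` (mm), `rms_residual` (mm, root-mean-square orthogonal distance
#'   of the points to the fitted surface) and `n_points`.
#' @examples
#' octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
#'               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
#' fit_sphere(octa)
#' @export
fit_sphere <- function(points, refine = TRUE) {
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  if (n < 4L) {
    stop_antkin("sphere fitting needs at least 4 points", "invalid_input")
  }
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[length(sv)] < 1e-9 * sv[1]) {
    stop_antkin(
      "point cloud is (near-)coplanar: sphere parameters are not identifiable",
      "degenerate_geometry"
    )
  }
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  r2 <- sol[4] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0) {
    stop_antkin("degenerate sphere fit (non-positive squared radius)",
                "degenerate_geometry")
  }
  radius <- sqrt(r2)

  if (isTRUE(refine)) {
    for (it in seq_len(25L)) {
      d <- sqrt(rowSums(sweep(pts, 2, center)^2))
      if (any(d < 1e-12)) break  # point at center: geometric criterion singular
      res <- d - radius
      # Jacobian of residual wrt (center, radius)
      J <- cbind(-sweep(pts, 2, center) / d, -1)
      step <- tryCatch(qr.solve(J, -res), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      center <- center + step[1:3]
      radius <- radius + step[4]
      if (max(abs(step)) < 1e-13 * max(1, radius)) break
    }
    if (radius <= 0) {
      stop_antkin("geometric refinement collapsed the radius",
                  "degenerate_geometry")
    }
  }

  d <- sqrt(rowSums(sweep(pts, 2, center)^2))
  structure(
    list(center = as.numeric(center), radius = radius,
         rms_residual = sqrt(mean((d - radius)^2)), n_points = n),
    class = "sphere_fit"
  )
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "<sphere_fit> center (%.4f, %.4f, %.4f) mm, radius %.4f mm, rms %.2e mm, n = %d\n",
    x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual, x$n_points
  ))
  invisible(x)
}

#' Hinge axis from two condyle spheres
#'
#' The rotation axis of a hinge joint is the line through the centers of
#' two spheres fitted to the condyles of the joint.
#'
#' @param condyle_points_a,condyle_points_b point clouds (n x 3, mm) sampled
#'   on the two condyles.
#' @param refine passed to [fit_sphere()].
#' @return Object of class `hinge_axis_fit` with fields `condyle_a`,
#'   `condyle_b` (both `sphere_fit`), `axis_dir` (unit 3-vector from
#'   condyle a to condyle b) and `midpoint` (mm, mean of the two centers;
#'   the origin of the joint coordinate system).
#' @export
fit_hinge_axis <- function(condyle_points_a, condyle_points_b, refine = TRUE) {
  fa <- fit_sphere(condyle_points_a, refine = refine)
  fb <- fit_sphere(condyle_points_b, refine = refine)
  hinge_axis_from_centers(fa, fb)
}

# Shared by fit_hinge_axis and the joint-perturbation machinery, which
# re-derives axes from displaced center points rather than point clouds.
hinge_axis_from_centers <- function(fa, fb) {
  ca <- if (inherits(fa, "sphere_fit")) fa$center else as_point3(fa)
  cb <- if (inherits(fb, "sphere_fit")) fb$center else as_point3(fb)
  sep <- vnorm(cb - ca)
  if (sep < 1e-9) {
    stop_antkin("condyle sphere centers coincide: hinge axis undefined",
                "degenerate_geometry")
  }
  structure(
    list(condyle_a = fa, condyle_b = fb,
         axis_dir = (cb - ca) / sep, midpoint = (ca + cb) / 2),
    class = "hinge_axis_fit"
  )
}

#' @export
print.hinge_axis_fit <- function(x, ...) {
  cat(sprintf(
    "<hinge_axis_fit> midpoint (%.4f, %.4f, %.4f) mm, axis (%.4f, %.4f, %.4f)\n",
    x$midpoint[1], x$midpoint[2], x$midpoint[3],
    x$axis_dir[1], x$axis_dir[2], x$axis_dir[3]
  ))
  invisible(x)
}

#' Plane definition
#'
#' A plane given by a unit normal and a point on the plane.  Used for the
#' body's sagittal plane, which fixes lateral axis directions during frame
#' construction.
#'
#' @param unit_normal 3-vector, normalized internally.
#' @param point_on_plane 3-vector (mm).
#' @return Object of class `plane_def`.
#' @export
plane_def <- function(unit_normal, point_on_plane) {
  n <- normalize(as_point3(unit_normal, "unit_normal"), "plane normal")
  structure(
    list(unit_normal = n, point_on_plane = as_point3(point_on_plane)),
    class = "plane_def"
  )
}

#' @export
print.plane_def <- function(x, ...) {
  cat(sprintf("<plane_def> normal (%.4f, %.4f, %.4f), point (%.4f, %.4f, %.4f) mm\n",
              x$unit_normal[1], x$unit_normal[2], x$unit_normal[3],
              x$point_on_plane[1], x$point_on_plane[2], x$point_on_plane[3]))
  invisible(x)
}

#' Sagittal plane from the propodeal spiracles
#'
#' The sagittal plane is perpendicular to the line through the centers of
#' two spheres fitted to the left and right propodeal spiracles and contains
#' the midpoint of those centers (the point commonly written P_SP).
#'
#' @param spiracle_points_left,spiracle_points_right spiracle point clouds
#'   (n x 3, mm).
#' @param refine passed to [fit_sphere()].
#' @return A [plane_def()]; `unit_normal` points from the left toward the
#'   right spiracle center.
#' @export
define_sagittal_plane <- function(spiracle_points_left, spiracle_points_right,
                                  refine = TRUE) {
  fl <- fit_sphere(spiracle_points_left, refine = refine)
  fr <- fit_sphere(spiracle_points_right, refine = refine)
  sep <- vnorm(fr$center - fl$center)
  if (sep < 1e-9) {
    stop_antkin("spiracle centers coincide: sagittal plane undefined",
                "degenerate_geometry")
  }
  plane_def((fr$center - fl$center) / sep, (fr$center + fl$center) / 2)
}

#' Segment coordinate system
#'
#' A right-handed orthonormal frame: an origin (mm, in a stated reference
#' frame) and a rotation matrix whose columns are the frame's x, y, z axes
#' expressed in the reference frame (local -> reference mapping).
#'
#' @param origin 3-vector (mm).
#' @param rotation 3x3 rotation matrix, validated orthonormal with
#'   determinant +1 (tolerance 1e-10).
#' @return Object of class `frame_def`.
#' @export
frame_def <- function(origin, rotation) {
  origin <- as_point3(origin, "origin")
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) {
    stop_antkin("rotation must be a 3x3 matrix", "invalid_input")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10 ||
      abs(det(rotation) - 1) > 1e-10) {
    stop_antkin("rotation is not right-handed orthonormal within 1e-10",
                "invalid_input")
  }
  structure(list(origin = origin, rotation = rotation), class = "frame_def")
}

#' @rdname frame_def
#' @param origin origin of the identity-orientation frame (mm).
#' @export
identity_frame <- function(origin = c(0, 0, 0)) frame_def(origin, diag(3))

#' @export
print.frame_def <- function(x, ...) {
  cat(sprintf("<frame_def> origin (%.4f, %.4f, %.4f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat("  axes (columns x, y, z):\n")
  print(round(x$rotation, 6))
  invisible(x)
}

# x-axis shared by thorax and ball frames: common perpendicular to the
# sagittal normal and the y-axis.  The sign is free in the anatomical
# definition; the fixed convention is x = normal x y (flip_x reverses it).
frame_from_y_and_plane <- function(origin, y_dir, sagittal, flip_x = FALSE,
                                   what = "frame") {
  y <- normalize(y_dir, paste(what, "y-axis"))
  n <- sagittal$unit_normal
  xun <- cross3(n, y)
  if (vnorm(xun) < 1e-6) {
    stop_antkin(
      sprintf("%s y-axis is parallel to the sagittal normal", what),
      "degenerate_geometry"
    )
  }
  x <- normalize(xun)
  if (isTRUE(flip_x)) x <- -x
  z <- cross3(x, y)
  frame_def(origin, cbind(x, y, z, deparse.level = 0))
}

#' Thorax coordinate system
#'
#' Origin at the midpoint of the segment joining the thorax/head and
#' thorax/abdomen joint centers (P_h and P_a); y parallel to that segment
#' and pointing anteriorly (toward P_h); x the common perpendicular to the
#' sagittal-plane normal and y; z completes the right-handed triad.
#'
#' @param P_h,P_a thorax/head and thorax/abdomen joint centers (mm).
#' @param sagittal a [plane_def()], the sagittal plane.
#' @param flip_x flip the free sign of the x-axis (and hence z).
#' @return A [frame_def()].
#' @export
build_thorax_frame <- function(P_h, P_a, sagittal, flip_x = FALSE) {
  P_h <- as_point3(P_h, "P_h"); P_a <- as_point3(P_a, "P_a")
  if (vnorm(P_h - P_a) < 1e-9) {
    stop_antkin("P_h and P_a coincide", "degenerate_geometry")
  }
  frame_from_y_and_plane((P_h + P_a) / 2, P_h - P_a, sagittal,
                         flip_x = flip_x, what = "thorax frame")
}

#' Hinge-joint coordinate system
#'
#' Origin at the midpoint of the rotation axis; z parallel to the axis and
#' pointing medially (sign chosen so that z points toward the sagittal
#' plane); y perpendicular to z and pointing toward the origin of the
#' previous segment's coordinate system; x = y x z.
#'
#' @param axis a [fit_hinge_axis()] result.
#' @param previous_frame_origin origin of the parent segment's frame (mm).
#' @param sagittal a [plane_def()], used only to resolve the medial sign
#'   of z.
#' @return A [frame_def()].
#' @export
build_hinge_frame <- function(axis, previous_frame_origin, sagittal) {
  stopifnot(inherits(axis, "hinge_axis_fit"))
  origin <- axis$midpoint
  prev <- as_point3(previous_frame_origin, "previous_frame_origin")
  z <- axis$axis_dir
  # medial direction: from the axis midpoint toward its foot on the sagittal
  # plane; flip z if it points away from the plane
  medial <- -sum((origin - sagittal$point_on_plane) * sagittal$unit_normal) *
    sagittal$unit_normal
  if (vnorm(medial) > 1e-12 && sum(z * medial) < 0) z <- -z
  yraw <- prev - origin
  yperp <- yraw - sum(yraw * z) * z
  if (vnorm(yperp) < 1e-9) {
    stop_antkin("previous frame origin lies on the hinge axis",
                "degenerate_geometry")
  }
  y <- normalize(yperp)
  x <- cross3(y, z)
  frame_def(origin, cbind(x, y, z, deparse.level = 0))
}

#' Ball-and-socket joint coordinate system
#'
#' Origin at the fitted sphere center; y along the line to the previous
#' segment's frame origin, pointing proximally (toward it); x the common
#' perpendicular to the sagittal normal and y; z completes the triad.
#'
#' @param center fitted joint center (3-vector, mm) or a `sphere_fit`.
#' @param previous_frame_origin origin of the parent segment's frame (mm).
#' @param sagittal a [plane_def()].
#' @param flip_x flip the free sign of the x-axis.
#' @return A [frame_def()].
#' @export
build_ball_frame <- function(center, previous_frame_origin, sagittal,
                             flip_x = FALSE) {
  if (inherits(center, "sphere_fit")) center <- center$center
  center <- as_point3(center, "center")
  prev <- as_point3(previous_frame_origin, "previous_frame_origin")
  if (vnorm(prev - center) < 1e-9) {
    stop_antkin("joint center coincides with the previous frame origin",
                "degenerate_geometry")
  }
  frame_from_y_and_plane(center, prev - center, sagittal,
                         flip_x = flip_x, what = "ball frame")
}

#' Read a point cloud from disk
#'
#' Accepts whitespace- or comma-separated XYZ text, ASCII PLY (vertex
#' elements only) or ASCII STL (facet vertices, deduplicated).  Only vertex
#' coordinates are used; mesh topology is ignored.  Units are assumed mm.
#'
#' @param path file path.
#' @return n x 3 numeric matrix (mm).
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) {
    stop_antkin(sprintf("no such file: %s", path), "format_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    lines <- readLines(path, warn = FALSE)
    if (!identical(lines[1], "ply")) stop_antkin("not a PLY file", "format_error")
    if (!any(grepl("^format\\s+ascii", lines))) {
      stop_antkin("only ASCII PLY is supported", "format_error")
    }
    nv <- suppressWarnings(
      as.integer(sub("^element\\s+vertex\\s+", "",
                     grep("^element\\s+vertex\\s+", lines, value = TRUE)[1]))
    )
    hdr_end <- match("end_header", lines)
    if (is.na(nv) || is.na(hdr_end)) {
      stop_antkin("malformed PLY header", "format_error")
    }
    body <- lines[(hdr_end + 1):(hdr_end + nv)]
    vals <- lapply(strsplit(trimws(body), "\\s+"),
                   function(v) as.numeric(v[1:3]))
    return(as_points_matrix(do.call(rbind, vals), "PLY vertices"))
  }
  if (ext == "stl") {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s+", lines, value = TRUE)
    if (length(vl) == 0) {
      stop_antkin("no ASCII STL vertex records found", "format_error")
    }
    vals <- lapply(strsplit(trimws(vl), "\\s+"),
                   function(v) as.numeric(v[2:4]))
    pts <- unique(do.call(rbind, vals))
    return(as_points_matrix(pts, "STL vertices"))
  }
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  vals <- lapply(strsplit(trimws(raw), "[[:space:],]+"),
                 function(v) suppressWarnings(as.numeric(v[1:3])))
  pts <- do.call(rbind, vals)
  if (any(!is.finite(pts))) {
    stop_antkin("could not parse XYZ point cloud", "format_error")
  }
  as_points_matrix(pts, "XYZ points")
}

#' Write fitted joint geometry to JSON
#'
#' Serializes a named list of `sphere_fit` / `hinge_axis_fit` / `plane_def`
#' objects into a JSON document consumed by the model builder.
#'
#' @param fits named list of fitted geometry objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(fits, path) {
  ser <- lapply(fits, function(f) {
    if (inherits(f, "sphere_fit")) {
      list(kind = "sphere", center = f$center, radius = f$radius,
           rms_residual = f$rms_residual, n_points = f$n_points)
    } else if (inherits(f, "hinge_axis_fit")) {
      list(kind = "hinge_axis", axis_dir = f$axis_dir, midpoint = f$midpoint,
           center_a = if (inherits(f$condyle_a, "sphere_fit"))
             f$condyle_a$center else f$condyle_a,
           center_b = if (inherits(f$condyle_b, "sphere_fit"))
             f$condyle_b$center else f$condyle_b)
    } else if (inherits(f, "plane_def")) {
      list(kind = "plane", unit_normal = f$unit_normal,
           point_on_plane = f$point_on_plane)
    } else {
      stop_antkin("unsupported geometry object in write_geometry_json",
                  "invalid_input")
    }
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
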