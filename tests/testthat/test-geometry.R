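test_that("sphere fitting recovers exact spheres to machine precision", {
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  f <- fit_sphere(octa)
  expect_equal(f$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(f$radius, 1, tolerance = 1e-12)
  expect_equal(f$rms_residual, 0, tolerance = 1e-12)
  expect_identical(f$n_points, 6L)

  # noiseless spherical cap, off-origin center
  cap <- make_articular_surface(center = c(1, 2, 0.5), radius = 0.35,
                                cap_half_angle_deg = 60, n = 200, seed = 11)
  f2 <- fit_sphere(cap)
  expect_lt(max(abs(f2$center - c(1, 2, 0.5))), 1e-9)
  expect_lt(abs(f2$radius - 0.35), 1e-9)
  # the algebraic start alone is already exact on noiseless data
  f3 <- fit_sphere(cap, refine = FALSE)
  expect_lt(max(abs(f3$center - c(1, 2, 0.5))), 1e-9)
})

test_that("sphere fit residual and radius are invariant under rigid motion", {
  set.seed(21)
  cap <- make_articular_surface(center = c(0.4, -0.2, 0.1), radius = 0.3,
                                cap_half_angle_deg = 50, n = 120,
                                noise_sd = 0.004, seed = 5)
  f <- fit_sphere(cap)
  for (k in 1:5) {
    R <- random_rotation()
    t <- rnorm(3)
    f2 <- fit_sphere(sweep(cap %*% t(R), 2, t, `+`))
    expect_equal(f2$radius, f$radius, tolerance = 1e-9)
    expect_equal(f2$rms_residual, f$rms_residual, tolerance = 1e-9)
    expect_equal(f2$center, as.numeric(R %*% f$center + t), tolerance = 1e-8)
  }
})

test_that("sphere fit rejects degenerate input", {
  expect_error_class(fit_sphere(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
                     "invalid_input")
  set.seed(1)
  flat <- cbind(runif(30), runif(30), 0)
  expect_error_class(fit_sphere(flat), "degenerate_geometry")
})

test_that("noisy cap centers are recovered within the stated bound", {
  errs <- vapply(1:100, function(s) {
    cap <- make_articular_surface(center = c(1, 2, 0.5), radius = 0.35,
                                  cap_half_angle_deg = 60, n = 200,
                                  noise_sd = 0.005, seed = s)
    sqrt(sum((fit_sphere(cap)$center - c(1, 2, 0.5))^2))
  }, 0)
  expect_lt(median(errs), 0.01)
})

test_that("hinge axes pass through the two condyle centers", {
  a <- make_articular_surface(center = c(0, 0, -1), radius = 0.2,
                              cap_half_angle_deg = 70, n = 80, seed = 1)
  b <- make_articular_surface(center = c(0, 0, 1), radius = 0.2,
                              cap_half_angle_deg = 70, n = 80, seed = 2)
  h <- fit_hinge_axis(a, b)
  expect_equal(h$axis_dir, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(h$midpoint, c(0, 0, 0), tolerance = 1e-9)

  h2 <- antkin:::hinge_axis_from_centers(c(1, 0, 0), c(1, 0, 0.4))
  expect_equal(h2$midpoint, c(1, 0, 0.2))
  expect_equal(h2$axis_dir, c(0, 0, 1))

  expect_error_class(antkin:::hinge_axis_from_centers(c(1, 1, 1), c(1, 1, 1)),
                     "degenerate_geometry")
})

test_that("noisy condyle axes stay within 5 degrees of truth (median)", {
  errs <- vapply(1:100, function(s) {
    a <- make_articular_surface(center = c(0, 0, -0.15), radius = 0.05,
                                cap_half_angle_deg = 70, n = 100,
                                noise_sd = 0.005, seed = 2 * s)
    b <- make_articular_surface(center = c(0, 0, 0.15), radius = 0.05,
                                cap_half_angle_deg = 70, n = 100,
                                noise_sd = 0.005, seed = 2 * s + 1)
    h <- fit_hinge_axis(a, b)
    acos(min(1, abs(sum(h$axis_dir * c(0, 0, 1))))) / pi * 180
  }, 0)
  expect_lt(median(errs), 5)
})

test_that("the sagittal plane follows the spiracle centers", {
  sl <- make_articular_surface(center = c(-0.5, 0, 0), radius = 0.08,
                               cap_half_angle_deg = 80, n = 60, seed = 3)
  sr <- make_articular_surface(center = c(0.5, 0, 0), radius = 0.08,
                               cap_half_angle_deg = 80, n = 60, seed = 4)
  pl <- define_sagittal_plane(sl, sr)
  expect_equal(pl$unit_normal, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(pl$point_on_plane, c(0, 0, 0), tolerance = 1e-9)

  # plane built from rigidly moved clouds rotates identically
  set.seed(9)
  R <- random_rotation(); t <- rnorm(3)
  pl2 <- define_sagittal_plane(sweep(sl %*% t(R), 2, t, `+`),
                               sweep(sr %*% t(R), 2, t, `+`))
  expect_equal(pl2$unit_normal, as.numeric(R %*% pl$unit_normal),
               tolerance = 1e-8)
  expect_equal(pl2$point_on_plane,
               as.numeric(R %*% pl$point_on_plane + t), tolerance = 1e-8)
})

frame_checks <- function(f) {
  expect_lt(max(abs(crossprod(f$rotation) - diag(3))), 1e-10)
  expect_lt(abs(det(f$rotation) - 1), 1e-10)
}

test_that("the thorax frame is orthonormal, anterior-pointing and equivariant", {
  sag <- plane_def(c(1, 0, 0), c(0, 0, 0))
  f <- build_thorax_frame(c(0, 1, 0), c(0, -1, 0), sag)
  expect_equal(f$origin, c(0, 0, 0))
  expect_equal(as.numeric(f$rotation[, 2]), c(0, 1, 0))
  frame_checks(f)

  set.seed(31)
  for (k in 1:5) {
    R <- random_rotation(); t <- rnorm(3)
    P_h <- rnorm(3); P_a <- rnorm(3)
    if (sqrt(sum((P_h - P_a)^2)) < 0.1) next
    f1 <- build_thorax_frame(P_h, P_a, sag)
    sag2 <- plane_def(R %*% sag$unit_normal, R %*% sag$point_on_plane + t)
    f2 <- build_thorax_frame(R %*% P_h + t, R %*% P_a + t, sag2)
    expect_equal(f2$origin, as.numeric(R %*% f1$origin + t),
                 tolerance = 1e-9)
    expect_equal(f2$rotation, R %*% f1$rotation, tolerance = 1e-9)
  }

  expect_error_class(
    build_thorax_frame(c(1, 0, 0), c(-1, 0, 0), sag), "degenerate_geometry")
})

test_that("hinge frames point z medially and y toward the previous origin", {
  sag <- plane_def(c(1, 0, 0), c(-5, 0, 0))
  ax <- antkin:::hinge_axis_from_centers(c(0, 0, -1), c(0, 0, 1))
  f <- build_hinge_frame(ax, c(0, 2, 0), sag)
  expect_equal(f$origin, c(0, 0, 0))
  expect_equal(as.numeric(f$rotation[, 2]), c(0, 1, 0), tolerance = 1e-12)
  frame_checks(f)
  # x = y cross z
  expect_equal(as.numeric(f$rotation[, 1]),
               as.numeric(antkin:::cross3(f$rotation[, 2], f$rotation[, 3])),
               tolerance = 1e-12)
  # medial sign: the plane sits at x = -5, so z points toward -x
  axx <- antkin:::hinge_axis_from_centers(c(-1, 3, 0), c(1, 3, 0))
  fx <- build_hinge_frame(axx, c(0, 5, 0), sag)
  expect_equal(as.numeric(fx$rotation[, 3]), c(-1, 0, 0), tolerance = 1e-12)

  expect_error_class(build_hinge_frame(ax, c(0, 0, 0.3), sag),
                     "degenerate_geometry")

  set.seed(41)
  # equivariance needs a configuration whose medial sign is well defined
  # (axis not perpendicular to the sagittal normal)
  pa <- c(0.3, 0, -1); pb <- c(-0.2, 0.1, 1)
  axg <- antkin:::hinge_axis_from_centers(pa, pb)
  for (k in 1:5) {
    R <- random_rotation(); t <- rnorm(3)
    prev <- c(0.3, 2, 0.5)
    f1 <- build_hinge_frame(axg, prev, sag)
    ax2 <- antkin:::hinge_axis_from_centers(R %*% pa + t, R %*% pb + t)
    sag2 <- plane_def(R %*% sag$unit_normal, R %*% sag$point_on_plane + t)
    f2 <- build_hinge_frame(ax2, R %*% prev + t, sag2)
    expect_equal(f2$rotation, R %*% f1$rotation, tolerance = 1e-9)
    expect_equal(f2$origin, as.numeric(R %*% f1$origin + t), tolerance = 1e-9)
  }
})

test_that("ball frames point y proximally and reject degenerate input", {
  sag <- plane_def(c(1, 0, 0), c(0, 0, 0))
  f <- build_ball_frame(c(0, 0, 0), c(0, 3, 0), sag)
  expect_equal(as.numeric(f$rotation[, 2]), c(0, 1, 0))
  frame_checks(f)
  expect_error_class(build_ball_frame(c(0, 0, 0), c(2, 0, 0), sag),
                     "degenerate_geometry")
  expect_error_class(build_ball_frame(c(1, 1, 1), c(1, 1, 1), sag),
                     "degenerate_geometry")
  # the flip_x switch mirrors x and z, keeping det +1
  ff <- build_ball_frame(c(0, 0, 0), c(0, 3, 0), sag, flip_x = TRUE)
  expect_equal(ff$rotation[, 1], -f$rotation[, 1])
  expect_equal(ff$rotation[, 3], -f$rotation[, 3])
  frame_checks(ff)
})

test_that("point clouds round-trip through XYZ, PLY and STL readers", {
  pts <- matrix(round(rnorm(30), 6), 10, 3)
  xyz <- tempfile(fileext = ".xyz")
  writeLines(c("# comment", apply(pts, 1, paste, collapse = " ")), xyz)
  expect_equal(read_point_cloud(xyz), pts, ignore_attr = TRUE)

  ply <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(pts)),
               "property float x", "property float y", "property float z",
               "end_header",
               apply(pts, 1, paste, collapse = " ")), ply)
  expect_equal(read_point_cloud(ply), pts, ignore_attr = TRUE)

  stl <- tempfile(fileext = ".stl")
  tri <- pts[1:3, ]
  writeLines(c("solid synthetic", "facet normal 0 0 1", "outer loop",
               sprintf("vertex %s", apply(tri, 1, paste, collapse = " ")),
               "endloop", "endfacet", "endsolid synthetic"), stl)
  expect_equal(read_point_cloud(stl), tri, ignore_attr = TRUE)

  expect_error_class(read_point_cloud(tempfile()), "format_error")
})

test_that("fitted geometry serializes to JSON for the model builder", {
  f <- fit_sphere(make_articular_surface(c(0, 1, 0), 0.2, 60, 50, seed = 2))
  h <- antkin:::hinge_axis_from_centers(c(0, 0, 0), c(0, 0, 1))
  path <- tempfile(fileext = ".json")
  write_geometry_json(list(head_socket = f, knee_axis = h,
                           sagittal = plane_def(c(1, 0, 0), c(0, 0, 0))),
                      path)
  doc <- jsonlite::read_json(path)
  expect_named(doc, c("head_socket", "knee_axis", "sagittal"))
  expect_equal(doc$head_socket$kind, "sphere")
  expect_equal(unlist(doc$knee_axis$axis_dir), c(0, 0, 1))
})
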