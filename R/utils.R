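#' @useDynLib antkin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd rnorm runif setNames
#' @importFrom utils head tail
#' @importFrom graphics plot lines polygon
#' @importFrom grDevices adjustcolor
NULL

DEG <- pi / 180

deg2rad <- function(x) x * DEG
rad2deg <- function(x) x / DEG

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) {
    stop_antkin(sprintf("cannot normalize near-zero %s", what),
                "degenerate_geometry")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, used throughout the
#' joint parameterization (intrinsic x-y-z sequence for ball joints,
#' z for hinges).
#'
#' @param a angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
#' @name elementary-rotations
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

#' @rdname elementary-rotations
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' @rdname elementary-rotations
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

# Classed error helper: condition classes are antkin_<class> so callers can
# distinguish invalid_input, degenerate_geometry, format_error,
# invalid_parameter, invalid_topology, unit_error.
stop_antkin <- function(msg, class) {
  stop(structure(
    class = c(paste0("antkin_", class), "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

as_point3 <- function(x, name = "point") {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x))) {
    stop_antkin(sprintf("%s must be a finite 3-vector", name), "invalid_input")
  }
  x
}

as_points_matrix <- function(points, name = "points") {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.list(points) && !is.matrix(points)) {
    points <- do.call(rbind, lapply(points, as.numeric))
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) {
    stop_antkin(sprintf("%s must have 3 columns (x, y, z in mm)", name),
                "invalid_input")
  }
  if (any(!is.finite(points))) {
    stop_antkin(sprintf("%s contains non-finite coordinates", name),
                "invalid_input")
  }
  points
}
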