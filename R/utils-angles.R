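#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' @keywords internal
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle into (-180, 180] degrees
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped into the half-open interval (-180, 180].
#' @keywords internal
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Wrap an axial angle (orientation) into [0, 180) degrees
#' @keywords internal
wrap_axial_deg <- function(x) {
  ((x %% 180) + 180) %% 180
}

#' Mean of axial angles on the branch nearest a center
#'
#' Orientations live on a half-circle (mod 180 degrees); a naive mean across
#' the 0/180 seam would be wrong. Each value is mapped to the representative
#' within 90 degrees of `center` before averaging.
#'
#' @param x Orientations in degrees.
#' @param center Branch center in degrees (default 90, the bisector-normal).
#' @param na.rm Drop missing values.
#' @return Mean orientation in degrees, on the branch around `center`.
#' @export
axial_mean_deg <- function(x, center = 90, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  branch <- center + ((x - center + 90) %% 180) - 90
  mean(branch)
}

# 2D rotation by theta (radians), counterclockwise, applied to an n x 2 matrix
#' @keywords internal
rotate2 <- function(pts, theta) {
  pts <- as_points_matrix(pts)
  ct <- cos(theta); st <- sin(theta)
  cbind(pts[, 1] * ct - pts[, 2] * st,
        pts[, 1] * st + pts[, 2] * ct)
}

#' @keywords internal
as_points_matrix <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x", "y") %in% names(points))) {
      points <- cbind(points$x, points$y)
    } else {
      points <- as.matrix(points[, 1:2])
    }
  }
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  m <- as.matrix(points)
  storage.mode(m) <- "double"
  if (ncol(m) != 2) {
    rlang::abort("`points` must be an n x 2 matrix or a data frame with x, y columns.",
                 class = "stripeflow_error_bad_points")
  }
  m
}

# cross product z-component of 2D vectors a, b (each length-2 or n x 2)
#' @keywords internal
cross2 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 2)
  if (is.null(dim(b))) b <- matrix(b, ncol = 2)
  a[, 1] * b[, 2] - a[, 2] * b[, 1]
}
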