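#' Rotation matrix from ZYZ Euler angles
#'
#' Builds the rotation that carries model-frame coordinates into the image
#' frame, using the ZYZ convention common in single-particle work:
#' `R = Rz(psi) %*% Ry(tilt) %*% Rz(rot)`. All angles are in degrees. With
#' `tilt = 90` the model z axis (the microtubule axis) maps onto the image
#' x axis at `psi = 0`.
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
#' @examples
#' euler_matrix(0, 0, 0)            # identity
#' euler_matrix(90, 0, 0)[1, 2]     # z-rotation by 90 degrees
euler_matrix <- function(rot, tilt, psi) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  rz(psi) %*% ry(tilt) %*% rz(rot)
}

#' Wrap an angle into [0, 360)
#' @param a angle(s) in degrees.
#' @return wrapped angle(s).
#' @export
wrap360 <- function(a) ((a %% 360) + 360) %% 360

# smallest absolute angular difference in degrees
ang_diff <- function(a, b) {
  d <- wrap360(a - b)
  pmin(d, 360 - d)
}
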