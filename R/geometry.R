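# Inverse perspective projection onto the tabletop plane Z = 0 and the
# raised bowl-mouth plane Z = H.

#' Camera height above the tabletop from the ToF reading
#'
#' Converts the time-of-flight distance and the device pitch into the
#' camera height above the table. The default `"paper_tan"` model uses
#' `h = dtof * tan(pitch)`; the alternative `"slant_sin"` model treats
#' the reading as a slant range along the optical axis,
#' `h = dtof * sin(pitch)` (see [geometry_config()]).
#'
#' @param dtof_mm ToF distance in mm (> 0).
#' @param pitch_deg Device pitch in degrees, strictly between 0 and 90;
#'   the tan model refuses pitches above 89 degrees where `tan` blows up.
#' @param config A [geometry_config()].
#' @return Camera height in mm.
#' @examples
#' camera_height(460, 42) # 414.19 mm
#' camera_height(580, 55, geometry_config("slant_sin")) # 475.11 mm
#' @export
camera_height <- function(dtof_mm, pitch_deg, config = geometry_config()) {
  stopifnot(is.finite(dtof_mm), is.finite(pitch_deg))
  if (dtof_mm <= 0) stop("`dtof_mm` must be positive", call. = FALSE)
  if (pitch_deg <= 0 || pitch_deg >= 90) {
    stop("`pitch_deg` must lie strictly between 0 and 90 degrees",
         call. = FALSE)
  }
  w <- pitch_deg * pi / 180
  switch(config$height_model,
    paper_tan = {
      if (pitch_deg > 89) {
        stop("pitch above 89 degrees: tan-model height would overflow",
             call. = FALSE)
      }
      dtof_mm * tan(w)
    },
    slant_sin = dtof_mm * sin(w)
  )
}

#' Pose of the camera relative to a working plane
#'
#' Describes the camera relative to the horizontal plane on which
#' dimensions are measured: its height `h_mm` above that plane, its
#' downward pitch, and the plane's world height `plane_z_mm` (0 for the
#' tabletop, H for a bowl mouth).
#'
#' @param h_mm Camera height above the working plane, mm (> 0).
#' @param pitch_deg Downward pitch in degrees, strictly in (0, 90).
#' @param plane_z_mm World height of the working plane, mm.
#' @return An object of class `plane_pose`.
#' @export
plane_pose <- function(h_mm, pitch_deg, plane_z_mm = 0) {
  stopifnot(is.finite(h_mm), is.finite(pitch_deg), is.finite(plane_z_mm))
  if (h_mm <= 0) stop("camera height must be positive", call. = FALSE)
  if (pitch_deg <= 0 || pitch_deg >= 90) {
    stop("`pitch_deg` must lie strictly between 0 and 90 degrees",
         call. = FALSE)
  }
  structure(
    list(h_mm = h_mm, pitch_deg = pitch_deg, plane_z_mm = plane_z_mm),
    class = "plane_pose"
  )
}

#' Backproject undistorted image points onto a horizontal plane
#'
#' Inverts the perspective projection for points known to lie on the
#' working plane. With the camera at height `h` above the plane and
#' pitched down by `theta`, the depth along the optical axis of the point
#' seen at ideal image coordinates `(u, v)` is
#' `W = h / (sin(theta) + (v / fc) * cos(theta))`, after which
#' `(U, V) = (W / fc) * (u, v)` and the world point follows from the
#' inverse rigid transform. The closed form agrees with generic ray-plane
#' intersection to machine precision; rays that run to the horizon
#' (vanishing denominator) or hit the plane behind the camera are
#' rejected.
#'
#' @param points Data frame or matrix of ideal (undistorted) image
#'   coordinates `u, v` in mm.
#' @param pose A [plane_pose()].
#' @param intr A [camera_intrinsics()].
#' @param eps Horizon guard on the denominator.
#' @return A tibble with world coordinates `X, Y, Z` (mm); `Z` equals
#'   `pose$plane_z_mm`.
#' @examples
#' # the principal ray hits the table h / tan(theta) ahead of the camera
#' backproject_to_plane(data.frame(u = 0, v = 0), plane_pose(350, 55))
#' @export
backproject_to_plane <- function(points, pose, intr = camera_intrinsics(),
                                 eps = 1e-9) {
  stopifnot(inherits(pose, "plane_pose"))
  out <- backproject_m(as_point_matrix(points, c("u", "v")),
                       pose$h_mm, pose$pitch_deg, pose$plane_z_mm, intr,
                       eps = eps)
  tibble::tibble(X = out[, 1], Y = out[, 2], Z = out[, 3])
}

#' True bowl height from its tabletop-projected extent
#'
#' When the rim and base of a bowl wall are both backprojected onto the
#' tabletop plane, the wall appears as a stretch of length `H'` along the
#' world y-axis; the true wall height is `H = tan(pitch) * H'`. The
#' relation is exact for wall points seen along a ray at depression angle
#' equal to the device pitch (the image's horizontal midline) and is an
#' approximation elsewhere.
#'
#' @param H_prime_mm Projected height extent on the tabletop, mm (>= 0).
#' @param pitch_deg Device pitch in degrees.
#' @return Bowl height in mm.
#' @examples
#' bowl_height(30, 45) # 30
#' @export
bowl_height <- function(H_prime_mm, pitch_deg) {
  stopifnot(is.finite(H_prime_mm), is.finite(pitch_deg))
  if (H_prime_mm < 0) stop("`H_prime_mm` must be nonnegative", call. = FALSE)
  tan(pitch_deg * pi / 180) * H_prime_mm
}

#' Camera height above the raised bowl-mouth plane
#'
#' Once the bowl height H is known, measurements of the mouth are made on
#' the plane Z = H, for which the camera height must be reduced. The
#' default `"paper_sec"` model uses `h' = h - H * sec(pitch)`; the
#' `"geometric"` model uses the plain vertical offset `h' = h - H`,
#' which is exact in this camera geometry (see [geometry_config()]).
#'
#' @param h_mm Camera height above the tabletop, mm.
#' @param H_mm Bowl height, mm (>= 0).
#' @param pitch_deg Device pitch in degrees.
#' @param config A [geometry_config()].
#' @return Adjusted camera height in mm (> 0).
#' @examples
#' adjusted_camera_height(500, 60, 60) # 380 (sec 60 deg = 2)
#' adjusted_camera_height(500, 60, 60, geometry_config(bowl_plane_model = "geometric")) # 440
#' @export
adjusted_camera_height <- function(h_mm, H_mm, pitch_deg,
                                   config = geometry_config()) {
  stopifnot(is.finite(h_mm), is.finite(H_mm), is.finite(pitch_deg))
  if (H_mm < 0) stop("`H_mm` must be nonnegative", call. = FALSE)
  h_adj <- switch(config$bowl_plane_model,
    paper_sec = h_mm - H_mm / cos(pitch_deg * pi / 180),
    geometric = h_mm - H_mm
  )
  if (h_adj <= 0) {
    stop("adjusted camera height is not positive: the bowl reaches the camera",
         call. = FALSE)
  }
  h_adj
}
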