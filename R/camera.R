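# Pinhole camera model: intrinsics, rigid transform, perspective division,
# radial distortion, and the pixel <-> image-plane coordinate mapping.

#' Camera intrinsic parameters
#'
#' Bundles the intrinsic parameters of the wearable camera. The defaults
#' reproduce the factory parameters of the device: a 2.4 mm lens over a
#' 3.67 mm x 2.74 mm sensor, working in the distortion-corrected
#' 3378 x 2347 px frame, with the principal point at the frame centre and
#' scale factors `img_w / sensor_w` and `img_h / sensor_h` (px/mm).
#'
#' @param fc_mm Focal length in mm. Must be positive.
#' @param sensor_w_mm,sensor_h_mm Physical sensor size in mm.
#' @param img_w,img_h Image size in pixels.
#' @param ccx,ccy Principal point in pixel coordinates (origin top-left).
#' @param scx,scy Scale factors in px/mm.
#' @param kc Radial distortion coefficient in 1/mm^2. `0` disables
#'   distortion.
#'
#' @return An object of class `camera_intrinsics` (a named list).
#' @examples
#' intr <- camera_intrinsics()
#' intr$ccx # 1689
#' @export
camera_intrinsics <- function(fc_mm = 2.4,
                              sensor_w_mm = 3.67, sensor_h_mm = 2.74,
                              img_w = 3378, img_h = 2347,
                              ccx = img_w / 2, ccy = img_h / 2,
                              scx = img_w / sensor_w_mm,
                              scy = img_h / sensor_h_mm,
                              kc = 0) {
  stopifnot(
    is.numeric(fc_mm), length(fc_mm) == 1L, is.finite(fc_mm),
    is.numeric(kc), length(kc) == 1L, is.finite(kc)
  )
  if (fc_mm <= 0) stop("`fc_mm` must be positive", call. = FALSE)
  if (scx <= 0 || scy <= 0) stop("scale factors must be positive", call. = FALSE)
  if (ccx <= 0 || ccx >= img_w || ccy <= 0 || ccy >= img_h) {
    stop("principal point must lie inside the image frame", call. = FALSE)
  }
  structure(
    list(
      fc_mm = fc_mm,
      sensor_w_mm = sensor_w_mm, sensor_h_mm = sensor_h_mm,
      img_w = img_w, img_h = img_h,
      ccx = ccx, ccy = ccy, scx = scx, scy = scy,
      kc = kc
    ),
    class = "camera_intrinsics"
  )
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat("<camera_intrinsics>\n")
  cat(sprintf("  fc = %g mm, sensor %g x %g mm, image %d x %d px\n",
              x$fc_mm, x$sensor_w_mm, x$sensor_h_mm, x$img_w, x$img_h))
  cat(sprintf("  principal point (%g, %g) px, scale (%.3f, %.3f) px/mm, kc = %g mm^-2\n",
              x$ccx, x$ccy, x$scx, x$scy, x$kc))
  invisible(x)
}

#' Read or write a camera configuration file
#'
#' Camera configurations are stored as YAML or JSON (chosen by file
#' extension) with keys `fc_mm, sensor_w_mm, sensor_h_mm, img_w, img_h,
#' ccx, ccy, scx, scy, kc`. The file shipped at
#' `system.file("extdata", "aim2_camera.yaml", package = "dishmetry")`
#' holds the default wearable-camera parameters.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_camera_config()` returns a [camera_intrinsics()] object;
#'   `write_camera_config()` returns `path` invisibly.
#' @export
read_camera_config <- function(path) {
  cfg <- read_config_file(path)
  keys <- c("fc_mm", "sensor_w_mm", "sensor_h_mm", "img_w", "img_h",
            "ccx", "ccy", "scx", "scy", "kc")
  unknown <- setdiff(names(cfg), keys)
  if (length(unknown) > 0) {
    stop("unknown camera config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # YAML integers arrive as integer vectors; the intrinsics are doubles
  do.call(camera_intrinsics, lapply(cfg, as.numeric))
}

#' @rdname read_camera_config
#' @param intr A [camera_intrinsics()] object.
#' @export
write_camera_config <- function(intr, path) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  write_config_file(unclass(intr), path)
  invisible(path)
}

#' Pitch-only rotation matrix
#'
#' Rotation about the x-axis by the pitch angle; roll and yaw are assumed
#' zero throughout the model (the device is worn level while eating).
#'
#' @param pitch_deg Pitch angle in degrees.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' rotation_matrix(0) # identity
#' @export
rotation_matrix <- function(pitch_deg) {
  stopifnot(is.numeric(pitch_deg), length(pitch_deg) == 1L, is.finite(pitch_deg))
  w <- pitch_deg * pi / 180
  matrix(c(
    1, 0, 0,
    0, cos(w), -sin(w),
    0, sin(w), cos(w)
  ), nrow = 3, byrow = TRUE)
}

# Axis permutation taking the world frame (X right, Y forward, Z up) into
# the camera frame at zero pitch (U right, V down, W forward). Composed
# with the pitch rotation it defines the one sign convention used by every
# module; the synthetic renderer is its source of truth.
.world_to_cam_axes <- matrix(c(
  1, 0, 0,
  0, 0, -1,
  0, 1, 0
), nrow = 3, byrow = TRUE)

#' Camera extrinsics for a pitched-down camera above the tabletop
#'
#' The world frame has the tabletop at Z = 0, Z pointing up, and the
#' camera centre at (0, 0, `h_mm`). The camera looks forward along +Y and
#' is pitched down by `pitch_deg`. Returns the rigid transform (R, T) such
#' that camera coordinates are `R %*% P + T` for a world point `P`.
#'
#' @param pitch_deg Downward pitch of the optical axis from horizontal,
#'   in degrees.
#' @param h_mm Camera height above the world Z = 0 plane, in mm.
#' @return A list with elements `R` (3x3) and `T` (length-3 vector).
#' @export
camera_extrinsics <- function(pitch_deg, h_mm) {
  R <- .world_to_cam_axes %*% rotation_matrix(pitch_deg)
  Tv <- -as.numeric(R %*% c(0, 0, h_mm))
  list(R = R, T = Tv)
}

as_point_matrix <- function(points, cols) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == length(cols))
    m <- points
  } else {
    missing <- setdiff(cols, names(points))
    if (length(missing) > 0) {
      stop("points are missing columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    m <- as.matrix(points[, cols, drop = FALSE])
  }
  # bare numeric matrix: single-row subsets would otherwise carry
  # dimnames into downstream tibble columns
  dimnames(m) <- NULL
  m
}

#' Rigid transform between world and camera coordinates
#'
#' `world_to_camera()` applies `(U, V, W) = R (X, Y, Z) + T`;
#' `camera_to_world()` is its algebraic inverse.
#'
#' @param points A data frame (or matrix) with columns `X, Y, Z`
#'   (world, mm) or `U, V, W` (camera, mm).
#' @param R 3x3 orthonormal rotation matrix.
#' @param T Length-3 translation vector.
#' @return A tibble of transformed coordinates.
#' @export
world_to_camera <- function(points, R, T = c(0, 0, 0)) {
  out <- cam_from_world_m(as_point_matrix(points, c("X", "Y", "Z")), R, T)
  tibble::tibble(U = out[, 1], V = out[, 2], W = out[, 3])
}

#' @rdname world_to_camera
#' @export
camera_to_world <- function(points, R, T = c(0, 0, 0)) {
  out <- world_from_cam_m(as_point_matrix(points, c("U", "V", "W")), R, T)
  tibble::tibble(X = out[, 1], Y = out[, 2], Z = out[, 3])
}

#' Perspective projection onto the image plane
#'
#' Projects camera-frame points through the pinhole:
#' `(u, v) = fc / W * (U, V)`, in mm on the image plane with origin at the
#' principal point. Points must lie in front of the camera (`W > 0`).
#'
#' @param points Data frame or matrix with columns `U, V, W` (mm).
#' @inheritParams image_to_pixel
#' @return A tibble with columns `u, v` (mm, ideal/undistorted).
#' @export
camera_to_image <- function(points, intr = camera_intrinsics()) {
  out <- img_from_cam_m(as_point_matrix(points, c("U", "V", "W")), intr)
  tibble::tibble(u = out[, 1], v = out[, 2])
}

#' Radial lens distortion and its inverse
#'
#' The radial model displaces an ideal image point along its radius:
#' `(u, v) = (u0, v0) * (1 + kc * (u0^2 + v0^2))`. `undistort_points()`
#' inverts the model through its radial profile: the distorted radius
#' satisfies `rd = r * (1 + kc * r^2)`, solved per point by Newton
#' iteration from `rd`, stopping when the update falls below `tol`; the
#' default tolerance (1e-9 mm) is three orders of magnitude below the
#' ~1.1 um pixel pitch. Inversion requires the radial map to be monotone
#' at the point (`1 + 3 * kc * r^2 > 0`); for a barrel lens
#' (`kc < 0`) that bounds the usable radius at `1 / sqrt(3 |kc|)`.
#'
#' @param points Data frame or matrix with columns `u, v` (mm).
#' @param kc Radial distortion coefficient (1/mm^2).
#' @param tol Convergence tolerance in mm.
#' @param max_iter Maximum number of fixed-point iterations.
#' @return A tibble with columns `u, v`.
#' @export
distort_points <- function(points, kc) {
  out <- distort_m(as_point_matrix(points, c("u", "v")), kc)
  tibble::tibble(u = out[, 1], v = out[, 2])
}

#' @rdname distort_points
#' @export
undistort_points <- function(points, kc, tol = 1e-9, max_iter = 50L) {
  out <- undistort_m(as_point_matrix(points, c("u", "v")), kc,
                     tol = tol, max_iter = max_iter)
  tibble::tibble(u = out[, 1], v = out[, 2])
}

#' Map between image-plane (mm) and pixel coordinates
#'
#' The pixel mapping is pure scale plus principal-point offset:
#' `x = scx * u + ccx`, `y = scy * v + ccy`. Pixel y grows downward and
#' image v grows downward in lockstep. `pixel_to_image()` is the exact
#' affine inverse.
#'
#' @param points Data frame or matrix with columns `u, v` (mm) or
#'   `x, y` (px).
#' @param intr A [camera_intrinsics()] object.
#' @return A tibble with columns `x, y` (px) or `u, v` (mm).
#' @export
image_to_pixel <- function(points, intr = camera_intrinsics()) {
  out <- px_from_img_m(as_point_matrix(points, c("u", "v")), intr)
  tibble::tibble(x = out[, 1], y = out[, 2])
}

#' @rdname image_to_pixel
#' @export
pixel_to_image <- function(points, intr = camera_intrinsics()) {
  out <- img_from_px_m(as_point_matrix(points, c("x", "y")), intr)
  tibble::tibble(u = out[, 1], v = out[, 2])
}

#' Full forward projection from world points to pixels
#'
#' Convenience chain used by the synthetic renderer: rigid transform,
#' perspective division, radial distortion, pixel mapping.
#'
#' @param points Data frame or matrix with columns `X, Y, Z` (mm).
#' @param pitch_deg Downward camera pitch in degrees.
#' @param h_mm Camera height above the tabletop (world Z = 0), mm.
#' @param intr A [camera_intrinsics()] object.
#' @return A tibble with pixel columns `x, y`.
#' @export
project_world_to_pixel <- function(points, pitch_deg, h_mm,
                                   intr = camera_intrinsics()) {
  out <- px_from_world_m(as_point_matrix(points, c("X", "Y", "Z")),
                         pitch_deg, h_mm, intr)
  tibble::tibble(x = out[, 1], y = out[, 2])
}
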