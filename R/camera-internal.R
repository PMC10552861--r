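# Matrix-only projection kernels shared by the user-facing tibble API,
# the renderer and the measurement pipeline (hot paths).

cam_from_world_m <- function(P, R, Tv) {
  t(R %*% t(P) + Tv)
}

world_from_cam_m <- function(P, R, Tv) {
  t(t(R) %*% (t(P) - Tv))
}

img_from_cam_m <- function(P, intr) {
  if (any(P[, 3] <= 0)) {
    stop("behind-camera: all points must have W > 0", call. = FALSE)
  }
  cbind(intr$fc_mm * P[, 1] / P[, 3], intr$fc_mm * P[, 2] / P[, 3])
}

distort_m <- function(P, kc) {
  f <- 1 + kc * (P[, 1]^2 + P[, 2]^2)
  cbind(P[, 1] * f, P[, 2] * f)
}

# Inversion works on the scalar radius: the distorted radius satisfies
# rd = r (1 + kc r^2), solved per point by Newton iteration started at
# rd (the undamped fixed point stalls near the monotonicity limit
# r^2 -> 1 / (3 |kc|) of a barrel lens).
undistort_m <- function(P, kc, tol = 1e-9, max_iter = 50L) {
  if (kc == 0) return(P)
  rd <- sqrt(P[, 1]^2 + P[, 2]^2)
  r <- rd
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    fp <- 1 + 3 * kc * r^2
    if (any(abs(fp) < 1e-12)) break # stationary radius: not invertible
    step <- (r * (1 + kc * r^2) - rd) / fp
    r <- r - step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged || any(!is.finite(r)) || any(r < 0)) {
    stop("undistortion did not converge within ", max_iter, " iterations",
         call. = FALSE)
  }
  scale <- ifelse(rd > 0, r / rd, 1)
  cbind(P[, 1] * scale, P[, 2] * scale)
}

px_from_img_m <- function(P, intr) {
  cbind(intr$scx * P[, 1] + intr$ccx, intr$scy * P[, 2] + intr$ccy)
}

img_from_px_m <- function(P, intr) {
  cbind((P[, 1] - intr$ccx) / intr$scx, (P[, 2] - intr$ccy) / intr$scy)
}

# world (Z = plane_z working plane) -> distorted pixel, full chain
px_from_world_m <- function(P, pitch_deg, h_mm, intr) {
  ext <- camera_extrinsics(pitch_deg, h_mm)
  px_from_img_m(distort_m(img_from_cam_m(
    cam_from_world_m(P, ext$R, ext$T), intr), intr$kc), intr)
}

# ideal image points -> world points on the working plane
backproject_m <- function(P_uv, h_mm, pitch_deg, plane_z_mm, intr,
                          eps = 1e-9) {
  th <- pitch_deg * pi / 180
  vp <- P_uv[, 2] / intr$fc_mm
  denom <- sin(th) + vp * cos(th)
  if (any(abs(denom) < eps)) {
    stop("horizon: viewing ray is (near-)parallel to the working plane",
         call. = FALSE)
  }
  W <- h_mm / denom
  if (any(W <= 0)) {
    stop("behind-camera: ray meets the working plane behind the camera",
         call. = FALSE)
  }
  U <- W * P_uv[, 1] / intr$fc_mm
  V <- W * vp
  ext <- camera_extrinsics(pitch_deg, plane_z_mm + h_mm)
  world <- world_from_cam_m(cbind(U, V, W), ext$R, ext$T)
  world[, 3] <- plane_z_mm # exact by construction
  world
}

# distorted pixel points -> world points on the working plane
world_from_px_m <- function(P_px, h_mm, pitch_deg, plane_z_mm, intr) {
  backproject_m(undistort_m(img_from_px_m(P_px, intr), intr$kc),
                h_mm, pitch_deg, plane_z_mm, intr)
}
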