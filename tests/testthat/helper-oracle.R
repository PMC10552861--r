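# Independent geometric oracle: intersect the viewing ray through an
# ideal image point with a horizontal plane, built from first principles
# (explicit camera axes in world coordinates), not from the package's
# matrix chain.
ray_plane_oracle <- function(u, v, h_mm, pitch_deg, plane_z_mm = 0,
                             fc_mm = 2.4) {
  th <- pitch_deg * pi / 180
  # camera centre and axis directions in world coordinates
  C <- c(0, 0, plane_z_mm + h_mm)
  U_axis <- c(1, 0, 0)
  V_axis <- c(0, -sin(th), -cos(th))
  W_axis <- c(0, cos(th), -sin(th))
  d <- u * U_axis + v * V_axis + fc_mm * W_axis
  s <- (plane_z_mm - C[3]) / d[3]
  C + s * d
}

# Random valid (pose, image point) draws for oracle-equivalence checks:
# points are kept away from the horizon and in front of the camera.
random_oracle_cases <- function(n, fc_mm = 2.4,
                                sensor_w = 3.67, sensor_h = 2.74) {
  h <- stats::runif(n, 120, 900)
  pitch <- stats::runif(n, 15, 85)
  plane_z <- ifelse(stats::runif(n) < 0.5, 0, stats::runif(n, 0, 100))
  u <- stats::runif(n, -sensor_w / 2, sensor_w / 2)
  v <- stats::runif(n, -sensor_h / 2, sensor_h / 2)
  th <- pitch * pi / 180
  ok <- (sin(th) + (v / fc_mm) * cos(th)) > 0.05
  tibble::tibble(h = h, pitch = pitch, plane_z = plane_z, u = u, v = v)[ok, ]
}
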