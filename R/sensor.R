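# Accelerometer/ToF sensor stream: parsing, gravity-band pitch
# extraction, and alignment of pose readings to image timestamps.

#' Construct a sensor log
#'
#' A sensor log holds the 128 Hz accelerometer stream and the
#' time-of-flight (ToF) distance stream of the wearable device. ToF
#' readings outside the sensor's working range (30-2000 mm) are retained
#' but flagged invalid.
#'
#' @param accel Tibble with columns `t` (s), `ax, ay, az` (g).
#' @param tof Tibble with columns `t` (s), `d` (mm; `NA` for missing
#'   ticks).
#' @param nominal_rate Nominal sampling rate in Hz (128 for the device).
#' @return An object of class `sensor_log`.
#' @export
sensor_log <- function(accel, tof, nominal_rate = 128) {
  accel <- tibble::as_tibble(accel)
  tof <- tibble::as_tibble(tof)
  stopifnot(all(c("t", "ax", "ay", "az") %in% names(accel)),
            all(c("t", "d") %in% names(tof)))
  if (nrow(accel) == 0) stop("empty sensor log", call. = FALSE)
  if (is.unsorted(accel$t) || is.unsorted(tof$t[!is.na(tof$t)])) {
    stop("timestamps must be nondecreasing", call. = FALSE)
  }
  if (!all(is.finite(c(accel$ax, accel$ay, accel$az)))) {
    stop("accelerometer samples must be finite", call. = FALSE)
  }
  tof$valid <- !is.na(tof$d) & tof$d >= 30 & tof$d <= 2000
  structure(
    list(accel = accel, tof = tof, nominal_rate = nominal_rate),
    class = "sensor_log"
  )
}

#' @export
print.sensor_log <- function(x, ...) {
  cat(sprintf(
    "<sensor_log> %d accel samples, %d ToF samples (%d valid), %g Hz, span [%.3f, %.3f] s\n",
    nrow(x$accel), nrow(x$tof), sum(x$tof$valid), x$nominal_rate,
    min(x$accel$t), max(x$accel$t)))
  invisible(x)
}

#' Read or write a sensor log CSV
#'
#' The on-disk format is a CSV with header `t,ax,ay,az,dtof`, one row per
#' sampling tick: `t` in seconds, accelerations in g, `dtof` in mm with
#' missing ToF ticks encoded as an empty field.
#'
#' @param path CSV file path.
#' @param nominal_rate Nominal sampling rate in Hz.
#' @return `read_sensor_log()` returns a [sensor_log()];
#'   `write_sensor_log()` returns `path` invisibly.
#' @export
read_sensor_log <- function(path, nominal_rate = 128) {
  if (!file.exists(path)) stop("sensor log not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  required <- c("t", "ax", "ay", "az", "dtof")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("sensor log is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("empty sensor log: ", path, call. = FALSE)
  sensor_log(
    accel = df[, c("t", "ax", "ay", "az")],
    tof = tibble::tibble(t = df$t, d = df$dtof),
    nominal_rate = nominal_rate
  )
}

#' @rdname read_sensor_log
#' @param log A [sensor_log()] object.
#' @export
write_sensor_log <- function(log, path) {
  stopifnot(inherits(log, "sensor_log"))
  df <- dplyr::left_join(log$accel,
                         dplyr::select(log$tof, t = "t", dtof = "d"),
                         by = "t")
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(path)
}

# Causal Butterworth low-pass initialized at the steady state of the first
# sample, so that a static recording passes through unchanged (no edge
# transient). Returns the gravity-band signal.
lowpass_gravity <- function(x, rate, cutoff_hz, order) {
  wn <- cutoff_hz / (rate / 2)
  if (wn >= 1) stop("filter cutoff must be below the Nyquist frequency",
                    call. = FALSE)
  bf <- signal::butter(order, wn, type = "low")
  as.numeric(signal::filter(bf, x,
                            init.x = rep(x[1], order),
                            init.y = rep(x[1], order)))
}

#' Split the accelerometer stream into gravity and motion bands
#'
#' The gravity branch is a low-pass of the raw signal at `cutoff_hz`
#' (default 0.1 Hz); the motion branch is its complement (raw minus
#' gravity), i.e. the high-pass component used for motion analysis.
#'
#' @param log A [sensor_log()].
#' @param filter A [filter_config()].
#' @return A tibble with columns `t`, `ax, ay, az` (gravity band) and
#'   `hx, hy, hz` (motion band).
#' @export
accel_bands <- function(log, filter = filter_config()) {
  stopifnot(inherits(log, "sensor_log"))
  a <- log$accel
  if (nrow(a) < 2) stop("at least 2 accelerometer samples required",
                        call. = FALSE)
  g <- lapply(a[, c("ax", "ay", "az")], lowpass_gravity,
              rate = log$nominal_rate, cutoff_hz = filter$cutoff_hz,
              order = filter$order)
  tibble::new_tibble(list(
    t = a$t,
    ax = g$ax, ay = g$ay, az = g$az,
    hx = a$ax - g$ax, hy = a$ay - g$ay, hz = a$az - g$az
  ), nrow = nrow(a))
}

#' Sensor pitch series from the gravity band
#'
#' The device pitch is read off the orientation of gravity in the device
#' frame: with `ay` the forward axis and `ax, az` the lateral/normal
#' axes, `sensor_pitch = atan2(ay, sqrt(ax^2 + az^2))` on the
#' gravity-band (low-frequency) acceleration. A device lying flat
#' (gravity along `az`) has pitch 0.
#'
#' @param log A [sensor_log()].
#' @param filter A [filter_config()].
#' @return A tibble with columns `t` and `sensor_pitch_deg`.
#' @examples
#' log <- sensor_log(
#'   accel = tibble::tibble(t = 0:9 / 128, ax = 0,
#'                          ay = sin(pi / 6), az = cos(pi / 6)),
#'   tof = tibble::tibble(t = 0:9 / 128, d = 500)
#' )
#' pitch_series(log) # 30 degrees throughout
#' @export
pitch_series <- function(log, filter = filter_config()) {
  bands <- accel_bands(log, filter)
  norm2 <- bands$ax^2 + bands$ay^2 + bands$az^2
  if (any(norm2 == 0)) {
    stop("undefined pitch: all-zero acceleration in the gravity band",
         call. = FALSE)
  }
  tibble::new_tibble(list(
    t = bands$t,
    sensor_pitch_deg = atan2(bands$ay, sqrt(bands$ax^2 + bands$az^2)) * 180 / pi
  ), nrow = nrow(bands))
}

#' Device pitch from sensor pitch
#'
#' The camera and ranging sensor sit at a fixed +21 degree offset from
#' the accelerometer axis in the device enclosure; the device (camera)
#' pitch is the sensor pitch plus that offset.
#'
#' @param sensor_pitch_deg Sensor pitch in degrees (vectorised).
#' @param offset_deg Enclosure offset in degrees (21 for this device).
#' @return Device pitch in degrees.
#' @examples
#' device_pitch(34) # 55
#' @export
device_pitch <- function(sensor_pitch_deg, offset_deg = 21) {
  stopifnot(is.numeric(sensor_pitch_deg), all(is.finite(sensor_pitch_deg)))
  sensor_pitch_deg + offset_deg
}

#' Device pose
#'
#' The pose actually used by the geometric model: device pitch (including
#' the enclosure offset), roll and yaw (zero by model assumption), and
#' the ToF distance reading.
#'
#' @param pitch_deg Device pitch in degrees; a valid table-viewing pose
#'   has `0 < pitch_deg < 90`.
#' @param dtof_mm ToF distance in mm.
#' @param roll_deg,yaw_deg Roll and yaw in degrees (must be 0).
#' @param camera_offset_deg Enclosure offset in degrees.
#' @return An object of class `device_pose`.
#' @export
device_pose <- function(pitch_deg, dtof_mm, roll_deg = 0, yaw_deg = 0,
                        camera_offset_deg = 21) {
  stopifnot(is.finite(pitch_deg), is.finite(dtof_mm))
  if (roll_deg != 0 || yaw_deg != 0) {
    stop("the model assumes zero roll and yaw", call. = FALSE)
  }
  if (dtof_mm <= 0) stop("`dtof_mm` must be positive", call. = FALSE)
  structure(
    list(pitch_deg = pitch_deg, roll_deg = 0, yaw_deg = 0,
         camera_offset_deg = camera_offset_deg, dtof_mm = dtof_mm),
    class = "device_pose"
  )
}

#' @export
print.device_pose <- function(x, ...) {
  cat(sprintf("<device_pose> pitch %.2f deg, dtof %.1f mm (roll = yaw = 0)\n",
              x$pitch_deg, x$dtof_mm))
  invisible(x)
}

#' Extract the device pose at an image timestamp
#'
#' Images are captured every 10 s while the sensors stream at 128 Hz;
#' the pose attached to an image is the median device pitch and the
#' median valid ToF distance over a window of `+/- window_s` seconds
#' around the image timestamp. The median makes the alignment robust to
#' isolated ToF outliers and is invariant to sample order.
#'
#' @param log A [sensor_log()].
#' @param t_image Image timestamp in seconds; must lie within the span
#'   of the log.
#' @param filter A [filter_config()]; its `window_s` sets the window
#'   half-width.
#' @return A [device_pose()].
#' @export
pose_at <- function(log, t_image, filter = filter_config()) {
  stopifnot(inherits(log, "sensor_log"), is.finite(t_image))
  span <- range(log$accel$t)
  if (t_image < span[1] || t_image > span[2]) {
    stop(sprintf("image timestamp %.3f s outside log span [%.3f, %.3f] s",
                 t_image, span[1], span[2]), call. = FALSE)
  }
  w <- filter$window_s
  ps <- pitch_series(log, filter)
  in_win <- ps$t >= t_image - w & ps$t <= t_image + w
  pitch <- stats::median(device_pitch(ps$sensor_pitch_deg[in_win]))
  tof <- log$tof
  tof_win <- tof$valid & tof$t >= t_image - w & tof$t <= t_image + w
  if (!any(tof_win)) {
    stop("no valid ToF reading within the alignment window", call. = FALSE)
  }
  dtof <- stats::median(tof$d[tof_win])
  device_pose(pitch_deg = pitch, dtof_mm = dtof)
}
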