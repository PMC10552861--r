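# A static sensor log at a fixed sensor pitch (degrees), as a tibble pair.
static_log <- function(sensor_pitch_deg, dtof_mm = 500, duration_s = 2,
                       rate = 128) {
  t <- seq(0, duration_s, by = 1 / rate)
  s <- sensor_pitch_deg * pi / 180
  sensor_log(
    accel = tibble::tibble(t = t, ax = 0, ay = sin(s), az = cos(s)),
    tof = tibble::tibble(t = t, d = dtof_mm),
    nominal_rate = rate
  )
}

# Write a sensor-log CSV by hand (independent of write_sensor_log).
write_log_csv <- function(path, t, ax, ay, az, dtof) {
  dtof_chr <- ifelse(is.na(dtof), "", format(dtof, trim = TRUE))
  lines <- c("t,ax,ay,az,dtof",
             sprintf("%.10g,%.10g,%.10g,%.10g,%s", t, ax, ay, az, dtof_chr))
  writeLines(lines, path)
  path
}

shipped <- function(...) {
  system.file("extdata", ..., package = "dishmetry", mustWork = TRUE)
}
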