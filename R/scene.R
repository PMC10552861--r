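# Forward renderer: projects containers of known dimensions into pixel
# annotations and sensor logs, replicating the physical test bench. It is
# the source of truth for the package's coordinate conventions and the
# oracle for every inverse operation.

#' Specify a container of known dimensions
#'
#' @param shape One of `"circular_plate"`, `"square_plate"`,
#'   `"cylinder_bowl"`, `"rect_box"`.
#' @param size_mm Diameter (circular) or side/x-extent (square, box), mm.
#' @param height_mm Container height, mm (0 for plates).
#' @param size2_mm y-extent of a box mouth, mm (defaults to `size_mm`).
#' @param center Optional `(X, Y)` mm position of the mouth centre on the
#'   table. The default (`NULL`) centres the mouth on the camera's
#'   principal axis, nudged away from the camera if needed to fit the
#'   frame — how a wearer naturally frames a dish.
#' @param rotation_deg In-plane rotation of the container, degrees.
#' @param object Label used in truth records and reports.
#' @return A list of class `container_spec`.
#' @export
container_spec <- function(shape, size_mm, height_mm = 0,
                           size2_mm = size_mm, center = NULL,
                           rotation_deg = 0, object = shape) {
  shape <- match.arg(shape, c("circular_plate", "square_plate",
                              "cylinder_bowl", "rect_box"))
  stopifnot(size_mm > 0, size2_mm > 0, height_mm >= 0)
  if (shape %in% c("circular_plate", "square_plate") && height_mm != 0) {
    stop("plates have height 0", call. = FALSE)
  }
  if (shape %in% c("cylinder_bowl", "rect_box") && height_mm <= 0) {
    stop("bowls and boxes need a positive height", call. = FALSE)
  }
  structure(
    list(shape = shape, size_mm = size_mm, size2_mm = size2_mm,
         height_mm = height_mm, center = center,
         rotation_deg = rotation_deg, object = object),
    class = "container_spec"
  )
}

#' The eight-container bench set
#'
#' Three circular plates (180, 220, 260 mm diameter), two square plates
#' (180, 230 mm side), three cylindrical bowls (height x mouth diameter:
#' 30 x 70, 70 x 110, 60 x 150 mm).
#'
#' @return A list of [container_spec()] objects.
#' @export
bench_containers <- function() {
  list(
    container_spec("circular_plate", 180, object = "Circular Plate (Small)"),
    container_spec("circular_plate", 220, object = "Circular Plate (Medium)"),
    container_spec("circular_plate", 260, object = "Circular Plate (Large)"),
    container_spec("square_plate", 180, object = "Square Plate (Small)"),
    container_spec("square_plate", 230, object = "Square Plate (Medium)"),
    container_spec("cylinder_bowl", 70, height_mm = 30,
                   object = "Circular Bowl (Small)"),
    container_spec("cylinder_bowl", 110, height_mm = 70,
                   object = "Circular Bowl (Medium)"),
    container_spec("cylinder_bowl", 150, height_mm = 60,
                   object = "Circular Bowl (Large)")
  )
}

#' The 3 x 3 bench condition grid
#'
#' Camera heights of 200, 350 and 500 mm crossed with pitch angles of
#' 40, 55 and 70 degrees — the stand configurations of the physical test
#' bench.
#'
#' @param heights_mm,pitches_deg Grid axes.
#' @return A tibble with columns `camera_height_mm`, `pitch_deg`.
#' @export
bench_conditions <- function(heights_mm = c(200, 350, 500),
                             pitches_deg = c(40, 55, 70)) {
  tidyr::crossing(camera_height_mm = heights_mm, pitch_deg = pitches_deg)
}

# Evaluate an expression with a temporarily seeded RNG, restoring the
# caller's RNG state afterwards; NULL seed leaves the RNG alone.
with_scene_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Mouth perimeter sample points in the container's local frame (origin at
# the mouth centre): n equally spaced points for circles, 4 corners plus
# 4 edge midpoints for rectangles.
mouth_points_local <- function(spec, n_rim) {
  rot <- spec$rotation_deg * pi / 180
  if (spec$shape %in% c("circular_plate", "cylinder_bowl")) {
    a <- seq(0, 2 * pi, length.out = n_rim + 1)[-(n_rim + 1)] + rot
    r <- spec$size_mm / 2
    cbind(x = r * cos(a), y = r * sin(a))
  } else {
    w <- spec$size_mm / 2
    d <- spec$size2_mm / 2
    pts <- rbind(
      c(w, d), c(-w, d), c(-w, -d), c(w, -d),
      c(0, d), c(-w, 0), c(0, -d), c(w, 0)
    )
    R2 <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2, byrow = TRUE)
    pts <- pts %*% t(R2)
    colnames(pts) <- c("x", "y")
    pts
  }
}

# Point on the mouth perimeter with world y-coordinate y_target, taking
# the largest x among intersections; NULL if the perimeter does not cross
# that line.
perimeter_point_at_y <- function(spec, center, y_target) {
  yl <- y_target - center[2]
  if (spec$shape %in% c("circular_plate", "cylinder_bowl")) {
    r <- spec$size_mm / 2
    if (abs(yl) > r) return(NULL)
    c(center[1] + sqrt(r^2 - yl^2), y_target)
  } else {
    poly <- mouth_points_local(spec, 8L)[1:4, , drop = FALSE]
    nh <- nrow(poly)
    xs <- c()
    for (i in seq_len(nh)) {
      p1 <- poly[i, ]
      p2 <- poly[if (i == nh) 1 else i + 1, ]
      dy <- p2[2] - p1[2]
      if (dy == 0) {
        if (p1[2] == yl) xs <- c(xs, p1[1], p2[1])
        next
      }
      t <- (yl - p1[2]) / dy
      if (t >= 0 && t <= 1) xs <- c(xs, p1[1] + t * (p2[1] - p1[1]))
    }
    if (length(xs) == 0) return(NULL)
    c(center[1] + max(xs), y_target)
  }
}

# All world points the renderer will annotate for a container placed at
# `center`: mouth samples at Z = height, and (for raised containers) the
# height pair top/base.
scene_world_points <- function(spec, center, h_mm, pitch_deg, n_rim) {
  H <- spec$height_mm
  local <- mouth_points_local(spec, n_rim)
  mouth <- cbind(X = local[, "x"] + center[1],
                 Y = local[, "y"] + center[2],
                 Z = H)
  hp <- NULL
  if (H > 0) {
    # exactness line for the planar height relation: rays at depression
    # angle equal to the device pitch
    y_star <- (h_mm - H) / tan(pitch_deg * pi / 180)
    top <- perimeter_point_at_y(spec, center, y_star)
    if (is.null(top)) {
      # fall back to the perimeter point closest to the exactness line
      i <- which.min(abs(mouth[, "Y"] - y_star))
      top <- c(mouth[i, "X"], mouth[i, "Y"])
    }
    hp <- rbind(
      top = c(X = top[1], Y = top[2], Z = H),
      base = c(X = top[1], Y = top[2], Z = 0)
    )
  }
  list(mouth = mouth, height_pair = hp)
}

# TRUE if every scene point projects inside the sensor frame (with a
# fractional margin) and in front of the camera.
scene_fits <- function(world, pitch_deg, h_mm, intr, margin = 0.02) {
  ext <- camera_extrinsics(pitch_deg, h_mm)
  cam <- cam_from_world_m(world, ext$R, ext$T)
  if (any(cam[, 3] <= 0)) return(FALSE)
  img <- distort_m(cbind(intr$fc_mm * cam[, 1] / cam[, 3],
                         intr$fc_mm * cam[, 2] / cam[, 3]), intr$kc)
  all(abs(img[, 1]) <= intr$sensor_w_mm / 2 * (1 - margin)) &&
    all(abs(img[, 2]) <= intr$sensor_h_mm / 2 * (1 - margin))
}

place_container <- function(spec, h_mm, pitch_deg, intr, n_rim,
                            margin = 0.02, max_shift_mm = 1000) {
  H <- spec$height_mm
  if (!is.null(spec$center)) {
    center <- spec$center
    pts <- scene_world_points(spec, center, h_mm, pitch_deg, n_rim)
    world <- rbind(pts$mouth, pts$height_pair)
    if (!scene_fits(world, pitch_deg, h_mm, intr, margin)) {
      stop("framing error: container does not fit inside the camera frame",
           call. = FALSE)
    }
    return(center)
  }
  y0 <- (h_mm - H) / tan(pitch_deg * pi / 180)
  fits_at <- function(shift) {
    pts <- scene_world_points(spec, c(0, y0 + shift), h_mm, pitch_deg, n_rim)
    scene_fits(rbind(pts$mouth, pts$height_pair), pitch_deg, h_mm, intr,
               margin)
  }
  # smallest fitting shift on a 1 mm grid (deterministic); the feasible
  # window can be only a few mm wide at steep close-up poses
  for (shift in seq(0, max_shift_mm, by = 1)) {
    if (fits_at(shift)) return(c(0, y0 + shift))
  }
  stop("framing error: container does not fit inside the camera frame ",
       "at this pose", call. = FALSE)
}

#' Render a container scene into an annotation and a sensor log
#'
#' Forward-projects a container of known dimensions seen from a given
#' bench condition into (a) a pixel annotation of its rim (and height
#' pair, for raised containers), (b) a static sensor log encoding the
#' device pitch in the gravity direction and the ToF distance consistent
#' with the configured height model (`paper_tan`: `dtof = h / tan(pitch)`),
#' and (c) a ground-truth record. Gaussian noise, when configured, is
#' applied to the observed quantities only — pixel coordinates, logged
#' pitch, logged distance — after exact projection. Deterministic under
#' `seed`.
#'
#' @param spec A [container_spec()].
#' @param camera_height_mm True camera height above the table, mm.
#' @param pitch_deg True device pitch, degrees (strictly inside (0, 90)).
#' @param intr A [camera_intrinsics()].
#' @param config A [geometry_config()]; sets how `dtof` is generated.
#' @param noise A [noise_config()].
#' @param n_rim Number of rim points for circular mouths.
#' @param seed RNG seed for the noise draws (`NULL` uses the current
#'   RNG state).
#' @param log_duration_s Length of the emitted sensor log, seconds; the
#'   image timestamp sits at its midpoint.
#' @return A list of class `dishmetry_scene` with elements `annotation`
#'   ([image_annotation()]), `log` ([sensor_log()]), `truth` (one-row
#'   tibble) and `t_image`.
#' @export
render_scene <- function(spec, camera_height_mm, pitch_deg,
                         intr = camera_intrinsics(),
                         config = geometry_config(),
                         noise = noise_config(), n_rim = 8L, seed = NULL,
                         log_duration_s = 3) {
  stopifnot(inherits(spec, "container_spec"), camera_height_mm > 0)
  if (pitch_deg <= 0 || pitch_deg >= 90) {
    stop("`pitch_deg` must lie strictly between 0 and 90 degrees",
         call. = FALSE)
  }
  h <- camera_height_mm
  if (h <= spec$height_mm) {
    stop("camera must sit above the container", call. = FALSE)
  }
  w <- pitch_deg * pi / 180
  dtof_true <- switch(config$height_model,
    paper_tan = h / tan(w),
    slant_sin = h / sin(w)
  )
  if (dtof_true < 30 || dtof_true > 2000) {
    stop(sprintf(
      "ToF distance %.1f mm at this pose is outside the sensor range (30-2000 mm)",
      dtof_true), call. = FALSE)
  }

  center <- place_container(spec, h, pitch_deg, intr, n_rim)
  pts <- scene_world_points(spec, center, h, pitch_deg, n_rim)

  with_scene_seed(seed, {
    rim_m <- px_from_world_m(pts$mouth, pitch_deg, h, intr)
    hp <- NULL
    if (!is.null(pts$height_pair)) {
      hp_px <- px_from_world_m(pts$height_pair, pitch_deg, h, intr)
      hp <- list(top = hp_px[1, ], base = hp_px[2, ])
    }
    rim_px <- tibble::new_tibble(list(x = rim_m[, 1], y = rim_m[, 2]),
                                 nrow = nrow(rim_m))
    if (noise$pixel_sigma_px > 0) {
      rim_px$x <- rim_px$x + stats::rnorm(nrow(rim_px), 0, noise$pixel_sigma_px)
      rim_px$y <- rim_px$y + stats::rnorm(nrow(rim_px), 0, noise$pixel_sigma_px)
      if (!is.null(hp)) {
        hp$top <- hp$top + stats::rnorm(2, 0, noise$pixel_sigma_px)
        hp$base <- hp$base + stats::rnorm(2, 0, noise$pixel_sigma_px)
      }
    }
    pitch_meas <- pitch_deg + noise$pitch_bias_deg +
      if (noise$pitch_sigma_deg > 0) stats::rnorm(1, 0, noise$pitch_sigma_deg) else 0
    dtof_meas <- dtof_true +
      if (noise$tof_sigma_mm > 0) stats::rnorm(1, 0, noise$tof_sigma_mm) else 0

    ann_type <- switch(spec$shape,
      circular_plate = "circular_plate",
      square_plate = "square_plate",
      cylinder_bowl = "bowl",
      rect_box = "rect_box"
    )
    ann <- image_annotation(
      image_id = sprintf("%s_h%g_p%g", gsub("\\W+", "_", spec$object),
                         h, pitch_deg),
      t_image = log_duration_s / 2,
      containers = list(container_annotation(ann_type, rim_px, hp))
    )

    t <- seq(0, log_duration_s, by = 1 / 128)
    nt <- length(t)
    s <- (pitch_meas - 21) * pi / 180
    log <- sensor_log(
      accel = tibble::new_tibble(list(t = t, ax = rep(0, nt),
                                      ay = rep(sin(s), nt),
                                      az = rep(cos(s), nt)), nrow = nt),
      tof = tibble::new_tibble(list(t = t, d = rep(dtof_meas, nt)), nrow = nt),
      nominal_rate = 128
    )

    truth <- tibble::tibble(
      object = spec$object, shape = spec$shape,
      size_mm = spec$size_mm, size2_mm = spec$size2_mm,
      height_mm = spec$height_mm,
      center_x_mm = center[1], center_y_mm = center[2],
      rotation_deg = spec$rotation_deg,
      camera_height_mm = h, pitch_deg = pitch_deg,
      dtof_mm = dtof_true,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )

    structure(list(annotation = ann, log = log, truth = truth,
                   t_image = log_duration_s / 2),
              class = "dishmetry_scene")
  })
}

#' @export
print.dishmetry_scene <- function(x, ...) {
  cat(sprintf("<dishmetry_scene> %s at h = %g mm, pitch = %g deg\n",
              x$truth$object, x$truth$camera_height_mm, x$truth$pitch_deg))
  invisible(x)
}

# Ground-truth values (cm) for the quantities a measurement of this
# container reports.
truth_quantities <- function(spec) {
  switch(spec$shape,
    circular_plate = tibble::tibble(quantity = "diameter",
                                    original_cm = spec$size_mm / 10),
    square_plate = tibble::tibble(quantity = "side",
                                  original_cm = spec$size_mm / 10),
    cylinder_bowl = tibble::tibble(
      quantity = c("height", "diameter"),
      original_cm = c(spec$height_mm, spec$size_mm) / 10
    ),
    rect_box = tibble::tibble(
      quantity = c("height", "diameter"),
      original_cm = c(spec$height_mm, (spec$size_mm + spec$size2_mm) / 2) / 10
    )
  )
}

#' Run the synthetic test bench
#'
#' Crosses container specs with bench conditions (and replicates), runs
#' each scene through the full inverse pipeline — sensor-log parsing,
#' pose extraction at the image timestamp, undistortion, backprojection,
#' measurement — and tabulates percent errors against ground truth.
#'
#' @param specs List of [container_spec()] (default: the eight bench
#'   containers).
#' @param conditions Tibble from [bench_conditions()].
#' @param intr,config,noise,n_rim Passed to [render_scene()] and the
#'   measurement stage.
#' @param replicates Scenes per spec x condition cell (0 gives an empty
#'   table with the right columns).
#' @param seed Integer seed; each scene derives its own sub-seed, so the
#'   whole bench is reproducible.
#' @return A tibble of class `dishmetry_bench`: one row per measured
#'   quantity with `object`, `shape`, `quantity`, condition columns,
#'   `replicate`, `predicted_cm`, `original_cm`, `error_pct` and `error`
#'   (failure message, `NA` on success).
#' @export
run_bench <- function(specs = bench_containers(),
                      conditions = bench_conditions(),
                      intr = camera_intrinsics(),
                      config = geometry_config(),
                      noise = noise_config(),
                      replicates = 1L, n_rim = 8L, seed = 1L) {
  empty <- tibble::tibble(
    object = character(0), shape = character(0), quantity = character(0),
    camera_height_mm = double(0), pitch_deg = double(0),
    replicate = integer(0), dtof_mm = double(0),
    predicted_cm = double(0), original_cm = double(0),
    error_pct = double(0), error = character(0)
  )
  counter <- 0L
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    for (spec in specs) {
      for (rep in seq_len(replicates)) {
        counter <- counter + 1L
        scene_seed <- if (is.null(seed)) NULL else seed + counter
        row <- tryCatch({
          scene <- render_scene(
            spec, conditions$camera_height_mm[ci], conditions$pitch_deg[ci],
            intr = intr, config = config, noise = noise, n_rim = n_rim,
            seed = scene_seed
          )
          pose <- pose_at(scene$log, scene$t_image)
          m <- measure_containers(scene$annotation, pose, intr, config)
          truth <- truth_quantities(spec)
          pred <- c(height = m$height_cm[1], diameter = m$diameter_cm[1],
                    side = m$diameter_cm[1])
          nq <- nrow(truth)
          predq <- unname(pred[truth$quantity])
          tibble::new_tibble(list(
            object = rep(spec$object, nq), shape = rep(spec$shape, nq),
            quantity = truth$quantity,
            camera_height_mm = rep(conditions$camera_height_mm[ci], nq),
            pitch_deg = rep(conditions$pitch_deg[ci], nq),
            replicate = rep(rep, nq),
            dtof_mm = rep(pose$dtof_mm, nq),
            predicted_cm = predq,
            original_cm = truth$original_cm,
            error_pct = 100 * (predq - truth$original_cm) / truth$original_cm,
            error = rep(NA_character_, nq)
          ), nrow = nq)
        }, error = function(e) {
          truth <- truth_quantities(spec)
          nq <- nrow(truth)
          tibble::new_tibble(list(
            object = rep(spec$object, nq), shape = rep(spec$shape, nq),
            quantity = truth$quantity,
            camera_height_mm = rep(conditions$camera_height_mm[ci], nq),
            pitch_deg = rep(conditions$pitch_deg[ci], nq),
            replicate = rep(rep, nq), dtof_mm = rep(NA_real_, nq),
            predicted_cm = rep(NA_real_, nq), original_cm = truth$original_cm,
            error_pct = rep(NA_real_, nq),
            error = rep(conditionMessage(e), nq)
          ), nrow = nq)
        })
        rows[[counter]] <- row
      }
    }
  }
  out <- if (counter == 0L) empty else dplyr::bind_rows(rows)
  class(out) <- c("dishmetry_bench", class(out))
  out
}

#' Summaries and plots of bench results
#'
#' `tidy()` summarises errors per object and quantity; `glance()` gives
#' one row per quantity class (plate widths, bowl heights, bowl
#' diameters) with mean and sample sd of the percent error.
#'
#' @param x,object A `dishmetry_bench` tibble from [run_bench()].
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @export
tidy.dishmetry_bench <- function(x, ...) {
  x |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$object, .data$quantity) |>
    dplyr::summarise(
      mean_pct = mean(.data$error_pct),
      sd_pct = stats::sd(.data$error_pct),
      n = dplyr::n(),
      .groups = "drop"
    )
}

bench_quantity_class <- function(shape, quantity) {
  dplyr::case_when(
    shape %in% c("circular_plate", "square_plate") ~ "plate_dimension",
    quantity == "height" ~ "container_height",
    TRUE ~ "container_diameter"
  )
}

#' @rdname tidy.dishmetry_bench
#' @export
glance.dishmetry_bench <- function(x, ...) {
  x |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::mutate(class = bench_quantity_class(.data$shape, .data$quantity)) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      mean_pct = mean(.data$error_pct),
      sd_pct = stats::sd(.data$error_pct),
      max_abs_rel = max(abs(.data$error_pct)) / 100,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' @rdname tidy.dishmetry_bench
#' @export
autoplot.dishmetry_bench <- function(object, ...) {
  df <- dplyr::filter(object, is.na(.data$error)) |>
    dplyr::mutate(class = bench_quantity_class(.data$shape, .data$quantity))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$pitch_deg), y = .data$error_pct,
    colour = factor(.data$camera_height_mm)
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = "pitch (deg)", y = "error (%)",
                  colour = "camera height (mm)") +
    ggplot2::theme_minimal()
}
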