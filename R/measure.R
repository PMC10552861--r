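# Turning annotated pixel points plus a device pose into metric
# container dimensions.

# Orthogonal extents of a point set in its own frame, found by rotating
# calipers over the convex hull: for each hull edge direction the points
# are rotated edge-parallel and the bounding-box extents taken; the
# orientation with the smallest larger-extent wins. Rotation invariant,
# and equal to the plain x/y extents for an axis-aligned shape.
caliper_extents <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) {
    ex <- max(x) - min(x)
    ey <- max(y) - min(y)
    return(c(ex, ey))
  }
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[hull, , drop = FALSE]
  nh <- nrow(hp)
  edges <- hp[c(2:nh, 1), ] - hp
  angles <- unique(round(atan2(edges[, 2], edges[, 1]) %% (pi / 2), 12))
  best <- NULL
  best_key <- c(Inf, Inf)
  for (a in angles) {
    ca <- cos(-a)
    sa <- sin(-a)
    rx <- ca * x - sa * y
    ry <- sa * x + ca * y
    ext <- c(max(rx) - min(rx), max(ry) - min(ry))
    key <- c(max(ext), abs(a))
    if (key[1] < best_key[1] - 1e-12 ||
        (abs(key[1] - best_key[1]) <= 1e-12 && key[2] < best_key[2])) {
      best <- ext
      best_key <- key
    }
  }
  best
}

# Undistort annotated pixels and drop them onto a working plane;
# matrix in, matrix (X, Y, Z) out.
backproject_rim <- function(rim_px, h_mm, pitch_deg, plane_z_mm, intr) {
  world_from_px_m(as_point_matrix(rim_px, c("x", "y")),
                  h_mm, pitch_deg, plane_z_mm, intr)
}

circle_dimensions <- function(world) {
  n <- nrow(world)
  if (n == 2) {
    d <- sqrt(diff(world[, 1])^2 + diff(world[, 2])^2)
    if (d < 1e-9) {
      stop("degenerate-fit: rim points backproject to the same world point",
           call. = FALSE)
    }
    return(list(diameter = d, width_x = d, width_y = d))
  }
  fit <- fit_circle_pratt(world[, 1], world[, 2])
  # a circle's extent along any axis equals its diameter; reporting the
  # fitted diameter keeps the estimate invariant to in-plane rotation of
  # the marked points
  list(diameter = 2 * fit$r, width_x = 2 * fit$r, width_y = 2 * fit$r)
}

polygon_dimensions <- function(world) {
  ext <- caliper_extents(world[, 1], world[, 2])
  if (any(ext < 1e-9)) {
    stop("degenerate-fit: rim points are collinear", call. = FALSE)
  }
  list(diameter = mean(ext), width_x = ext[1], width_y = ext[2])
}

measurement_row <- function(type, dims, height_mm, pose, config) {
  tibble::new_tibble(list(
    type = type,
    width_x_cm = dims$width_x / 10,
    width_y_cm = dims$width_y / 10,
    diameter_cm = dims$diameter / 10,
    height_cm = height_mm / 10,
    pitch_deg = pose$pitch_deg,
    dtof_mm = pose$dtof_mm,
    height_model = config$height_model,
    bowl_plane_model = config$bowl_plane_model
  ), nrow = 1L)
}

#' Measure a plate from its rim annotation
#'
#' Undistorts the annotated rim pixels, backprojects them onto the
#' tabletop plane Z = 0 (plates are treated as flat, their thickness
#' approximated to zero), and reads dimensions off the metric plane:
#' circular plates get a Pratt circle-fit diameter (>= 5 points) or the
#' endpoint distance of a marked diameter (2 points); square plates get
#' the mean of the two orthogonal extremal extents.
#'
#' @param container A [container_annotation()] of a plate type.
#' @param pose A [device_pose()].
#' @param intr A [camera_intrinsics()].
#' @param config A [geometry_config()].
#' @return A one-row tibble with `type`, `width_x_cm`, `width_y_cm`,
#'   `diameter_cm`, `height_cm` (0 for plates) and provenance columns
#'   (`pitch_deg`, `dtof_mm`, model flags).
#' @export
measure_plate <- function(container, pose, intr = camera_intrinsics(),
                          config = geometry_config()) {
  stopifnot(inherits(container, "container_annotation"),
            inherits(pose, "device_pose"))
  if (!container$type %in% c("circular_plate", "square_plate")) {
    stop("measure_plate() expects a plate annotation", call. = FALSE)
  }
  h <- camera_height(pose$dtof_mm, pose$pitch_deg, config)
  world <- backproject_rim(container$rim, h, pose$pitch_deg, 0, intr)
  dims <- if (container$type == "circular_plate") {
    circle_dimensions(world)
  } else {
    polygon_dimensions(world)
  }
  measurement_row(container$type, dims, 0, pose, config)
}

#' Measure a bowl (or box) height and mouth dimensions
#'
#' Stages: (1) the height-pair top and base pixels are backprojected
#' onto the tabletop plane; the wall appears there as a y-extent `H'`.
#' (2) The true height is `H = tan(pitch) * H'` ([bowl_height()]).
#' (3) The camera height is adjusted to the raised mouth plane Z = H
#' ([adjusted_camera_height()]). (4) The rim points are backprojected
#' onto that plane. (5) The mouth diameter is measured there: circle fit
#' for circular bowls, orthogonal extents for boxes; the mean of the x-
#' and y-extents is the headline diameter and both are retained.
#'
#' @inheritParams measure_plate
#' @param container A [container_annotation()] of type `"bowl"` or
#'   `"rect_box"`, with a height pair.
#' @return A one-row tibble as in [measure_plate()], with `height_cm` the
#'   estimated container height.
#' @export
measure_bowl <- function(container, pose, intr = camera_intrinsics(),
                         config = geometry_config()) {
  stopifnot(inherits(container, "container_annotation"),
            inherits(pose, "device_pose"))
  if (!container$type %in% c("bowl", "rect_box")) {
    stop("measure_bowl() expects a bowl or rect_box annotation", call. = FALSE)
  }
  if (is.null(container$height_pair)) {
    stop("annotation error: height_pair is required for ", container$type,
         call. = FALSE)
  }
  h <- camera_height(pose$dtof_mm, pose$pitch_deg, config)
  hp_px <- rbind(container$height_pair$top, container$height_pair$base)
  hp_world <- backproject_rim(hp_px, h, pose$pitch_deg, 0, intr)
  H_prime <- abs(diff(hp_world[, 2]))
  H <- bowl_height(H_prime, pose$pitch_deg)
  h_adj <- adjusted_camera_height(h, H, pose$pitch_deg, config)
  world <- backproject_rim(container$rim, h_adj, pose$pitch_deg, H, intr)
  dims <- if (container$type == "bowl") {
    circle_dimensions(world)
  } else {
    polygon_dimensions(world)
  }
  measurement_row(container$type, dims, H, pose, config)
}

#' Measure every container in an image annotation
#'
#' Dispatches each annotated container to [measure_plate()] or
#' [measure_bowl()].
#'
#' @param ann An [image_annotation()].
#' @inheritParams measure_plate
#' @param on_error `"stop"` to propagate per-container errors, `"row"`
#'   to keep going and record the failure message in an `error` column
#'   (used by the command-line `measure` subcommand).
#' @return A tibble with one row per container; columns as in
#'   [measure_plate()] plus `image_id` and `container` (index).
#' @export
measure_containers <- function(ann, pose, intr = camera_intrinsics(),
                               config = geometry_config(),
                               on_error = c("stop", "row")) {
  stopifnot(inherits(ann, "image_annotation"))
  on_error <- match.arg(on_error)
  na_row <- function(cont, msg) {
    tibble::new_tibble(list(
      type = cont$type, width_x_cm = NA_real_, width_y_cm = NA_real_,
      diameter_cm = NA_real_, height_cm = NA_real_, pitch_deg = NA_real_,
      dtof_mm = NA_real_, height_model = config$height_model,
      bowl_plane_model = config$bowl_plane_model, error = msg
    ), nrow = 1L)
  }
  rows <- lapply(seq_along(ann$containers), function(i) {
    cont <- ann$containers[[i]]
    measure_one <- function() {
      f <- if (cont$type %in% c("bowl", "rect_box")) measure_bowl else measure_plate
      out <- f(cont, pose, intr, config)
      out$error <- NA_character_
      out
    }
    out <- if (on_error == "stop") {
      measure_one()
    } else {
      tryCatch(measure_one(),
               error = function(e) na_row(cont, conditionMessage(e)))
    }
    tibble::new_tibble(
      c(list(image_id = ann$image_id, container = i), as.list(out)),
      nrow = 1L
    )
  })
  if (length(rows) == 0) {
    proto <- na_row(list(type = character(0)), character(0))[0, ]
    return(tibble::new_tibble(
      c(list(image_id = character(0), container = integer(0)),
        as.list(proto)),
      nrow = 0L
    ))
  }
  dplyr::bind_rows(rows)
}
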