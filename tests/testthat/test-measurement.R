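geo_consistent <- geometry_config(bowl_plane_model = "geometric")

scene_measure <- function(spec, h, pitch, config = geo_consistent, ...) {
  scene <- render_scene(spec, h, pitch, config = config, ...)
  pose <- pose_at(scene$log, scene$t_image)
  measure_containers(scene$annotation, pose, config = config)
}

test_that("Pratt circle fit recovers circles exactly and flags degeneracy", {
  # full circle and a partial arc
  for (arc in list(seq(0, 2 * pi, length.out = 9)[-9],
                   seq(0.3, 1.8, length.out = 6))) {
    fit <- fit_circle_pratt(12 + 45 * cos(arc), -7 + 45 * sin(arc))
    expect_equal(fit$cx, 12, tolerance = 1e-9)
    expect_equal(fit$cy, -7, tolerance = 1e-9)
    expect_equal(fit$r, 45, tolerance = 1e-9)
    expect_lt(fit$rms, 1e-9)
  }
  # near-least-squares behaviour on noisy points
  set.seed(41)
  a <- runif(60, 0, 2 * pi)
  fit <- fit_circle_pratt(100 * cos(a) + rnorm(60, 0, 0.5),
                          100 * sin(a) + rnorm(60, 0, 0.5))
  expect_equal(fit$r, 100, tolerance = 0.02)

  expect_error(fit_circle_pratt(1:5, 2 * (1:5) + 3), "degenerate|collinear")
  expect_error(fit_circle_pratt(1:2, 2:3), "at least 3")
  expect_error(fit_circle_pratt(rep(1, 6), rep(2, 6)), "degenerate")
})

test_that("noiseless plates are recovered exactly at bench conditions", {
  # circular 18 cm plate at the 35 cm / 55 degree bench point
  m <- scene_measure(container_spec("circular_plate", 180), 350, 55)
  expect_equal(m$diameter_cm, 18, tolerance = 1e-6)
  expect_equal(m$height_cm, 0)
  expect_true(is.na(m$error))

  # square 23 cm plate, a different grid pose
  m2 <- scene_measure(container_spec("square_plate", 230), 500, 40)
  expect_equal(m2$diameter_cm, 23, tolerance = 1e-6)
  expect_equal(m2$width_x_cm, 23, tolerance = 1e-6)
  expect_equal(m2$width_y_cm, 23, tolerance = 1e-6)
})

test_that("two-point diameter marking matches the circle fit", {
  spec <- container_spec("circular_plate", 180)
  scene <- render_scene(spec, 350, 55, n_rim = 8)
  pose <- pose_at(scene$log, scene$t_image)
  rim <- scene$annotation$containers[[1]]$rim
  # points 1 and 5 of 8 are diametrically opposite
  two <- container_annotation("circular_plate", rim[c(1, 5), ])
  m2 <- measure_plate(two, pose)
  m8 <- measure_plate(scene$annotation$containers[[1]], pose)
  expect_equal(m2$diameter_cm, m8$diameter_cm, tolerance = 1e-9)
})

test_that("degenerate annotations are rejected", {
  pose <- device_pose(55, 580)
  same <- container_annotation("circular_plate",
                               data.frame(x = c(1200, 1200), y = c(900, 900)))
  expect_error(measure_plate(same, pose), "degenerate")
  expect_error(container_annotation("circular_plate",
                                    data.frame(x = 1:3, y = 1:3)),
               "2 rim points")
  expect_error(container_annotation("bowl", data.frame(x = 1:5, y = 1:5)),
               "height_pair")
})

test_that("noiseless bowls recover height and mouth diameter exactly", {
  m <- scene_measure(container_spec("cylinder_bowl", 150, height_mm = 60),
                     350, 55)
  expect_equal(m$height_cm, 6, tolerance = 1e-6)
  expect_equal(m$diameter_cm, 15, tolerance = 1e-6)

  # a 3.8 cm tall hollow box, as in handheld validation scenes
  mb <- scene_measure(container_spec("rect_box", 250, height_mm = 38,
                                     size2_mm = 170), 400, 55)
  expect_equal(mb$height_cm, 3.8, tolerance = 1e-6)
  expect_equal(mb$width_x_cm, 25, tolerance = 1e-6)
  expect_equal(mb$width_y_cm, 17, tolerance = 1e-6)
})

test_that("a zero height pair degenerates the bowl into a plate", {
  spec <- container_spec("circular_plate", 150)
  scene <- render_scene(spec, 350, 55)
  pose <- pose_at(scene$log, scene$t_image)
  rim <- scene$annotation$containers[[1]]$rim
  # same pixel marked as top and base: H' = 0
  hp <- list(top = c(rim$x[1], rim$y[1]), base = c(rim$x[1], rim$y[1]))
  bowl <- container_annotation("bowl", rim, hp)
  plate <- container_annotation("circular_plate", rim)
  mb <- measure_bowl(bowl, pose, config = geo_consistent)
  mp <- measure_plate(plate, pose, config = geo_consistent)
  expect_equal(mb$height_cm, 0)
  expect_equal(mb$diameter_cm, mp$diameter_cm, tolerance = 1e-12)
})

test_that("estimates are invariant to in-plane translation and rotation", {
  h <- 400
  pitch <- 50
  ref_specs <- list(
    container_spec("circular_plate", 200),
    container_spec("square_plate", 180),
    container_spec("cylinder_bowl", 150, height_mm = 60)
  )
  for (spec0 in ref_specs) {
    base <- scene_measure(spec0, h, pitch)
    # translations stay small enough that the bowl mouth still crosses
    # the image midline, where the height annotation is made
    for (tweak in list(c(dx = 40, dy = 60, rot = 0),
                       c(dx = -35, dy = 55, rot = 25),
                       c(dx = 0, dy = -45, rot = 60))) {
      y0 <- (h - spec0$height_mm) / tan(pitch * pi / 180)
      spec1 <- container_spec(spec0$shape, spec0$size_mm,
                              height_mm = spec0$height_mm,
                              center = c(tweak["dx"], y0 + tweak["dy"]),
                              rotation_deg = tweak["rot"])
      m <- scene_measure(spec1, h, pitch)
      expect_lt(abs(m$diameter_cm - base$diameter_cm), 1e-6)
      expect_lt(abs(m$height_cm - base$height_cm), 1e-6)
    }
  }
})

test_that("error_report reproduces the bench-table arithmetic", {
  expect_equal(
    error_report(tibble::tibble(object = "x", predicted_cm = 16.95,
                                original_cm = 18))$error_pct,
    -5.84, tolerance = 0.01
  )
  expect_equal(
    error_report(tibble::tibble(object = "x", predicted_cm = 18,
                                original_cm = 18))$error_pct,
    0
  )
  # the small circular plate group of the published bench table
  plates <- readr::read_csv(shipped("bench_plates.csv"),
                            show_col_types = FALSE)
  rep <- error_report(plates[, c("object", "predicted_cm", "original_cm")])
  small <- dplyr::filter(rep, object == "Circular Plate (Small)")
  expect_equal(small$group_mean_pct[1], -1.31, tolerance = 0.02)
  expect_equal(small$group_sd_pct[1], 4.82, tolerance = 0.02)
})

test_that("error_report validates the join and summarises groups", {
  res <- tibble::tibble(object = c("a", "a", "b"),
                        predicted_cm = c(9, 11, 20))
  truth <- tibble::tibble(object = c("a", "b"), original_cm = c(10, 20))
  rep <- error_report(res, truth)
  expect_equal(rep$error_pct, c(-10, 10, 0))
  expect_equal(unique(rep$group_mean_pct[rep$object == "a"]), 0)
  expect_equal(unique(rep$group_sd_pct[rep$object == "a"]),
               stats::sd(c(-10, 10)))
  expect_error(error_report(
    tibble::tibble(object = "c", predicted_cm = 1), truth), "no matching")

  g <- glance(rep)
  expect_equal(g$n, 3L)
  expect_equal(g$mean_pct, 0)
  td <- tidy(rep)
  expect_equal(nrow(td), 2L)
})

test_that("annotation JSON round-trips through disk", {
  rim <- data.frame(x = c(100.5, 200.25, 300, 410, 520), y = c(50, 60, 80, 90, 100))
  ann <- image_annotation("img_1", 12.5, list(
    container_annotation("circular_plate", rim),
    container_annotation("bowl", rim,
                         list(top = c(1, 2), base = c(3, 4)))
  ))
  path <- withr::local_tempfile(fileext = ".json")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_equal(back$image_id, "img_1")
  expect_equal(back$t_image, 12.5)
  expect_equal(back$containers[[1]]$rim, ann$containers[[1]]$rim)
  expect_equal(back$containers[[2]]$height_pair, ann$containers[[2]]$height_pair)
  # schema violations are named errors
  writeLines("{\"image_id\": \"x\"}", path)
  expect_error(read_annotation(path), "missing field")
})
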