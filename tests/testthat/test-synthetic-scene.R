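test_that("container specs validate their dimensions", {
  expect_error(container_spec("circular_plate", -1), "size_mm > 0")
  expect_error(container_spec("circular_plate", 180, height_mm = 20),
               "height 0")
  expect_error(container_spec("cylinder_bowl", 150), "positive height")
  specs <- bench_containers()
  expect_length(specs, 8L)
  expect_equal(vapply(specs, `[[`, 0, "size_mm"),
               c(180, 220, 260, 180, 230, 70, 110, 150))
  expect_equal(vapply(specs, `[[`, 0, "height_mm"),
               c(0, 0, 0, 0, 0, 30, 70, 60))
  grid <- bench_conditions()
  expect_equal(nrow(grid), 9L)
  expect_setequal(unique(grid$camera_height_mm), c(200, 350, 500))
  expect_setequal(unique(grid$pitch_deg), c(40, 55, 70))
})

test_that("rendered scenes are deterministic under a seed", {
  spec <- container_spec("cylinder_bowl", 110, height_mm = 70)
  noise <- noise_config(pixel_sigma_px = 2, pitch_sigma_deg = 1,
                        tof_sigma_mm = 3)
  a <- render_scene(spec, 350, 55, noise = noise, seed = 7)
  b <- render_scene(spec, 350, 55, noise = noise, seed = 7)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$log, b$log)
  expect_identical(a$truth, b$truth)
  c <- render_scene(spec, 350, 55, noise = noise, seed = 8)
  expect_false(identical(a$annotation, c$annotation))

  # byte-level determinism of the files the simulate command writes
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cmd_simulate(spec, 350, 55, d1, noise = noise, seed = 7, verbosity = 0)
  cmd_simulate(spec, 350, 55, d2, noise = noise, seed = 7, verbosity = 0)
  for (f in c("annotation.json", "sensorlog.csv", "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("the renderer's sensor log encodes pose consistently", {
  spec <- container_spec("circular_plate", 180)
  for (model in c("paper_tan", "slant_sin")) {
    cfg <- geometry_config(height_model = model)
    scene <- render_scene(spec, 350, 55, config = cfg)
    pose <- pose_at(scene$log, scene$t_image)
    expect_equal(pose$pitch_deg, 55, tolerance = 1e-9)
    # inverting the height model recovers the true camera height
    expect_equal(camera_height(pose$dtof_mm, pose$pitch_deg, cfg), 350,
                 tolerance = 1e-9)
  }
})

test_that("unrenderable poses raise the configured guard errors", {
  spec <- container_spec("circular_plate", 180)
  # near-vertical view with the tan model drives the ToF reading under
  # the sensor's minimum range
  expect_error(render_scene(spec, 350, 89.5), "outside the sensor range")
  expect_error(render_scene(spec, 350, 95), "between 0 and 90")
  # a container wider than the visible table cannot be framed
  expect_error(render_scene(container_spec("circular_plate", 4000), 350, 55),
               "framing")
  expect_error(
    render_scene(container_spec("cylinder_bowl", 100, height_mm = 80), 70, 55),
    "above the container")
})

test_that("the zero-noise bench recovers every dimension exactly", {
  bench <- run_bench(config = geometry_config(bowl_plane_model = "geometric"),
                     seed = 1)
  expect_s3_class(bench, "dishmetry_bench")
  # 5 plates x 1 quantity + 3 bowls x 2 quantities, over 9 conditions
  expect_equal(nrow(bench), 99L)
  expect_true(all(is.na(bench$error)))
  expect_lt(max(abs(bench$error_pct)) / 100, 1e-6)
})

test_that("replicates = 0 yields an empty table with the right header", {
  bench <- run_bench(replicates = 0, seed = 1)
  expect_equal(nrow(bench), 0L)
  expect_true(all(c("object", "quantity", "predicted_cm", "original_cm",
                    "error_pct", "error") %in% names(bench)))
})

test_that("plate error dispersion grows with pixel noise", {
  one_plate <- list(container_spec("circular_plate", 220))
  cond <- bench_conditions(350, 55)
  sds <- vapply(c(0.5, 4, 16), function(sigma) {
    b <- run_bench(one_plate, cond,
                   noise = noise_config(pixel_sigma_px = sigma),
                   replicates = 60, seed = 99)
    stats::sd(b$error_pct, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("plate error dispersion grows with pitch noise", {
  one_plate <- list(container_spec("circular_plate", 220))
  cond <- bench_conditions(350, 55)
  sds <- vapply(c(0.2, 1, 3), function(sigma) {
    b <- run_bench(one_plate, cond,
                   noise = noise_config(pitch_sigma_deg = sigma),
                   replicates = 60, seed = 7)
    stats::sd(b$error_pct, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("bowl heights are the fragile quantity under equal noise", {
  noise <- noise_config(pixel_sigma_px = 2, pitch_sigma_deg = 1.36,
                        pitch_bias_deg = -2.43)
  b <- run_bench(
    list(container_spec("circular_plate", 180),
         container_spec("cylinder_bowl", 150, height_mm = 60)),
    noise = noise, replicates = 25, seed = 5
  )
  plate_sd <- stats::sd(b$error_pct[b$shape == "circular_plate"], na.rm = TRUE)
  height_sd <- stats::sd(b$error_pct[b$quantity == "height"], na.rm = TRUE)
  expect_gt(height_sd, plate_sd)
})

test_that("bench summaries expose per-class error statistics", {
  bench <- run_bench(config = geometry_config(bowl_plane_model = "geometric"),
                     seed = 1)
  g <- glance(bench)
  expect_setequal(g$class, c("plate_dimension", "container_height",
                             "container_diameter"))
  expect_true(all(g$max_abs_rel < 1e-6))
  td <- tidy(bench)
  expect_equal(nrow(td), 11L) # 5 plates + 3 bowls x 2 quantities
  p <- autoplot(bench)
  expect_s3_class(p, "ggplot")
})
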