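test_that("maximum projection is the elementwise max, invariant to order", {
  a <- matrix(0, 8, 8)
  b <- matrix(runif(64, 0, 100), 8, 8)
  stack <- list(a, b)
  expect_equal(max_project(stack), b)
  expect_equal(max_project(list(b, a)), max_project(stack))
  expect_warning(one <- max_project(stack, 2), "2-4")
  expect_equal(one, b)
  expect_error(max_project(stack, integer(0)), "empty")
  expect_error(max_project(stack, 3), "outside")
})

test_that("probe mean is exact on constant and piecewise-constant images", {
  img <- matrix(42, 20, 20)
  pr <- line_probe(x = c(2, 15), y = c(3, 12))
  expect_equal(probe_mean(img, pr), 42)

  # vertical step edge at x = 10: left 10 AU, right 90 AU
  step <- cbind(matrix(10, 20, 10), matrix(90, 20, 10))
  left <- line_probe(x = c(1, 7), y = c(2, 16))
  right <- line_probe(x = c(12, 18), y = c(2, 16))
  expect_equal(probe_mean(step, left), 10)
  expect_equal(probe_mean(step, right), 90)

  expect_error(probe_mean(img, line_probe(x = c(5, 25), y = c(5, 5))),
               "outside image bounds")
})

test_that("probe mean is invariant under joint image and probe translation", {
  set.seed(61)
  img <- matrix(runif(900, 0, 255), 30, 30)
  big <- matrix(0, 40, 40)
  big[6:35, 6:35] <- img # same content shifted by (+5, +5)
  pr <- line_probe(x = c(3.2, 20.7, 24.1), y = c(4.5, 8.3, 22.9))
  pr_shift <- line_probe(x = pr$vertices$x + 5, y = pr$vertices$y + 5)
  padded <- matrix(0, 40, 40); padded[1:30, 1:30] <- img
  expect_equal(probe_mean(big, pr_shift), probe_mean(padded, pr),
               tolerance = 1e-6)
})

test_that("the synthetic follicle ridge is measured to within 2 AU of truth", {
  fix <- synth_follicle_image(membrane = 200, cytoplasm = 50, noise_sd = 0, seed = 3)
  img <- max_project(fix$stack, 1:2)
  expect_equal(probe_mean(img, fix$membrane_probe), 200, tolerance = 2)
  ci <- corrected_membrane_intensity(img, fix$membrane_probe, fix$cytoplasm_probe)
  expect_equal(ci$corrected, fix$truth$corrected, tolerance = 2)
  expect_false(ci$flagged_negative)
})

test_that("corrected intensity is linear and offset-invariant", {
  fix <- synth_follicle_image(membrane = 120, cytoplasm = 30, noise_sd = 0, seed = 8)
  fix2 <- synth_follicle_image(membrane = 240, cytoplasm = 60, noise_sd = 0, seed = 8)
  img <- max_project(fix$stack, 1:2)
  img2 <- max_project(fix2$stack, 1:2)
  c1 <- corrected_membrane_intensity(img, fix$membrane_probe, fix$cytoplasm_probe)
  c2 <- corrected_membrane_intensity(img2, fix2$membrane_probe, fix2$cytoplasm_probe)
  expect_equal(c2$corrected, 2 * c1$corrected, tolerance = 1e-9)

  # adding a constant to the whole image cancels exactly in the subtraction
  c3 <- corrected_membrane_intensity(img + 500, fix$membrane_probe, fix$cytoplasm_probe)
  expect_equal(c3$corrected, c1$corrected, tolerance = 1e-9)
  expect_equal(c3$membrane_mean, c1$membrane_mean + 500, tolerance = 1e-9)
})

test_that("fixture generation is seed-reproducible; negatives flagged not clipped", {
  f1 <- synth_follicle_image(seed = 42, noise_sd = 5)
  f2 <- synth_follicle_image(seed = 42, noise_sd = 5)
  expect_identical(f1$stack, f2$stack)

  # inverted contrast: membrane dimmer than cytoplasm
  inv <- synth_follicle_image(membrane = 20, cytoplasm = 80, noise_sd = 0, seed = 2)
  ci <- corrected_membrane_intensity(max_project(inv$stack, 1:2),
                                     inv$membrane_probe, inv$cytoplasm_probe)
  expect_lt(ci$corrected, 0)
  expect_true(ci$flagged_negative)
})

test_that("overlapping membrane and cytoplasm probes are rejected", {
  fix <- synth_follicle_image(seed = 4)
  img <- max_project(fix$stack, 1:2)
  v <- fix$membrane_probe$vertices
  inside <- region_probe(
    x = c(v$x[1] - 3, v$x[2] + 3, v$x[2] + 3, v$x[1] - 3),
    y = c(v$y[1] - 3, v$y[2] - 3, v$y[2] + 3, v$y[1] + 3)
  )
  expect_error(corrected_membrane_intensity(img, fix$membrane_probe, inside),
               "disjoint")
})

test_that("image stacks round-trip through 16-bit TIFF", {
  set.seed(63)
  stack <- list(matrix(sample(0:65535, 256), 16, 16),
                matrix(sample(0:65535, 256), 16, 16))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(stack, path)
  back <- read_image_stack(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]], stack[[1]])
  expect_equal(back[[2]], stack[[2]])
})

test_that("line probes load from JSON and CSV", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(vertices = data.frame(x = c(1, 5), y = c(2, 9)), width = 3),
    path, auto_unbox = TRUE
  )
  pr <- read_line_probe(path)
  expect_equal(pr$width, 3)
  expect_equal(pr$length, sqrt(16 + 49))

  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(x = c(0, 3), y = c(0, 4)), csv)
  expect_equal(read_line_probe(csv)$length, 5)
})

test_that("densitometry normalizes to loading control and to wild type", {
  rec <- tibble::tibble(
    lane = c("wt1", "wt2", "mut"),
    band_intensity = c(100, 110, 84),
    loading_intensity = c(100, 110, 100)
  )
  out <- densitometry_normalize(rec, control_lanes = c("wt1", "wt2"))
  expect_equal(out$normalized, c(1, 1, 0.84))
  expect_equal(out$relative_to_control, c(1, 1, 0.84))

  # halving a lane's loading doubles its normalized value
  rec2 <- rec; rec2$loading_intensity[3] <- 50
  out2 <- densitometry_normalize(rec2, control_lanes = c("wt1", "wt2"))
  expect_equal(out2$normalized[3], 2 * out$normalized[3])

  # common rescaling of all lanes leaves relative values unchanged
  rec3 <- rec
  rec3$band_intensity <- rec3$band_intensity * 7.5
  rec3$loading_intensity <- rec3$loading_intensity * 7.5
  out3 <- densitometry_normalize(rec3, control_lanes = c("wt1", "wt2"))
  expect_equal(out3$relative_to_control, out$relative_to_control)

  rec4 <- rec; rec4$loading_intensity[1] <- 0
  expect_error(densitometry_normalize(rec4, "wt1"), "wt1")
  expect_error(densitometry_normalize(rec, "absent"), "control_lanes")
})
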