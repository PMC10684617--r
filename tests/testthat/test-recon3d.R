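# Serial-section reconstruction: image primitives, registration, volume IO.

test_that("resolution unification takes block means with half-up rounding", {
  img <- matrix(7, 20, 20)
  expect_equal(unify_resolution(img, 20L), matrix(7, 1, 1))
  expect_identical(unify_resolution(img, 1L), img)
  chk <- outer(1:4, 1:4, function(i, j) ifelse((i + j) %% 2 == 0, 255, 0))
  expect_true(all(unify_resolution(chk, 2L) == 128))
  expect_error(unify_resolution(img, 0L), class = "ccsmap_input_error")
  stack <- section_stack(list(array(50, c(8, 8, 3))), pixel_size_um = 0.5)
  down <- unify_resolution(stack, 2L)
  expect_equal(dim(down$images[[1]]), c(4, 4, 3))
  expect_equal(down$pixel_size_um, 1.0)
})

test_that("hole filling closes enclosed regions and matches a BFS oracle", {
  ring <- matrix(FALSE, 11, 11)
  ring[3:9, 3:9] <- TRUE
  ring[5:7, 5:7] <- FALSE
  filled <- fill_holes(ring)
  solid <- matrix(FALSE, 11, 11); solid[3:9, 3:9] <- TRUE
  expect_identical(filled, solid)
  # A solid disk is unchanged; filling is idempotent and a superset.
  expect_identical(fill_holes(solid), solid)
  expect_identical(fill_holes(filled), filled)
  # Nested rings become one filled block.
  nested <- matrix(FALSE, 15, 15)
  nested[2:14, 2:14] <- TRUE; nested[4:12, 4:12] <- FALSE
  nested[6:10, 6:10] <- TRUE; nested[7:9, 7:9] <- FALSE
  expect_identical(fill_holes(nested), oracle_fill_holes(nested))
  set.seed(101)
  for (rep in 1:20) {
    m <- matrix(runif(15 * 15) < 0.55, 15, 15)
    got <- fill_holes(m)
    expect_identical(got, oracle_fill_holes(m))
    expect_true(all(got[m]))
  }
})

test_that("Sobel magnitude matches direct kernel arithmetic", {
  expect_true(all(sobel_magnitude(matrix(80, 6, 6)) == 0))
  # Vertical step edge responds exactly at the step columns.
  step <- cbind(matrix(0, 5, 3), matrix(100, 5, 3))
  mag <- sobel_magnitude(step)
  expect_true(all(mag[, c(3, 4)] > 0))
  expect_true(all(mag[, c(1, 2, 5, 6)] == 0))
  # 3x3 patch against hand convolution (replicate padding).
  patch <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, byrow = TRUE)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  pad <- patch[c(1, 1:3, 3), c(1, 1:3, 3)]
  gx <- gy <- 0
  for (dy in -1:1) for (dx in -1:1) {
    gx <- gx + kx[dy + 2, dx + 2] * pad[2 + 1 + dy, 2 + 1 + dx]
    gy <- gy + t(kx)[dy + 2, dx + 2] * pad[2 + 1 + dy, 2 + 1 + dx]
  }
  expect_equal(sobel_magnitude(patch)[2, 2], sqrt(gx^2 + gy^2))
  uni <- extract_contour(matrix(5, 8, 8))
  expect_false(any(uni$edges))
  expect_identical(uni$image, matrix(5, 8, 8))
})

test_that("contrast enhancement follows gain/bias with clipping", {
  expect_equal(enhance(matrix(0:255, 16), 1, 0), matrix(0:255, 16),
               ignore_attr = FALSE)
  expect_equal(enhance(matrix(100), 2, 10)[1, 1], 210)
  expect_equal(enhance(matrix(200), 2, 0)[1, 1], 255)
  expect_equal(enhance(matrix(3), -2, 0)[1, 1], 0)
  # Monotone in the input for positive gain.
  set.seed(5)
  x <- sort(runif(50, 0, 255))
  y <- as.vector(enhance(matrix(x, 1), 1.7, 12))
  expect_true(all(diff(y) >= 0))
})

test_that("channel recoding maps tissue, positives and background", {
  img <- array(0, c(12, 12, 3))
  img[3:10, 3:10, 3] <- 200      # tissue (blue), solid
  img[5:6, 5:6, 3] <- 0          # an enclosed hole -> profile only
  img[8:9, 8:9, 1] <- 230        # red positives
  img[4, 4, 2] <- 250            # green must be ignored
  out <- recode_channels(img)
  expect_equal(out[5, 5], 40)    # hole filled to profile
  expect_equal(out[3, 3], 10)    # blue-positive pixel
  expect_equal(out[8, 8], 180)   # red overrides
  expect_equal(out[1, 1], 0)     # background
  expect_true(all(out %in% c(0, 10, 40, 180)))
})

test_that("layer merging averages but preserves canonical positives", {
  a <- matrix(40, 4, 4)
  b <- matrix(40, 4, 4); b[2, 2] <- 180; b[3, 3] <- 10
  expect_identical(merge_layers(list(a)), a)
  expect_identical(merge_layers(list(b, b)), b)
  m <- merge_layers(list(a, b))
  expect_equal(m[2, 2], 180)
  expect_equal(m[3, 3], 10)
  expect_equal(m[1, 1], 40)
  expect_error(merge_layers(list(a, matrix(0, 3, 3))),
               class = "ccsmap_input_error")
})

test_that("frequency analysis reports histograms and moment summaries", {
  set.seed(6)
  img <- matrix(runif(400, 60, 120), 20)
  same <- frequency_analysis(img, img)
  expect_identical(same$histograms$before, same$histograms$after)
  expect_equal(same$sd_ratio, 1)
  expect_equal(sum(same$histograms$before[[1]]), length(img))
  # Doubling gain on a mid-range image doubles the spread.
  enh <- frequency_analysis(img, enhance(img, 2, 0))
  expect_equal(enh$sd_ratio, 2, tolerance = 0.02)
})

test_that("rigid transforms invert exactly and registration recovers them", {
  cfg <- sim_config(seed = 7, noise_sd = 0)
  gs <- gen_sections(cfg, 2, size_px = 96, z_range = c(0.45, 0.5))
  img <- gs$stack$images[[1]]
  fwd <- warp_rigid(img, 6, 3, -4)
  back <- warp_rigid(fwd, -6, invert_rigid(6, 3, -4)$dx,
                     invert_rigid(6, 3, -4)$dy)
  # Resampling blurs the speckle, but the binarised tissue footprint must
  # survive the round trip almost everywhere.
  inner <- 20:76
  m0 <- img[inner, inner, 3] > 100
  m1 <- back[inner, inner, 3] > 100
  expect_gt(mean(m0 == m1), 0.9)

  # Identical consecutive slices give the identity transform.
  twin <- section_stack(list(img, img))
  reg0 <- register_slices(twin)
  expect_equal(reg0$transforms[[2]]$rotation_deg, 0, tolerance = 1e-8)
  expect_equal(abs(reg0$transforms[[2]]$dx), 0, tolerance = 1e-6)

  # Pure translation and pure rotation, applied and recovered.
  for (tr in list(list(r = 0, dx = 5, dy = -3), list(r = 7, dx = 0, dy = 0))) {
    moved <- warp_rigid(img, tr$r, tr$dx, tr$dy)
    reg <- register_slices(section_stack(list(img, moved)))
    est <- reg$transforms[[2]]
    expect_lt(abs(est$rotation_deg - tr$r), 1)
    expect_lt(abs(est$dx - tr$dx), 0.5)
    expect_lt(abs(est$dy - tr$dy), 0.5)
  }

  # An empty slice is a registration error.
  blank <- array(0, dim(img))
  expect_error(register_slices(section_stack(list(img, blank))),
               class = "ccsmap_input_error")
  expect_error(register_slices(section_stack(list(img))),
               class = "ccsmap_input_error")
})

test_that("rotation and shift are recovered across seeded phantoms", {
  worst_rot <- 0; worst_shift <- 0
  for (seed in 1:20) {
    cfg <- sim_config(seed = 200 + seed, noise_sd = 5)
    gs <- gen_sections(cfg, 4, size_px = 160, z_range = c(0.35, 0.55))
    reg <- register_slices(gs$stack)
    for (i in 2:4) {
      est <- reg$transforms[[i]]; tru <- gs$affine_truth[[i]]
      worst_rot <- max(worst_rot, abs(est$rotation_deg - tru$rotation_deg))
      worst_shift <- max(worst_shift, abs(est$dx - tru$dx),
                         abs(est$dy - tru$dy))
    }
  }
  expect_lt(worst_rot, 1)
  expect_lt(worst_shift, 0.5)
})

test_that("volumes serialise to legacy VTK and round-trip exactly", {
  layers <- list(matrix(c(0, 10, 40, 180, 0, 0, 40, 40, 180, 10, 0, 0,
                          40, 0, 10, 180), 4),
                 matrix(runif(16, 0, 255), 4))
  vol <- build_volume(layers, pixel_size_um = 0.65, dz_um = 10)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(vol, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# vtk DataFile Version")
  expect_true("DIMENSIONS 4 4 2" %in% lines)
  expect_true(any(grepl("^SPACING 0.65 0.65 10", lines)))
  back <- read_vtk(path)
  expect_identical(back$data, vol$data)
  expect_identical(back$spacing, vol$spacing)
  # Slice order is preserved in the grid.
  expect_identical(vol$data[, , 2], layers[[2]])
})
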