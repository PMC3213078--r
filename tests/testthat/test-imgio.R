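# TIFF and table I/O, configuration handling.

test_that("volumes round-trip through multi-page TIFF", {
  set.seed(1)
  arr <- array(runif(2 * 4 * 4, 0, 50), dim = c(2, 4, 4))
  vol <- volume_image(arr, c(0.1075, 0.1075, 0.15), time_index = 3L)
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(dim(back$data), c(2, 4, 4))
  expect_equal(back$voxel_size, vol$voxel_size)
  expect_equal(back$time_index, 3L)
  # first round trip exact to 32-bit float precision...
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  # ...and subsequent round trips bit-exact
  path2 <- withr::local_tempfile(fileext = ".tif")
  write_volume(back, path2)
  expect_identical(read_volume(path2)$data, back$data)
})

test_that("voxel-size override wins over file metadata, with a notice", {
  vol <- volume_image(array(1, dim = c(2, 3, 3)), c(0.1, 0.1, 0.2))
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(vol, path)
  expect_message(
    back <- read_volume(path, voxel_size_override = c(0.1075, 0.1075, 0.15)),
    "override")
  expect_equal(back$voxel_size, c(0.1075, 0.1075, 0.15))
})

test_that("a TIFF without voxel metadata needs an override", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 4, 4), matrix(0.2, 4, 4)), path)
  expect_error(read_volume(path), "voxel size")
  back <- read_volume(path, voxel_size_override = c(0.1, 0.1, 0.2))
  expect_equal(dim(back$data), c(2, 4, 4))
})

test_that("volume_image validates its inputs", {
  expect_error(volume_image(matrix(1, 2, 2), c(1, 1, 1)), "3D")
  expect_error(volume_image(array(1, c(2, 2, 2)), c(0, 1, 1)), "positive")
  expect_error(volume_image(array(-1, c(2, 2, 2)), c(1, 1, 1)), "nonnegative")
  expect_warning(volume_image(array(1, c(2, 2, 2)), c(0.01, 0.01, 0.3)),
                 "anisotropy")
})

test_that("spine tables round-trip with 6-significant-digit fidelity", {
  sp <- small_phantom()
  df <- as.data.frame(sp$fit)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spine_table(df, path)
  back <- read_spine_table(path)
  expect_equal(nrow(back), nrow(df))
  for (cc in c("length", "head_width", "neck_width", "head_volume",
               "attach_x", "attach_y", "attach_z")) {
    expect_equal(signif(back[[cc]], 6), signif(df[[cc]], 6))
  }
  expect_identical(back$class, df$class)

  # empty records give a header-only file
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_spine_table(df[0, ], path2)
  expect_equal(length(readLines(path2)), 1)
  expect_equal(nrow(read_spine_table(path2)), 0)
})

test_that("analysis configurations validate and round-trip", {
  cfg <- analysis_config("fixed")
  expect_equal(cfg$min_spine_end_diameter, 0.215)
  expect_equal(cfg$max_spine_length, 5)
  live <- analysis_config("live")
  expect_equal(live$min_spine_end_diameter, 0.3)
  expect_equal(live$max_spine_length, 15)

  expect_error(analysis_config(min_spine_end_diameter = 0.8),
               "smaller than min_dendrite_end_diameter")
  expect_error(analysis_config(stubby_length_max = 6), "smaller than")
  expect_error(analysis_config(max_spine_length = -1), "positive")

  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(analysis_config("live", tracking_gate = 0.8), path)
  back <- read_config(path)
  expect_equal(back$mode, "live")
  expect_equal(back$tracking_gate, 0.8)
  writeLines("bogus_key: 1", path)
  expect_error(read_config(path), "unknown configuration")
})
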