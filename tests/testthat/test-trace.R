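# Segmentation and dendrite centerline extraction.

test_that("segmentation keeps the seeded component and rejects bad input", {
  spec <- phantom_spec(field_of_view = c(8, 5, 5), seed = 1)
  ph <- rasterize(spec)
  seg <- segment_volume(ph$volume, c(0.2, 2.5, 2.5))
  # mask within one boundary voxel of the rendered solid
  expect_lt(mean(xor(seg$mask, ph$solid)), 0.01)
  expect_gt(sum(seg$mask & ph$solid) / sum(ph$solid), 0.95)

  flat <- volume_image(array(5, c(4, 8, 8)), c(0.1, 0.1, 0.15))
  expect_error(segment_volume(flat, c(0.4, 0.4, 0.3)), "constant")

  # two disjoint bright objects: only the seeded one survives
  arr <- array(0, c(10, 20, 20))
  arr[3:5, 3:6, 3:6] <- 100
  arr[6:8, 14:17, 14:17] <- 100
  vol <- volume_image(arr, c(0.1, 0.1, 0.1))
  segA <- segment_volume(vol, c(0.45, 0.45, 0.4))
  expect_true(segA$mask[4, 4, 4])
  expect_false(any(segA$mask[6:8, 14:17, 14:17]))

  expect_error(segment_volume(vol, c(1.05, 1.05, 0.45)), "background")
})

test_that("a straight tube is traced at full length with the right radius", {
  spec <- phantom_spec(field_of_view = c(20, 6, 6), seed = 1)
  ph <- rasterize(spec)
  tr <- trace_dendrite(ph$volume, c(0.1, 3, 3))
  expect_lt(abs(tr$length - 20) / 20, 0.02)
  expect_lt(abs(mean(tr$radius) - 0.6), 0.1075)
  # arclength bookkeeping: total equals summed segment lengths
  expect_equal(tr$length, sum(sqrt(rowSums(diff(tr$points)^2))),
               tolerance = 1e-9)
})

test_that("a sine-curved tube recovers the analytic arc length within 2%", {
  spec <- phantom_spec(field_of_view = c(24, 12, 7),
                       dendrite_path = list(type = "sine",
                                            amplitude = 2, period = 14),
                       seed = 2)
  ph <- rasterize(spec)
  path <- spinemorph:::phantom_path(spec)
  inside <- path$points[, 1] >= 0 & path$points[, 1] <= 24
  true_len <- spinemorph:::arc_length(path$points[inside, ])
  st <- spinemorph:::path_at(path, 0.05)$point
  tr <- trace_dendrite(ph$volume, st)
  expect_lt(abs(tr$length - true_len) / true_len, 0.02)
})

test_that("spine branches are excluded from the dendrite path", {
  sp <- small_phantom()
  bare <- phantom_spec(field_of_view = c(15, 9, 9), seed = 42)
  tr_bare <- trace_dendrite(rasterize(bare)$volume, c(0.1, 4.5, 4.5))
  tr_spiny <- sp$fit$trace
  # spines (diameter < 0.75 um) must not extend the dendrite path
  expect_lt(abs(tr_spiny$length - tr_bare$length), 0.5)
  # and every path point keeps a dendrite-caliber radius
  expect_true(all(2 * tr_spiny$radius >= 0.75))
})

test_that("trace length is invariant to sub-voxel translation", {
  base_len <- NULL
  for (dy in c(0, 0.04, 0.07)) {
    spec <- phantom_spec(field_of_view = c(12, 6, 6), seed = 1)
    spec$dendrite_path <- list(type = "sine", amplitude = dy, period = 1e6)
    ph <- rasterize(spec)
    tr <- trace_dendrite(ph$volume, c(0.1, 3 + dy * sin(0), 3))
    if (is.null(base_len)) base_len <- tr$length
    expect_lt(abs(tr$length - base_len) / base_len, 0.02)
  }
})

test_that("dilating the tube never shortens the traced dendrite", {
  lens <- vapply(c(0.45, 0.6, 0.8), function(r) {
    spec <- phantom_spec(field_of_view = c(12, 6, 6), dendrite_radius = r,
                         seed = 1)
    trace_dendrite(rasterize(spec)$volume, c(0.1, 3, 3))$length
  }, numeric(1))
  expect_true(all(diff(lens) > -0.02 * lens[-length(lens)]))
})

test_that("a start point far from any skeleton voxel is an error", {
  spec <- phantom_spec(field_of_view = c(10, 6, 6), seed = 1)
  ph <- rasterize(spec)
  # inside the mask near the surface but > 3 voxels from the centerline:
  # fails either at thresholding or at skeleton lookup
  expect_error(trace_dendrite(ph$volume, c(5, 3, 3.55)),
               "skeleton|background")
})

test_that("short dendrite paths warn about a mis-set ROI", {
  spec <- phantom_spec(field_of_view = c(3.5, 5, 5), seed = 1)
  ph <- rasterize(spec)
  expect_warning(trace_dendrite(ph$volume, c(0.1, 2.5, 2.5)), "5 um")
})

test_that("trace export writes the polyline with radii", {
  sp <- small_phantom()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(sp$fit$trace, path)
  back <- read.csv(path)
  expect_named(back, c("x", "y", "z", "radius", "arclength"))
  expect_equal(nrow(back), nrow(sp$fit$trace$points))
})
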