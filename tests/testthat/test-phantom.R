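# Phantom rendering, ground truth and the remodeling script machinery.

test_that("rasterized sphere volume matches the analytic value within 5%", {
  # lone sphere rendered via a degenerate zero-length-neck spine is awkward;
  # rasterize the primitive directly through the scene renderer
  vox <- c(0.1075, 0.1075, 0.1075)
  dimz <- c(21L, 21L, 21L)
  ctr <- (21 / 2) * 0.1075
  cov <- spinemorph:::rasterize_scene_cpp(
    dimz, vox, matrix(c(ctr, ctr, ctr, 0.3), 1), matrix(numeric(0), ncol = 7))
  analytic <- (4 / 3) * pi * 0.3^3
  expect_lt(abs(sum(cov) * prod(vox) - analytic) / analytic, 0.05)
  # binary count at half coverage is also close
  expect_lt(abs(sum(cov >= 0.5) * prod(vox) - analytic) / analytic, 0.05)
})

test_that("a spec with no spines renders only the tube, with empty truth", {
  spec <- phantom_spec(field_of_view = c(8, 5, 5), seed = 1)
  ph <- rasterize(spec)
  expect_equal(nrow(ph$truth), 0)
  # solid is a tube through the x faces: present in every x slab
  occupancy <- apply(ph$solid, 3, sum)
  expect_true(all(occupancy > 0))
  expect_lt(max(abs(occupancy - mean(occupancy))) / mean(occupancy), 0.2)
})

test_that("rendering is deterministic under a fixed seed", {
  spec <- phantom_spec(field_of_view = c(8, 5, 5), seed = 99,
                       spines = list(spine_spec(4, 0, 1.2, 0.5, 0.2)),
                       noise = list(type = "gaussian", sd = 8))
  ph1 <- rasterize(spec)
  ph2 <- rasterize(spec)
  expect_identical(ph1$volume$data, ph2$volume$data)
  expect_identical(ph1$truth, ph2$truth)
})

test_that("blur and noise never alter the truth table", {
  base <- phantom_spec(field_of_view = c(8, 6, 6), seed = 2,
                       spines = list(spine_spec(4, 1, 1.4, 0.55, 0.22)))
  noisy <- base; noisy$noise <- list(type = "poisson", scale = 2)
  blurred <- base; blurred$psf_sigma <- c(0.1, 0.1, 0.2)
  expect_identical(rasterize(base)$truth, rasterize(noisy)$truth)
  expect_identical(rasterize(base)$truth, rasterize(blurred)$truth)
})

test_that("generated truth classes agree with the classifier", {
  spec <- standard_phantom(n_spines = 12, dendrite_length = 32, seed = 8)
  ph <- rasterize(spec)
  expect_equal(nrow(ph$truth), 12)
  expect_identical(
    ph$truth$class,
    classify_spines(ph$truth$length, ph$truth$head_width,
                    ph$truth$neck_width))
})

test_that("a spine outside the field of view is rejected by id", {
  spec <- phantom_spec(field_of_view = c(10, 4, 4),
                       spines = list(spine_spec(5, 0, 1.0, 0.4, 0.3),
                                     spine_spec(7, 0, 3.0, 0.4, 0.3)))
  expect_error(rasterize(spec), "spine 2")
})

test_that("too-narrow dendrites and bad voxel sizes are rejected", {
  expect_error(phantom_spec(dendrite_radius = 0.3), "0.75")
  # both the renderer and the volume container flag the anisotropy
  expect_warning(expect_warning(
    rasterize(phantom_spec(field_of_view = c(4, 3, 3),
                           voxel_size = c(0.05, 0.05, 0.3), seed = 1)),
    "anisotropy"), "anisotropy")
})

test_that("series events are book-kept exactly", {
  spines <- lapply(1:3, function(i) spine_spec(2 + 2 * i, i, 2.2, 0.28, 0.25))
  spec <- phantom_spec(field_of_view = c(12, 8, 8), spines = spines, seed = 4)
  script <- remodel_script(n_time = 13, events = list(
    ev_prune(1, 6), ev_appear(2, 3),
    ev_morph(3, 6, 2.0, 0.6, 0.25)), jitter_amplitude = 0)
  ser <- rasterize_series(spec, script)
  tr <- ser$truth
  expect_equal(nrow(tr), 3 * 13)
  expect_identical(tr$present[tr$id == 1], c(rep(TRUE, 6), rep(FALSE, 7)))
  expect_identical(tr$present[tr$id == 2], c(rep(FALSE, 3), rep(TRUE, 10)))
  expect_identical(tr$class[tr$id == 3],
                   c(rep("thin", 6), rep("mushroom", 7)))
})

test_that("zero jitter and no events give identical noise-free volumes", {
  spec <- phantom_spec(field_of_view = c(8, 6, 6), seed = 3,
                       spines = list(spine_spec(4, 0, 1.5, 0.6, 0.2)))
  ser <- rasterize_series(spec, remodel_script(n_time = 3,
                                               jitter_amplitude = 0))
  expect_identical(ser$volumes[[1]]$data, ser$volumes[[2]]$data)
  expect_identical(ser$volumes[[2]]$data, ser$volumes[[3]]$data)
})

test_that("invalid morph targets fail naming the spine and time", {
  spec <- phantom_spec(field_of_view = c(8, 6, 6), seed = 3,
                       spines = list(spine_spec(4, 0, 1.5, 0.6, 0.2)))
  script <- remodel_script(n_time = 3,
                           events = list(ev_morph(1, 1, -2, 0.6, 0.2)))
  expect_error(rasterize_series(spec, script), "spine 1 at t = 1")
})

test_that("events outside the series and unknown ids are rejected", {
  expect_error(remodel_script(n_time = 5, events = list(ev_prune(1, 7))),
               "outside the series")
  spec <- phantom_spec(field_of_view = c(8, 6, 6), seed = 3,
                       spines = list(spine_spec(4, 0, 1.5, 0.6, 0.2)))
  expect_error(rasterize_series(spec, remodel_script(
    n_time = 3, events = list(ev_prune(4, 1)))), "unknown spine")
})

test_that("phantom configs round-trip through YAML", {
  spec <- phantom_spec(field_of_view = c(10, 7, 7), seed = 21,
                       spines = list(spine_spec(5, 0.4, 1.5, 0.6, 0.2)),
                       noise = list(type = "gaussian", sd = 5))
  script <- remodel_script(n_time = 5, events = list(ev_prune(1, 2)),
                           jitter_amplitude = 0.05)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_config(spec, path, script)
  back <- read_phantom_config(path)
  expect_equal(back$spec$field_of_view, spec$field_of_view)
  expect_equal(back$spec$spines[[1]]$length, 1.5)
  expect_equal(back$spec$noise$sd, 5)
  expect_equal(back$script$n_time, 5)
  expect_equal(back$script$events[[1]]$type, "prune")
  # and the round-tripped spec renders identically
  expect_identical(rasterize(back$spec)$volume$data,
                   rasterize(spec)$volume$data)
})
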