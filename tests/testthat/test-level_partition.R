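phantom_default <- build_phantom(phantom_spec(noise_sigma = 0), seed = 1)

test_that("fitted clipping planes match the phantom's true disc planes", {
  planes <- fit_clipping_planes(phantom_default$labels)
  truth <- phantom_default$truth$planes
  expect_identical(names(planes),
                   c("above_L3", "L3_L4", "L4_L5", "L5_S1", "below_S1"))
  for (nm in names(planes)) {
    offset <- abs(plane_signed_distance(truth[[nm]],
                                        matrix(planes[[nm]]$point, 1)))
    expect_lt(offset, 1, label = paste(nm, "offset (mm)"))
    angle <- acos(min(1, sum(planes[[nm]]$normal * truth[[nm]]$normal))) *
      180 / pi
    expect_lt(angle, 2, label = paste(nm, "angle (deg)"))
  }
})

test_that("coaxial stacked bodies give plane normals along the common axis", {
  # the default phantom's vertebrae share one vertical axis
  planes <- fit_clipping_planes(phantom_default$labels)
  for (p in planes)
    expect_gt(p$normal[3], cos(0.5 * pi / 180))  # within 0.5 degrees of z
})

test_that("missing or degenerate vertebral labels are rejected", {
  lv <- phantom_default$labels
  lv$grid[lv$grid == 2L] <- 0L  # drop L4
  expect_error(fit_clipping_planes(lv), "missing label: L4")
})

test_that("horizontal equidistant planes cut a straight tube into equal segments", {
  tube <- make_tube_labels(r = 8, center = c(20.3, 20.3),
                           dims = c(40L, 40L, 130L))
  zs <- c(125, 95, 65, 35, 5)
  planes <- lapply(zs, function(z) clip_plane(c(20.3, 20.3, z), c(0, 0, 1)))
  names(planes) <- c("above_L3", "L3_L4", "L4_L5", "L5_S1", "below_S1")
  part <- partition_dural_sac(tube, planes)
  vols <- vapply(part$levels, length, 0L) / 1000
  layer <- pi * 64 / 1000  # one voxel layer of the cross-section
  expect_true(all(abs(vols - pi * 64 * 30 / 1000) <= layer))
  # conservation: exact integer cover of the in-range dural voxels
  idx <- which(tube$grid == 10L)
  co <- duravol:::.voxel_coords(idx, dim(tube$grid), tube$spacing)
  in_range <- plane_signed_distance(planes[[1]], co) <= 0 &
    plane_signed_distance(planes[[5]], co) > 0
  expect_identical(sum(vapply(part$levels, length, 0L)), sum(in_range))
  expect_identical(sort(unlist(part$levels, use.names = FALSE)),
                   sort(idx[in_range]))
})

test_that("tilted planes reproduce a fine-grid oracle within 2%", {
  tube <- make_tube_labels(r = 8, center = c(20.3, 20.3),
                           dims = c(40L, 40L, 130L))
  th <- 10 * pi / 180
  n_tilt <- c(sin(th), 0, cos(th))
  zs <- c(125, 95, 65, 35, 5)
  planes <- lapply(zs, function(z) clip_plane(c(20.3, 20.3, z), n_tilt))
  part <- partition_dural_sac(tube, planes)
  for (i in 1:4) {
    vol <- length(part$levels[[i]]) / 1000
    oracle <- tube_segment_fine_oracle(8, c(20.3, 20.3), xy_max = 40,
                                       z_max = 130, upper = planes[[i]],
                                       lower = planes[[i + 1]], h = 0.25)
    expect_equal(vol, oracle, tolerance = 0.02,
                 label = paste("segment", i, "volume"))
  }
})

test_that("partition validates plane order and dural intersection", {
  tube <- make_tube_labels(dims = c(40L, 40L, 130L))
  mk <- function(z) clip_plane(c(20.3, 20.3, z), c(0, 0, 1))
  expect_error(partition_dural_sac(tube, lapply(c(95, 125, 65, 35, 5), mk)),
               "unordered")
  # planes entirely above the tube: no dural voxel falls in any level
  expect_error(partition_dural_sac(tube, lapply(c(230, 225, 220, 215, 210), mk)),
               "not intersecting")
})

test_that("segments are disjoint and cover the in-range voxels on the default phantom", {
  planes <- fit_clipping_planes(phantom_default$labels)
  part <- partition_dural_sac(phantom_default$labels, planes)
  all_idx <- unlist(part$levels, use.names = FALSE)
  expect_identical(anyDuplicated(all_idx), 0L)
  idx <- which(phantom_default$labels$grid == 10L)
  co <- duravol:::.voxel_coords(idx, dim(phantom_default$labels$grid),
                                phantom_default$labels$spacing)
  in_range <- plane_signed_distance(planes[[1]], co) <= 0 &
    plane_signed_distance(planes[[5]], co) > 0
  expect_identical(sort(all_idx), sort(idx[in_range]))
})

test_that("segment volumes are robust to 0.5 mm boundary noise", {
  truth_planes <- phantom_default$truth$planes
  base_part <- partition_dural_sac(phantom_default$labels, truth_planes)
  base <- vapply(base_part$levels, length, 0L)
  rel <- vapply(1:20, function(s) {
    noisy <- perturb_labels(phantom_default$labels, 0.5, seed = s)
    p <- partition_dural_sac(noisy, truth_planes)
    abs(vapply(p$levels, length, 0L) / base - 1)
  }, numeric(4))
  expect_true(all(rowMeans(rel) < 0.05))
})
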