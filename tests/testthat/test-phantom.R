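test_that("ground truth volumes are closed-form exact for straight geometry", {
  spec <- straight_tube_spec(r = 8, concavity = 0)
  ph <- build_phantom(spec, seed = 1)
  # 30 mm between successive planes, constant radius 8: pi r^2 L
  expect_equal(unname(ph$truth$dural_volume),
               rep(pi * 64 * 30 / 1000, 4), tolerance = 1e-6)
  # plain elliptic cylinder: pi a b h
  v <- spec$vertebrae
  expect_equal(unname(ph$truth$vertebral_volume),
               pi * v$ap_semi * v$lat_semi * v$height / 1000)
  # segment volumes sum to the dural volume between the outer planes
  expect_equal(sum(ph$truth$dural_volume), ph$truth$dural_volume_total,
               tolerance = 1e-9)
})

test_that("ectasia factor 1 leaves the radius profile unchanged and >1 widens caudally", {
  base <- build_phantom(phantom_spec(noise_sigma = 0), seed = 1)
  same <- build_phantom(phantom_spec(noise_sigma = 0, ectasia_factor = 1),
                        seed = 1)
  expect_identical(base$labels$grid, same$labels$grid)
  wide <- build_phantom(phantom_spec(noise_sigma = 0, ectasia_factor = 1.4),
                        seed = 1)
  expect_gt(wide$truth$dural_volume[["S1"]], base$truth$dural_volume[["S1"]])
  expect_equal(wide$truth$dural_volume[["L3"]], base$truth$dural_volume[["L3"]])
})

test_that("rasterized volumes converge to the analytic truth with resolution", {
  # default geometry at 1 mm: every structure within 2% of closed form
  ph1 <- build_phantom(phantom_spec(noise_sigma = 0), seed = 1)
  part1 <- partition_dural_sac(ph1$labels, ph1$truth$planes)
  vox1 <- prod(ph1$labels$spacing) / 1000
  err1 <- abs(vapply(part1$levels, length, 0L) * vox1 -
                ph1$truth$dural_volume) / ph1$truth$dural_volume
  expect_true(all(err1 < 0.02))
  verr1 <- vapply(c("L3", "L4", "L5", "S1"), function(lv)
    abs(label_volume_ml(ph1$labels, ph1$labels$labels[[lv]]) -
          ph1$truth$vertebral_volume[[lv]]) / ph1$truth$vertebral_volume[[lv]],
    0)
  expect_true(all(verr1 < 0.02))
  # same geometry at 0.5 mm: within 0.5%
  ph05 <- build_phantom(phantom_spec(voxel_spacing = 0.5,
                                     grid_shape = c(192L, 192L, 320L),
                                     noise_sigma = 0), seed = 1)
  part05 <- partition_dural_sac(ph05$labels, ph05$truth$planes)
  vox05 <- prod(ph05$labels$spacing) / 1000
  err05 <- abs(vapply(part05$levels, length, 0L) * vox05 -
                 ph05$truth$dural_volume) / ph05$truth$dural_volume
  expect_true(all(err05 < 0.005))
  verr05 <- vapply(c("L3", "L4", "L5", "S1"), function(lv)
    abs(label_volume_ml(ph05$labels, ph05$labels$labels[[lv]]) -
          ph05$truth$vertebral_volume[[lv]]) /
      ph05$truth$vertebral_volume[[lv]], 0)
  expect_true(all(verr05 < 0.005))
})

test_that("phantom construction is deterministic given the seed", {
  a <- build_phantom(phantom_spec(), seed = 5)
  b <- build_phantom(phantom_spec(), seed = 5)
  expect_identical(a$intensity$grid, b$intensity$grid)
  expect_identical(a$labels$grid, b$labels$grid)
  c2 <- build_phantom(phantom_spec(), seed = 6)
  expect_false(identical(a$intensity$grid, c2$intensity$grid))
})

test_that("invalid geometry is rejected", {
  v <- phantom_spec()$vertebrae
  v$center_y <- 40  # push the bodies into the dural tube
  expect_error(build_phantom(phantom_spec(vertebrae = v), seed = 1),
               "overlaps")
  v2 <- phantom_spec()$vertebrae
  v2$center_z[1] <- 155  # L3 pokes out of the grid
  expect_error(build_phantom(phantom_spec(vertebrae = v2), seed = 1),
               "exceeds grid")
  expect_error(phantom_spec(ectasia_factor = 0.5))
})

test_that("boundary perturbation is identity at zero noise and volume-stable at 0.5 mm", {
  tube <- make_tube_labels(r = 8, dims = c(40L, 40L, 60L))
  expect_identical(perturb_labels(tube, 0, seed = 1)$grid, tube$grid)
  v0 <- sum(tube$grid == 10L) / 1000
  rel <- vapply(1:20, function(s) {
    vp <- sum(perturb_labels(tube, 0.5, seed = s)$grid == 10L) / 1000
    abs(vp - v0) / v0
  }, 0)
  expect_lt(mean(rel), 0.05)
})

test_that("volume error grows monotonically with boundary noise", {
  tube <- make_tube_labels(r = 8, dims = c(40L, 40L, 60L))
  v0 <- sum(tube$grid == 10L)
  mae <- vapply(c(0, 0.5, 1.0), function(noise) {
    if (noise == 0) return(0)
    mean(vapply(1:10, function(s)
      abs(sum(perturb_labels(tube, noise, seed = s)$grid == 10L) - v0), 0))
  }, 0)
  expect_true(all(diff(mae) >= 0))
})

test_that("perturbed labels remain mutually exclusive and deterministic", {
  ph <- build_phantom(phantom_spec(noise_sigma = 0), seed = 1)
  a <- perturb_labels(ph$labels, 0.8, seed = 9)
  b <- perturb_labels(ph$labels, 0.8, seed = 9)
  expect_identical(a$grid, b$grid)
  expect_true(all(a$grid %in% c(0L, 1L, 2L, 3L, 4L, 10L)))
})

test_that("threshold segmentation recovers the phantom structures", {
  ph <- build_phantom(phantom_spec(noise_sigma = 0), seed = 1)
  seg <- simple_segment(ph$intensity)
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  for (id in c(1L, 2L, 3L, 4L, 10L))
    expect_gte(dice(seg$grid == id, ph$labels$grid == id), 0.95)
  # all-zero image has no component to segment
  zero <- intensity_volume(array(0, c(10, 10, 10)))
  expect_error(simple_segment(zero), "empty component")
  # thresholds covering everything give one component = full foreground
  all_in <- simple_segment(ph$intensity,
                           thresholds = list(dural_sac = c(0, Inf)))
  expect_true(all(all_in$grid == 10L))
  expect_error(simple_segment(ph$intensity,
                              thresholds = list(dural_sac = c(5, 2))),
               "ordered")
})
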