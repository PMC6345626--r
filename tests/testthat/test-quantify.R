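test_that("defect delineation matches the analytic cylinder volume", {
  dims <- c(170, 170, 170)
  m <- delineate_defect(dims, origin = c(-8.5, -8.5, -8.5),
                        voxel_size = 0.1)
  analytic <- pi * 7.5^2 * 15 / 0.1^3
  expect_lt(abs(sum(m) - analytic) / analytic, 0.01)
  expect_error(delineate_defect(dims, origin = c(-8.5, -8.5, -8.5),
                                voxel_size = 0.1, depth = 0), "geometry")
  expect_error(delineate_defect(c(50, 50, 50), origin = c(0, 0, 0),
                                voxel_size = 0.1), "geometry")
})

test_that("otsu threshold separates a clean bimodal sample", {
  set.seed(1)
  v <- c(rnorm(5000, 0.2, 0.02), rnorm(5000, 0.6, 0.02))
  thr <- otsu_threshold(v)
  expect_gt(thr, 0.3); expect_lt(thr, 0.5)
  expect_error(otsu_threshold(rep(1, 10)), "degenerate")
})

test_that("scaffold segmentation dilates and guards against implausible masks", {
  vol <- array(0.2, c(20, 20, 20))
  vol[10, 10, 10] <- 1.0
  m <- segment_scaffold_titanium(vol)
  expect_true(m[10, 10, 10])
  ## 3x3x3 kernel: 27 voxels after dilation
  expect_equal(sum(m), 27)
  expect_gt(sum(m), sum(vol >= 0.72))
  ## empty volume gives an empty mask
  expect_equal(sum(segment_scaffold_titanium(array(0.2, c(5, 5, 5)))), 0)
  ## a flood of metal inside the defect is rejected
  defect <- array(TRUE, c(20, 20, 20))
  expect_error(segment_scaffold_titanium(array(1, c(20, 20, 20)),
                                         defect = defect), "implausible")
})

test_that("global bone threshold is monotone and empty on background", {
  vol <- array(0.2, c(20, 20, 20))
  defect <- array(TRUE, c(20, 20, 20))
  m <- segment_bone_global(vol, defect, threshold = 0.385)
  expect_equal(sum(m), 0)
  vol[5:8, 5:8, 5:8] <- 0.6
  m1 <- segment_bone_global(vol, defect, threshold = 0.385)
  m2 <- segment_bone_global(vol, defect, threshold = 0.5)
  expect_true(all(m2[m1 == FALSE] == FALSE))
  expect_lte(sum(m2), sum(m1))
  expect_equal(sum(m1), 64)
})

test_that("slice interpolation fills unprocessed slices", {
  vol <- array(0.2, c(40, 40, 11))
  vol[15:25, 15:25, ] <- 0.6   # a bone column spanning all slices
  defect <- array(TRUE, dim(vol))
  scaf <- array(FALSE, dim(vol))
  m <- segment_bone_local_interpolated(vol, defect, scaf)
  even <- seq(2, 10, by = 2)
  expect_true(all(vapply(even, function(z) sum(m[, , z]) > 0, TRUE)))
  ## scaffold exclusion is absolute
  scaf[15:25, 15:25, ] <- TRUE
  m2 <- segment_bone_local_interpolated(vol, defect, scaf)
  expect_equal(sum(m2 & scaf), 0)
  expect_error(segment_bone_local_interpolated(vol[, , 1:2, drop = FALSE],
                                               defect[, , 1:2],
                                               scaf[, , 1:2]),
               "interpolation error")
})

test_that("ingrowth fraction arithmetic and guards", {
  bone <- array(FALSE, c(40, 40, 20)); defect <- array(FALSE, dim(bone))
  defect[1:25, 1:40, 1:20] <- TRUE  # 20000 defect voxels
  bone[sample(which(defect), 1000)] <- TRUE
  r <- ingrowth_fraction(bone, defect, 0.5)
  expect_equal(r$fraction, 10.0)
  expect_equal(ingrowth_fraction(array(FALSE, dim(bone)), defect,
                                 0.5)$fraction, 0)
  expect_error(ingrowth_fraction(bone, array(FALSE, dim(bone)), 0.5),
               "division error")
  expect_error(ingrowth_fraction(bone, defect, 0), "porosity")
})

test_that("virtual sections come at the five depths with 3 mm spacing", {
  sub <- memo("coarse_PC2", phantom_substrate("PC", voxel_size = 0.2))
  ph <- build_phantom(sub, 12, seed = 5)
  secs <- virtual_sections(ph)
  expect_length(secs, 5)
  expect_equal(vapply(secs, function(s) s$depth_mm, numeric(1)),
               c(2, 5, 8, 11, 14))
  ## geometric orientation: depth measured from the periosteal (top) face
  ## so a 2 mm and a 13 mm section differ
  s2 <- secs[[1]]; s14 <- secs[[5]]
  expect_false(identical(s2$bone, s14$bone))
})
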