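## Phantom generator contracts at a coarse desk voxel (0.2 mm) so each
## build stays fast; end-to-end recovery at the working 0.1 mm scale is
## exercised in test-recovery.R.

coarse_sub <- function(acr) {
  memo(paste0("coarse_", acr), phantom_substrate(acr, voxel_size = 0.2))
}

test_that("zero latent ingrowth gives an empty truth bone mask", {
  ph <- build_phantom(coarse_sub("PC"), 0, peripheral_pp = 0, seed = 1)
  expect_equal(sum(ph$bone), 0)
})

test_that("truth bone count honours the construction contract", {
  for (lt in c(6.8, 15)) {
    ph <- build_phantom(coarse_sub("PC"), lt, peripheral_pp = 6.8, seed = 2)
    got <- 100 * ph$truth$n_bone / (ph$truth$n_defect * ph$porosity)
    expect_lt(abs(got - lt), 0.2)
    ## conservation: peripheral + central = total, exactly
    expect_equal(ph$truth$n_peripheral + ph$truth$n_central,
                 ph$truth$n_bone)
  }
})

test_that("phantom gray ordering holds and bone avoids the scaffold", {
  ph <- build_phantom(coarse_sub("PC"), 15, seed = 3,
                      blur_sd_vox = 0, noise_frac = 0)
  expect_equal(sum(ph$bone & ph$scaffold), 0)
  g <- osteoscaffold:::phantom_gray()
  marrow <- !ph$scaffold & !ph$bone & ph$defect
  expect_lt(max(ph$vol[marrow]), g$polyamide + 1e-9)
  expect_true(all(ph$vol[ph$bone] > g$polyamide))
  ti <- build_phantom(coarse_sub("TC"), 6.8, seed = 3,
                      blur_sd_vox = 0, noise_frac = 0)
  expect_true(all(ti$vol[ti$scaffold] >= g$titanium - 1e-9))
  expect_true(all(ti$vol[ti$bone] >= g$bone - 1e-9))
  expect_gt(min(ti$vol[ti$scaffold]), max(ti$vol[ti$bone]))
})

test_that("titanium halo hugs the scaffold and is not truth bone", {
  sub <- coarse_sub("TC")
  ph <- build_phantom(sub, 6.8, seed = 4, blur_sd_vox = 0, noise_frac = 0)
  expect_gt(sum(ph$halo), 0)
  expect_equal(sum(ph$halo & ph$bone), 0)
  ## halo voxels sit within 3 voxels of the scaffold surface
  expect_true(all(sub$dist[ph$halo] <= 3 * sub$voxel_size + 1e-9))
})

test_that("phantoms reproduce bit-identically under a fixed seed", {
  a <- build_phantom(coarse_sub("PB"), 12, seed = 9)
  b <- build_phantom(coarse_sub("PB"), 12, seed = 9)
  expect_identical(a$vol, b$vol)
  expect_identical(a$bone, b$bone)
  expect_false(identical(a$vol,
                         build_phantom(coarse_sub("PB"), 12, seed = 10)$vol))
})

test_that("latent totals beyond the eligible pore space raise capacity errors", {
  expect_error(build_phantom(coarse_sub("TB"), 60, peripheral_pp = 0,
                             seed = 1), "capacity error")
  expect_error(build_phantom(coarse_sub("PB"), 70, seed = 1), "latent")
})

test_that("fluorescence sections encode the band offset and interior activity", {
  fs <- render_fluor_section(7.5, 35, seed = 1)
  expect_equal(fs$band_offset_truth, 35)
  expect_equal(fs$interval, 14)
  expect_error(render_fluor_section(7.5, 300, seed = 1), "band_offset")
  ## zero central activity leaves the interior at background level
  f0 <- render_fluor_section(7.5, 35, seed = 2, central_activity = 0)
  interior <- f0$image[1:30, ]
  expect_lt(mean(interior), 0.1)
  f1 <- render_fluor_section(7.5, 35, seed = 2, central_activity = 1)
  expect_gt(mean(f1$image[1:30, ]), mean(interior))
})
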