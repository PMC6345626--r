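## End-to-end recovery at the working scale (100 um): phantom -> the
## material-appropriate segmentation path -> ingrowth fraction.

test_that("the pipeline recovers the latent ingrowth of every design", {
  cases <- list(TC = 6.8, PB = 20.8, PC = 13.5, TB = 10.9)
  tol <- c(TC = 0.5, PB = 0.5, PC = 0.5, TB = 0.8)
  for (acr in names(cases)) {
    ph <- build_phantom(substrate(acr), cases[[acr]], peripheral_pp = 6.8,
                        seed = 11)
    got <- quantify_phantom(ph)$fraction
    expect_lt(abs(got - cases[[acr]]), tol[[acr]],
              label = sprintf("%s recovery error %.2f", acr,
                              got - cases[[acr]]))
  }
})

test_that("noiseless unblurred phantoms are recovered almost exactly", {
  ph <- build_phantom(substrate("PB"), 15, seed = 12, blur_sd_vox = 0,
                      noise_frac = 0)
  expect_lt(abs(quantify_phantom(ph)$fraction - 15), 0.2)
  ti <- build_phantom(substrate("TC"), 6.8, seed = 12, blur_sd_vox = 0,
                      noise_frac = 0)
  expect_lt(abs(quantify_phantom(ti)$fraction - 6.8), 0.5)
})

test_that("global-threshold bone segmentation overlaps truth (Dice >= 0.9)", {
  ph <- build_phantom(substrate("PC"), 13.5, seed = 13)
  m <- segment_bone_global(ph)
  dice <- 2 * sum(m & ph$bone) / (sum(m) + sum(ph$bone))
  expect_gte(dice, 0.9)
})

test_that("the local path excludes the halo that breaks a naive threshold", {
  ph <- build_phantom(substrate("TC"), 6.8, seed = 14)
  defect <- delineate_defect(ph)
  local <- segment_bone_local_interpolated(ph, defect = defect)
  ## at least 95% of halo voxels stay out of the bone label
  expect_lt(sum(local & ph$halo) / sum(ph$halo), 0.05)
  ## the naive global path (no scaffold exclusion, absolute threshold)
  ## grossly overestimates by counting halo and metal as bone
  naive <- segment_bone_global(ph, defect)
  f_naive <- ingrowth_fraction(naive, defect, ph$porosity)$fraction
  f_local <- ingrowth_fraction(local, defect, ph$porosity)$fraction
  expect_gt(f_naive, f_local + 5)
})

test_that("recovered fraction is invariant to axis-aligned 90-degree rotation", {
  ph <- build_phantom(substrate("PC"), 13.5, seed = 15)
  defect <- delineate_defect(ph)
  m <- segment_bone_global(ph, defect)
  f0 <- ingrowth_fraction(m, defect, ph$porosity)$fraction
  rot <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , ]
  f1 <- ingrowth_fraction(rot(m), rot(defect), ph$porosity)$fraction
  expect_equal(f1, f0, tolerance = 1e-12)
})

test_that("adding truth bone never decreases the recovered fraction", {
  s <- substrate("PC")
  ph_lo <- build_phantom(s, 8, peripheral_pp = 6.8, seed = 16)
  ph_hi <- build_phantom(s, 16, peripheral_pp = 6.8, seed = 16)
  expect_gt(quantify_phantom(ph_hi)$fraction,
            quantify_phantom(ph_lo)$fraction)
})

test_that("interior scores rank the compliant design above the stiff one", {
  ## strong responder: PC carries the central gain, TC only the rim
  ph_pc <- build_phantom(substrate("PC"), 20.8, peripheral_pp = 6.8,
                         seed = 17)
  ph_tc <- build_phantom(substrate("TC"), 6.8, peripheral_pp = 6.8,
                         seed = 17)
  sc_pc <- score_sections(virtual_sections(ph_pc), "PC")
  sc_tc <- score_sections(virtual_sections(ph_tc), "TC")
  expect_true(all(sc_pc$interior >= sc_tc$interior))
  expect_gt(mean(sc_pc$interior), mean(sc_tc$interior))
})
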