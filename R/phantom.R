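## Synthetic micro-CT phantoms of the scaffold-bearing metaphyseal defect.
##
## Gray-level model (arbitrary units on [0, ~1.5]): marrow background
## 0.20 < polyamide 0.25 (same radiographic density as soft tissue)
## < bone 0.60 < titanium 1.00. Titanium adds a structureless
## beam-hardening halo to surrounding voxels, decaying over 3 voxels.
## Partial volume is emulated by a Gaussian blur of 1 voxel, then
## additive Gaussian noise with sigma = 5 percent of the bone-marrow
## contrast.
phantom_gray <- function() {
  list(marrow = 0.20, polyamide = 0.25, bone = 0.60, titanium = 1.00,
       halo_amp = 0.45, halo_decay_vox = 1.2, halo_cutoff_vox = 3,
       blur_sd_vox = 1, noise_frac = 0.05)
}

#' Voxel substrate of a design's defect phantom
#'
#' Precomputes everything about a design that is shared by all phantoms
#' of that design at a given voxel size: the scaffold lattice press-fit
#' into the 15 x 15 mm defect cylinder, its voxel mask and near-surface
#' distance field, the defect mask, and deposition orderings for the
#' peripheral (outermost pore tier, filled from the defect wall inward)
#' and central (interior) bone components. For titanium designs all
#' eligible bone voxels are kept at least 2 voxels clear of the metal
#' surface, reflecting the fibrous separation of woven bone from metal
#' struts; for polyamide the central ordering climbs outward from the
#' strut surfaces (apposition onto the scaffold).
#'
#' @param design a [scaffold_design()] or acronym.
#' @param voxel_size voxel edge, mm (default 0.1; >= 0.027).
#' @param seed stochastic-generator seed for the lattice.
#' @param margin world margin around the defect, mm.
#' @param tier_width outermost pore tier (peripheral band) width, mm.
#' @return an object of class `phantom_substrate`.
#' @export
phantom_substrate <- function(design, voxel_size = 0.1, seed = 1L,
                              margin = 1, tier_width = 1.5) {
  if (is.character(design)) design <- scaffold_design(design)
  if (voxel_size < 0.027) stop("voxel_size below the scanner range")
  h <- voxel_size
  Rdef <- 7.5; Hdef <- 15
  r <- solve_radius_for_porosity(design, voxel_size = max(h, 0.1),
                                 seed = seed)
  base <- attr(r, "lattice")
  scaf <- trim_to_cylinder(base, 2 * Rdef, Hdef, center = c(0, 0, 0))
  half <- Rdef + margin
  bbox <- rbind(c(-half, -half, -half), c(half, half, half))
  vx <- voxelize_lattice(scaf, h, bbox = bbox, near_field = 5 * h)
  dims <- vx$dims
  defect <- cylinder_mask(dims, vx$origin, h, c(0, 0, 0), Rdef,
                          -Hdef / 2, Hdef / 2)
  pore <- defect & !vx$mask
  xs <- vx$origin[1] + (seq_len(dims[1]) - 0.5) * h
  ys <- vx$origin[2] + (seq_len(dims[2]) - 0.5) * h
  rho2d <- sqrt(outer(xs^2, ys^2, "+"))
  rho <- array(rep(as.vector(rho2d), dims[3]), dims)
  surf <- vx$dist
  titanium <- design$material$name == "titanium"
  ## fibrous separation of woven bone from metal: a fixed 0.2 mm
  ## stand-off (>= 2 voxels at the working 100 um scale)
  clear <- if (titanium)
    (surf >= 0.2 - 1e-12 | !is.finite(surf)) else TRUE
  periph_idx <- which(pore & rho >= Rdef - tier_width & clear)
  centr_idx <- which(pore & rho < Rdef - tier_width & clear)
  dist_vox <- surf / h
  dist_vox[!is.finite(dist_vox)] <- 10
  structure(list(design = design, voxel_size = h, origin = vx$origin,
                 dims = dims, radius = as.numeric(r),
                 porosity = design$nominal_porosity,
                 porosity_measured = attr(r, "porosity"),
                 lattice = scaf, scaffold = vx$mask, dist = surf,
                 defect = defect, pore = pore, rho = rho,
                 tier_width = tier_width, titanium = titanium,
                 periph_idx = periph_idx,
                 periph_depth_vox = (Rdef - rho[periph_idx]) / h,
                 centr_idx = centr_idx,
                 centr_dist_vox = dist_vox[centr_idx]),
            class = "phantom_substrate")
}

## Smooth random field in [0 mean, unit sd] over the volume, generated
## on a coarse grid (downsample factor ds) and replicated back up; the
## correlation length is scale_vox. Draws from the current RNG stream.
smooth_field <- function(dims, scale_vox, ds = 4L) {
  cd <- pmax(2L, as.integer(ceiling(dims / ds)))
  f <- array(runif(prod(cd)), cd)
  f <- blur3d(f, max(0.5, scale_vox / ds), dims = cd)
  f <- (f - mean(f)) / max(sd(f), 1e-12)
  ix <- pmin(cd[1], 1L + (seq_len(dims[1]) - 1L) %/% ds)
  iy <- pmin(cd[2], 1L + (seq_len(dims[2]) - 1L) %/% ds)
  iz <- pmin(cd[3], 1L + (seq_len(dims[3]) - 1L) %/% ds)
  f[ix, iy, iz]
}

#' @export
print.phantom_substrate <- function(x, ...) {
  cat(sprintf(
    "<phantom_substrate> %s at %g um voxels, dims %s, defect %d voxels\n",
    x$design$acronym, x$voxel_size * 1000, paste(x$dims, collapse = "x"),
    sum(x$defect)))
  invisible(x)
}

gaussian_kernel <- function(sd, radius = max(1L, ceiling(3 * sd))) {
  k <- exp(-((-radius):radius)^2 / (2 * sd^2))
  k / sum(k)
}

## Separable 3D Gaussian blur (replicate boundaries), compiled kernel.
blur3d <- function(vol, sd_vox, dims = dim(vol)) {
  k <- gaussian_kernel(sd_vox)
  v <- as.numeric(vol)
  for (ax in 1:3) v <- cpp_conv_axis(v, dims, k, ax)
  array(v, dims)
}

#' Build a micro-CT phantom of one implanted scaffold
#'
#' Deposits the latent bone truth into the pore space of the substrate
#' and renders the gray-level volume. The peripheral (injury-driven)
#' component fills the outermost pore tier from the defect wall inward
#' and engulfs the outer struts; the central (strain-driven) component
#' is deposited on interior strut surfaces for polyamide scaffolds
#' (lamellar apposition proxy) or as free-floating reticulate elements
#' away from the struts for titanium scaffolds (woven-bone proxy).
#' Titanium struts cast an additive beam-hardening halo decaying over 3
#' voxels. The volume is then blurred (partial volume) and Gaussian
#' noise is added.
#'
#' @param substrate a [phantom_substrate()].
#' @param latent_total_pp total latent ingrowth, percent of pore volume
#'   (0 to 60).
#' @param peripheral_pp injury-driven component, percent of pore volume.
#' @param seed integer seed (noise and deposit patch fields).
#' @param blur_sd_vox override the partial-volume blur sigma (voxels);
#'   0 disables the blur.
#' @param noise_frac override the noise level (fraction of bone-marrow
#'   contrast); 0 gives a noiseless phantom.
#' @return an object of class `uct_phantom` with `vol`, truth masks
#'   (`bone`, `scaffold`, `defect`, `halo`), truth counts and
#'   acquisition parameters.
#' @export
build_phantom <- function(substrate, latent_total_pp, peripheral_pp = 6.8,
                          seed = 1L, blur_sd_vox = NULL,
                          noise_frac = NULL) {
  s <- substrate
  if (latent_total_pp < 0 || latent_total_pp > 60)
    stop("latent_total_pp must be in [0, 60]")
  g <- phantom_gray()
  if (!is.null(blur_sd_vox)) g$blur_sd_vox <- blur_sd_vox
  if (!is.null(noise_frac)) g$noise_frac <- noise_frac
  h <- s$voxel_size
  n_def <- sum(s$defect)
  quota_total <- round(latent_total_pp / 100 * s$porosity * n_def)
  quota_p <- min(quota_total,
                 round(min(peripheral_pp, latent_total_pp) / 100 *
                         s$porosity * n_def))
  quota_c <- quota_total - quota_p
  if (quota_p > length(s$periph_idx))
    stop("capacity error: peripheral quota exceeds outer-tier pore volume")
  with_seed(child_seed(seed, "phantom"), {
    ## peripheral rim: patchy arcs at the defect wall, filled from the
    ## wall inward, deeper where the (seeded) patch field is high - the
    ## deposits stay several voxels thick so partial volume does not
    ## dissolve them, as a uniform film of the same total volume would
    pf <- smooth_field(s$dims, 12)
    score_p <- 8 * pf[s$periph_idx] - s$periph_depth_vox
    bone_idx <- s$periph_idx[order(score_p,
                                   decreasing = TRUE)[seq_len(quota_p)]]
    if (quota_c > 0) {
      if (quota_c > length(s$centr_idx))
        stop("capacity error: central quota exceeds interior pore volume")
      if (s$titanium) {
        ## free-floating woven-bone islands away from the struts:
        ## compact balls around random interior pore centres, filled
        ## nearest-centre-first until the quota is met (patches of
        ## embryonic woven bone unattached to the metal)
        ctr <- arrayInd(s$centr_idx, s$dims)
        navail <- length(s$centr_idx)
        ball_r <- 5
        n_balls <- max(1L, ceiling(quota_c / (2.5 * ball_r^3)))
        picks <- sample(navail, min(navail, 4L * n_balls))
        score_c <- rep(-Inf, navail)
        covered <- 0L
        for (pc in picks) {
          if (covered >= 1.2 * quota_c) break
          dx <- ctr[, 1] - ctr[pc, 1]
          dy <- ctr[, 2] - ctr[pc, 2]
          dz <- ctr[, 3] - ctr[pc, 3]
          d2 <- dx * dx + dy * dy + dz * dz
          inb <- d2 <= ball_r^2
          covered <- covered + sum(inb & !is.finite(score_c))
          score_c[inb] <- pmax(score_c[inb], ball_r^2 - d2[inb])
        }
        score_c[!is.finite(score_c)] <-
          -1e9 - s$centr_dist_vox[!is.finite(score_c)]
      } else {
        ## semilunar deposits climbing outward from the strut surfaces
        ## in the active pores
        cf <- smooth_field(s$dims, 10)
        score_c <- 9 * cf[s$centr_idx] - s$centr_dist_vox
      }
      ord <- s$centr_idx[order(score_c, decreasing = TRUE)[seq_len(quota_c)]]
      bone_idx <- c(bone_idx, ord)
    }
    bone <- array(FALSE, s$dims)
    bone[bone_idx] <- TRUE
    vol <- array(g$marrow, s$dims)
    halo <- NULL
    if (s$titanium) {
      vol[s$scaffold] <- g$titanium
      dv <- s$dist / h
      halo_reg <- which(!s$scaffold & is.finite(dv) &
                          dv <= g$halo_cutoff_vox)
      vol[halo_reg] <- vol[halo_reg] +
        g$halo_amp * exp(-pmax(0, dv[halo_reg]) / g$halo_decay_vox)
      halo <- array(FALSE, s$dims)
      halo[halo_reg] <- TRUE
      halo <- halo & !bone
    } else {
      vol[s$scaffold] <- g$polyamide
    }
    vol[bone] <- vol[bone] + (g$bone - g$marrow)
    if (g$blur_sd_vox > 0) vol <- blur3d(vol, g$blur_sd_vox)
    sigma <- g$noise_frac * (g$bone - g$marrow)
    if (sigma > 0)
      vol <- vol + array(rnorm(prod(s$dims), 0, sigma), s$dims)
    structure(list(vol = vol, bone = bone, scaffold = s$scaffold,
                   defect = s$defect, halo = halo,
                   origin = s$origin, voxel_size = h, dims = s$dims,
                   design = s$design$acronym,
                   porosity = s$porosity,
                   titanium = s$titanium,
                   truth = list(latent_total_pp = latent_total_pp,
                                peripheral_pp = min(peripheral_pp,
                                                    latent_total_pp),
                                n_bone = length(bone_idx),
                                n_peripheral = quota_p,
                                n_central = quota_c,
                                n_defect = n_def)),
              class = "uct_phantom")
  })
}

#' @export
print.uct_phantom <- function(x, ...) {
  cat(sprintf(
    "<uct_phantom> %s, %s um voxels, latent %.1f pp (%d bone voxels)\n",
    x$design, format(x$voxel_size * 1000), x$truth$latent_total_pp,
    x$truth$n_bone))
  invisible(x)
}

#' Render a fluorescence section of the bone-implant interface
#'
#' A polar-unwrapped patch of the peripheral rim at a given defect
#' depth: columns are angular positions along the defect outline, rows
#' run radially from the scaffold interior (top) into the host bone
#' (bottom). The nascent bone front carries elevated fluorochrome
#' uptake; a bright mineral-bound label band sits `band_offset` microns
#' behind the front (the bone deposited since label administration,
#' 14 days before endpoint). Interior fluorescence is scaled by the
#' central osteogenic activity.
#'
#' @param depth section depth from the periosteal surface, mm.
#' @param band_offset label-band offset from the current bone front,
#'   micrometers (0 to 200).
#' @param seed integer seed (front wobble and noise).
#' @param central_activity central component in [0, 1]; 0 leaves the
#'   interior at background level.
#' @param pixel_um pixel size, micrometers.
#' @param nx,ny image size (angular x radial).
#' @return object of class `fluor_section` with fields `image` (ny x nx
#'   matrix, rows radial), `band_offset_truth`, `interval` (14 days),
#'   `pixel_um`, `depth_mm`.
#' @export
render_fluor_section <- function(depth, band_offset, seed = 1L,
                                 central_activity = 0, pixel_um = 5,
                                 nx = 256, ny = 200) {
  if (band_offset < 0 || band_offset > 200)
    stop("band_offset must be in [0, 200] um")
  with_seed(child_seed(seed, "fluor"), {
    img <- matrix(0.05, ny, nx)
    front0 <- 60
    wob <- round(stats::filter(rnorm(nx + 20, 0, 2), rep(1 / 7, 7),
                               sides = 2))
    wob <- wob[11:(nx + 10)]
    wob[is.na(wob)] <- 0
    fronts <- pmax(10L, pmin(ny - 50L, front0 + as.integer(wob)))
    off_px <- band_offset / pixel_um
    for (j in seq_len(nx)) {
      f <- fronts[j]
      img[f:ny, j] <- 0.35                        # nascent peripheral bone
      b0 <- f + off_px
      rows <- which(abs(seq_len(ny) - b0) <= 1.5) # label band, ~3 px wide
      rows <- rows[rows >= f]
      img[rows, j] <- 1.0
    }
    if (central_activity > 0) {
      ## interior label binds in scattered woven-bone islands, not as a
      ## uniform glow: bright specks above the front
      nspeck <- round(central_activity * 0.02 * nx * ny)
      for (k in seq_len(nspeck)) {
        jx <- sample.int(nx, 1)
        iy <- sample.int(max(1L, fronts[jx] - 8L), 1)
        rows <- max(1, iy - 1L):min(ny, iy + 1L)
        cols <- max(1, jx - 1L):min(nx, jx + 1L)
        img[rows, cols] <- 0.9
      }
    }
    img <- img + matrix(rnorm(nx * ny, 0, 0.02), ny, nx)
    structure(list(image = img, band_offset_truth = band_offset,
                   interval = 14, pixel_um = pixel_um, depth_mm = depth,
                   front_truth = fronts),
              class = "fluor_section")
  })
}
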