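## Micro-CT quantification: defect delineation, the two segmentation
## paths (global threshold for polyamide, local-adaptive with scaffold
## exclusion for titanium), the ingrowth fraction, virtual sectioning.

#' Delineate the defect cylinder
#'
#' Boolean mask of the cylindrical defect (15 mm diameter x 15 mm depth
#' by default) on the volume grid; purely geometric, independent of the
#' gray content.
#'
#' @param dims volume dimensions (3 integers) or a `uct_phantom`.
#' @param origin world coordinate of the grid minimum corner, mm.
#' @param voxel_size voxel edge, mm.
#' @param center cylinder centre, mm (default origin-centred grid).
#' @param diameter,depth cylinder dimensions, mm.
#' @return logical 3D array.
#' @export
delineate_defect <- function(dims, origin = NULL, voxel_size = NULL,
                             center = c(0, 0, 0), diameter = 15,
                             depth = 15) {
  if (inherits(dims, "uct_phantom")) {
    p <- dims
    dims <- p$dims; origin <- p$origin; voxel_size <- p$voxel_size
  }
  if (diameter <= 0 || depth <= 0) stop("geometry error: degenerate cylinder")
  ext <- dims * voxel_size
  if (diameter > ext[1] + 1e-9 || diameter > ext[2] + 1e-9 ||
      depth > ext[3] + 1e-9)
    stop("geometry error: cylinder outside volume bounds")
  cylinder_mask(dims, origin, voxel_size, center, diameter / 2,
                center[3] - depth / 2, center[3] + depth / 2)
}

#' Otsu threshold of a gray-value sample
#'
#' Maximizes the between-class variance over a binned histogram.
#'
#' @param values numeric vector.
#' @param n_bins histogram bins (default 256).
#' @return threshold value.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  rng <- range(values)
  if (diff(rng) <= 0) stop("degenerate histogram")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  hst <- tabulate(findInterval(values, br, rightmost.closed = TRUE),
                  nbins = n_bins)
  w <- hst / sum(hst)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  ## the criterion plateaus across an empty valley between separated
  ## classes: take the plateau midpoint, not an arbitrary edge
  top <- which(sigma_b >= max(sigma_b) * (1 - 1e-9))
  mids[round((min(top) + max(top)) / 2)]
}

## 1-voxel 26-neighbourhood (3x3x3 cube) dilation via shift-union.
dilate3d_cube <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, dx, dy, dz) {
    src_x <- max(1, 1 - dx):min(d[1], d[1] - dx)
    src_y <- max(1, 1 - dy):min(d[2], d[2] - dy)
    src_z <- max(1, 1 - dz):min(d[3], d[3] - dz)
    res <- array(FALSE, d)
    res[src_x + dx, src_y + dy, src_z + dz] <- m[src_x, src_y, src_z]
    res
  }
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out | shift(mask, dx, dy, dz)
  }
  out
}

## 2D 8-neighbourhood dilation (3x3) for slice interpolation.
dilate2d_cube <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    src_x <- max(1, 1 - dx):min(d[1], d[1] - dx)
    src_y <- max(1, 1 - dy):min(d[2], d[2] - dy)
    res <- array(FALSE, d)
    res[src_x + dx, src_y + dy] <- mask[src_x, src_y]
    out <- out | res
  }
  out
}

#' Segment the titanium scaffold
#'
#' Global threshold at the metal gray level followed by a morphological
#' dilation with a 3-voxel (3 x 3 x 3) kernel, so that partial-volume
#' and near-halo voxels hugging the metal are swallowed by the scaffold
#' label rather than leaking into the bone label. The default threshold
#' (0.72) sits between the brightest bone (bone level plus halo tail
#' and noise) and the blurred metal cores: partial volume erodes thin
#' struts toward their centreline, so the threshold must be low enough
#' that the raw label plus one dilation still covers the physical strut
#' surface and its brightest halo shell, yet above anything bone
#' reaches.
#'
#' @param volume 3D gray array or `uct_phantom`.
#' @param metal_threshold gray threshold for metal (default 0.72).
#' @param defect optional defect mask for the plausibility check.
#' @return logical scaffold mask (dilated).
#' @export
segment_scaffold_titanium <- function(volume, metal_threshold = 0.72,
                                      defect = NULL) {
  if (inherits(volume, "uct_phantom")) {
    if (is.null(defect)) defect <- volume$defect
    volume <- volume$vol
  }
  raw <- volume >= metal_threshold
  if (!is.null(defect) && sum(raw & defect) > 0.6 * sum(defect))
    stop("implausible segmentation: metal threshold selects > 60% of defect")
  if (!any(raw)) return(raw)
  dilate3d_cube(raw)
}

#' Segment bone by a global threshold (polyamide path)
#'
#' Single global threshold within the defect mask, the laser-sintered
#' polyamide being radiographically equivalent to soft tissue. The
#' default threshold sits at 45.75 percent of the bone-marrow contrast
#' on the calibrated gray scale (marrow 0.2, bone 0.6, hence 0.383):
#' slightly below the midpoint, offsetting the volume shrinkage that
#' blur-then-threshold inflicts on curved deposit surfaces, so that
#' labelled volume tracks true volume. `threshold = "otsu"` selects
#' Otsu's value on the defect-restricted histogram instead; a numeric
#' value is used as-is.
#'
#' @param volume 3D gray array or `uct_phantom`.
#' @param defect defect mask.
#' @param threshold numeric gray threshold, `NULL` for the calibrated
#'   default, or `"otsu"`.
#' @return logical bone mask, with attribute `threshold`.
#' @export
segment_bone_global <- function(volume, defect = NULL, threshold = NULL) {
  if (inherits(volume, "uct_phantom")) {
    if (is.null(defect)) defect <- volume$defect
    volume <- volume$vol
  }
  vals <- volume[defect]
  if (is.null(threshold)) {
    g <- phantom_gray()
    threshold <- g$marrow + 0.4575 * (g$bone - g$marrow)
  } else if (identical(threshold, "otsu")) {
    threshold <- otsu_threshold(vals)
    rng <- range(vals)
    if (threshold < rng[1] + 0.02 * diff(rng) ||
        threshold > rng[2] - 0.02 * diff(rng))
      warning("thresholding warning: defect histogram may not be bimodal")
  }
  mask <- volume >= threshold & defect
  attr(mask, "threshold") <- threshold
  mask
}

## Mean filter over a (2r+1)^2 window of a 2D slice (replicate edges).
box_mean2d <- function(slice, half_width) {
  d <- dim(slice)
  k <- rep(1 / (2 * half_width + 1), 2 * half_width + 1)
  v <- cpp_conv_axis(as.numeric(slice), c(d[1], d[2], 1L), k, 1L)
  v <- cpp_conv_axis(v, c(d[1], d[2], 1L), k, 2L)
  matrix(v, d[1], d[2])
}

#' Segment bone by local thresholding with slice interpolation
#' (titanium path)
#'
#' On every second axial slice, a voxel is labelled bone when its gray
#' value exceeds the local window mean (window 15 voxels) by `offset`,
#' or exceeds the conservative bone floor `bright` (interiors of thick
#' deposits raise the local mean toward their own level, so the local
#' clause alone would hollow them out); the dilated scaffold mask is
#' excluded. Labels on the unprocessed slices are filled by shape-based
#' interpolation from the two neighbouring labelled slices
#' (intersection plus the union voxels adjacent to it). The local
#' contrast criterion rejects the smooth beam-hardening halo, which a
#' plain global threshold would count as bone.
#'
#' @param volume 3D gray array or `uct_phantom`.
#' @param defect defect mask.
#' @param scaffold_mask dilated scaffold mask to exclude.
#' @param offset local contrast offset (gray units, default 0.15).
#' @param window local window size in voxels (odd, default 15).
#' @param bright absolute gray level above which a non-scaffold voxel
#'   is always bone (default 0.55, above the brightest halo shell).
#' @param grow_low low threshold for the hysteresis growth step: after
#'   the seed clauses, the label grows into 8-connected neighbours
#'   whose gray value stays above this level (default 0.44, just above
#'   the bone-marrow contrast midpoint), recovering the partial-volume
#'   shell of each deposit without admitting the (darker, unseeded)
#'   halo.
#' @param grow_iter growth iterations (default 4).
#' @return logical bone mask.
#' @export
segment_bone_local_interpolated <- function(volume, defect = NULL,
                                            scaffold_mask = NULL,
                                            offset = 0.15, window = 15,
                                            bright = 0.55, grow_low = 0.44,
                                            grow_iter = 4L) {
  if (inherits(volume, "uct_phantom")) {
    ph <- volume
    if (is.null(defect)) defect <- ph$defect
    if (is.null(scaffold_mask)) scaffold_mask <- segment_scaffold_titanium(ph)
    volume <- ph$vol
  }
  d <- dim(volume)
  if (d[3] < 3) stop("interpolation error: fewer than 3 slices")
  hw <- (window - 1L) %/% 2L
  bone <- array(FALSE, d)
  zproc <- seq(1L, d[3], by = 2L)
  any_def <- apply(defect, 3, any)
  for (z in zproc) {
    if (!any_def[z]) next
    sl <- volume[, , z]
    m <- box_mean2d(sl, hw)
    ok <- defect[, , z] & !scaffold_mask[, , z]
    seed <- (sl - m > offset | sl >= bright) & ok
    for (it in seq_len(grow_iter))
      seed <- seed | (dilate2d_cube(seed) & sl >= grow_low & ok)
    bone[, , z] <- seed
  }
  for (z in setdiff(seq_len(d[3]), zproc)) {
    if (!any_def[z]) next
    a <- if (z > 1) bone[, , z - 1] else bone[, , z + 1]
    b <- if (z < d[3]) bone[, , z + 1] else bone[, , z - 1]
    core <- a & b
    interp <- core | ((a | b) & dilate2d_cube(core))
    bone[, , z] <- interp & defect[, , z] & !scaffold_mask[, , z]
  }
  bone
}

#' Bone ingrowth fraction of the pore volume
#'
#' The headline quantity: bone voxel count divided by the product of the
#' defect voxel count and the (design-nominal) scaffold porosity,
#' expressed in percent of the available pore volume.
#'
#' @param bone_mask logical bone mask.
#' @param defect_mask logical defect mask.
#' @param porosity scaffold porosity, fraction of unity in (0, 1].
#' @return object of class `ingrowth_result` with fields bone_voxels,
#'   defect_voxels, porosity_used, fraction (percent).
#' @export
ingrowth_fraction <- function(bone_mask, defect_mask, porosity) {
  if (porosity <= 0 || porosity > 1) stop("porosity must be in (0, 1]")
  nd <- sum(defect_mask)
  if (nd == 0) stop("division error: zero defect volume")
  nb <- sum(bone_mask & defect_mask)
  structure(list(bone_voxels = nb, defect_voxels = nd,
                 porosity_used = porosity,
                 fraction = 100 * nb / (nd * porosity)),
            class = "ingrowth_result")
}

#' @export
print.ingrowth_result <- function(x, ...) {
  cat(sprintf(
    "<ingrowth_result> %.2f%% of pore volume (%d bone / %d defect voxels, porosity %.2f)\n",
    x$fraction, x$bone_voxels, x$defect_voxels, x$porosity_used))
  invisible(x)
}

#' Quantify one phantom end to end
#'
#' Runs the material-appropriate segmentation path (local-adaptive with
#' scaffold exclusion for titanium, global Otsu for polyamide) and
#' returns the ingrowth fraction computed with the design-nominal
#' porosity.
#'
#' @param phantom a `uct_phantom`.
#' @return an `ingrowth_result`.
#' @export
quantify_phantom <- function(phantom) {
  defect <- delineate_defect(phantom)
  bone <- if (phantom$titanium) {
    segment_bone_local_interpolated(phantom, defect = defect)
  } else {
    segment_bone_global(phantom, defect = defect)
  }
  ingrowth_fraction(bone, defect, phantom$porosity)
}

#' Virtual axial sections of a sample
#'
#' Extracts the five axial slices used for semi-quantitative scoring, at
#' 2, 5, 8, 11 and 14 mm depth from the periosteal (top) face of the
#' defect, perpendicular to the implant axis.
#'
#' @param phantom a `uct_phantom` (or list with dims/origin/voxel_size).
#' @param bone_mask segmented bone mask; default re-segments via
#'   [quantify_phantom()] paths.
#' @param depths_mm section depths from the periosteal surface, mm.
#' @return list of `section2d` objects (fields bone, scaffold, defect,
#'   depth_mm, voxel_size, center_px, R_px, tier_px).
#' @export
virtual_sections <- function(phantom, bone_mask = NULL,
                             depths_mm = c(2, 5, 8, 11, 14)) {
  h <- phantom$voxel_size
  defect <- delineate_defect(phantom)
  zspan <- 15
  if (phantom$dims[3] * h < max(depths_mm) + 1e-9)
    stop("geometry error: volume too short for the requested depths")
  if (is.null(bone_mask)) {
    bone_mask <- if (phantom$titanium)
      segment_bone_local_interpolated(phantom, defect = defect)
    else segment_bone_global(phantom, defect = defect)
  }
  ## periosteal face = top of the defect (largest z)
  ztop_mm <- 7.5
  scaffold <- if (phantom$titanium) phantom$scaffold else phantom$scaffold
  lapply(depths_mm, function(dep) {
    zw <- ztop_mm - dep
    k <- round((zw - phantom$origin[3]) / h + 0.5)
    k <- max(1L, min(phantom$dims[3], as.integer(k)))
    structure(list(bone = bone_mask[, , k], scaffold = scaffold[, , k],
                   defect = defect[, , k], depth_mm = dep,
                   voxel_size = h,
                   center_px = (c(0, 0) - phantom$origin[1:2]) / h + 0.5,
                   R_px = 7.5 / h, tier_px = 1.5 / h),
              class = "section2d")
  })
}
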