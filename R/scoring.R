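## Semi-quantitative scoring of peripheral (bone-implant interface) and
## central (implant interior) osteogenesis on virtual sections, the
## three-rater consensus rule, and the mineral apposition rate.

#' Interface metrics of a section
#'
#' Measures, on one axial section, the fraction of the defect
#' circumference where bone touches the implant outline (within a
#' 2-pixel tolerance band at the defect wall) and whether nascent bone
#' engulfs the outer scaffold struts (occupancy of the outermost pore
#' tier of at least 80 percent).
#'
#' @param section a `section2d` (fields bone, scaffold, defect,
#'   center_px, R_px, tier_px) from [virtual_sections()].
#' @param n_arc_bins angular bins for the contact arc (default 180).
#' @param band_px outline tolerance band in pixels (default 2).
#' @param engulf_occupancy outer-tier occupancy defining engulfment.
#' @return list with `contact_arc_fraction` in [0, 1] and
#'   `engulfment_flag`.
#' @export
interface_metrics <- function(section, n_arc_bins = 180, band_px = 2,
                              engulf_occupancy = 0.8) {
  s <- section
  if (!any(s$defect)) stop("geometry error: defect outline not found")
  d <- dim(s$bone)
  ix <- rep(seq_len(d[1]), d[2])
  iy <- rep(seq_len(d[2]), each = d[1])
  rx <- ix - s$center_px[1]
  ry <- iy - s$center_px[2]
  rr <- sqrt(rx^2 + ry^2)
  band <- rr >= s$R_px - band_px & rr <= s$R_px + 0.5
  th <- atan2(ry, rx)
  bin <- pmin(n_arc_bins, 1L + floor((th + pi) / (2 * pi) * n_arc_bins))
  bone_v <- as.vector(s$bone)
  touched <- unique(bin[band & bone_v])
  arc <- length(touched) / n_arc_bins
  tier <- rr >= s$R_px - s$tier_px & rr <= s$R_px & as.vector(s$defect)
  pore_tier <- tier & !as.vector(s$scaffold)
  occ <- if (any(pore_tier)) sum(bone_v & pore_tier) / sum(pore_tier) else 0
  list(contact_arc_fraction = arc,
       engulfment_flag = occ >= engulf_occupancy,
       outer_tier_occupancy = occ)
}

#' Interface (peripheral) score, 0-4
#'
#' Ordinal rubric on the contact arc: no contact (0), about one third
#' of the outline (1), about two thirds (2), complete circular contact
#' (3); engulfment of the outer struts overrides to 4. Cut points are
#' the band midpoints 1/6, 1/2 and 5/6.
#'
#' @param metrics output of [interface_metrics()].
#' @return integer score 0-4.
#' @export
score_interface <- function(metrics) {
  a <- metrics$contact_arc_fraction
  if (isTRUE(metrics$engulfment_flag)) return(4L)
  if (a < 1 / 6) 0L else if (a < 1 / 2) 1L else if (a < 5 / 6) 2L else 3L
}

## Mean 2D component thickness proxy: erosions until empty (4-neighbour).
erode2d <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    res <- array(FALSE, d)
    sx <- max(1, 1 - sh[1]):min(d[1], d[1] - sh[1])
    sy <- max(1, 1 - sh[2]):min(d[2], d[2] - sh[2])
    res[sx + sh[1], sy + sh[2]] <- mask[sx, sy]
    out <- out & res
  }
  out
}

component_thickness_px <- function(mask, max_iter = 25) {
  if (!any(mask)) return(0)
  m <- mask
  n <- 0
  while (any(m) && n < max_iter) {
    m <- erode2d(m)
    n <- n + 1
  }
  2 * n - 1
}

#' Interior (central) score, 0-4
#'
#' Ordinal rubric on the interior bone area fraction a (bone pixels over
#' interior pore pixels, the interior being the defect minus the
#' outermost pore tier) and deposit morphology: a = 0 scores 0; specks
#' (a < 0.02) score 1; thin or reticulate deposits at 0.02 <= a < 0.08
#' score 2 (thicker deposits in that range already score 3); substantial
#' deposits (0.08 <= a < 0.2) score 3; massive, well-defined bone
#' (a >= 0.2) scores 4 when bone reaches at least 90 percent of the
#' discernible pore blocks, else 3. Thin vs thick is proxied by an
#' erosion-based component thickness with a 3-pixel threshold.
#'
#' @param section a `section2d`.
#' @param pore_block_mm block size for "discernible pores", mm.
#' @return integer score 0-4.
#' @export
score_interior <- function(section, pore_block_mm = 3) {
  s <- section
  d <- dim(s$bone)
  ix <- rep(seq_len(d[1]), d[2])
  iy <- rep(seq_len(d[2]), each = d[1])
  rr <- sqrt((ix - s$center_px[1])^2 + (iy - s$center_px[2])^2)
  interior <- array(rr < s$R_px - s$tier_px, d) & s$defect
  pore <- interior & !s$scaffold
  if (!any(pore)) return(0L)
  bone_in <- s$bone & pore
  a <- sum(bone_in) / sum(pore)
  if (a == 0) return(0L)
  if (a < 0.02) return(1L)
  if (a < 0.08) {
    thick <- component_thickness_px(bone_in)
    return(if (thick <= 3) 2L else 3L)
  }
  if (a < 0.2) return(3L)
  ## pore coverage: fraction of interior pore blocks containing bone
  bs <- max(2L, round(pore_block_mm / s$voxel_size))
  gx <- ceiling(d[1] / bs); gy <- ceiling(d[2] / bs)
  fx <- pmin(gx, 1L + (seq_len(d[1]) - 1L) %/% bs)
  fy <- pmin(gy, 1L + (seq_len(d[2]) - 1L) %/% bs)
  blk <- fx[ix] + gx * (fy[iy] - 1L)
  ## "discernible pores": blocks holding at least 10% pore content;
  ## sliver blocks clipped by the interior boundary are not pores
  tab <- table(blk[as.vector(pore)])
  pore_blocks <- as.integer(names(tab)[tab >= 0.1 * bs^2])
  if (!length(pore_blocks)) return(3L)
  bone_blocks <- unique(blk[as.vector(bone_in)])
  cover <- length(intersect(pore_blocks, bone_blocks)) / length(pore_blocks)
  if (cover >= 0.9) 4L else 3L
}

#' Score a list of sections (truth scores)
#'
#' Applies [score_interface()] and [score_interior()] to each section of
#' a sample.
#'
#' @param sections list of `section2d` from [virtual_sections()].
#' @param sample_id identifier copied to the output.
#' @return data frame: sample, depth_mm, interface, interior.
#' @export
score_sections <- function(sections, sample_id = NA) {
  do.call(rbind, lapply(sections, function(s) {
    data.frame(sample = sample_id, depth_mm = s$depth_mm,
               interface = score_interface(interface_metrics(s)),
               interior = score_interior(s))
  }))
}

#' Resolve three-rater consensus
#'
#' For every image and score kind, the consensus is the mean of the
#' three raters when their discrepancy (max - min) does not exceed 1
#' unit. Images with a larger discrepancy are flagged and rescored: the
#' raters re-draw (fresh rater noise around the true score) until the
#' discrepancy is within 1 unit, up to `max_retries` rounds.
#'
#' @param records long data frame from [simulate_raters()]: columns
#'   sample, depth_mm, rater and the score columns.
#' @param truth truth data frame (sample, depth_mm, score columns),
#'   required if any image needs rescoring.
#' @param score_cols score column names (default interface, interior).
#' @param p_err rater noise used for rescoring.
#' @param seed seed for the rescore draws.
#' @param max_retries rescore rounds before a consensus error.
#' @return list with `consensus` (sample, depth_mm, one column per score
#'   kind) and `rescore_log` (flagged images).
#' @export
consensus_scores <- function(records, truth = NULL,
                             score_cols = c("interface", "interior"),
                             p_err = 0.1, seed = 1L, max_retries = 25L) {
  key <- interaction(records$sample, records$depth_mm, drop = TRUE)
  if (any(tapply(records$rater, key, function(r) length(unique(r))) != 3))
    stop("exactly 3 raters per image are required")
  images <- unique(records[c("sample", "depth_mm")])
  log <- list()
  cons <- images
  for (sc in score_cols) cons[[sc]] <- NA_real_
  rng_k <- 0L
  for (i in seq_len(nrow(images))) {
    sel <- records$sample == images$sample[i] &
      records$depth_mm == images$depth_mm[i]
    for (sc in score_cols) {
      v <- records[[sc]][sel]
      retries <- 0L
      while (max(v) - min(v) > 1) {
        if (is.null(truth))
          stop("consensus error: rescoring requires the truth scores")
        if (retries >= max_retries)
          stop("consensus error: no consensus after ", max_retries,
               " rescores")
        tsel <- truth$sample == images$sample[i] &
          truth$depth_mm == images$depth_mm[i]
        tv <- truth[[sc]][tsel][1]
        rng_k <- rng_k + 1L
        v <- with_seed(child_seed(seed, "rescore", rng_k), {
          eps <- sample(c(-1L, 0L, 1L), 3, replace = TRUE,
                        prob = c(p_err, 1 - 2 * p_err, p_err))
          pmin(4L, pmax(0L, as.integer(tv) + eps))
        })
        retries <- retries + 1L
      }
      if (retries > 0)
        log[[length(log) + 1L]] <- data.frame(
          sample = images$sample[i], depth_mm = images$depth_mm[i],
          score = sc, retries = retries)
      cons[[sc]][i] <- mean(v)
    }
  }
  list(consensus = cons,
       rescore_log = if (length(log)) do.call(rbind, log) else
         data.frame(sample = character(), depth_mm = numeric(),
                    score = character(), retries = integer()))
}

#' Mineral apposition rate from a fluorescence section
#'
#' Detects the bone front and the mineral-bound label band on the
#' polar-unwrapped interface image and returns the mean perpendicular
#' front-to-band distance divided by the 14-day labelling interval.
#'
#' @param section a `fluor_section` from [render_fluor_section()].
#' @param front_level intensity threshold locating the bone front.
#' @param band_level minimum band prominence over the bone level.
#' @param run_len consecutive above-threshold rows required for the
#'   front (rejects isolated interior label specks).
#' @return MAR in micrometers per day.
#' @export
mineral_apposition_rate <- function(section, front_level = 0.25,
                                    band_level = 0.25, run_len = 5L) {
  img <- section$image
  ny <- nrow(img); nx <- ncol(img)
  dist_px <- rep(NA_real_, nx)
  for (j in seq_len(nx)) {
    col <- img[, j]
    above <- col > front_level
    ## the peripheral bone region is the contiguous above-threshold run
    ## touching the host-bone edge of the patch; its interior end is the
    ## bone front (interior label specks sit beyond it and are ignored)
    if (!above[ny]) next
    f <- ny
    while (f > 1L && above[f - 1L]) f <- f - 1L
    if (ny - f + 1L < run_len) next
    seg <- col[f:ny]
    pk <- which.max(seg)
    if (seg[pk] - median(seg) < band_level) next
    dist_px[j] <- pk - 1L
  }
  if (all(is.na(dist_px)))
    stop("detection error: no label band found")
  mean(dist_px, na.rm = TRUE) * section$pixel_um / section$interval
}
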