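## 3D frame solver: direct stiffness method with 6 DOF per node
## (3 translations, 3 rotations), circular strut sections. Elements are
## Timoshenko beams by default (shear deformation matters for the
## stocky struts of the low-porosity designs); the Euler-Bernoulli
## limit is available via shear = FALSE.

## Local 12x12 stiffness of a 3D frame element (local x along the axis).
frame_element_local <- function(E, G, A, I, J, L) {
  k <- matrix(0, 12, 12)
  ax <- E * A / L
  tz <- G * J / L
  b1 <- 12 * E * I / L^3
  b2 <- 6 * E * I / L^2
  b3 <- 4 * E * I / L
  b4 <- 2 * E * I / L
  ## axial: u1, u7
  k[1, 1] <- k[7, 7] <- ax; k[1, 7] <- k[7, 1] <- -ax
  ## torsion: rx4, rx10
  k[4, 4] <- k[10, 10] <- tz; k[4, 10] <- k[10, 4] <- -tz
  ## bending about z (v, rz): DOFs 2, 6, 8, 12
  k[2, 2] <- k[8, 8] <- b1; k[2, 8] <- k[8, 2] <- -b1
  k[2, 6] <- k[6, 2] <- b2; k[2, 12] <- k[12, 2] <- b2
  k[8, 6] <- k[6, 8] <- -b2; k[8, 12] <- k[12, 8] <- -b2
  k[6, 6] <- k[12, 12] <- b3; k[6, 12] <- k[12, 6] <- b4
  ## bending about y (w, ry): DOFs 3, 5, 9, 11 (note sign convention)
  k[3, 3] <- k[9, 9] <- b1; k[3, 9] <- k[9, 3] <- -b1
  k[3, 5] <- k[5, 3] <- -b2; k[3, 11] <- k[11, 3] <- -b2
  k[9, 5] <- k[5, 9] <- b2; k[9, 11] <- k[11, 9] <- b2
  k[5, 5] <- k[11, 11] <- b3; k[5, 11] <- k[11, 5] <- b4
  k
}

## Rotation of local axes: local x along the strut, y/z arbitrary normal.
element_rotation <- function(u) {
  x <- u / sqrt(sum(u^2))
  ref <- if (abs(x[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  y <- ref - sum(ref * x) * x
  y <- y / sqrt(sum(y^2))
  z <- c(x[2] * y[3] - x[3] * y[2],
         x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  rbind(x, y, z)
}

## Assemble the global sparse stiffness matrix (6 DOF per node).
## shear = TRUE uses Timoshenko elements with the Cowper shear
## coefficient for circular sections; FALSE gives Euler-Bernoulli.
assemble_frame <- function(lattice, slenderness_warn = 3, shear = TRUE,
                           joints = c("rigid", "pin")) {
  joints <- match.arg(joints)
  E <- lattice$material$elastic_modulus
  nu <- lattice$material$poisson_ratio
  G <- E / (2 * (1 + nu))
  kappa <- if (shear) 6 * (1 + nu) / (7 + 6 * nu) else 0
  n <- nrow(lattice$nodes)
  m <- nrow(lattice$struts)
  lens <- strut_lengths(lattice)
  if (!shear && any(lens / lattice$radii < slenderness_warn))
    warning(sprintf(
      "%d struts with slenderness L/r < %g: Euler-Bernoulli theory is stiff for stocky struts",
      sum(lens / lattice$radii < slenderness_warn), slenderness_warn))
  bending_factor <- if (joints == "pin") 1e-8 else 1
  tr <- cpp_frame_triplets(lattice$nodes, lattice$struts, lattice$radii,
                           E, G, kappa, bending_factor)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(6 * n, 6 * n))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

## Connected components of the strut graph (igraph).
lattice_components <- function(lattice) {
  g <- igraph::graph_from_edgelist(lattice$struts, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(lattice$nodes) - igraph::vcount(g)))
  igraph::components(g)$membership
}

#' Apparent elastic modulus of a lattice
#'
#' Compresses the lattice between rigid platens perpendicular to
#' `direction` using the 3D frame direct-stiffness method: nodes on the
#' rear face are fixed, nodes on the loaded face receive a uniform
#' prescribed displacement along the load direction (free laterally), and
#' the apparent modulus is (reaction force / cross-sectional area)
#' divided by (displacement / span). Components of the network that do
#' not connect the two faces are discarded; if none connects them the
#' system is a floating mechanism and an error is raised.
#'
#' @param lattice a [lattice3d()].
#' @param direction loading direction (length-3, need not be unit).
#' @param span platen separation, mm; default the lattice extent along
#'   `direction`.
#' @param area loaded cross-sectional area, mm^2. For implant cylinders
#'   this is the full cylinder footprint; default the bounding-box
#'   cross-section perpendicular to `direction` (axis-aligned directions
#'   only).
#' @param face_tol tolerance for identifying face nodes, mm.
#' @param shear include Timoshenko shear deformation (default TRUE;
#'   FALSE gives the Euler-Bernoulli limit). Shear deformation matters
#'   for the stocky struts of the low-porosity designs (slenderness
#'   below ~3), where it dominates off-axis bending compliance.
#' @param joints "rigid" for frame behaviour; "pin" approximates a
#'   pin-jointed (axial-only) truss by scaling the bending and torsion
#'   stiffness down by 1e-8, which keeps the system nonsingular while
#'   making bending contributions negligible.
#' @return apparent modulus, MPa.
#' @examples
#' m <- material("polyamide", 2000, 0.39)
#' l <- lattice3d(rbind(c(0, 0, 0), c(0, 0, 10)), rbind(c(1, 2)),
#'                sqrt(1 / pi), m)
#' apparent_modulus(l, c(0, 0, 1), area = 1)  # = E_s when A = loaded area
#' @export
apparent_modulus <- function(lattice, direction = c(0, 0, 1), span = NULL,
                             area = NULL, face_tol = 1e-6, shear = TRUE,
                             joints = c("rigid", "pin")) {
  joints <- match.arg(joints)
  d <- direction / sqrt(sum(direction^2))
  ## rotate so the load is along +z
  if (max(abs(d - c(0, 0, 1))) > 1e-12) {
    theta <- acos(max(-1, min(1, d[3]))) * 180 / pi
    phi <- atan2(d[2], d[1]) * 180 / pi
    Rm <- rotation_to_z(phi, theta)
    lattice$nodes <- lattice$nodes %*% t(Rm)
  }
  z <- lattice$nodes[, 3]
  if (is.null(span)) span <- max(z) - min(z)
  if (is.null(area)) {
    bb <- lattice_bbox(lattice)
    area <- prod(pmax(bb[2, 1:2] - bb[1, 1:2], 1e-12))
  }
  bottom <- which(z <= min(z) + face_tol)
  top <- which(z >= max(z) - face_tol)
  if (!length(bottom) || !length(top))
    stop("singularity error: no nodes on the loading faces")
  comp <- lattice_components(lattice)
  good <- intersect(unique(comp[bottom]), unique(comp[top]))
  if (!length(good))
    stop("singularity error: no strut path connects the loading faces; ",
         "unconstrained components: ",
         paste(setdiff(unique(comp), good), collapse = ", "))
  keep_nodes <- which(comp %in% good)
  if (length(keep_nodes) < nrow(lattice$nodes)) {
    remap <- match(seq_len(nrow(lattice$nodes)), keep_nodes)
    ks <- comp[lattice$struts[, 1]] %in% good
    lattice <- lattice3d(lattice$nodes[keep_nodes, , drop = FALSE],
                         cbind(remap[lattice$struts[ks, 1]],
                               remap[lattice$struts[ks, 2]]),
                         lattice$radii[ks], lattice$material)
    z <- lattice$nodes[, 3]
    bottom <- which(z <= min(z) + face_tol)
    top <- which(z >= max(z) - face_tol)
  }
  K <- assemble_frame(lattice, shear = shear, joints = joints)
  ndof <- nrow(K)
  delta <- 0.001 * span
  fixed <- as.vector(outer(1:6, (bottom - 1L) * 6L, "+"))
  top_w <- (top - 1L) * 6L + 3L
  presc <- c(fixed, top_w)
  u_p <- c(rep(0, length(fixed)), rep(-delta, length(top)))
  free <- setdiff(seq_len(ndof), presc)
  Kfp <- K[free, presc, drop = FALSE]
  rhs <- -(Kfp %*% u_p)
  u_f <- tryCatch(
    as.numeric(Matrix::solve(K[free, free, drop = FALSE], rhs)),
    error = function(e)
      stop("singularity error: rank-deficient frame system (", e$message, ")"))
  u <- numeric(ndof)
  u[presc] <- u_p
  u[free] <- u_f
  reac <- as.numeric(K[top_w, , drop = FALSE] %*% u)
  Fz <- sum(reac)
  Eapp <- (abs(Fz) / area) / (delta / span)
  Eapp
}

#' Direction sweep of apparent modulus
#'
#' Samples the apparent modulus over the loading hemisphere on a regular
#' (phi, theta) grid at the given increment (degrees), rotating the
#' architecture relative to the load axis. For a [scaffold_design()] the
#' untrimmed design lattice is rigidly rotated and re-trimmed to the
#' implant cylinder for every direction, so each probe is a compression
#' test of the same architecture along a different material direction;
#' for a plain [lattice3d()] the lattice is rotated and loaded between
#' its extreme-z faces. The pole (theta = 0) is sampled once.
#'
#' @param x a [scaffold_design()], the result of
#'   [build_design_lattice()], or a [lattice3d()].
#' @param increment grid increment in degrees; must divide 90.
#' @param seed stochastic-generator seed (designs only).
#' @param voxel_size porosity-solve voxel (designs only), mm.
#' @param ... passed to [apparent_modulus()].
#' @return A `direction_sweep` object: data frame `angles` with columns
#'   phi_deg, theta_deg, modulus_MPa, weight (solid-angle), plus the
#'   increment.
#' @export
direction_sweep <- function(x, increment = 15, ...) UseMethod("direction_sweep")

sweep_grid <- function(increment) {
  if (90 %% increment != 0) stop("increment must divide 90")
  thetas <- seq(0, 90, by = increment)
  out <- list()
  for (th in thetas) {
    phis <- if (th == 0) 0 else seq(0, 360 - increment, by = increment)
    ## solid-angle weight: area of the theta band / number of phi samples
    t1 <- max(0, th - increment / 2) * pi / 180
    t2 <- min(90, th + increment / 2) * pi / 180
    w <- (cos(t1) - cos(t2)) / length(phis)
    out[[length(out) + 1L]] <- data.frame(phi_deg = phis, theta_deg = th,
                                          weight = w)
  }
  do.call(rbind, out)
}

#' @rdname direction_sweep
#' @export
direction_sweep.scaffold_design <- function(x, increment = 15, seed = 1L,
                                            voxel_size = 0.1, ...) {
  built <- build_design_lattice(x, voxel_size = voxel_size, seed = seed)
  direction_sweep(built, increment = increment, ...)
}

#' @rdname direction_sweep
#' @export
direction_sweep.osteo_design_build <- function(x, increment = 15, ...) {
  grid <- sweep_grid(increment)
  D <- x$design$cylinder_diameter
  H <- x$design$cylinder_height
  area <- pi * (D / 2)^2
  mods <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    Rm <- rotation_to_z(grid$phi_deg[i], grid$theta_deg[i])
    rot <- x$base
    rot$nodes <- rot$nodes %*% t(Rm)
    trimmed <- trim_to_cylinder(rot, D, H, center = c(0, 0, 0))
    mods[i] <- apparent_modulus(trimmed, c(0, 0, 1), span = H, area = area,
                                ...)
  }
  grid$modulus_MPa <- mods
  structure(list(angles = grid, increment = increment,
                 design = x$design$acronym),
            class = "direction_sweep")
}

#' @rdname direction_sweep
#' @export
direction_sweep.lattice3d <- function(x, increment = 15, ...) {
  grid <- sweep_grid(increment)
  mods <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    d <- direction_from_angles(grid$phi_deg[i], grid$theta_deg[i])
    mods[i] <- apparent_modulus(x, d, ...)
  }
  grid$modulus_MPa <- mods
  structure(list(angles = grid, increment = increment, design = NA),
            class = "direction_sweep")
}

#' @export
print.direction_sweep <- function(x, ...) {
  cat(sprintf(
    "<direction_sweep> %d directions at %g deg; modulus %.3g..%.3g MPa (max:min = %.2f)\n",
    nrow(x$angles), x$increment, min(x$angles$modulus_MPa),
    max(x$angles$modulus_MPa), anisotropy_coefficient(x)))
  invisible(x)
}

#' Anisotropy coefficient of a direction sweep
#'
#' The ratio of the maximal to the minimal apparent modulus over all
#' probed loading directions (reported as max:min, always >= 1).
#'
#' @param sweep a `direction_sweep`.
#' @return numeric ratio >= 1.
#' @export
anisotropy_coefficient <- function(sweep) {
  m <- sweep$angles$modulus_MPa
  if (!length(m)) stop("empty sweep")
  max(m) / min(m)
}

#' Direction-averaged apparent modulus
#'
#' Solid-angle-weighted mean of the apparent modulus over the hemisphere.
#'
#' @param sweep a `direction_sweep`.
#' @return mean modulus, MPa.
#' @export
direction_average_modulus <- function(sweep) {
  a <- sweep$angles
  if (!nrow(a)) stop("empty sweep")
  sum(a$modulus_MPa * a$weight) / sum(a$weight)
}

#' Grade strut thickness to a target axial modulus
#'
#' Scales all strut radii by a single global factor until the apparent
#' modulus along +z matches the target within 1 percent (relative),
#' using bisection on the log-scale factor (the modulus is monotone
#' non-decreasing in every radius). An optional `radius_field` hook
#' applies a per-strut multiplicative field before the global scaling,
#' for spatially graded designs.
#'
#' @param lattice a [lattice3d()].
#' @param target_axial_modulus MPa.
#' @param span,area passed to [apparent_modulus()].
#' @param radius_field optional function(midpoints-matrix) returning a
#'   per-strut multiplier.
#' @param rel_tol relative tolerance (default 0.01).
#' @return the re-graded [lattice3d()] with attribute `scale`.
#' @export
grade_thickness <- function(lattice, target_axial_modulus, span = NULL,
                            area = NULL, radius_field = NULL,
                            rel_tol = 0.01) {
  if (!is.null(radius_field)) {
    mid <- (lattice$nodes[lattice$struts[, 1], , drop = FALSE] +
              lattice$nodes[lattice$struts[, 2], , drop = FALSE]) / 2
    lattice$radii <- lattice$radii * radius_field(mid)
  }
  f <- function(s) {
    l <- lattice
    l$radii <- lattice$radii * s
    suppressWarnings(apparent_modulus(l, c(0, 0, 1), span = span, area = area))
  }
  e0 <- f(1)
  if (abs(e0 - target_axial_modulus) / target_axial_modulus <= rel_tol) {
    attr(lattice, "scale") <- 1
    return(lattice)
  }
  lo <- 1; hi <- 1
  if (e0 < target_axial_modulus) {
    while (f(hi) < target_axial_modulus) {
      hi <- hi * 2
      if (hi > 64) stop("calibration error: target modulus not bracketable")
    }
  } else {
    while (f(lo) > target_axial_modulus) {
      lo <- lo / 2
      if (lo < 1 / 64) stop("calibration error: target modulus not bracketable")
    }
  }
  for (it in 1:60) {
    mid <- sqrt(lo * hi)
    em <- f(mid)
    if (abs(em - target_axial_modulus) / target_axial_modulus <= rel_tol) {
      lattice$radii <- lattice$radii * mid
      attr(lattice, "scale") <- mid
      return(lattice)
    }
    if (em < target_axial_modulus) lo <- mid else hi <- mid
  }
  stop("calibration error: thickness grading did not converge")
}
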