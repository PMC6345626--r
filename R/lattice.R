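#' Strut lattice container
#'
#' A 3D strut network: node coordinates (mm), strut connectivity as node
#' index pairs, a per-strut radius (mm) and a strut material. Invariants
#' enforced at construction: no self-struts, no duplicate unordered pairs,
#' positive radii, indices in range.
#'
#' @param nodes numeric matrix, n x 3, node coordinates in mm.
#' @param struts integer matrix, m x 2, node index pairs.
#' @param radii numeric vector of length m (or length 1, recycled), mm.
#' @param material a [material()] object.
#' @return Object of class `lattice3d`.
#' @export
lattice3d <- function(nodes, struts, radii, material) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3) stop("nodes must be an n x 3 matrix")
  struts <- matrix(as.integer(struts), ncol = 2)
  if (nrow(struts) > 0) {
    if (any(struts < 1L) || any(struts > nrow(nodes)))
      stop("strut indices out of range")
    if (any(struts[, 1] == struts[, 2]))
      stop("self-connecting strut")
    key <- paste(pmin(struts[, 1], struts[, 2]),
                 pmax(struts[, 1], struts[, 2]))
    if (anyDuplicated(key)) stop("duplicate struts")
  }
  radii <- rep_len(as.numeric(radii), nrow(struts))
  if (nrow(struts) > 0 && any(radii <= 0)) stop("all radii must be > 0")
  if (!inherits(material, "material")) stop("material must be a material()")
  structure(list(nodes = nodes, struts = struts, radii = radii,
                 material = material),
            class = "lattice3d")
}

#' @export
print.lattice3d <- function(x, ...) {
  cat(sprintf("<lattice3d> %d nodes, %d struts, material %s\n",
              nrow(x$nodes), nrow(x$struts), x$material$name))
  invisible(x)
}

#' Strut lengths of a lattice (mm)
#' @param lattice a [lattice3d()] object.
#' @return numeric vector of per-strut lengths.
#' @export
strut_lengths <- function(lattice) {
  d <- lattice$nodes[lattice$struts[, 1], , drop = FALSE] -
    lattice$nodes[lattice$struts[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Node degrees of a lattice
#' @param lattice a [lattice3d()] object.
#' @return integer vector, one entry per node.
#' @export
node_degrees <- function(lattice) {
  tabulate(c(lattice$struts[, 1], lattice$struts[, 2]),
           nbins = nrow(lattice$nodes))
}

lattice_bbox <- function(lattice) {
  rbind(min = apply(lattice$nodes, 2, min),
        max = apply(lattice$nodes, 2, max))
}

as_bbox <- function(bbox) {
  bbox <- as.matrix(bbox)
  if (length(bbox) == 6 && is.null(dim(bbox))) bbox <- matrix(bbox, 2, 3)
  if (!all(dim(bbox) == c(2, 3))) stop("bbox must be a 2 x 3 matrix (min; max)")
  if (any(bbox[2, ] <= bbox[1, ])) stop("degenerate bbox")
  unname(bbox)
}

## Deduplicate nodes by coordinate key; returns relabelled lattice pieces.
dedupe_nodes <- function(nodes, struts, digits = 9) {
  key <- apply(round(nodes, digits), 1, paste, collapse = "/")
  first <- !duplicated(key)
  relab <- match(key, key[first])  # position among the unique rows
  list(nodes = nodes[first, , drop = FALSE],
       struts = matrix(relab[struts], ncol = 2))
}

#' Generate an octet-truss lattice
#'
#' Tiles the bounding box with the fully triangulated octet (FCC) truss:
#' lattice sites at cube corners and face centres, struts joining all
#' nearest-neighbour site pairs at distance `unit_cell / sqrt(2)`. Struts
#' shared by adjacent cells are generated once. The box is tiled with
#' whole cells from its minimum corner.
#'
#' @param bbox 2 x 3 matrix (rows: min, max) in mm; must span at least
#'   one unit cell per axis.
#' @param unit_cell cube edge length, mm.
#' @param radius strut radius, mm; must be below `unit_cell / 2`.
#' @param material a [material()].
#' @return A [lattice3d()].
#' @examples
#' l <- generate_octetruss(rbind(c(0, 0, 0), c(3, 3, 3)), 3, 0.3,
#'                         material("polyamide", 2000, 0.39))
#' @export
generate_octetruss <- function(bbox, unit_cell, radius, material) {
  bbox <- as_bbox(bbox)
  if (unit_cell <= 0) stop("unit_cell must be > 0")
  if (radius >= unit_cell / 2) stop("radius must be < unit_cell / 2")
  ncell <- floor((bbox[2, ] - bbox[1, ]) / unit_cell + 1e-9)
  if (any(ncell < 1)) stop("degenerate domain: bbox smaller than one unit cell")
  ## FCC sites on a half-integer grid: (i,j,k) with i+j+k even, units of a/2
  rng <- lapply(1:3, function(ax) 0:(2L * ncell[ax]))
  g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  g <- g[(g$i + g$j + g$k) %% 2L == 0L, , drop = FALSE]
  site <- as.matrix(g)
  nk <- c(max(site[, 1]) + 2L, max(site[, 2]) + 2L)
  code <- function(s) s[, 1] + nk[1] * (s[, 2] + nk[2] * s[, 3])
  idx <- integer(max(code(site)) + 1L)
  idx[code(site) + 1L] <- seq_len(nrow(site))
  ## 12 FCC nearest-neighbour offsets in half-units; keep a canonical half
  off <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
               c(0, 1, 1), c(0, 1, -1))
  e1 <- integer(0); e2 <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- sweep(site, 2, off[r, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0 &
      nb[, 1] <= 2 * ncell[1] & nb[, 2] <= 2 * ncell[2] & nb[, 3] <= 2 * ncell[3]
    j <- idx[code(nb[ok, , drop = FALSE]) + 1L]
    stopifnot(all(j > 0L))
    e1 <- c(e1, which(ok)); e2 <- c(e2, j)
  }
  nodes <- sweep(site * (unit_cell / 2), 2, bbox[1, ], "+")
  lattice3d(nodes, cbind(e1, e2), radius, material)
}

#' Generate an orthogonal cubic-grid lattice
#'
#' Nodes on a regular grid, struts along the three coordinate axes with
#' length equal to the unit cell; a 3D orthogonal (cuboid-cell) grid.
#'
#' @inheritParams generate_octetruss
#' @return A [lattice3d()].
#' @export
generate_cubic <- function(bbox, unit_cell, radius, material) {
  bbox <- as_bbox(bbox)
  if (unit_cell <= 0) stop("unit_cell must be > 0")
  if (radius >= unit_cell / 2) stop("radius must be < unit_cell / 2")
  ncell <- floor((bbox[2, ] - bbox[1, ]) / unit_cell + 1e-9)
  if (any(ncell < 1)) stop("degenerate domain: bbox smaller than one unit cell")
  g <- as.matrix(expand.grid(i = 0:ncell[1], j = 0:ncell[2], k = 0:ncell[3]))
  nk <- ncell + 2L
  code <- g[, 1] + nk[1] * (g[, 2] + nk[2] * g[, 3])
  idx <- integer(max(code) + 1L)
  idx[code + 1L] <- seq_len(nrow(g))
  e1 <- integer(0); e2 <- integer(0)
  for (ax in 1:3) {
    nb <- g
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= ncell[ax]
    j <- idx[(nb[ok, 1] + nk[1] * (nb[ok, 2] + nk[2] * nb[ok, 3])) + 1L]
    e1 <- c(e1, which(ok)); e2 <- c(e2, j)
  }
  nodes <- sweep(g * unit_cell, 2, bbox[1, ], "+")
  lattice3d(nodes, cbind(e1, e2), radius, material)
}

## ---- Poisson-disk stochastic lattice ------------------------------------

## Dart-throwing Poisson-disk sampling with a cell grid accelerator.
poisson_disk_sample <- function(bbox, n_points, rmin, max_attempts = 200L) {
  ext <- bbox[2, ] - bbox[1, ]
  cell <- rmin / sqrt(3)
  ndiv <- pmax(1L, as.integer(ceiling(ext / cell)))
  grid <- vector("list", prod(ndiv))
  cell_of <- function(p) {
    ijk <- pmin(ndiv - 1L, pmax(0L, as.integer(floor((p - bbox[1, ]) / cell))))
    1L + ijk[1] + ndiv[1] * (ijk[2] + ndiv[2] * ijk[3])
  }
  pts <- matrix(NA_real_, n_points, 3)
  count <- 0L
  attempts <- 0L
  budget <- max_attempts * n_points
  while (count < n_points && attempts < budget) {
    attempts <- attempts + 1L
    p <- bbox[1, ] + runif(3) * ext
    ijk <- pmin(ndiv - 1L, pmax(0L, as.integer(floor((p - bbox[1, ]) / cell))))
    reach <- as.integer(ceiling(rmin / cell))
    lo <- pmax(0L, ijk - reach); hi <- pmin(ndiv - 1L, ijk + reach)
    cand <- integer(0)
    for (kk in lo[3]:hi[3]) for (jj in lo[2]:hi[2]) {
      base <- 1L + lo[1] + ndiv[1] * (jj + ndiv[2] * kk)
      cand <- c(cand, unlist(grid[base:(base + (hi[1] - lo[1]))]))
    }
    if (length(cand)) {
      d2 <- (pts[cand, 1] - p[1])^2 + (pts[cand, 2] - p[2])^2 +
        (pts[cand, 3] - p[3])^2
      if (any(d2 < rmin^2)) next
    }
    count <- count + 1L
    pts[count, ] <- p
    ci <- cell_of(p)
    grid[[ci]] <- c(grid[[ci]], count)
  }
  if (count < n_points)
    stop(sprintf(
      "packing error: placed %d of %d points at disk radius %.3g mm",
      count, n_points, rmin))
  pts
}

## k nearest neighbours via the same cell-grid idea (expanding search).
knn_edges <- function(pts, k) {
  n <- nrow(pts)
  bbox <- rbind(apply(pts, 2, min), apply(pts, 2, max))
  ext <- pmax(bbox[2, ] - bbox[1, ], 1e-9)
  target_per_cell <- 2
  cell <- (prod(ext) * target_per_cell / n)^(1 / 3)
  ndiv <- pmax(1L, as.integer(ceiling(ext / cell)))
  ijk <- pmin(sweep(matrix(1L, n, 3), 2, ndiv, `*`) - 1L,
              pmax(0L, floor(sweep(sweep(pts, 2, bbox[1, ]), 2, cell, "/"))))
  storage.mode(ijk) <- "integer"
  codes <- 1L + ijk[, 1] + ndiv[1] * (ijk[, 2] + ndiv[2] * ijk[, 3])
  buckets <- split(seq_len(n), codes)
  bucket_of <- vector("list", prod(ndiv))
  bucket_of[as.integer(names(buckets))] <- buckets
  e1 <- integer(0); e2 <- integer(0)
  for (i in seq_len(n)) {
    reach <- 1L
    repeat {
      lo <- pmax(0L, ijk[i, ] - reach); hi <- pmin(ndiv - 1L, ijk[i, ] + reach)
      cand <- integer(0)
      for (kk in lo[3]:hi[3]) for (jj in lo[2]:hi[2]) {
        base <- 1L + lo[1] + ndiv[1] * (jj + ndiv[2] * kk)
        cand <- c(cand, unlist(bucket_of[base:(base + (hi[1] - lo[1]))]))
      }
      cand <- cand[cand != i]
      if (length(cand) >= k || all(lo == 0L) && all(hi == ndiv - 1L)) {
        ## require candidates within reach*cell radius to be exact enough
        if (length(cand) >= k) {
          d2 <- (pts[cand, 1] - pts[i, 1])^2 + (pts[cand, 2] - pts[i, 2])^2 +
            (pts[cand, 3] - pts[i, 3])^2
          ord <- order(d2)
          need <- cand[ord[seq_len(k)]]
          ## widen once if the kth distance exceeds the guaranteed radius
          if (d2[ord[k]] <= (reach * cell)^2 ||
              (all(lo == 0L) && all(hi == ndiv - 1L))) {
            e1 <- c(e1, rep.int(i, k)); e2 <- c(e2, need)
            break
          }
        } else {
          e1 <- c(e1, rep.int(i, length(cand))); e2 <- c(e2, cand)
          break
        }
      }
      reach <- reach + 1L
    }
  }
  a <- pmin(e1, e2); b <- pmax(e1, e2)
  key <- !duplicated(paste(a, b))
  cbind(a[key], b[key])
}

#' Generate a stochastic Poisson-disk lattice
#'
#' Fills the box with `n_points` random points under a Poisson-disk
#' minimum-distance constraint, connects each point to its nearest
#' neighbours, then prunes the longest non-bridge struts until the mean
#' node degree reaches `target_connectivity` (within 0.1) while keeping
#' the network a single connected component.
#'
#' @param bbox 2 x 3 matrix, mm.
#' @param n_points number of lattice nodes (>= 10). Default scales with
#'   box volume at the study density of about 5000 nodes per implant
#'   cylinder (1.66 nodes per mm^3).
#' @param target_connectivity target mean node degree (default 4.5).
#' @param seed integer seed; identical seeds give identical lattices.
#' @param material a [material()].
#' @param radius strut radius, mm.
#' @return A [lattice3d()].
#' @export
generate_stochastic <- function(bbox, n_points = NULL,
                                target_connectivity = 4.5, seed = 1L,
                                material = mat_titanium(), radius = 0.25) {
  bbox <- as_bbox(bbox)
  vol <- prod(bbox[2, ] - bbox[1, ])
  if (is.null(n_points)) n_points <- max(10L, round(vol * 5000 / 3016))
  if (n_points < 10) stop("n_points must be >= 10")
  if (target_connectivity < 3) stop("target_connectivity must be >= 3")
  kmax <- 12L
  if (target_connectivity > kmax - 2L)
    stop(sprintf(
      "connectivity error: target mean degree %.1f infeasible (supported <= %d)",
      target_connectivity, kmax - 2L))
  rmin <- 0.7 * (vol / n_points)^(1 / 3)
  with_seed(seed, {
    pts <- poisson_disk_sample(bbox, n_points, rmin)
    k0 <- max(6L, min(kmax, as.integer(ceiling(target_connectivity)) + 2L),
              if (n_points <= 20L) n_points - 1L else 0L)
    k0 <- min(k0, n_points - 1L)
    ed <- knn_edges(pts, k0)
    g <- igraph::graph_from_edgelist(ed, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n_points - igraph::vcount(g)))
    ## stitch components together with shortest inter-component links
    comp <- igraph::components(g)
    while (comp$no > 1L) {
      main <- which(comp$membership == which.max(comp$csize))
      other <- which(comp$membership != which.max(comp$csize))
      d2 <- outer(rowSums(pts[other, , drop = FALSE]^2),
                  rowSums(pts[main, , drop = FALSE]^2), "+") -
        2 * pts[other, , drop = FALSE] %*% t(pts[main, , drop = FALSE])
      w <- arrayInd(which.min(d2), dim(d2))
      ed <- rbind(ed, c(other[w[1]], main[w[2]]))
      g <- igraph::add_edges(g, c(other[w[1]], main[w[2]]))
      comp <- igraph::components(g)
    }
    ## prune longest non-bridge edges until the mean degree hits target
    mean_deg <- function(g) 2 * igraph::ecount(g) / n_points
    len_of <- function(el) sqrt(rowSums((pts[el[, 1], , drop = FALSE] -
                                           pts[el[, 2], , drop = FALSE])^2))
    if (mean_deg(g) < target_connectivity - 0.1)
      stop("connectivity error: initial graph below target mean degree")
    guard <- 0L
    frac <- 4
    while (mean_deg(g) > target_connectivity && guard < 10000L) {
      el <- igraph::as_edgelist(g, names = FALSE)
      lens <- len_of(el)
      br <- rep(FALSE, nrow(el))
      br[igraph::bridges(g)] <- TRUE
      cand <- which(!br)
      if (!length(cand)) break
      excess <- (mean_deg(g) - target_connectivity) * n_points / 2
      take <- cand[order(lens[cand], decreasing = TRUE)]
      take <- take[seq_len(max(1L, min(length(take), floor(excess / frac))))]
      ## batch removal of non-bridges can still disconnect (an edge may
      ## become a bridge once an earlier batch member is gone): verify
      ## and retry with a smaller batch if so
      g2 <- igraph::delete_edges(g, take)
      if (igraph::components(g2)$no == 1L) {
        g <- g2
      } else if (length(take) == 1L) {
        ## a stale singleton bridge; recompute on the next pass
        frac <- frac * 2
      } else {
        frac <- frac * 2
      }
      guard <- guard + 1L
    }
    if (abs(mean_deg(g) - target_connectivity) > 0.1)
      stop(sprintf("connectivity error: achieved mean degree %.2f, target %.2f",
                   mean_deg(g), target_connectivity))
    el <- igraph::as_edgelist(g, names = FALSE)
    lattice3d(pts, el, radius, material)
  })
}

#' Trim a lattice to a cylinder
#'
#' Removes struts wholly outside the cylinder and clips boundary-crossing
#' struts at the cylinder surface (side wall and end caps), keeping the
#' partial struts; orphan nodes are dropped. The cylinder axis is z,
#' centred on the lattice bounding box unless `center` is given.
#'
#' @param lattice a [lattice3d()].
#' @param diameter,height cylinder dimensions, mm.
#' @param center length-3 centre of the cylinder (mm); default the lattice
#'   bounding-box centre.
#' @return A trimmed [lattice3d()].
#' @export
trim_to_cylinder <- function(lattice, diameter, height, center = NULL) {
  if (diameter <= 0 || height <= 0) stop("degenerate cylinder")
  bb <- lattice_bbox(lattice)
  if (is.null(center)) center <- colMeans(bb)
  R <- diameter / 2
  z0 <- center[3] - height / 2
  z1 <- center[3] + height / 2
  P <- sweep(lattice$nodes, 2, center, "-")
  A <- P[lattice$struts[, 1], , drop = FALSE]
  B <- P[lattice$struts[, 2], , drop = FALSE]
  U <- B - A
  m <- nrow(A)
  zl <- z0 - center[3]; zu <- z1 - center[3]
  ## z-slab clipping (vectorized over struts)
  uz <- U[, 3]
  par_z <- abs(uz) < 1e-12
  ta <- ifelse(par_z, 0, (zl - A[, 3]) / uz)
  tb <- ifelse(par_z, 1, (zu - A[, 3]) / uz)
  lo <- pmax(0, pmin(ta, tb))
  hi <- pmin(1, pmax(ta, tb))
  bad <- par_z & (A[, 3] < zl - 1e-12 | A[, 3] > zu + 1e-12)
  lo[bad] <- 1; hi[bad] <- 0
  ## lateral surface: |A_xy + t U_xy|^2 <= R^2
  a <- U[, 1]^2 + U[, 2]^2
  b <- 2 * (A[, 1] * U[, 1] + A[, 2] * U[, 2])
  cc <- A[, 1]^2 + A[, 2]^2 - R^2
  par_r <- a < 1e-14
  disc <- b^2 - 4 * a * cc
  s <- sqrt(pmax(disc, 0))
  qlo <- ifelse(par_r, 0, (-b - s) / (2 * pmax(a, 1e-300)))
  qhi <- ifelse(par_r, 1, (-b + s) / (2 * pmax(a, 1e-300)))
  lo <- pmax(lo, qlo); hi <- pmin(hi, qhi)
  out_r <- (par_r & cc > 1e-12) | (!par_r & disc <= 0)
  lo[out_r] <- 1; hi[out_r] <- 0
  t0 <- lo; t1 <- hi
  keep <- t1 - t0 > 1e-9
  if (!any(keep)) stop("degenerate domain: cylinder does not intersect lattice")
  A2 <- A[keep, , drop = FALSE] + U[keep, , drop = FALSE] * t0[keep]
  B2 <- A[keep, , drop = FALSE] + U[keep, , drop = FALSE] * t1[keep]
  nodes <- sweep(rbind(A2, B2), 2, center, "+")
  nkeep <- sum(keep)
  struts <- cbind(seq_len(nkeep), nkeep + seq_len(nkeep))
  dd <- dedupe_nodes(nodes, struts)
  ok <- dd$struts[, 1] != dd$struts[, 2]
  key <- paste(pmin(dd$struts[ok, 1], dd$struts[ok, 2]),
               pmax(dd$struts[ok, 1], dd$struts[ok, 2]))
  first <- !duplicated(key)
  lattice3d(dd$nodes, dd$struts[ok, , drop = FALSE][first, , drop = FALSE],
            lattice$radii[keep][ok][first], lattice$material)
}
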