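## Shared fixtures: tiny materials/lattices, and lazily-built heavyweight
## objects (design builds, substrates, cohort runs) memoized for the whole
## test session so expensive geometry is computed once.

fix_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fix_env[[key]])) fix_env[[key]] <- force(expr)
  fix_env[[key]]
}

mat_pa <- function() material("polyamide", 2000, 0.39)
mat_ti <- function() material("titanium", 100000, 0.34)

unit_box <- function(a = 1) rbind(c(0, 0, 0), c(a, a, a))

single_strut <- function(L = 10, r = 0.5, m = mat_pa()) {
  lattice3d(rbind(c(0, 0, 0), c(0, 0, L)), rbind(c(1, 2)), r, m)
}

## Independent brute-force oracle for the octet (FCC) edge set of one
## cell: enumerate all 14 sites, connect every pair at distance a/sqrt(2).
octet_cell_edges_oracle <- function(a = 1) {
  corners <- as.matrix(expand.grid(c(0, a), c(0, a), c(0, a)))
  faces <- rbind(c(a/2, a/2, 0), c(a/2, a/2, a), c(a/2, 0, a/2),
                 c(a/2, a, a/2), c(0, a/2, a/2), c(a, a/2, a/2))
  sites <- rbind(corners, faces)
  d <- as.matrix(dist(sites))
  hits <- which(abs(d - a / sqrt(2)) < 1e-9 & upper.tri(d), arr.ind = TRUE)
  key <- apply(hits, 1, function(e) {
    p <- sites[e[1], ]; q <- sites[e[2], ]
    if (p[1] < q[1] || (p[1] == q[1] && (p[2] < q[2] ||
        (p[2] == q[2] && p[3] <= q[3]))))
      paste(signif(c(p, q), 10), collapse = "/")
    else paste(signif(c(q, p), 10), collapse = "/")
  })
  unname(sort(key))
}

lattice_edge_keys <- function(l) {
  key <- apply(l$struts, 1, function(e) {
    p <- l$nodes[e[1], ]; q <- l$nodes[e[2], ]
    if (p[1] < q[1] || (p[1] == q[1] && (p[2] < q[2] ||
        (p[2] == q[2] && p[3] <= q[3]))))
      paste(signif(c(p, q), 10), collapse = "/")
    else paste(signif(c(q, p), 10), collapse = "/")
  })
  unname(sort(key))
}

## Independent sign-enumeration oracle for the exact Wilcoxon signed rank
## (deliberately written differently from the package implementation).
wilcoxon_oracle <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Wall <- apply(grid, 1, function(s) sum(r[as.logical(s)]))
  p <- min(1, 2 * min(mean(Wall <= W + 1e-9), mean(Wall >= W - 1e-9)))
  list(statistic = W, p.value = p)
}

design_build <- function(acr) {
  memo(paste0("build_", acr), build_design_lattice(acr, voxel_size = 0.1))
}

substrate <- function(acr, h = 0.1) {
  ## share the package-level cache so cohort runs reuse the same builds
  osteoscaffold:::cached_substrate(acr, h)
}

cohort_run <- function(seed) {
  memo(paste0("cohort_", seed), run_cohort_analysis(seed = seed))
}

## A synthetic scored section: circular defect of radius R_px with a bone
## annulus spanning the given angular arc and radial band.
synthetic_section <- function(n = 121, R_px = 55, arc = c(0, 2 * pi),
                              band = c(51, 55), interior_fill = 0,
                              tier_px = 11, scaffold = NULL, seed = 1) {
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  ix <- rep(seq_len(n), n); iy <- rep(seq_len(n), each = n)
  rr <- sqrt((ix - ctr[1])^2 + (iy - ctr[2])^2)
  th <- atan2(iy - ctr[2], ix - ctr[1]) %% (2 * pi)
  defect <- matrix(rr <= R_px, n, n)
  bone <- matrix(rr >= band[1] & rr <= band[2] &
                   th >= arc[1] & th <= arc[2], n, n)
  if (interior_fill > 0) {
    set.seed(seed)
    interior <- rr < R_px - tier_px
    pick <- which(interior)
    bone[sample(pick, round(interior_fill * length(pick)))] <- TRUE
  }
  if (is.null(scaffold)) scaffold <- matrix(FALSE, n, n)
  structure(list(bone = bone, scaffold = scaffold, defect = defect,
                 depth_mm = 8, voxel_size = 0.1, center_px = ctr,
                 R_px = R_px, tier_px = tier_px),
            class = "section2d")
}
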