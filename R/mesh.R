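## Surface mesh export of strut lattices (binary STL + JSON sidecar).

## Tessellate one strut as a closed (capped) cylinder with n_seg side
## segments: 2*n_seg side triangles + 2*n_seg cap triangles.
strut_facets <- function(a, b, r, n_seg) {
  u <- b - a
  L <- sqrt(sum(u^2))
  x <- u / L
  ref <- if (abs(x[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * x) * x
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(x[2] * e1[3] - x[3] * e1[2],
          x[3] * e1[1] - x[1] * e1[3],
          x[1] * e1[2] - x[2] * e1[1])
  ang <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  ring <- t(vapply(ang, function(t0) cos(t0) * e1 + sin(t0) * e2,
                   numeric(3)))
  ra <- sweep(ring * r, 2, a, "+")
  rb <- sweep(ring * r, 2, b, "+")
  nxt <- c(seq_len(n_seg)[-1], 1L)
  tri <- vector("list", 4L * n_seg)
  k <- 0L
  for (i in seq_len(n_seg)) {
    j <- nxt[i]
    k <- k + 1L; tri[[k]] <- rbind(ra[i, ], rb[i, ], rb[j, ])
    k <- k + 1L; tri[[k]] <- rbind(ra[i, ], rb[j, ], ra[j, ])
    k <- k + 1L; tri[[k]] <- rbind(a, ra[j, ], ra[i, ])
    k <- k + 1L; tri[[k]] <- rbind(b, rb[i, ], rb[j, ])
  }
  tri
}

#' Export a lattice as a binary STL mesh
#'
#' Writes every strut as a closed capped-cylinder tessellation
#' (`4 * n_seg` triangles per strut) into a binary STL file, with unit
#' facet normals, plus a JSON sidecar (same path with extension
#' `.json`) recording the strut count, tessellation resolution and any
#' supplied design parameters.
#'
#' @param lattice a [lattice3d()]; must be non-empty.
#' @param path output STL path.
#' @param n_seg segments around each strut (default 12).
#' @param design optional [scaffold_design()] recorded in the sidecar.
#' @return invisibly, the facet count.
#' @export
export_mesh <- function(lattice, path, n_seg = 12, design = NULL) {
  if (nrow(lattice$struts) == 0) stop("cannot export an empty lattice")
  m <- nrow(lattice$struts)
  n_fac <- 4L * n_seg * m
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(raw(80), con)
  writeBin(as.integer(n_fac), con, size = 4, endian = "little")
  for (s in seq_len(m)) {
    a <- lattice$nodes[lattice$struts[s, 1], ]
    b <- lattice$nodes[lattice$struts[s, 2], ]
    tris <- strut_facets(a, b, lattice$radii[s], n_seg)
    for (tr in tris) {
      e1 <- tr[2, ] - tr[1, ]
      e2 <- tr[3, ] - tr[1, ]
      nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
               e1[3] * e2[1] - e1[1] * e2[3],
               e1[1] * e2[2] - e1[2] * e2[1])
      nn <- sqrt(sum(nrm^2))
      nrm <- if (nn > 0) nrm / nn else c(0, 0, 1)
      writeBin(as.numeric(c(nrm, t(tr))), con, size = 4,
               endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  sidecar <- sub("\\.stl$", ".json", path, ignore.case = TRUE)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  meta <- list(struts = m, nodes = nrow(lattice$nodes), n_seg = n_seg,
               facets = n_fac, material = lattice$material$name)
  if (!is.null(design))
    meta$design <- list(acronym = design$acronym,
                        generator = design$generator,
                        nominal_porosity = design$nominal_porosity,
                        unit_cell = design$unit_cell,
                        cylinder_diameter = design$cylinder_diameter,
                        cylinder_height = design$cylinder_height)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(n_fac)
}

#' Read the facet count and normals of a binary STL file
#'
#' Minimal reader used for round-trip checks: returns the facet count
#' and the n x 3 matrix of facet normals.
#'
#' @param path STL file path.
#' @return list with `n_facets` and `normals`.
#' @export
read_stl_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  normals <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    normals[i, ] <- rec[1:3]
    invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
  }
  list(n_facets = n, normals = normals)
}
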