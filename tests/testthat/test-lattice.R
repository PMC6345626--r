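test_that("octet cell reproduces the brute-force FCC edge enumeration", {
  l <- generate_octetruss(unit_box(1), 1, 0.1, mat_pa())
  expect_identical(lattice_edge_keys(l), octet_cell_edges_oracle(1))
  ## all strut lengths are the FCC nearest-neighbour distance
  expect_true(all(abs(strut_lengths(l) - 1 / sqrt(2)) < 1e-12))
})

test_that("octet tiling grows monotonically with the box", {
  l1 <- generate_octetruss(unit_box(2), 1, 0.1, mat_pa())
  l2 <- generate_octetruss(rbind(c(0, 0, 0), c(4, 2, 2)), 1, 0.1, mat_pa())
  expect_gt(nrow(l2$struts), nrow(l1$struts))
  k1 <- apply(round(l1$nodes, 9), 1, paste, collapse = "/")
  k2 <- apply(round(l2$nodes, 9), 1, paste, collapse = "/")
  expect_true(all(k1 %in% k2))
})

test_that("cubic grid has the exact closed-form node and strut counts", {
  for (n in 1:3) {
    l <- generate_cubic(unit_box(n), 1, 0.1, mat_pa())
    expect_equal(nrow(l$nodes), (n + 1)^3)
    expect_equal(nrow(l$struts), 3 * n * (n + 1)^2)
    ## every strut axis-aligned with unit length
    d <- abs(l$nodes[l$struts[, 1], ] - l$nodes[l$struts[, 2], ])
    expect_true(all(rowSums(d > 1e-12) == 1))
    expect_true(all(abs(strut_lengths(l) - 1) < 1e-12))
  }
})

test_that("generators reject degenerate domains and bad radii", {
  expect_error(generate_cubic(rbind(c(0, 0, 0), c(0.5, 2, 2)), 1, 0.1,
                              mat_pa()), "degenerate")
  expect_error(generate_octetruss(unit_box(0.5), 1, 0.1, mat_pa()),
               "degenerate")
  expect_error(generate_octetruss(unit_box(2), 1, 0.6, mat_pa()), "radius")
})

test_that("lattice3d enforces its invariants", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_error(lattice3d(nodes, rbind(c(1, 1)), 0.1, mat_pa()), "self")
  expect_error(lattice3d(nodes, rbind(c(1, 2), c(2, 1)), 0.1, mat_pa()),
               "duplicate")
  expect_error(lattice3d(nodes, rbind(c(1, 3)), 0.1, mat_pa()),
               "out of range")
  expect_error(lattice3d(nodes, rbind(c(1, 2)), -1, mat_pa()), "radii")
})

test_that("stochastic lattice meets degree, spacing and determinism contracts", {
  bx <- rbind(c(0, 0, 0), c(10, 10, 10))
  l <- generate_stochastic(bx, n_points = 800, seed = 42)
  deg <- node_degrees(l)
  expect_lt(abs(mean(deg) - 4.5), 0.1)
  ## single connected component
  comps <- igraph::components(igraph::graph_from_edgelist(l$struts,
                                                          directed = FALSE))
  expect_equal(comps$no, 1L)
  ## Poisson-disk minimum distance holds for all pairs
  rmin <- 0.7 * (1000 / 800)^(1 / 3)
  dmin <- min(dist(l$nodes))
  expect_gte(dmin, rmin - 1e-9)
  ## bit-identical reproduction under the same seed
  expect_identical(l, generate_stochastic(bx, n_points = 800, seed = 42))
  expect_false(identical(l, generate_stochastic(bx, n_points = 800,
                                                seed = 43)))
})

test_that("infeasible stochastic targets raise packing/connectivity errors", {
  bx <- unit_box(3)
  expect_error(generate_stochastic(bx, n_points = 27,
                                   target_connectivity = 26, seed = 1),
               "connectivity error")
  expect_error(generate_stochastic(bx, n_points = 5, seed = 1), ">= 10")
})

test_that("cylinder trim clips, preserves length monotonicity and is idempotent", {
  l <- generate_octetruss(rbind(c(-3, -3, -3), c(3, 3, 3)), 1, 0.1, mat_pa())
  ## enclosing cylinder leaves the lattice unchanged (same totals)
  big <- trim_to_cylinder(l, 20, 20)
  expect_equal(sum(strut_lengths(big)), sum(strut_lengths(l)), tolerance = 1e-9)
  tr <- trim_to_cylinder(l, 4, 4)
  expect_lt(sum(strut_lengths(tr)), sum(strut_lengths(l)))
  ## all retained geometry inside the cylinder
  expect_true(all(sqrt(rowSums(tr$nodes[, 1:2]^2)) <= 2 + 1e-9))
  expect_true(all(abs(tr$nodes[, 3]) <= 2 + 1e-9))
  ## idempotence
  tr2 <- trim_to_cylinder(tr, 4, 4, center = c(0, 0, 0))
  expect_equal(sum(strut_lengths(tr2)), sum(strut_lengths(tr)),
               tolerance = 1e-9)
  expect_equal(nrow(tr2$struts), nrow(tr$struts))
  ## empty intersection errors
  expect_error(trim_to_cylinder(l, 4, 4, center = c(100, 0, 0)),
               "degenerate")
})
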