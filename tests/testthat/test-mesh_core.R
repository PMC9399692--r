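# core mesh geometry: areas, centroids, volume, boundaries, watertightness

test_that("surface_area handles planar, degenerate and spherical patches", {
  sq <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)), "square")
  expect_equal(surface_area(surface_patch(sq, 1:2, "origin")), 1.0)

  degen <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                   rbind(c(1, 2, 3)), "degen")
  expect_equal(surface_area(surface_patch(degen, 1, "origin")), 0.0)

  for (k in 1:3) {
    sp <- icosphere(radius = 10, subdiv = k)
    a <- mesh_surface_area(sp)
    expect_equal(a, brute_force_area(sp), tolerance = 1e-12)
    expect_lt(a, 4 * pi * 100)          # inscribed polyhedron
    if (k > 1) expect_gt(a, a_prev)     # monotone approach
    a_prev <- a
  }
  expect_rel(a_prev, 4 * pi * 100, 0.01)

  expect_error(surface_patch(sq, integer(0), "origin"), "empty selection")
})

test_that("area_weighted_centroid matches symmetry and Monte-Carlo oracles", {
  sq <- trimesh(rbind(c(-0.5, -0.5, 0), c(0.5, -0.5, 0), c(0.5, 0.5, 0),
                      c(-0.5, 0.5, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)), "square")
  expect_equal(area_weighted_centroid(surface_patch(sq, 1:2, "origin")),
               c(0, 0, 0))

  tri <- trimesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                 rbind(c(1, 2, 3)), "tri")
  expect_equal(area_weighted_centroid(surface_patch(tri, 1, "origin")),
               c(1, 1, 0))

  set.seed(42)
  sp <- icosphere(radius = 5, subdiv = 3)
  cap <- which(face_z <- vapply(seq_len(nrow(sp$faces)), function(i)
    mean(sp$vertices[sp$faces[i, ], 3]), numeric(1)) > 2)
  patch <- surface_patch(sp, cap, "origin")
  got <- area_weighted_centroid(patch)
  mc <- mc_patch_centroid(sp, cap, n = 40000)
  expect_lt(sqrt(sum((got - mc)^2)), 0.05)   # MC sampling error at n=4e4

  # centroid lies in the convex hull of the patch vertices (bounding box
  # relaxation of the hull property)
  pv <- sp$vertices[unique(as.vector(sp$faces[cap, ])), ]
  expect_true(all(got >= apply(pv, 2, min) & got <= apply(pv, 2, max)))

  degen <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                   rbind(c(1, 2, 3)), "degen")
  expect_error(area_weighted_centroid(surface_patch(degen, 1, "origin")),
               "degenerate patch")
})

test_that("enclosed_volume: cube exact, rigid-invariant, voxel oracle", {
  cu <- cube_mesh()
  expect_equal(enclosed_volume(cu), 1.0)
  expect_equal(enclosed_volume(cube_mesh(at = c(100, -50, 7))), 1.0)

  set.seed(7)
  for (rep in 1:3) {
    R <- rand_rotation(); t <- rnorm(3, sd = 50)
    m <- transform_mesh(icosphere(radius = 5, subdiv = 2), R, t)
    expect_rel(enclosed_volume(m),
               enclosed_volume(icosphere(radius = 5, subdiv = 2)), 1e-9)
    expect_rel(mesh_surface_area(m),
               mesh_surface_area(icosphere(radius = 5, subdiv = 2)), 1e-9)
  }

  vols <- vapply(1:3, function(k)
    enclosed_volume(icosphere(radius = 5, subdiv = k)), numeric(1))
  expect_true(all(diff(vols) > 0))               # monotone approach
  expect_true(all(vols < 4 / 3 * pi * 125))
  expect_rel(vols[3], 4 / 3 * pi * 125, 0.01)
  # independent voxel-count oracle at its own resolution
  expect_rel(vols[2], voxel_volume(icosphere(radius = 5, subdiv = 2), 40),
             0.05)

  open <- trimesh(cu$vertices, cu$faces[-1, ], "open")
  expect_error(enclosed_volume(open), "open mesh")
})

test_that("is_watertight detects closure, holes and disjoint components", {
  cu <- cube_mesh()
  expect_true(is_watertight(cu))
  expect_false(is_watertight(trimesh(cu$vertices, cu$faces[-1, ], "open")))
  two <- merge_two <- trimesh(
    rbind(icosphere(1, 1)$vertices, icosphere(1, 1, center = c(5, 0, 0))$vertices),
    rbind(icosphere(1, 1)$faces, icosphere(1, 1)$faces + nrow(icosphere(1, 1)$vertices)),
    "two_spheres")
  expect_true(is_watertight(two))
  # per-edge incidence oracle agrees
  f <- two$faces
  key <- paste(pmin(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])),
               pmax(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])))
  expect_true(all(table(key) == 2))
})

test_that("extract_boundary_loops: triangle, annulus, icosphere cap", {
  tri <- trimesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                 rbind(c(1, 2, 3)), "tri")
  loops <- extract_boundary_loops(surface_patch(tri, 1, "origin"))
  expect_length(loops, 1)
  expect_equal(nrow(loops[[1]]$points), 3)

  # annulus: 4x4 cell grid minus the central 2x2 cells -> 2 loops
  pg <- plane_grid(4)
  centre_cells <- c(6, 7, 10, 11)
  keep <- which(!pg$cell %in% centre_cells)
  suppressWarnings(patch <- surface_patch(pg$mesh, keep, "origin"))
  loops <- extract_boundary_loops(patch)
  expect_length(loops, 2)
  expect_gt(loop_per <- sum(sqrt(rowSums((diff(rbind(loops[[1]]$points,
    loops[[1]]$points[1, ])))^2))), 15.9)     # outer (16) sorted first

  # simply-connected cap on an icosphere: one loop; its edge set equals the
  # once-used-edge oracle
  sp <- icosphere(radius = 5, subdiv = 2)
  cap <- which(vapply(seq_len(nrow(sp$faces)), function(i)
    mean(sp$vertices[sp$faces[i, ], 3]), numeric(1)) > 1.5)
  patch <- surface_patch(sp, cap, "origin")
  loops <- extract_boundary_loops(patch)
  expect_length(loops, 1)
  ring <- loops[[1]]$vertex_ids
  loop_edges <- paste(pmin(ring, c(ring[-1], ring[1])),
                      pmax(ring, c(ring[-1], ring[1])))
  expect_setequal(loop_edges, boundary_edge_set(sp, cap))

  # every loop point has exactly two incident loop edges (closure)
  expect_equal(anyDuplicated(ring), 0)

  expect_error(
    extract_boundary_loops(surface_patch(sp, seq_len(nrow(sp$faces)),
                                         "origin")),
    "no boundary")
})

test_that("align_boundary_to_plane recovers pose-independent 2D shape", {
  th <- 2 * pi * (0:63) / 64
  # circle of radius 2 in the YZ plane
  circ <- list(points = cbind(0, 2 * cos(th), 2 * sin(th)))
  p <- align_boundary_to_plane(circ)
  expect_equal(max(abs(sqrt(rowSums(p$points2d^2)) - 2)), 0,
               tolerance = 1e-12)

  # ellipse a=4 b=2, arbitrary pose: semi-axes recovered on plane axes
  set.seed(11)
  R <- rand_rotation()
  ell <- cbind(4 * cos(th), 2 * sin(th), 0) %*% t(R)
  ell <- sweep(ell, 2, c(3, -8, 2), `+`)
  p <- align_boundary_to_plane(list(points = ell))
  expect_equal(max(abs(p$points2d[, 1])), 4, tolerance = 1e-9)
  expect_equal(max(abs(p$points2d[, 2])), 2, tolerance = 1e-9)
  # deterministic orientation: CCW and non-negative first coordinate of the
  # first point
  expect_gt(shoelace(p$points2d), 0)
  expect_gte(p$points2d[1, 1], 0)
  # transform round-trip restores world coordinates
  back <- sweep(p$points2d %*% t(p$axes[, 1:2]), 2, p$origin, `+`)
  expect_lt(max(abs(back - ell)), 1e-9)

  # slightly non-planar saddle: projected area <= 3D area, equal to an
  # independent least-squares plane fit projection
  saddle <- cbind(cos(th), sin(th), 0.2 * sin(2 * th))
  p <- align_boundary_to_plane(list(points = saddle))
  a_pkg <- shoelace(p$points2d)
  ev <- eigen(stats::cov(saddle))            # independent plane fit
  nrm <- ev$vectors[, 3]
  basis <- qr.Q(qr(cbind(nrm, diag(3)[, 1:2])))[, 2:3]
  q2 <- sweep(saddle, 2, colMeans(saddle)) %*% basis
  expect_equal(a_pkg, abs(shoelace(q2)), tolerance = 1e-8)
  expect_lte(a_pkg, brute_force_area(trimesh(
    rbind(colMeans(saddle), saddle),
    cbind(1, 1 + seq_len(64), 1 + c(2:64, 1)), "fan")))

  line <- list(points = cbind(0:5, 0, 0))
  expect_error(align_boundary_to_plane(line), "degenerate boundary")
})
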