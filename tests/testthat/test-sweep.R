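# cross-section resampling, moving frames, and the sweep generator

test_that("resample_loop spaces points by arc length and preserves shape", {
  th <- 2 * pi * (0:63) / 64
  circ64 <- cbind(cos(th), sin(th))
  r <- resample_loop(circ64, 64)
  expect_rel(abs(shoelace(r)), pi, 0.005)

  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  r8 <- resample_loop(sq, 8)
  expect_equal(ring_perimeter(r8), 8.0)     # corners + midpoints exactly

  set.seed(5)
  for (rep in 1:5) {
    k <- sample(5:30, 1)
    a <- sort(runif(k, 0, 2 * pi))
    poly <- cbind(cos(a), sin(a)) * runif(k, 0.5, 1.5)
    n <- sample(3:50, 1)
    expect_lte(ring_perimeter(resample_loop(poly, n)),
               ring_perimeter(poly) + 1e-12)   # chord shortening
  }

  expect_error(resample_loop(circ64, 2), "ring vertices")
})

test_that("rotation-minimizing frames carry no twist", {
  # straight curve: all frames identical
  cl <- default_centerline(c(0, 0, 0), c(10, 0, 0), 16)
  fr <- build_frames(cl)
  expect_lt(max(abs(sweep(fr$e1, 2, fr$e1[1, ]))), 1e-12)
  expect_lt(max(abs(sweep(fr$tangents, 2, c(1, 0, 0)))), 1e-12)

  # planar quarter circle: out-of-plane axis transported without rotation
  th <- seq(0, pi / 2, length.out = 65)
  qc <- centerline(cbind(20 * cos(th), 0, 20 * sin(th)), 65)
  fr <- build_frames(qc, e1_init = c(0, 1, 0))
  expect_lt(max(abs(fr$e1 %*% c(1, 0, 0))), 1e-9)   # e1 stays out-of-plane
  expect_lt(max(abs(fr$e1 %*% c(0, 0, 1))), 1e-9)
  # orthonormality
  expect_lt(max(abs(rowSums(fr$e1 * fr$tangents))), 1e-9)
  expect_lt(max(abs(rowSums(fr$e1^2) - 1)), 1e-9)

  # s-curve with an inflection: Frenet normals flip, RMF axes do not
  t <- seq(-2, 2, length.out = 101)
  s <- cbind(t, sin(t), 0)
  cl <- centerline(s, 101)
  fr <- build_frames(cl)
  rmf_steps <- rowSums(fr$e1[-1, ] * fr$e1[-101, ])
  expect_true(all(rmf_steps > 0.99))
  d1 <- diff(cl$samples); d2 <- diff(d1)
  nrm <- sqrt(rowSums(d2^2))
  frenet_n <- (d2 / nrm)[nrm > 1e-9, ]     # drop the inflection itself
  frenet_steps <- rowSums(frenet_n[-1, ] * frenet_n[-nrow(frenet_n), ])
  expect_lt(min(frenet_steps), 0)          # the flip RMF avoids
})

test_that("sweep reproduces cylinder, cone and Pappus volumes", {
  sc <- make_parallel_plates(radius = 3, gap = 20)
  cyl <- build_fixture_muscles(sc)[[1]]
  expect_true(is_watertight(cyl$mesh))
  expect_rel(enclosed_volume(cyl$mesh), pi * 9 * 20, 0.02)
  expect_equal(nrow(cyl$ring_ids), cyl$curve$n_samples)

  # cone: insertion shrunk to a point-like patch, linear blend
  pa <- coin_plate(c(0, 0, 0), c(0, 0, 1), 3, k = 64, name = "po")
  pb <- coin_plate(c(0, 0, 20), c(0, 0, -1), 3e-4, k = 64, name = "pi")
  o <- surface_patch(pa$mesh, pa$patch_faces, "origin", "cone")
  i <- surface_patch(pb$mesh, pb$patch_faces, "insertion", "cone")
  cl <- default_centerline(area_weighted_centroid(o),
                           area_weighted_centroid(i))
  cone <- sweep_muscle(o, i, cl, sweep_params(64), name = "cone")
  expect_true(is_watertight(cone$mesh))
  expect_rel(enclosed_volume(cone$mesh), pi * 9 * 20 / 3, 0.03)

  # origin_only blend keeps the origin cross-section all the way
  tube <- sweep_muscle(o, i, cl, sweep_params(64, blend = "origin_only"),
                       name = "tube")
  expect_rel(enclosed_volume(tube$mesh), pi * 9 * 20, 0.02)

  # quarter-circle centerline: Pappus volume and curve length
  cc <- make_curved_channel(radius_curve = 20, radius_xsec = 2)
  curved <- build_fixture_muscles(cc)[[1]]
  expect_true(is_watertight(curved$mesh))
  expect_rel(enclosed_volume(curved$mesh), pi * 4 * (pi * 20 / 2), 0.03)
  expect_rel(curve_length(curved$curve), 31.4159, 0.01)
})

test_that("sweep output is invariant under rigid motion of the scene", {
  set.seed(9)
  R <- rand_rotation(); tr <- rnorm(3, sd = 30)
  base <- make_parallel_plates(radius = 3, gap = 20)
  m0 <- build_fixture_muscles(base)[[1]]

  rot <- lapply(base$muscle_specs[[1]][c("origin", "insertion")], function(p)
    surface_patch(transform_mesh(p$mesh, R, tr), p$face_ids, p$role,
                  p$muscle))
  cl <- default_centerline(area_weighted_centroid(rot$origin),
                           area_weighted_centroid(rot$insertion))
  m1 <- sweep_muscle(rot$origin, rot$insertion, cl, sweep_params(),
                     name = "cyl")
  expect_rel(enclosed_volume(m1$mesh), enclosed_volume(m0$mesh), 1e-6)
  expect_rel(surface_area(m1$origin), surface_area(m0$origin), 1e-9)
  expect_rel(curve_length(m1$curve), curve_length(m0$curve), 1e-9)
})

test_that("scale_ring scales sections locally and protects the ends", {
  sc <- make_parallel_plates()
  m <- build_fixture_muscles(sc)[[1]]
  v0 <- enclosed_volume(m$mesh)

  expect_equal(enclosed_volume(scale_ring(m, 16, 1)$mesh), v0)
  expect_gt(enclosed_volume(scale_ring(m, 16, 2)$mesh), v0)
  expect_true(is_watertight(scale_ring(m, 16, 2)$mesh))

  # scaling every interior ring by s approaches the s^2 volume ratio as
  # ring density grows (ends stay pinned to the attachments)
  ratio_at <- function(n_samples) {
    cl <- default_centerline(c(0, 0, 0), c(0, 0, 20), n_samples)
    sp <- sc$muscle_specs[[1]]
    mm <- sweep_muscle(sp$origin, sp$insertion, cl, sweep_params(),
                       name = "cyl")
    v1 <- enclosed_volume(mm$mesh)
    for (k in 2:(n_samples - 1)) mm <- scale_ring(mm, k, 1.5)
    enclosed_volume(mm$mesh) / v1
  }
  r32 <- ratio_at(32); r96 <- ratio_at(96)
  expect_lt(abs(r96 - 1.5^2), abs(r32 - 1.5^2))
  expect_rel(r96, 1.5^2, 0.02)

  expect_error(scale_ring(m, 1, 2), "fixed")
  expect_error(scale_ring(m, nrow(m$ring_ids), 2), "fixed")
  expect_error(scale_ring(m, 16, 0), "positive")
})
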