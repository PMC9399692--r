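#' Closed "coin" plate with a circular attachment patch
#'
#' A watertight disc-shaped plate whose front face carries a fan-triangulated
#' circular patch of radius `r_patch` centred on `center`.  The plate body
#' extends behind the front face (opposite `normal`), so a muscle swept off
#' the patch leaves the plate cleanly.
#'
#' @param center patch centre (length-3, mm).
#' @param normal unit outward normal of the patch face.
#' @param r_patch patch radius (mm).
#' @param r_plate plate radius (mm), > `r_patch`.
#' @param thickness plate thickness (mm).
#' @param k segments around the circumference.
#' @param name mesh name.
#' @return list with `mesh` (watertight [trimesh()]) and `patch_faces`
#'   (1-based ids of the k patch triangles).
#' @export
coin_plate <- function(center, normal, r_patch, r_plate = 2 * r_patch,
                       thickness = max(0.5, r_patch / 4), k = 64L,
                       name = "plate") {
  if (r_plate <= r_patch) stop("r_plate must exceed r_patch")
  th <- 2 * pi * (seq_len(k) - 1) / k
  ring_r <- cbind(r_patch * cos(th), r_patch * sin(th), 0)
  ring_R <- cbind(r_plate * cos(th), r_plate * sin(th), 0)
  ring_B <- cbind(r_plate * cos(th), r_plate * sin(th), -thickness)
  v <- rbind(c(0, 0, 0), ring_r, ring_R, ring_B, c(0, 0, -thickness))
  ctop <- 1L
  i_r <- 1L + seq_len(k)
  i_R <- 1L + k + seq_len(k)
  i_B <- 1L + 2L * k + seq_len(k)
  cbot <- 2L + 3L * k
  nx <- c(2:k, 1)
  faces <- rbind(
    cbind(ctop, i_r, i_r[nx]),            # patch fan (front, +z)
    cbind(i_r, i_R, i_R[nx]),             # annulus
    cbind(i_r, i_R[nx], i_r[nx]),
    cbind(i_R, i_B, i_B[nx]),             # side wall
    cbind(i_R, i_B[nx], i_R[nx]),
    cbind(cbot, i_B[nx], i_B))            # back fan (-z)
  normal <- normal / sqrt(sum(normal^2))
  R <- rotation_between(c(0, 0, 1), normal)
  v <- sweep(v %*% t(R), 2, as.numeric(center), `+`)
  mesh <- trimesh(v, faces, name)
  list(mesh = mesh, patch_faces = seq_len(k))
}

new_fixture_scene <- function(name, bones, muscle_specs, expected, seed,
                              muscles = NULL) {
  structure(list(name = name, bones = bones, muscle_specs = muscle_specs,
                 expected = expected, seed = as.integer(seed),
                 muscles = muscles),
            class = "fixture_scene")
}

#' @export
print.fixture_scene <- function(x, ...) {
  cat(sprintf("<fixture_scene '%s': %d bones, %d muscles, %d expected>\n",
              x$name, length(x$bones), length(x$muscle_specs),
              length(x$expected)))
  invisible(x)
}

#' Parallel-plates cylinder fixture
#'
#' Two coin plates facing each other across `gap`, each carrying a circular
#' attachment patch of radius `radius`.  Sweeping between them yields a
#' straight cylindrical muscle with closed-form area, length and volume.
#' Fully deterministic (no randomness; `seed` is recorded only).
#'
#' @param radius patch radius (mm), default 3.
#' @param gap plate separation (mm), default 20.
#' @param resolution segments around the patch circle, default 64.
#' @param seed recorded seed (unused; generation is deterministic).
#' @return a `fixture_scene`; `expected` holds analytic values with
#'   tolerances (`patch_area` 2%, `volume` 2%, lengths 1e-6 relative).
#' @export
make_parallel_plates <- function(radius = 3, gap = 20, resolution = 64L,
                                 seed = 0L) {
  stopifnot(radius > 0, gap > 0)
  pa <- coin_plate(c(0, 0, 0), c(0, 0, 1), radius, k = resolution,
                   name = "plate_origin")
  pb <- coin_plate(c(0, 0, gap), c(0, 0, -1), radius, k = resolution,
                   name = "plate_insertion")
  origin <- surface_patch(pa$mesh, pa$patch_faces, "origin", muscle = "cyl")
  insertion <- surface_patch(pb$mesh, pb$patch_faces, "insertion",
                             muscle = "cyl")
  curve <- default_centerline(area_weighted_centroid(origin),
                              area_weighted_centroid(insertion))
  expected <- list(
    patch_area = list(value = pi * radius^2, tol = 0.02),
    origin_centroid = list(value = c(0, 0, 0), tol = 1e-9),
    linear_length = list(value = gap, tol = 1e-9),
    muscle_length = list(value = gap, tol = 1e-9),
    volume = list(value = pi * radius^2 * gap, tol = 0.02))
  new_fixture_scene("parallel_plates", list(pa$mesh, pb$mesh),
                    list(list(name = "cyl", origin = origin,
                              insertion = insertion, curve = curve)),
                    expected, seed)
}

#' Quarter-circle curved-channel fixture
#'
#' Attachments oriented so the natural centerline is a quarter circle of
#' radius `radius_curve` with circular cross-section `radius_xsec`,
#' exercising the divergence between curved and linear muscle length
#' (closed forms: curved pi*R/2, linear R*sqrt(2), volume by Pappus).
#'
#' @param radius_curve centerline radius (mm), default 20.
#' @param radius_xsec cross-section radius (mm), default 2; must be smaller
#'   than `radius_curve`.
#' @param resolution segments around the patch circle, default 64.
#' @param seed recorded seed (unused; generation is deterministic).
#' @return a `fixture_scene`.
#' @export
make_curved_channel <- function(radius_curve = 20, radius_xsec = 2,
                                resolution = 64L, seed = 0L) {
  if (radius_curve <= radius_xsec)
    stop("radius_curve must exceed radius_xsec")
  R <- radius_curve
  pa <- coin_plate(c(R, 0, 0), c(0, 0, 1), radius_xsec, k = resolution,
                   name = "plate_origin")
  pb <- coin_plate(c(0, 0, R), c(1, 0, 0), radius_xsec, k = resolution,
                   name = "plate_insertion")
  origin <- surface_patch(pa$mesh, pa$patch_faces, "origin",
                          muscle = "curved")
  insertion <- surface_patch(pb$mesh, pb$patch_faces, "insertion",
                             muscle = "curved")
  th <- seq(0, pi / 2, length.out = 9)
  arc <- cbind(R * cos(th), 0, R * sin(th))
  curve <- centerline(arc, n_samples = 64L)
  expected <- list(
    curved_length = list(value = pi * R / 2, tol = 0.01),
    linear_length = list(value = R * sqrt(2), tol = 1e-6),
    length_ratio = list(value = (pi / 2) / sqrt(2), tol = 0.01),
    volume = list(value = pi * radius_xsec^2 * (pi * R / 2), tol = 0.03))
  new_fixture_scene("curved_channel", list(pa$mesh, pb$mesh),
                    list(list(name = "curved", origin = origin,
                              insertion = insertion, curve = curve)),
                    expected, seed)
}

#' Overlapping congruent-cylinder pair fixture
#'
#' Two congruent cylindrical muscles with parallel axes offset laterally by
#' `offset`; their intersection volume has the circular-segment ("lens")
#' closed form, exercising [resolve_overlaps()].
#'
#' @param offset lateral axis separation (mm); must be < 2*`radius` for the
#'   muscles to intersect.  Default 2.
#' @param radius cylinder radius (mm), default 3.
#' @param gap cylinder length (mm), default 20.
#' @param resolution segments around the patch circle, default 64.
#' @param seed recorded seed (unused; generation is deterministic).
#' @return a `fixture_scene` whose `muscles` element holds the two built
#'   `muscle_model`s (named A and B); `bones` is empty.
#' @export
make_overlap_pair <- function(offset = 2, radius = 3, gap = 20,
                              resolution = 64L, seed = 0L) {
  stopifnot(offset >= 0, radius > 0, gap > 0)
  build_one <- function(x0, nm) {
    pa <- coin_plate(c(x0, 0, 0), c(0, 0, 1), radius, k = resolution,
                     name = paste0("plate_", nm, "_o"))
    pb <- coin_plate(c(x0, 0, gap), c(0, 0, -1), radius, k = resolution,
                     name = paste0("plate_", nm, "_i"))
    origin <- surface_patch(pa$mesh, pa$patch_faces, "origin", muscle = nm)
    insertion <- surface_patch(pb$mesh, pb$patch_faces, "insertion",
                               muscle = nm)
    curve <- default_centerline(area_weighted_centroid(origin),
                                area_weighted_centroid(insertion))
    sweep_muscle(origin, insertion, curve, sweep_params(resolution),
                 name = nm)
  }
  mA <- build_one(0, "A")
  mB <- build_one(offset, "B")
  d <- offset; r <- radius
  lens <- if (d >= 2 * r) 0 else
    2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  expected <- list(
    intersection_volume = list(value = lens * gap, tol = 0.02),
    cylinder_volume = list(value = pi * r^2 * gap, tol = 0.02))
  specs <- list(
    list(name = "A", origin = mA$origin, insertion = mA$insertion,
         curve = mA$curve),
    list(name = "B", origin = mB$origin, insertion = mB$insertion,
         curve = mB$curve))
  new_fixture_scene("overlap_pair", list(), specs, expected, seed,
                    muscles = list(A = mA, B = mB))
}

#' Build the muscle models of a fixture scene
#'
#' @param scene a `fixture_scene`.
#' @param params a [sweep_params()].
#' @return named list of `muscle_model`s.
#' @export
build_fixture_muscles <- function(scene, params = sweep_params()) {
  out <- lapply(scene$muscle_specs, function(sp)
    sweep_muscle(sp$origin, sp$insertion, sp$curve, params, name = sp$name))
  stats::setNames(out, vapply(scene$muscle_specs, `[[`, "", "name"))
}

#' Write a fixture scene to disk
#'
#' Writes every mesh as OBJ (bones plus any attachment-bearing plates not
#' listed as bones), each attachment selection as JSON, the expected-values
#' table as JSON, and a ready-to-run `config.json` for [run_generate()].
#'
#' @param scene a `fixture_scene`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meshes <- scene$bones
  for (sp in scene$muscle_specs)
    for (p in list(sp$origin, sp$insertion))
      if (!p$mesh$name %in% vapply(meshes, `[[`, "", "name"))
        meshes[[length(meshes) + 1]] <- p$mesh
  for (b in meshes)
    write_mesh(b, file.path(dir, paste0(b$name, ".obj")))
  sel_files <- character(0)
  for (sp in scene$muscle_specs) {
    for (role in c("origin", "insertion")) {
      fn <- paste0(sp$name, "_", role, ".json")
      write_selection(sp[[role]], file.path(dir, fn))
      sel_files <- c(sel_files, fn)
    }
  }
  jsonlite::write_json(scene$expected,
                       file.path(dir, "expected.json"),
                       auto_unbox = TRUE, digits = NA)
  # non-straight fixture centerlines are encoded as control-point offsets
  # from the default straight curve, so run_generate() reproduces them
  mus <- list()
  n_samples <- 32L
  for (sp in scene$muscle_specs) {
    cp <- sp$curve$control_points
    k <- nrow(cp)
    n_samples <- max(n_samples, sp$curve$n_samples)
    if (k > 2) {
      t <- seq(0, 1, length.out = k)
      straight <- outer(1 - t, cp[1, ]) + outer(t, cp[k, ])
      offs <- lapply(2:(k - 1), function(i)
        c(i, cp[i, ] - straight[i, ]))
      mus[[length(mus) + 1]] <- list(name = sp$name, control_points = k,
                                     offsets = offs)
    }
  }
  cfg <- list(
    bones = paste0(vapply(meshes, `[[`, "", "name"), ".obj"),
    selections = sel_files,
    muscles = mus,
    sweep = list(ring_vertex_count = 64L, blend = "linear_blend",
                 n_samples = n_samples),
    priority = vapply(scene$muscle_specs, `[[`, "", "name"),
    stress = 0.3, resolution = 96L, seed = scene$seed)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
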