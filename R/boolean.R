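#' Boolean evaluation lattice
#'
#' Regular lattice covering a set of meshes, on which signed-distance fields
#' are sampled for Boolean operations.  The spacing is the longest
#' bounding-box extent divided by `resolution`; a padding margin and a small
#' irrational offset (to dodge symmetric degeneracies) are applied.
#'
#' @param meshes list of [trimesh()] objects the lattice must cover.
#' @param resolution cells along the longest axis (default 96).
#' @param pad padding cells on every side.
#' @return list with `origin`, `h`, `dims` (grid points per axis).
#' @export
boolean_grid <- function(meshes, resolution = 96L, pad = 4L) {
  vs <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  lo <- apply(vs, 2, min); hi <- apply(vs, 2, max)
  h <- max(hi - lo) / resolution
  if (h <= 0) stop("degenerate scene bounding box")
  origin <- lo - pad * h - 0.1234567890 * h
  dims <- as.integer(ceiling((hi - origin) / h)) + pad + 1L
  list(origin = as.numeric(origin), h = h, dims = dims)
}

mesh_field <- function(mesh, grid) {
  cpp_sdf_grid(mesh$vertices, mesh$faces - 1L, grid$origin, grid$h,
               grid$dims)
}

field_to_mesh <- function(field, grid, name) {
  if (all(field <= 0))
    return(trimesh(matrix(0, 0, 3), matrix(0L, 0, 3), name,
                   validate = FALSE))
  res <- cpp_marching_tets(field, grid$dims, grid$origin, grid$h)
  trimesh(res$vertices, res$faces, name, validate = FALSE)
}

bbox_overlap <- function(a, b, margin = 0) {
  la <- apply(a$vertices, 2, min); ha <- apply(a$vertices, 2, max)
  lb <- apply(b$vertices, 2, min); hb <- apply(b$vertices, 2, max)
  all(la <= hb + margin) && all(lb <= ha + margin)
}

require_watertight <- function(mesh, what) {
  if (!is_watertight(mesh))
    stop(sprintf("%s '%s' is not watertight: Boolean undefined for %s",
                 what, mesh$name, "open meshes"))
}

#' Volume of the Boolean intersection of two watertight meshes
#'
#' @param a,b watertight [trimesh()] objects.
#' @param grid optional [boolean_grid()]; built from the pair when missing.
#' @param resolution lattice resolution when `grid` is missing.
#' @return intersection volume in mm^3 (0 when disjoint).
#' @export
intersection_volume <- function(a, b, grid = NULL, resolution = 96L) {
  require_watertight(a, "mesh"); require_watertight(b, "mesh")
  if (!bbox_overlap(a, b)) return(0)
  if (is.null(grid)) grid <- boolean_grid(list(a, b), resolution)
  fab <- pmin(mesh_field(a, grid), mesh_field(b, grid))
  if (all(fab <= 0)) return(0)
  enclosed_volume(field_to_mesh(fab, grid, "intersection"))
}

#' Boolean difference of two watertight meshes
#'
#' Subtracts `cutter` from `target` by contouring the combined
#' signed-distance field \eqn{\min(f_{target}, -f_{cutter})}.  A disjoint
#' cutter returns the target unchanged (no remeshing).  If the difference
#' splits into several components the largest is kept with a warning.
#'
#' @param target,cutter watertight [trimesh()] objects.
#' @param grid optional [boolean_grid()]; built from the pair when missing.
#' @param resolution lattice resolution when `grid` is missing.
#' @param keep_largest keep only the largest connected component if the
#'   difference is disconnected.
#' @return a watertight [trimesh()].
#' @export
subtract <- function(target, cutter, grid = NULL, resolution = 96L,
                     keep_largest = TRUE) {
  require_watertight(target, "target"); require_watertight(cutter, "cutter")
  if (!bbox_overlap(target, cutter)) return(target)
  if (is.null(grid)) grid <- boolean_grid(list(target, cutter), resolution)
  ft <- mesh_field(target, grid)
  fc <- mesh_field(cutter, grid)
  if (all(pmin(ft, fc) <= 0)) return(target)   # overlap below lattice scale
  out <- field_to_mesh(pmin(ft, -fc), grid, target$name)
  if (nrow(out$faces) == 0)
    stop(sprintf("subtract: cutter '%s' removes all of '%s'",
                 cutter$name, target$name))
  if (keep_largest) out <- largest_component(out)
  if (!is_watertight(out))
    stop("Boolean difference produced a non-watertight mesh; ",
         "retry with higher resolution or jittered inputs")
  out
}

#' Split a mesh into face-connected components
#'
#' @param mesh a [trimesh()].
#' @return list of [trimesh()] objects sorted by descending enclosed size
#'   (absolute signed volume).
#' @export
mesh_components <- function(mesh) {
  n <- nrow(mesh$faces)
  memb <- face_component_membership(mesh$faces, nrow(mesh$vertices))
  comp_faces <- split(seq_len(n), memb)
  comps <- lapply(comp_faces, function(fi) {
    f <- mesh$faces[fi, , drop = FALSE]
    used <- sort(unique(as.vector(f)))
    remap <- integer(nrow(mesh$vertices)); remap[used] <- seq_along(used)
    trimesh(mesh$vertices[used, , drop = FALSE],
            matrix(remap[f], ncol = 3), mesh$name, validate = FALSE)
  })
  vol <- vapply(comps, function(m) abs(signed_volume(m)), numeric(1))
  unname(comps[order(vol, decreasing = TRUE)])
}

# keep the largest solid component plus any cavity (negatively oriented)
# components nested inside it; drop detached fragments with a warning
largest_component <- function(mesh) {
  comps <- mesh_components(mesh)
  if (length(comps) == 1) return(comps[[1]])
  sv <- vapply(comps, signed_volume, numeric(1))
  main <- comps[[which.max(sv)]]
  keep <- list(main)
  n_solid <- sum(sv > 0)
  for (i in seq_along(comps)) {
    if (identical(comps[[i]], main)) next
    if (sv[i] < 0 && point_in_mesh(main, comps[[i]]$vertices[1, ]))
      keep[[length(keep) + 1]] <- comps[[i]]   # cavity wall of the main solid
  }
  if (n_solid > 1)
    warning(sprintf(
      "mesh '%s' split into %d solid components by subtraction; %s",
      mesh$name, n_solid, "keeping largest"))
  merge_meshes(keep, mesh$name)
}

merge_meshes <- function(meshes, name) {
  nv <- 0L
  vs <- list(); fs <- list()
  for (m in meshes) {
    vs[[length(vs) + 1]] <- m$vertices
    fs[[length(fs) + 1]] <- m$faces + nv
    nv <- nv + nrow(m$vertices)
  }
  trimesh(do.call(rbind, vs), do.call(rbind, fs), name, validate = FALSE)
}

#' Test whether a point lies inside a watertight mesh
#'
#' Ray-parity point classification (sign of the sampled signed-distance
#' field at a degenerate one-point lattice).
#'
#' @param mesh a watertight [trimesh()].
#' @param point length-3 coordinates (mm).
#' @return logical.
#' @export
point_in_mesh <- function(mesh, point) {
  f <- cpp_sdf_grid(mesh$vertices, mesh$faces - 1L, as.numeric(point), 1.0,
                    c(1L, 1L, 1L))
  f > 0
}

#' Remove muscle-bone and muscle-muscle overlap
#'
#' Every muscle has all bone overlap subtracted; for each intersecting muscle
#' pair the lower-priority muscle is cut by the higher-priority one (default
#' priority: creation order, earlier wins).  All operations share one
#' scene-fixed lattice, so after resolution no lattice point remains inside
#' two solids: residual overlap, measured on that lattice, is exactly zero.
#'
#' @param muscles list of `muscle_model` objects from [sweep_muscle()].
#' @param bones list of watertight [trimesh()] bones (may be empty).
#' @param priority character vector of muscle names, highest priority first.
#' @param resolution lattice resolution (cells along longest scene axis).
#' @return list with `muscles` (updated models; `mesh` replaced where cut)
#'   and `reports`, a data frame with columns `first`, `second`,
#'   `intersection_volume`, `loser`, `resolved`.
#' @export
resolve_overlaps <- function(muscles, bones = list(), priority = NULL,
                             resolution = 96L) {
  if (length(muscles) == 0) stop("no muscles configured")
  mnames <- vapply(muscles, `[[`, "", "name")
  if (anyDuplicated(mnames)) stop("muscle names must be unique")
  names(muscles) <- mnames
  if (is.null(priority)) priority <- mnames
  if (!setequal(priority, mnames))
    stop("priority list must name every muscle exactly once")
  for (m in muscles) require_watertight(m$mesh, "muscle")
  for (b in bones) require_watertight(b, "bone")

  scene <- c(lapply(muscles, `[[`, "mesh"), bones)
  grid <- boolean_grid(scene, resolution)
  fields <- lapply(muscles, function(m) mesh_field(m$mesh, grid))
  changed <- setNames(logical(length(muscles)), mnames)

  rep_first <- rep_second <- rep_loser <- character(0)
  rep_vol <- numeric(0)

  for (b in bones) {
    fb <- mesh_field(b, grid)
    for (nm in mnames) {
      fint <- pmin(fields[[nm]], fb)
      if (any(fint > 0)) {
        iv <- enclosed_volume(field_to_mesh(fint, grid, "overlap"))
        fields[[nm]] <- pmin(fields[[nm]], -fb)
        changed[nm] <- TRUE
        rep_first <- c(rep_first, nm); rep_second <- c(rep_second, b$name)
        rep_vol <- c(rep_vol, iv); rep_loser <- c(rep_loser, nm)
      }
    }
  }

  if (length(priority) > 1) {
    for (i in seq_len(length(priority) - 1)) {
      for (j in (i + 1):length(priority)) {
        win <- priority[i]; lose <- priority[j]
        fint <- pmin(fields[[win]], fields[[lose]])
        if (any(fint > 0)) {
          iv <- enclosed_volume(field_to_mesh(fint, grid, "overlap"))
          fields[[lose]] <- pmin(fields[[lose]], -fields[[win]])
          changed[lose] <- TRUE
          rep_first <- c(rep_first, win); rep_second <- c(rep_second, lose)
          rep_vol <- c(rep_vol, iv); rep_loser <- c(rep_loser, lose)
        }
      }
    }
  }

  for (nm in mnames[changed]) {
    cut <- field_to_mesh(fields[[nm]], grid, nm)
    if (nrow(cut$faces) == 0)
      stop(sprintf("muscle '%s' entirely removed by overlap resolution", nm))
    cut <- largest_component(cut)
    muscles[[nm]]$mesh <- cut
  }

  reports <- data.frame(first = rep_first, second = rep_second,
                        intersection_volume = rep_vol, loser = rep_loser,
                        resolved = rep(TRUE, length(rep_vol)),
                        stringsAsFactors = FALSE)
  list(muscles = muscles, reports = reports, grid = grid)
}
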