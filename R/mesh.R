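#' Triangle mesh surface
#'
#' Constructs a `trimesh`, the package's basic indexed triangle surface.
#' Coordinates are millimetres in a right-handed system.  Face indices are
#' stored 1-based internally (R convention); the on-disk selection format is
#' 0-based (see [read_selection()]).
#'
#' @param vertices numeric matrix, one row per vertex, three columns (x,y,z).
#' @param faces integer matrix, one row per triangle, three 1-based vertex
#'   indices per row.
#' @param name identifier string carried through exports.
#' @param validate check structural invariants (indices in range, no
#'   degenerate index triples).
#' @return an object of class `trimesh` with elements `vertices`, `faces`,
#'   `name`.
#' @examples
#' m <- trimesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0)), rbind(c(1,2,3)), "tri")
#' mesh_surface_area(m)
#' @export
trimesh <- function(vertices, faces, name = "mesh", validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = NULL)
  faces <- matrix(as.integer(faces), ncol = 3, dimnames = NULL)
  m <- structure(list(vertices = vertices, faces = faces, name = name),
                 class = "trimesh")
  if (validate) validate_trimesh(m)
  m
}

validate_trimesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (!is.numeric(v) || ncol(v) != 3 || anyNA(v))
    stop("vertices must be a numeric n x 3 matrix without NA")
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > nrow(v))
      stop("face index out of range")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      stop("face repeats a vertex")
  }
  invisible(mesh)
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# per-face un-normalized normals (cross products); rows of length 2*area
face_cross <- function(mesh, face_ids = seq_len(nrow(mesh$faces))) {
  f <- mesh$faces[face_ids, , drop = FALSE]
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  c <- mesh$vertices[f[, 3], , drop = FALSE]
  u <- b - a; w <- c - a
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

face_areas <- function(mesh, face_ids = seq_len(nrow(mesh$faces))) {
  cr <- face_cross(mesh, face_ids)
  0.5 * sqrt(rowSums(cr * cr))
}

face_centroids <- function(mesh, face_ids = seq_len(nrow(mesh$faces))) {
  f <- mesh$faces[face_ids, , drop = FALSE]
  (mesh$vertices[f[, 1], , drop = FALSE] +
   mesh$vertices[f[, 2], , drop = FALSE] +
   mesh$vertices[f[, 3], , drop = FALSE]) / 3
}

#' Total surface area of a mesh
#'
#' @param mesh a [trimesh()].
#' @return area in mm^2.
#' @export
mesh_surface_area <- function(mesh) sum(face_areas(mesh))

#' Enclosed volume of a watertight mesh
#'
#' Signed-tetrahedra (divergence theorem) volume: each triangle spans a
#' tetrahedron with the origin; the absolute value of the summed signed
#' volumes is the enclosed volume.  Translation and rotation invariant.
#'
#' @param mesh a watertight [trimesh()].
#' @return volume in mm^3.
#' @export
enclosed_volume <- function(mesh) {
  if (!is_watertight(mesh))
    stop("volume undefined for open mesh")
  f <- mesh$faces
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  c <- mesh$vertices[f[, 3], , drop = FALSE]
  # scalar triple product a . (b x c)
  s <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
       a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
       a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  abs(sum(s)) / 6
}

# undirected edge table of a face set: one row per face edge, columns
# (lo, hi, face, from, to) keeping the directed orientation
edge_table <- function(faces) {
  e_from <- c(faces[, 1], faces[, 2], faces[, 3])
  e_to   <- c(faces[, 2], faces[, 3], faces[, 1])
  data.frame(lo = pmin(e_from, e_to), hi = pmax(e_from, e_to),
             face = rep(seq_len(nrow(faces)), 3),
             from = e_from, to = e_to)
}

#' Watertightness (closed orientable manifold) test
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces and the two incident faces traverse it in opposite directions
#' (consistent orientation).  Disconnected meshes are watertight when every
#' component is closed.
#'
#' @param mesh a [trimesh()].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  nv <- nrow(mesh$vertices)
  e_from <- c(f[, 1], f[, 2], f[, 3])
  e_to   <- c(f[, 2], f[, 3], f[, 1])
  key <- pmin(e_from, e_to) * (nv + 1) + pmax(e_from, e_to)
  r <- rle(sort(key, method = "radix"))
  if (any(r$lengths != 2L)) return(FALSE)
  # orientability: each undirected edge must appear once in each direction
  !anyDuplicated(e_from * (nv + 1) + e_to)
}

#' Attachment surface patch
#'
#' A subset of a mesh's faces representing a painted origin or insertion
#' attachment area.
#'
#' @param mesh parent [trimesh()].
#' @param face_ids 1-based face indices into `mesh$faces`.
#' @param role `"origin"` or `"insertion"`.
#' @param muscle optional muscle name the patch belongs to.
#' @return object of class `surface_patch`.
#' @export
surface_patch <- function(mesh, face_ids, role = c("origin", "insertion"),
                          muscle = NULL) {
  role <- match.arg(role)
  face_ids <- unique(as.integer(face_ids))
  if (length(face_ids) == 0) stop("empty selection")
  if (min(face_ids) < 1L || max(face_ids) > nrow(mesh$faces))
    stop("patch face index out of range")
  p <- structure(list(mesh = mesh, face_ids = face_ids, role = role,
                      muscle = muscle),
                 class = "surface_patch")
  comp <- patch_components(p)
  if (length(comp) > 1)
    warning(sprintf("patch (%s) is not edge-connected: %d components; %s",
                    role, length(comp),
                    "largest component used for sweeping"))
  p
}

#' @export
print.surface_patch <- function(x, ...) {
  cat(sprintf("<surface_patch %s on '%s': %d faces, area %.4g mm^2>\n",
              x$role, x$mesh$name, length(x$face_ids), surface_area(x)))
  invisible(x)
}

#' Patch surface area
#'
#' Sum of the areas of the selected triangles.  Degenerate (zero-area) faces
#' contribute 0.  Fragmented selections are summed over all faces ("painted
#' area" semantics).
#'
#' @param patch a [surface_patch()].
#' @return area in mm^2.
#' @export
surface_area <- function(patch) {
  if (length(patch$face_ids) == 0) stop("empty selection")
  sum(face_areas(patch$mesh, patch$face_ids))
}

#' Area-weighted centroid of a patch
#'
#' Face centroids weighted by face area, over the whole selection.
#'
#' @param patch a [surface_patch()].
#' @return numeric length-3 point (mm).
#' @export
area_weighted_centroid <- function(patch) {
  ar <- face_areas(patch$mesh, patch$face_ids)
  tot <- sum(ar)
  if (tot <= 0) stop("degenerate patch")
  ce <- face_centroids(patch$mesh, patch$face_ids)
  as.numeric(colSums(ce * ar) / tot)
}

# membership vector: which edge-connected component each face belongs to
face_component_membership <- function(faces, nv) {
  n <- nrow(faces)
  e_from <- c(faces[, 1], faces[, 2], faces[, 3])
  e_to   <- c(faces[, 2], faces[, 3], faces[, 1])
  key <- pmin(e_from, e_to) * (nv + 1) + pmax(e_from, e_to)
  fidx <- rep(seq_len(n), 3)
  o <- order(key, method = "radix")
  ks <- key[o]; fs <- fidx[o]
  same <- which(ks[-length(ks)] == ks[-1])   # faces sharing an edge
  g <- igraph::graph_from_edgelist(cbind(fs[same], fs[same + 1]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

# edge-connected components of a patch's face set (list of face-id vectors,
# sorted by descending total area)
patch_components <- function(patch) {
  fids <- patch$face_ids
  faces <- patch$mesh$faces[fids, , drop = FALSE]
  memb <- face_component_membership(faces, nrow(patch$mesh$vertices))
  comp <- split(fids, memb)
  ar <- vapply(comp, function(ids)
    sum(face_areas(patch$mesh, ids)), numeric(1))
  comp[order(ar, decreasing = TRUE)]
}

#' Extract boundary loops of a patch
#'
#' Boundary edges are those used by exactly one face of the selection; they
#' are chained into closed ordered loops.  Loop orientation follows the face
#' winding (counter-clockwise seen from the outward normal side).  Loops are
#' returned sorted by descending perimeter.
#'
#' @param patch a [surface_patch()].
#' @param faces_override optional face-id vector replacing the patch's
#'   selection (used internally to work on one connected component).
#' @return list of `boundary_loop` objects: each a list with `points`
#'   (k x 3 matrix, closure implicit) and `vertex_ids`.
#' @export
extract_boundary_loops <- function(patch, faces_override = NULL) {
  fids <- if (is.null(faces_override)) patch$face_ids else faces_override
  faces <- patch$mesh$faces[fids, , drop = FALSE]
  et <- edge_table(faces)
  key <- paste(et$lo, et$hi)
  cnt <- table(key)
  boundary <- et[cnt[key] == 1L, , drop = FALSE]
  if (nrow(boundary) == 0)
    stop("patch has no boundary")
  # chain directed boundary edges from -> to
  nxt <- boundary$to
  names(nxt) <- as.character(boundary$from)
  if (anyDuplicated(boundary$from))
    stop("non-manifold patch boundary (vertex with >2 boundary edges)")
  visited <- logical(nrow(boundary))
  names(visited) <- as.character(boundary$from)
  loops <- list()
  for (start in boundary$from) {
    s <- as.character(start)
    if (visited[s]) next
    ring <- integer(0)
    cur <- start
    repeat {
      cs <- as.character(cur)
      if (is.na(nxt[cs])) stop("open boundary chain: patch is not manifold")
      visited[cs] <- TRUE
      ring <- c(ring, cur)
      cur <- nxt[[cs]]
      if (cur == start) break
      if (length(ring) > nrow(boundary)) stop("boundary chaining failed")
    }
    loops[[length(loops) + 1]] <- ring
  }
  v <- patch$mesh$vertices
  out <- lapply(loops, function(ring) {
    structure(list(points = v[ring, , drop = FALSE], vertex_ids = ring),
              class = "boundary_loop")
  })
  perim <- vapply(out, function(l) loop_perimeter(l$points), numeric(1))
  out[order(perim, decreasing = TRUE)]
}

loop_perimeter <- function(pts) {
  d <- pts[c(2:nrow(pts), 1), , drop = FALSE] - pts
  sum(sqrt(rowSums(d * d)))
}

#' Align a boundary loop to its best-fit plane
#'
#' Principal-component analysis of the loop points: the two largest-variance
#' directions become the plane axes, the smallest the plane normal.  Sign
#' conventions make the result deterministic: the first axis is oriented so
#' the loop's first point has non-negative first coordinate, and the frame is
#' flipped so the projected loop winds counter-clockwise.
#'
#' @param loop a `boundary_loop` (or any k x 3 matrix of ordered points via
#'   `list(points = ...)`).
#' @return a `planar_polygon`: list with `points2d` (k x 2), `origin`
#'   (centroid, length 3) and `axes` (3 x 3, columns e1,e2,normal) such that
#'   `world = origin + points2d %*% t(axes[,1:2])`.
#' @export
align_boundary_to_plane <- function(loop) {
  pts <- loop$points
  if (nrow(pts) < 3) stop("degenerate boundary")
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate boundary")
  axes <- sv$v                       # columns ordered by decreasing variance
  p2 <- x %*% axes[, 1:2, drop = FALSE]
  if ((sv$d[1] - sv$d[2]) / sv$d[1] < 1e-6) {
    # in-plane variance (near-)isotropic: the principal directions are
    # arbitrary, so anchor the first axis to the loop's first vertex to make
    # the frame intrinsic to the geometry (exact rigid invariance)
    ang <- atan2(p2[1, 2], p2[1, 1])
    rot <- cbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
    p2 <- p2 %*% t(rot)
    axes[, 1:2] <- axes[, 1:2] %*% t(rot)
  }
  # orient first axis: first point gets non-negative first coordinate
  if (p2[1, 1] < 0) { axes[, 1] <- -axes[, 1]; p2[, 1] <- -p2[, 1] }
  # counter-clockwise winding in the plane; flipping e2 keeps right-handedness
  # with the flipped normal
  if (polygon_area2d(p2) < 0) {
    axes[, 2] <- -axes[, 2]; p2[, 2] <- -p2[, 2]
    axes[, 3] <- -axes[, 3]
  } else {
    # make normal = e1 x e2 (right-handed)
    n <- c(axes[2, 1] * axes[3, 2] - axes[3, 1] * axes[2, 2],
           axes[3, 1] * axes[1, 2] - axes[1, 1] * axes[3, 2],
           axes[1, 1] * axes[2, 2] - axes[2, 1] * axes[1, 2])
    axes[, 3] <- n
  }
  structure(list(points2d = p2, origin = as.numeric(ctr), axes = axes),
            class = "planar_polygon")
}

# signed shoelace area of an ordered 2D polygon (positive = CCW)
polygon_area2d <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  i2 <- c(2:nrow(p), 1)
  0.5 * sum(x * y[i2] - x[i2] * y)
}

# area centroid of a simple 2D polygon
polygon_centroid2d <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  i2 <- c(2:nrow(p), 1)
  cr <- x * y[i2] - x[i2] * y
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-300) return(colMeans(p))
  c(sum((x + x[i2]) * cr), sum((y + y[i2]) * cr)) / (6 * a)
}
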