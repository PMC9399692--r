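#' Sweep parameters
#'
#' @param ring_vertex_count vertices per cross-section ring (>= 3,
#'   default 64).
#' @param blend `"linear_blend"` (ring shape interpolated from the origin
#'   outline to the insertion outline by arc-length position, default) or
#'   `"origin_only"` (constant origin outline, the bare bevel).
#' @param scale_profile optional numeric vector of per-ring scale
#'   multipliers, length = curve sample count.
#' @return a `sweep_params` list.
#' @export
sweep_params <- function(ring_vertex_count = 64L,
                         blend = c("linear_blend", "origin_only"),
                         scale_profile = NULL) {
  blend <- match.arg(blend)
  if (ring_vertex_count < 3) stop("ring_vertex_count must be >= 3")
  structure(list(ring_vertex_count = as.integer(ring_vertex_count),
                 blend = blend, scale_profile = scale_profile),
            class = "sweep_params")
}

#' Resample a planar polygon to n points by arc length
#'
#' Points are equally spaced along the polygon's perimeter, counter-clockwise,
#' with the seam at the polygon's first point.  Resampling a convex polygon
#' preserves its area to O(1/n^2).
#'
#' @param polygon a `planar_polygon` from [align_boundary_to_plane()], or a
#'   plain k x 2 matrix (assumed counter-clockwise).
#' @param n number of output points (>= 3).
#' @return n x 2 matrix.
#' @export
resample_loop <- function(polygon, n) {
  if (n < 3) stop("need at least 3 ring vertices")
  p <- if (inherits(polygon, "planar_polygon")) polygon$points2d else polygon
  k <- nrow(p)
  closed <- rbind(p, p[1, ])
  seg <- sqrt(rowSums((diff(closed))^2))
  cum <- c(0, cumsum(seg))
  total <- cum[k + 1]
  if (total <= 0) stop("degenerate polygon")
  s <- (seq_len(n) - 1) / n * total
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i[i > k] <- k
  u <- (s - cum[i]) / seg[i]
  u[!is.finite(u)] <- 0
  closed[i, , drop = FALSE] * (1 - u) + closed[i + 1, , drop = FALSE] * u
}

#' Rotation-minimizing frames along a centerline
#'
#' Computes one orthonormal frame per curve sample with the third axis along
#' the local tangent, propagated by the double-reflection method so that no
#' twist accumulates (unlike Frenet frames, which flip at inflections).  For
#' a straight curve all frames are identical.
#'
#' @param curve a [centerline()].
#' @param e1_init optional initial first axis (length-3, need not be exactly
#'   orthogonal to the first tangent; it is orthogonalized).  Default: an
#'   arbitrary stable perpendicular.
#' @return list with `tangents`, `e1`, `e2` (each n x 3 matrices).
#' @export
build_frames <- function(curve, e1_init = NULL) {
  s <- curve$samples
  n <- nrow(s)
  d <- diff(s)
  seg_t <- d / sqrt(rowSums(d * d))
  tg <- matrix(0, n, 3)
  tg[1, ] <- seg_t[1, ]
  tg[n, ] <- seg_t[n - 1, ]
  if (n > 2) {
    mid <- seg_t[-(n - 1), , drop = FALSE] + seg_t[-1, , drop = FALSE]
    tg[2:(n - 1), ] <- mid / sqrt(rowSums(mid * mid))
  }
  if (is.null(e1_init)) e1_init <- stable_perp(tg[1, ])
  r <- e1_init - sum(e1_init * tg[1, ]) * tg[1, ]
  nr <- sqrt(sum(r * r))
  if (nr < 1e-12) stop("initial axis parallel to tangent")
  r <- r / nr
  e1 <- matrix(0, n, 3); e1[1, ] <- r
  for (i in seq_len(n - 1)) {
    # double reflection (Wang et al.): reflect in the chord bisector plane,
    # then in the bisector of the reflected and next tangents
    v1 <- s[i + 1, ] - s[i, ]
    c1 <- sum(v1 * v1)
    rL <- e1[i, ] - (2 / c1) * sum(v1 * e1[i, ]) * v1
    tL <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    v2 <- tg[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    e1[i + 1, ] <- if (c2 < 1e-24) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthogonalize against accumulated rounding
    e1[i + 1, ] <- e1[i + 1, ] - sum(e1[i + 1, ] * tg[i + 1, ]) * tg[i + 1, ]
    e1[i + 1, ] <- e1[i + 1, ] / sqrt(sum(e1[i + 1, ]^2))
  }
  e2 <- cbind(tg[, 2] * e1[, 3] - tg[, 3] * e1[, 2],
              tg[, 3] * e1[, 1] - tg[, 1] * e1[, 3],
              tg[, 1] * e1[, 2] - tg[, 2] * e1[, 1])
  # (e1, e2, t) right-handed: t x e1 = e2
  list(tangents = tg, e1 = e1, e2 = e2)
}

stable_perp <- function(t) {
  a <- if (abs(t[1]) <= abs(t[2]) && abs(t[1]) <= abs(t[3])) c(1, 0, 0)
       else if (abs(t[2]) <= abs(t[3])) c(0, 1, 0) else c(0, 0, 1)
  p <- a - sum(a * t) * t
  p / sqrt(sum(p * p))
}

# minimal rotation matrix taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {           # antiparallel: rotate pi about any perp
    p <- stable_perp(a)
    return(2 * outer(p, p) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# cyclic shift of ring B (n x 2) minimizing summed squared distance to A
best_cyclic_shift <- function(a, b) {
  n <- nrow(a)
  best <- Inf; bestj <- 0L
  for (j in 0:(n - 1)) {
    idx <- ((seq_len(n) - 1 + j) %% n) + 1
    d <- a - b[idx, , drop = FALSE]
    ss <- sum(d * d)
    if (ss < best) { best <- ss; bestj <- j }
  }
  ((seq_len(n) - 1 + bestj) %% n) + 1
}

#' Generate a muscle volume by sweeping the origin outline along a centerline
#'
#' The origin attachment boundary is PCA-aligned to a plane, resampled to
#' `ring_vertex_count` points and placed at every curve sample in its
#' rotation-minimizing frame (the outline's plane normal is carried onto the
#' initial tangent, so the bevel shape is independent of the bone's pose in
#' space).  Under `linear_blend` the ring shape is interpolated vertex-wise
#' towards the insertion outline (after seam alignment by the cyclic shift
#' minimizing squared distance).  Rings are stitched with quad-split
#' triangles and both ends are fan-capped at the attachment centroids,
#' yielding a watertight mesh.
#'
#' @param origin,insertion [surface_patch()] objects with positive area.
#' @param curve a [centerline()] whose endpoints lie on the patch centroids.
#' @param params a [sweep_params()].
#' @param name muscle name (default from the origin patch).
#' @return object of class `muscle_model`: list with `name`, `mesh`
#'   (watertight [trimesh()]), `origin`, `insertion`, `curve`, `frames`,
#'   `rings2d` (per-sample 2D outlines), `ring_ids` (n_sample x ring_count
#'   vertex-index matrix), `params`.
#' @export
sweep_muscle <- function(origin, insertion, curve, params = sweep_params(),
                         name = NULL) {
  if (is.null(name)) name <- origin$muscle %||% "muscle"
  m <- params$ring_vertex_count
  for (p in list(origin, insertion))
    if (surface_area(p) <= 0) stop("attachment patch has zero area")

  o_ctr <- area_weighted_centroid(origin)
  i_ctr <- area_weighted_centroid(insertion)
  llen <- linear_length(o_ctr, i_ctr)
  ends_tol <- max(1e-6, 1e-3 * llen)
  if (sqrt(sum((curve$samples[1, ] - o_ctr)^2)) > ends_tol ||
      sqrt(sum((curve$samples[nrow(curve$samples), ] - i_ctr)^2)) > ends_tol)
    stop("curve endpoints must coincide with the attachment centroids")

  ring2d_o <- patch_outline_2d(origin, m)
  poly_o <- attr(ring2d_o, "polygon")
  ring2d_i <- patch_outline_2d(insertion, m)
  ring2d_i <- ring2d_i[best_cyclic_shift(ring2d_o, ring2d_i), , drop = FALSE]

  fr <- sweep_initial_frames(curve, poly_o)
  n <- nrow(curve$samples)
  seg <- sqrt(rowSums((diff(curve$samples))^2))
  alpha <- c(0, cumsum(seg)) / sum(seg)     # normalized arc-length position

  scale_profile <- params$scale_profile %||% rep(1, n)
  if (length(scale_profile) != n)
    stop("scale_profile length must equal curve sample count")

  rings2d <- vector("list", n)
  for (k in seq_len(n)) {
    shape <- if (params$blend == "origin_only") ring2d_o
             else (1 - alpha[k]) * ring2d_o + alpha[k] * ring2d_i
    rings2d[[k]] <- shape * scale_profile[k]
  }
  build_muscle_mesh(name, curve, fr, rings2d, origin, insertion, params)
}

# largest-component boundary outline of a patch: PCA plane, CCW resample,
# re-centered on the outline's own area centroid
patch_outline_2d <- function(patch, m) {
  comp <- patch_components(patch)
  loops <- extract_boundary_loops(patch, faces_override = comp[[1]])
  if (length(loops) > 1)
    warning(sprintf("%s attachment boundary has %d loops (holes); %s",
                    patch$role, length(loops), "using the longest"))
  poly <- align_boundary_to_plane(loops[[1]])
  ring <- resample_loop(poly, m)
  ctr <- polygon_centroid2d(ring)
  ring <- sweep(ring, 2, ctr)
  attr(ring, "polygon") <- poly
  ring
}

# frames whose initial (e1,e2) are the origin outline's PCA plane axes,
# carried onto the first tangent by the minimal rotation
sweep_initial_frames <- function(curve, poly_o) {
  d1 <- curve$samples[2, ] - curve$samples[1, ]
  t0 <- d1 / sqrt(sum(d1 * d1))
  nrm <- poly_o$axes[, 3]
  if (sum(nrm * t0) < 0) nrm <- -nrm   # bevel plane faces along the sweep
  R <- rotation_between(nrm, t0)
  e1_0 <- as.numeric(R %*% poly_o$axes[, 1])
  build_frames(curve, e1_init = e1_0)
}

build_muscle_mesh <- function(name, curve, fr, rings2d, origin, insertion,
                              params) {
  n <- length(rings2d)
  m <- nrow(rings2d[[1]])
  centers <- curve$samples
  verts <- matrix(0, n * m + 2, 3)
  ring_ids <- matrix(0L, n, m)
  for (k in seq_len(n)) {
    ids <- (k - 1L) * m + seq_len(m)
    ring_ids[k, ] <- ids
    verts[ids, ] <- ring_world(rings2d[[k]], centers[k, ], fr$e1[k, ],
                               fr$e2[k, ])
  }
  c0 <- n * m + 1L; c1 <- n * m + 2L
  verts[c0, ] <- centers[1, ]
  verts[c1, ] <- centers[n, ]

  faces <- matrix(0L, (n - 1) * m * 2 + 2 * m, 3)
  fi <- 0L
  for (k in seq_len(n - 1)) {
    a <- ring_ids[k, ]; b <- ring_ids[k + 1, ]
    j2 <- c(2:m, 1)
    faces[fi + seq_len(m), ] <- cbind(a, b, b[j2])
    faces[fi + m + seq_len(m), ] <- cbind(a, b[j2], a[j2])
    fi <- fi + 2L * m
  }
  j2 <- c(2:m, 1)
  faces[fi + seq_len(m), ] <- cbind(c0, ring_ids[1, ], ring_ids[1, j2])
  fi <- fi + m
  faces[fi + seq_len(m), ] <- cbind(c1, ring_ids[n, j2], ring_ids[n, ])

  mesh <- trimesh(verts, faces, name)
  sv <- signed_volume(mesh)
  if (sv < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  if (!is_watertight(mesh)) stop("sweep not watertight")
  check_ring_monotone(centers, fr, rings2d, name)
  structure(list(name = name, mesh = mesh, origin = origin,
                 insertion = insertion, curve = curve, frames = fr,
                 rings2d = rings2d, ring_ids = ring_ids, params = params),
            class = "muscle_model")
}

ring_world <- function(r2, center, e1, e2) {
  cbind(center[1] + r2[, 1] * e1[1] + r2[, 2] * e2[1],
        center[2] + r2[, 1] * e1[2] + r2[, 2] * e2[2],
        center[3] + r2[, 1] * e1[3] + r2[, 2] * e2[3])
}

signed_volume <- function(mesh) {
  f <- mesh$faces
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  c <- mesh$vertices[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

# adjacent cross-sections should advance monotonically along the local
# tangent; violations indicate curvature tighter than the section radius
check_ring_monotone <- function(centers, fr, rings2d, name) {
  n <- length(rings2d)
  for (k in seq_len(n - 1)) {
    tmid <- fr$tangents[k, ] + fr$tangents[k + 1, ]
    tmid <- tmid / sqrt(sum(tmid * tmid))
    pa <- ring_world(rings2d[[k]], centers[k, ], fr$e1[k, ], fr$e2[k, ])
    pb <- ring_world(rings2d[[k + 1]], centers[k + 1, ], fr$e1[k + 1, ],
                     fr$e2[k + 1, ])
    adv <- (pb - pa) %*% tmid
    if (min(adv) <= 0) {
      warning(sprintf(
        "muscle '%s': cross-sections overlap between rings %d and %d %s",
        name, k, k + 1, "(curvature tighter than section radius)"))
      return(invisible(FALSE))
    }
  }
  invisible(TRUE)
}

#' @export
print.muscle_model <- function(x, ...) {
  cat(sprintf(
    "<muscle_model '%s': %d rings x %d vertices, volume %.4g mm^3>\n",
    x$name, nrow(x$ring_ids), ncol(x$ring_ids), enclosed_volume(x$mesh)))
  invisible(x)
}

#' Scale one interior cross-section ring of a muscle
#'
#' The ring is scaled about its curve sample point within its frame plane and
#' the mesh vertices are updated in place; curve, attachments and the two
#' terminal rings are untouched.
#'
#' @param muscle a `muscle_model` from [sweep_muscle()].
#' @param ring_index 1-based ring index; must be interior.
#' @param factor positive scale multiplier.
#' @return the modified `muscle_model`.
#' @export
scale_ring <- function(muscle, ring_index, factor) {
  n <- nrow(muscle$ring_ids)
  if (factor <= 0) stop("factor must be positive")
  if (ring_index <= 1L || ring_index >= n)
    stop("attachment rings are fixed")
  muscle$rings2d[[ring_index]] <- muscle$rings2d[[ring_index]] * factor
  ids <- muscle$ring_ids[ring_index, ]
  muscle$mesh$vertices[ids, ] <- ring_world(
    muscle$rings2d[[ring_index]], muscle$curve$samples[ring_index, ],
    muscle$frames$e1[ring_index, ], muscle$frames$e2[ring_index, ])
  if (signed_volume(muscle$mesh) < 0)
    muscle$mesh$faces <- muscle$mesh$faces[, c(1, 3, 2)]
  muscle
}
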