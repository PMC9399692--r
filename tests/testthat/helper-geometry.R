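# analytic fixtures and independent oracles used across the suite

cube_mesh <- function(edge = 1, at = c(0, 0, 0), name = "cube") {
  box_mesh(at, at + edge, name)
}

box_mesh <- function(lo, hi, name = "box") {
  v <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                             c(lo[3], hi[3])))
  f <- rbind(c(1, 3, 7), c(1, 7, 5), c(2, 6, 8), c(2, 8, 4),
             c(1, 5, 6), c(1, 6, 2), c(3, 4, 8), c(3, 8, 7),
             c(1, 2, 4), c(1, 4, 3), c(5, 7, 8), c(5, 8, 6))
  trimesh(v, f, name)
}

# icosphere: subdivided icosahedron projected to the sphere
icosphere <- function(radius = 1, subdiv = 2, center = c(0, 0, 0),
                      name = "icosphere") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_env <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mid_env[[key]]
      if (!is.null(id)) return(id)
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      mid_env[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v * v)) * radius
  v <- sweep(v, 2, center, `+`)
  trimesh(v, f, name)
}

# independent per-face area oracle: explicit loop, no shared code path
brute_force_area <- function(mesh, face_ids = seq_len(nrow(mesh$faces))) {
  tot <- 0
  for (i in face_ids) {
    a <- mesh$vertices[mesh$faces[i, 1], ]
    b <- mesh$vertices[mesh$faces[i, 2], ]
    c <- mesh$vertices[mesh$faces[i, 3], ]
    u <- b - a; w <- c - a
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    tot <- tot + 0.5 * sqrt(sum(cr^2))
  }
  tot
}

# voxel-count volume oracle: z-column ray parity at cell centres, written
# independently of the package's divergence-theorem path
voxel_volume <- function(mesh, n = 40) {
  v <- mesh$vertices; f <- mesh$faces
  lo <- apply(v, 2, min) - 1e-6; hi <- apply(v, 2, max) + 1e-6
  h <- (hi - lo) / n
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  zs <- lo[3] + (seq_len(n) - 0.5) * h[3]
  inside <- 0
  for (ix in seq_len(n)) {
    px <- lo[1] + (ix - 0.5) * h[1] + 1.7e-7
    for (iy in seq_len(n)) {
      py <- lo[2] + (iy - 0.5) * h[2] + 0.9e-7
      d <- (B[, 2] - C[, 2]) * (A[, 1] - C[, 1]) +
           (C[, 1] - B[, 1]) * (A[, 2] - C[, 2])
      w1 <- ((B[, 2] - C[, 2]) * (px - C[, 1]) +
             (C[, 1] - B[, 1]) * (py - C[, 2])) / d
      w2 <- ((C[, 2] - A[, 2]) * (px - C[, 1]) +
             (A[, 1] - C[, 1]) * (py - C[, 2])) / d
      w3 <- 1 - w1 - w2
      hit <- is.finite(w1) & w1 >= 0 & w2 >= 0 & w3 >= 0
      if (!any(hit)) next
      zh <- sort(w1[hit] * A[hit, 3] + w2[hit] * B[hit, 3] +
                 w3[hit] * C[hit, 3])
      inside <- inside + sum(findInterval(zs, zh) %% 2 == 1)
    }
  }
  inside * prod(h)
}

# Monte-Carlo surface-integral centroid oracle for a face subset
mc_patch_centroid <- function(mesh, face_ids, n = 20000) {
  ar <- numeric(length(face_ids))
  for (i in seq_along(face_ids)) ar[i] <- brute_force_area(mesh, face_ids[i])
  pick <- sample.int(length(face_ids), n, replace = TRUE, prob = ar)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  f <- mesh$faces[face_ids[pick], , drop = FALSE]
  A <- mesh$vertices[f[, 1], , drop = FALSE]
  B <- mesh$vertices[f[, 2], , drop = FALSE]
  C <- mesh$vertices[f[, 3], , drop = FALSE]
  pts <- (1 - r1) * A + r1 * (1 - r2) * B + r1 * r2 * C
  colMeans(pts)
}

# uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_mesh <- function(mesh, R, t = c(0, 0, 0)) {
  trimesh(sweep(mesh$vertices %*% t(R), 2, t, `+`), mesh$faces, mesh$name)
}

# planar n x n unit-cell grid in the z=0 plane, 2 triangles per cell;
# returns mesh plus the cell index of every face
plane_grid <- function(n = 4) {
  xs <- 0:n
  v <- as.matrix(expand.grid(x = xs, y = xs))
  v <- cbind(v, 0)
  id <- function(i, j) i + (n + 1) * j + 1   # 0-based i,j
  f <- matrix(0L, 0, 3); cell <- integer(0)
  for (j in 0:(n - 1)) for (i in 0:(n - 1)) {
    f <- rbind(f, c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
               c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
    cell <- c(cell, rep(i + n * j + 1L, 2))
  }
  list(mesh = trimesh(v, f, "grid"), cell = cell, n = n)
}

# once-used-edge oracle: the set of boundary edges of a face subset
boundary_edge_set <- function(mesh, face_ids) {
  f <- mesh$faces[face_ids, , drop = FALSE]
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
             cbind(f[, 3], f[, 1]))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  names(which(table(key) == 1))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}

# signed shoelace area (positive = counter-clockwise)
shoelace <- function(p) {
  i2 <- c(2:nrow(p), 1)
  0.5 * sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])
}

ring_perimeter <- function(p) {
  sum(sqrt(rowSums((rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]) - p)^2)))
}
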