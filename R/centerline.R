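#' Centerline curve between attachment centroids
#'
#' An ordered control polygon (first point = origin centroid, last point =
#' insertion centroid) densified into a sampled polyline by a clamped
#' interpolating Catmull-Rom spline.  The sampled polyline is what is swept
#' and what `muscle length' is measured on.
#'
#' @param control_points k x 3 matrix of control points (k >= 2).
#' @param n_samples number of polyline samples (>= 2, default 32).
#' @return object of class `centerline`: list with `control_points`,
#'   `samples` (n x 3) and `n_samples`.
#' @export
centerline <- function(control_points, n_samples = 32L) {
  cp <- matrix(as.numeric(control_points), ncol = 3)
  if (nrow(cp) < 2) stop("need at least 2 control points")
  if (n_samples < 2) stop("n_samples must be >= 2")
  d <- cp[-1, , drop = FALSE] - cp[-nrow(cp), , drop = FALSE]
  if (any(sqrt(rowSums(d * d)) < 1e-12))
    stop("consecutive control points coincide")
  samples <- catmull_rom(cp, n_samples)
  structure(list(control_points = cp, samples = samples,
                 n_samples = as.integer(n_samples)),
            class = "centerline")
}

#' Default straight centerline
#'
#' Straight polyline spanning from the origin centroid to the insertion
#' centroid, with equally spaced samples.
#'
#' @param origin_centroid,insertion_centroid length-3 points (mm).
#' @param n_samples number of samples (>= 2, default 32).
#' @return a [centerline()].
#' @examples
#' cl <- default_centerline(c(0, 0, 0), c(10, 0, 0), n_samples = 5)
#' cl$samples[, 1]  # 0 2.5 5 7.5 10
#' @export
default_centerline <- function(origin_centroid, insertion_centroid,
                               n_samples = 32L) {
  a <- as.numeric(origin_centroid); b <- as.numeric(insertion_centroid)
  if (sqrt(sum((a - b)^2)) < 1e-12) stop("zero-length muscle")
  centerline(rbind(a, b), n_samples)
}

#' Displace interior control points of a centerline
#'
#' Headless surrogate for interactive curve adjustment: selected interior
#' control points are displaced and the sample polyline is recomputed.
#' Endpoints remain pinned to the attachment centroids.
#'
#' @param curve a [centerline()].
#' @param offsets list of `c(index, dx, dy, dz)` vectors (or an n x 4
#'   matrix); `index` is the 1-based control-point index.
#' @return a new [centerline()].
#' @export
apply_control_offsets <- function(curve, offsets) {
  cp <- curve$control_points
  if (is.matrix(offsets)) offsets <- asplit(offsets, 1)
  for (off in offsets) {
    off <- as.numeric(off)
    i <- as.integer(off[1])
    if (i <= 1L || i >= nrow(cp))
      stop("endpoints are pinned to centroids")
    cp[i, ] <- cp[i, ] + off[2:4]
  }
  centerline(cp, curve$n_samples)
}

#' Insert interior control points on a straight centerline
#'
#' Utility for adjusting a 2-point default curve: subdivides the control
#' polygon so interior points exist to offset.
#'
#' @param curve a [centerline()].
#' @param k total number of control points after subdivision (>= 2).
#' @return a [centerline()] tracing the same polyline.
#' @export
subdivide_controls <- function(curve, k) {
  if (k < 2) stop("k must be >= 2")
  t0 <- cumsum(c(0, sqrt(rowSums((diff(curve$control_points))^2))))
  tt <- seq(0, t0[length(t0)], length.out = k)
  cp <- cbind(stats::approx(t0, curve$control_points[, 1], tt)$y,
              stats::approx(t0, curve$control_points[, 2], tt)$y,
              stats::approx(t0, curve$control_points[, 3], tt)$y)
  centerline(cp, curve$n_samples)
}

#' Curved muscle length
#'
#' Sum of the Euclidean lengths of consecutive sample segments of the
#' centerline polyline.
#'
#' @param curve a [centerline()], or any matrix of ordered points.
#' @return length in mm.
#' @export
curve_length <- function(curve) {
  pts <- if (inherits(curve, "centerline")) curve$samples else curve
  d <- diff(pts)
  sum(sqrt(rowSums(d * d)))
}

#' Linear (centroid-to-centroid) muscle length
#'
#' @param origin_centroid,insertion_centroid length-3 points (mm).
#' @return Euclidean distance in mm.
#' @export
linear_length <- function(origin_centroid, insertion_centroid) {
  sqrt(sum((as.numeric(origin_centroid) - as.numeric(insertion_centroid))^2))
}

# Clamped interpolating Catmull-Rom through the control polygon, sampled at
# n points uniformly in chord-length parameter.  With 2 control points this
# degenerates to uniform subdivision of the straight segment.
catmull_rom <- function(cp, n) {
  k <- nrow(cp)
  if (k == 2) {
    t <- seq(0, 1, length.out = n)
    return(cbind(cp[1, 1] + t * (cp[2, 1] - cp[1, 1]),
                 cp[1, 2] + t * (cp[2, 2] - cp[1, 2]),
                 cp[1, 3] + t * (cp[2, 3] - cp[1, 3])))
  }
  # phantom end points clamp the spline to interpolate the end segments
  ext <- rbind(2 * cp[1, ] - cp[2, ], cp, 2 * cp[k, ] - cp[k - 1, ])
  seg_len <- sqrt(rowSums((diff(cp))^2))
  knots <- cumsum(c(0, seg_len)) / sum(seg_len)      # chord-length knots
  tt <- seq(0, 1, length.out = n)
  seg <- findInterval(tt, knots, rightmost.closed = TRUE)
  seg[seg >= k] <- k - 1L
  out <- matrix(0, n, 3)
  for (j in seq_len(n)) {
    i <- seg[j]
    u <- (tt[j] - knots[i]) / (knots[i + 1] - knots[i])
    p0 <- ext[i, ]; p1 <- ext[i + 1, ]; p2 <- ext[i + 2, ]; p3 <- ext[i + 3, ]
    out[j, ] <- 0.5 * ((2 * p1) + (-p0 + p2) * u +
                       (2 * p0 - 5 * p1 + 4 * p2 - p3) * u^2 +
                       (-p0 + 3 * p1 - 3 * p2 + p3) * u^3)
  }
  # exact interpolation at the ends regardless of rounding
  out[1, ] <- cp[1, ]; out[n, ] <- cp[k, ]
  out
}
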