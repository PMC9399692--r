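#' Frustum (truncated-cone) muscle volume
#'
#' The classical attachment-area approximation of muscle volume:
#' \deqn{V = \frac{l}{3}\left(A_{or} + A_{ins} + \sqrt{A_{or} A_{ins}}\right)}
#' with `l` the *linear* (centroid-to-centroid) muscle length.  Symmetric in
#' the two areas; reduces to `A*l` for equal areas (cylinder) and to
#' `A*l/3` when one area vanishes (cone).
#'
#' @param a_or,a_ins origin and insertion attachment areas (mm^2).
#' @param l linear muscle length (mm).
#' @return volume in mm^3.
#' @export
frustum_volume <- function(a_or, a_ins, l) {
  if (any(a_or < 0) || any(a_ins < 0) || any(l < 0))
    stop("areas and length must be non-negative")
  # equal areas: take the exact cylinder limit A*l rather than rounding
  # through sqrt(A^2)
  ifelse(a_or == a_ins, a_or * l,
         l / 3 * (a_or + a_ins + sqrt(a_or * a_ins)))
}

#' Physiological cross-sectional area
#'
#' Muscle volume divided by muscle length, under the parallel-fibred
#' assumption that fibre length equals muscle length.  For the frustum
#' variant use the linear length; for the three-dimensional variant use the
#' curved muscle length.
#'
#' @param volume muscle volume (mm^3).
#' @param length muscle (fibre) length (mm).
#' @return PCSA in mm^2.
#' @export
pcsa <- function(volume, length) {
  if (any(length <= 0)) stop("length must be positive")
  volume / length
}

#' Isometric muscle force from PCSA
#'
#' @param pcsa physiological cross-sectional area (mm^2).
#' @param stress isometric muscle stress (N mm^-2), default 0.3.
#' @return force in N.
#' @export
muscle_force <- function(pcsa, stress = 0.3) {
  if (any(pcsa < 0)) stop("pcsa must be non-negative")
  if (any(stress <= 0)) stop("stress must be positive")
  pcsa * stress
}

#' Percent difference of a 3D metric relative to its frustum counterpart
#'
#' `100 * (value_3d - value_frustum) / value_3d`; the sign indicates whether
#' the frustum approximation under- (positive) or over-estimates (negative)
#' the three-dimensional value.
#'
#' @param value_3d the three-dimensional metric (non-zero).
#' @param value_frustum the frustum metric.
#' @return percent difference.
#' @export
percent_difference <- function(value_3d, value_frustum) {
  if (any(value_3d == 0)) stop("three-dimensional value must be non-zero")
  100 * (value_3d - value_frustum) / value_3d
}

#' Compute the exported metrics row for a muscle
#'
#' Areas and centroids come from the attachment patches, the linear length
#' from the centroid pair, the curved muscle length from the centerline
#' polyline, and the volume from the (post-Boolean) watertight muscle mesh.
#' Frustum volume, both PCSAs and both forces are derived.
#'
#' @param muscle a `muscle_model` (after [resolve_overlaps()] if overlap
#'   removal is wanted).
#' @param stress isometric muscle stress (N mm^-2), default 0.3.
#' @return object of class `muscle_metrics` (a named list; see fields in
#'   [write_metrics_csv()]).
#' @export
compute_metrics <- function(muscle, stress = 0.3) {
  o_ctr <- area_weighted_centroid(muscle$origin)
  i_ctr <- area_weighted_centroid(muscle$insertion)
  a_or <- surface_area(muscle$origin)
  a_ins <- surface_area(muscle$insertion)
  llen <- linear_length(o_ctr, i_ctr)
  mlen <- curve_length(muscle$curve)
  vol <- enclosed_volume(muscle$mesh)
  vfr <- frustum_volume(a_or, a_ins, llen)
  p_f <- pcsa(vfr, llen)
  p_3 <- pcsa(vol, mlen)
  structure(list(
    name = muscle$name,
    origin_area = a_or, insertion_area = a_ins,
    origin_centroid = o_ctr, insertion_centroid = i_ctr,
    linear_length = llen, muscle_length = mlen,
    volume = vol, frustum_volume = vfr,
    pcsa_frustum = p_f, pcsa_3d = p_3,
    force_frustum = muscle_force(p_f, stress),
    force_3d = muscle_force(p_3, stress),
    stress = stress), class = "muscle_metrics")
}

metrics_columns <- c(
  "name", "origin_area", "insertion_area",
  "origin_centroid_x", "origin_centroid_y", "origin_centroid_z",
  "insertion_centroid_x", "insertion_centroid_y", "insertion_centroid_z",
  "linear_length", "muscle_length", "muscle_volume",
  "frustum_volume", "pcsa_frustum", "pcsa_3d",
  "force_frustum", "force_3d", "stress")

metrics_row <- function(m) {
  data.frame(name = m$name, origin_area = m$origin_area,
             insertion_area = m$insertion_area,
             origin_centroid_x = m$origin_centroid[1],
             origin_centroid_y = m$origin_centroid[2],
             origin_centroid_z = m$origin_centroid[3],
             insertion_centroid_x = m$insertion_centroid[1],
             insertion_centroid_y = m$insertion_centroid[2],
             insertion_centroid_z = m$insertion_centroid[3],
             linear_length = m$linear_length,
             muscle_length = m$muscle_length,
             muscle_volume = m$volume,
             frustum_volume = m$frustum_volume,
             pcsa_frustum = m$pcsa_frustum, pcsa_3d = m$pcsa_3d,
             force_frustum = m$force_frustum, force_3d = m$force_3d,
             stress = m$stress, stringsAsFactors = FALSE)
}

#' Write muscle metrics to CSV
#'
#' One header line, one row per muscle, comma delimited, numbers at 6
#' significant digits.  A leading `#` comment records the parallel-fibred
#' PCSA assumption (fibre length = muscle length; no pennation).
#'
#' @param rows list of `muscle_metrics` (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(rows, path) {
  if (inherits(rows, "muscle_metrics")) rows <- list(rows)
  if (length(rows) == 0) stop("no metrics rows to write")
  df <- do.call(rbind, lapply(rows, metrics_row))
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- signif(df[[j]], 6)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("# PCSA/force assume parallel fibres with fibre length",
                   "= muscle length and no pennation"), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metrics CSV written by [write_metrics_csv()]
#'
#' @param path CSV path.
#' @return data frame with the columns of [write_metrics_csv()].
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Frustum/3D comparison table
#'
#' From per-muscle inputs (attachment areas, both lengths, 3D volume)
#' computes the frustum volume, both PCSAs, both forces and all percent
#' differences.
#'
#' @param df data frame with columns `name`, `A_or`, `A_ins`,
#'   `linear_length`, `muscle_length`, `volume_3d`.
#' @param stress isometric muscle stress (N mm^-2), default 0.3.
#' @return data frame with the derived comparison columns appended.
#' @export
frustum_comparison <- function(df, stress = 0.3) {
  need <- c("name", "A_or", "A_ins", "linear_length", "muscle_length",
            "volume_3d")
  for (cn in need)
    if (!cn %in% names(df)) stop("missing column '", cn, "'")
  out <- df
  out$frustum_volume <- frustum_volume(df$A_or, df$A_ins, df$linear_length)
  out$pct_diff_length <- percent_difference(df$muscle_length,
                                            df$linear_length)
  out$pct_diff_volume <- percent_difference(df$volume_3d, out$frustum_volume)
  out$pcsa_frustum <- pcsa(out$frustum_volume, df$linear_length)
  out$pcsa_3d <- pcsa(df$volume_3d, df$muscle_length)
  out$force_frustum <- muscle_force(out$pcsa_frustum, stress)
  out$force_3d <- muscle_force(out$pcsa_3d, stress)
  out$pct_diff_force <- percent_difference(out$force_3d, out$force_frustum)
  out
}
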