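#' Read a triangle mesh from OBJ, PLY or STL
#'
#' Format is chosen from the file extension.  OBJ `v`/`f` records (with
#' optional `/vt/vn` suffixes), ASCII PLY with `vertex` and `face` elements,
#' and ASCII STL are supported.  Polygonal faces are fan-triangulated.
#' Coordinates are taken as millimetres.
#'
#' @param path file path ending in `.obj`, `.ply` or `.stl`.
#' @param name mesh name; defaults to the file stem.
#' @return a [trimesh()].
#' @export
read_mesh <- function(path, name = NULL) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path, name),
         ply = read_ply(path, name),
         stl = read_stl(path, name),
         stop("unsupported mesh format: .", ext))
}

#' Write a triangle mesh to OBJ, PLY or STL
#'
#' @param mesh a [trimesh()].
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path),
         stl = write_stl(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

read_obj <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0) stop("OBJ has no vertices: ", path)
  v <- do.call(rbind, lapply(strsplit(sub("^v +", "", vlines), "[ \t]+"),
                             function(x) as.numeric(x[1:3])))
  tris <- list()
  for (fl in flines) {
    toks <- strsplit(sub("^f +", "", fl), "[ \t]+")[[1]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[`, "", 1))
    idx[idx < 0] <- nrow(v) + 1L + idx[idx < 0]
    if (length(idx) < 3) next
    for (k in seq_len(length(idx) - 2))    # fan-triangulate n-gons
      tris[[length(tris) + 1]] <- idx[c(1, k + 1, k + 2)]
  }
  trimesh(v, do.call(rbind, tris), name)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("o %s", mesh$name), con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

read_ply <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "ply")) stop("not a PLY file: ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format ascii", hdr)))
    stop("only ASCII PLY supported")
  el <- grep("^element ", hdr, value = TRUE)
  counts <- as.integer(sub("^element +\\S+ +", "", el))
  names(counts) <- sub("^element +(\\S+).*", "\\1", el)
  nv <- counts[["vertex"]]; nf <- counts[["face"]]
  body <- trimws(lines[(hdr_end + 1):length(lines)])
  body <- body[nzchar(body)]
  v <- do.call(rbind, lapply(strsplit(body[1:nv], "[ \t]+"),
                             function(x) as.numeric(x[1:3])))
  tris <- list()
  for (fl in body[(nv + 1):(nv + nf)]) {
    x <- as.integer(strsplit(fl, "[ \t]+")[[1]])
    idx <- x[2:(1 + x[1])] + 1L          # PLY indices are 0-based
    for (k in seq_len(length(idx) - 2))
      tris[[length(tris) + 1]] <- idx[c(1, k + 1, k + 2)]
  }
  trimesh(v, do.call(rbind, tris), name)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment %s", mesh$name),
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

read_stl <- function(path, name) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (!any(startsWith(lines, "solid")))
    stop("only ASCII STL supported")
  vlines <- lines[startsWith(lines, "vertex")]
  v <- do.call(rbind, lapply(strsplit(sub("^vertex +", "", vlines), "[ \t]+"),
                             function(x) as.numeric(x[1:3])))
  if (nrow(v) %% 3 != 0) stop("malformed STL: vertex count not multiple of 3")
  # weld identical vertices so downstream topology (watertightness) works
  key <- apply(v, 1, function(p) paste(sprintf("%.9g", p), collapse = ","))
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  faces <- matrix(map, ncol = 3, byrow = TRUE)
  trimesh(v[uk, , drop = FALSE], faces, name)
}

write_stl <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$name), con)
  nrm <- face_cross(mesh)
  len <- sqrt(rowSums(nrm * nrm)); len[len == 0] <- 1
  nrm <- nrm / len
  for (i in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[i, ]
    writeLines(sprintf("facet normal %.9g %.9g %.9g",
                       nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
    writeLines("outer loop", con)
    writeLines(sprintf("vertex %.9g %.9g %.9g",
                       mesh$vertices[f, 1], mesh$vertices[f, 2],
                       mesh$vertices[f, 3]), con)
    writeLines(c("endloop", "endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", mesh$name), con)
}

#' Read an attachment selection file
#'
#' Selections are JSON sidecars
#' `{"mesh": name, "muscle": name, "role": "origin"|"insertion",
#' "faces": [ints]}` with 0-based face indices.
#'
#' @param path JSON file path.
#' @param meshes named list of [trimesh()] objects to resolve `mesh` against.
#' @return a [surface_patch()].
#' @export
read_selection <- function(path, meshes) {
  sel <- jsonlite::fromJSON(path)
  for (fld in c("mesh", "muscle", "role", "faces"))
    if (is.null(sel[[fld]])) stop("selection file missing field '", fld, "'")
  if (!sel$mesh %in% names(meshes))
    stop("selection references unknown mesh '", sel$mesh, "'")
  surface_patch(meshes[[sel$mesh]], as.integer(sel$faces) + 1L,
                role = sel$role, muscle = sel$muscle)
}

#' Write an attachment selection file
#'
#' @param patch a [surface_patch()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(patch, path) {
  jsonlite::write_json(
    list(mesh = patch$mesh$name, muscle = patch$muscle %||% "",
         role = patch$role, faces = patch$face_ids - 1L),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
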