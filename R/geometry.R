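## Synthetic surface geometries and mesh readers (OFF / PLY ASCII).

#' Construct a surface geometry
#'
#' @param vertices numeric L x 3 coordinate matrix.
#' @param faces optional integer F x 3 matrix of 1-based triangle
#'   indices.
#' @return a [SurfaceGeometry-class].
#' @export
makeSurfaceGeometry <- function(vertices, faces = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (is.null(faces)) faces <- matrix(integer(), 0L, 3L)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  new("SurfaceGeometry", vertices = vertices, faces = faces)
}

#' Evenly distributed points on a sphere (Fibonacci lattice)
#'
#' @param n number of points.
#' @param radius sphere radius.
#' @return n x 3 coordinate matrix.
#' @export
fibonacciSphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Triangulated UV sphere mesh
#'
#' Latitude-longitude sphere with `nRings * nSegments + 2` vertices
#' (including both poles) and a full triangle list, suitable for
#' contiguity analysis and as a stand-in spherically registered cortex.
#'
#' @param nRings number of latitude rings (excluding poles).
#' @param nSegments number of longitude segments.
#' @param radius sphere radius.
#' @return a [SurfaceGeometry-class].
#' @export
makeSphereMesh <- function(nRings = 7L, nSegments = 14L, radius = 1) {
  th <- pi * seq_len(nRings) / (nRings + 1L)      # polar angle per ring
  ph <- 2 * pi * (seq_len(nSegments) - 1L) / nSegments
  ring <- function(t) cbind(sin(t) * cos(ph), sin(t) * sin(ph),
                            rep(cos(t), nSegments))
  verts <- rbind(c(0, 0, 1), do.call(rbind, lapply(th, ring)), c(0, 0, -1))
  idx <- function(r, s) 1L + (r - 1L) * nSegments + ((s - 1L) %% nSegments) + 1L
  south <- nrow(verts)
  faces <- list()
  for (s in seq_len(nSegments)) {   # north cap
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, s), idx(1L, s + 1L))
  }
  if (nRings > 1L) for (r in seq_len(nRings - 1L)) for (s in seq_len(nSegments)) {
    a <- idx(r, s); b <- idx(r, s + 1L)
    cc <- idx(r + 1L, s); d <- idx(r + 1L, s + 1L)
    faces[[length(faces) + 1L]] <- c(a, cc, b)
    faces[[length(faces) + 1L]] <- c(b, cc, d)
  }
  for (s in seq_len(nSegments)) {   # south cap
    faces[[length(faces) + 1L]] <- c(south, idx(nRings, s + 1L), idx(nRings, s))
  }
  makeSurfaceGeometry(radius * verts, do.call(rbind, faces))
}

#' Planar grid geometry
#'
#' Vertices at integer (x, y) positions with z = 0 and a triangulated
#' quad face list; cell (i, j) maps to vertex index `(j-1)*nx + i`.
#'
#' @param nx,ny grid dimensions.
#' @param spacing lattice spacing (cm).
#' @return a [SurfaceGeometry-class].
#' @export
makeGridGeometry <- function(nx, ny, spacing = 1) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  verts <- cbind(g$x * spacing, g$y * spacing, 0)
  id <- function(i, j) (j - 1L) * nx + i
  faces <- list()
  for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    faces[[length(faces) + 1L]] <- c(id(i, j), id(i + 1L, j), id(i, j + 1L))
    faces[[length(faces) + 1L]] <- c(id(i + 1L, j), id(i + 1L, j + 1L),
                                     id(i, j + 1L))
  }
  makeSurfaceGeometry(verts, do.call(rbind, faces))
}

#' Read a triangle mesh from OFF or PLY (ASCII)
#'
#' Minimal readers for the two ASCII mesh formats.  Malformed files
#' raise errors naming the offending line or face.
#'
#' @param path file path; format chosen by extension unless `format` is
#'   given.
#' @param format "off" or "ply".
#' @return a [SurfaceGeometry-class].
#' @export
readMesh <- function(path, format = c("auto", "off", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "off"
  if (format == "off") readMeshOFF(path) else readMeshPLY(path)
}

readMeshOFF <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (!grepl("^OFF", ln[1L])) stop("not an OFF file: missing OFF header")
  counts <- scan(text = ln[2L], quiet = TRUE)
  nv <- counts[1L]; nf <- counts[2L]
  verts <- matrix(scan(text = ln[3:(2 + nv)], quiet = TRUE),
                  ncol = 3L, byrow = TRUE)
  faces <- matrix(0L, nf, 3L)
  for (i in seq_len(nf)) {
    f <- scan(text = ln[2L + nv + i], quiet = TRUE)
    if (f[1L] != 3) stop(sprintf("face %d is not a triangle", i))
    fi <- as.integer(f[2:4]) + 1L
    if (any(fi < 1L) || any(fi > nv))
      stop(sprintf("face %d has out-of-range vertex index", i))
    faces[i, ] <- fi
  }
  makeSurfaceGeometry(verts, faces)
}

readMeshPLY <- function(path) {
  ln <- readLines(path)
  if (!identical(trimws(ln[1L]), "ply")) stop("not a PLY file")
  if (!any(grepl("format ascii", ln))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", ln, value = TRUE)[1L]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", ln, value = TRUE)[1L]))
  start <- which(trimws(ln) == "end_header")[1L]
  if (is.na(start)) stop("PLY header not terminated")
  verts <- matrix(scan(text = ln[(start + 1L):(start + nv)],
                       quiet = TRUE), nrow = nv, byrow = TRUE)[, 1:3,
                                                              drop = FALSE]
  faces <- matrix(0L, nf, 3L)
  for (i in seq_len(nf)) {
    f <- scan(text = ln[start + nv + i], quiet = TRUE)
    if (f[1L] != 3) stop(sprintf("face %d is not a triangle", i))
    fi <- as.integer(f[2:4]) + 1L
    if (any(fi < 1L) || any(fi > nv))
      stop(sprintf("face %d has out-of-range vertex index", i))
    faces[i, ] <- fi
  }
  makeSurfaceGeometry(verts, faces)
}

#' Write a mesh as ASCII OFF
#'
#' @param geom a [SurfaceGeometry-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMeshOFF <- function(geom, path) {
  stopifnot(is(geom, "SurfaceGeometry"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(geom@vertices), nrow(geom@faces)), con)
  write.table(format(geom@vertices, digits = 10, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (nrow(geom@faces))
    write.table(cbind(3L, geom@faces - 1L), con, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
  invisible(path)
}
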