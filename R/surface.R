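#' Triangulated surface
#'
#' Constructs a triangulated surface patch from vertex coordinates (mm) and
#' triangle indices, computing per-vertex areas and outward unit normals.
#' The vertex area is one third of the summed area of the incident
#' triangles; the vertex normal is the area-weighted average of the incident
#' face normals, normalized to unit length.
#'
#' @param vertices numeric matrix (n x 3) of vertex positions in mm.
#' @param triangles integer matrix (m x 3) of 1-based vertex indices with
#'   consistent (counter-clockwise seen from outside) orientation.
#' @return Object of class \code{tri_surface} with elements
#'   \code{vertices}, \code{triangles}, \code{areas} (per-vertex, mm^2) and
#'   \code{normals} (per-vertex unit vectors).
#' @export
tri_surface <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  n <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > n))
    stop("triangle indices out of range")
  fn <- .face_normals(vertices, triangles)     # area-scaled face normals
  fa <- 0.5 * sqrt(rowSums(fn^2))
  if (any(fa < 1e-12))
    stop("degenerate (zero-area) triangle(s): ",
         paste(head(which(fa < 1e-12)), collapse = ", "))
  areas <- numeric(n)
  acc <- rowsum(rep(fa / 3, 3L), group = as.vector(triangles))
  areas[as.integer(rownames(acc))] <- acc[, 1L]
  if (any(areas == 0))
    warning("isolated vertex (area 0): ",
            paste(head(which(areas == 0)), collapse = ", "))
  nrm <- matrix(0, n, 3L)
  for (k in 1:3) {
    acc <- rowsum(fn, group = triangles[, k])
    idx <- as.integer(rownames(acc))
    nrm[idx, ] <- nrm[idx, ] + acc
  }
  len <- sqrt(rowSums(nrm^2))
  bad <- which(len < 1e-12 & areas > 0)
  if (length(bad))
    stop("zero resultant normal at vertex ", paste(head(bad), collapse = ", "))
  ok <- len > 0
  nrm[ok, ] <- nrm[ok, ] / len[ok]
  structure(list(vertices = vertices, triangles = triangles,
                 areas = areas, normals = nrm),
            class = "tri_surface")
}

# cross products of triangle edges: length = 2 * area, direction = face normal
.face_normals <- function(v, tr) {
  a <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - a
  e2 <- v[tr[, 3], , drop = FALSE] - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("tri_surface: %d vertices, %d triangles, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$areas)))
  invisible(x)
}

#' Total surface area
#' @param surface a [tri_surface()].
#' @return total area in mm^2.
#' @export
surface_area <- function(surface) sum(surface$areas)

#' Per-vertex areas
#'
#' One third of the summed area of the triangles incident to each vertex;
#' the per-vertex areas sum to the total mesh area.
#'
#' @param surface a [tri_surface()].
#' @return numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(surface) surface$areas

#' Per-vertex outward unit normals
#'
#' Area-weighted average of incident face normals, normalized to unit
#' length.  Requires consistently oriented triangles; flipping every
#' triangle's winding negates all normals.
#'
#' @param surface a [tri_surface()].
#' @return numeric matrix (n x 3) of unit normals.
#' @export
vertex_normals <- function(surface) surface$normals

# undirected edge list with stable ordering; attributes carry the triangle
# incidence count per edge
.surface_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  first <- !duplicated(key)
  edges <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))[first, , drop = FALSE]
  counts <- as.vector(table(factor(key, levels = key[first])))
  attr(edges, "incidence") <- counts
  edges
}

#' Quadrisect every triangle
#'
#' Refines the mesh by splitting each triangle into four: the three corner
#' triangles plus the central triangle spanned by the edge midpoints.
#' Midpoints of shared edges are created once, so the refined mesh has
#' V + E vertices (V original vertices, E unique edges), 4 T triangles, and
#' for planar meshes exactly the original total area.
#'
#' @param surface a [tri_surface()].  Edges shared by more than two
#'   triangles (non-manifold input) are rejected.
#' @return the refined [tri_surface()].
#' @export
triangle_quadrisect <- function(surface) {
  v <- surface$vertices
  tr <- surface$triangles
  edges <- .surface_edges(tr)
  if (any(attr(edges, "incidence") > 2L))
    stop("non-manifold mesh: edge(s) shared by more than two triangles: ",
         paste(head(which(attr(edges, "incidence") > 2L)), collapse = ", "))
  nv <- nrow(v)
  mid <- (v[edges[, 1], , drop = FALSE] + v[edges[, 2], , drop = FALSE]) / 2
  # index of the midpoint vertex for an (a, b) edge
  ekey <- paste(edges[, 1], edges[, 2])
  mid_id <- function(a, b) nv + match(paste(pmin(a, b), pmax(a, b)), ekey)
  m12 <- mid_id(tr[, 1], tr[, 2])
  m23 <- mid_id(tr[, 2], tr[, 3])
  m31 <- mid_id(tr[, 3], tr[, 1])
  new_tr <- rbind(cbind(tr[, 1], m12, m31),
                  cbind(tr[, 2], m23, m12),
                  cbind(tr[, 3], m31, m23),
                  cbind(m12, m23, m31))
  tri_surface(rbind(v, mid), new_tr)
}

#' Read/write ASCII PLY and OFF meshes
#'
#' Minimal readers and writers for ASCII PLY and OFF triangle meshes;
#' coordinates are interpreted as millimetres.  Face indices are 0-based on
#' disk and 1-based in memory.
#'
#' @param path file path; format chosen by extension (".ply" or ".off").
#' @return [read_surface()] returns a [tri_surface()];
#'   [write_surface()] returns \code{path} invisibly.
#' @export
read_surface <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "ply") {
    if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
    end <- match("end_header", trimws(lines))
    if (is.na(end)) stop("PLY header without end_header")
    hdr <- lines[1:end]
    if (!any(grepl("format ascii", hdr))) stop("only ASCII PLY is supported")
    nv <- as.integer(sub(".*element vertex ", "", grep("element vertex", hdr, value = TRUE)[1]))
    nf <- as.integer(sub(".*element face ", "", grep("element face", hdr, value = TRUE)[1]))
    vt <- do.call(rbind, lapply(strsplit(trimws(lines[end + seq_len(nv)]), "\\s+"),
                                function(z) as.numeric(z[1:3])))
    fc <- do.call(rbind, lapply(strsplit(trimws(lines[end + nv + seq_len(nf)]), "\\s+"),
                                function(z) as.integer(z[2:4])))
  } else if (ext == "off") {
    lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
    if (trimws(lines[1]) != "OFF") stop("not an OFF file: ", path)
    cnt <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    nv <- cnt[1]; nf <- cnt[2]
    vt <- do.call(rbind, lapply(strsplit(trimws(lines[2 + seq_len(nv)]), "\\s+"),
                                function(z) as.numeric(z[1:3])))
    fc <- do.call(rbind, lapply(strsplit(trimws(lines[2 + nv + seq_len(nf)]), "\\s+"),
                                function(z) as.integer(z[2:4])))
  } else stop("unsupported mesh format: ", ext)
  tri_surface(vt, fc + 1L)
}

#' @param surface a [tri_surface()] to write.
#' @rdname read_surface
#' @export
write_surface <- function(surface, path) {
  ext <- tolower(tools::file_ext(path))
  v <- surface$vertices
  f <- surface$triangles - 1L
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
    writeLines(paste(3L, f[, 1], f[, 2], f[, 3]), con)
  } else if (ext == "off") {
    writeLines("OFF", con)
    writeLines(paste(nrow(v), nrow(f), 0L), con)
    writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
    writeLines(paste(3L, f[, 1], f[, 2], f[, 3]), con)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}
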