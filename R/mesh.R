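#' Triangle surface mesh
#'
#' Container for a cortical (or scalp) surface: vertex positions in meters in
#' the head coordinate frame (right-handed, origin at the conductor-sphere
#' center), triangular faces as 1-based vertex index triples, and per-vertex
#' unit normals.
#'
#' @param vertices numeric matrix, n x 3, positions in meters.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param normals optional n x 3 matrix of unit normals; computed by
#'   [vertex_normals()] when `NULL`.
#' @param validate check face index bounds and normal lengths.
#' @return an object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `normals`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (validate) {
    if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
      stop("face index out of range: faces reference vertices outside 1..",
           nrow(vertices))
  }
  mesh <- structure(list(vertices = vertices, faces = faces, normals = NULL),
                    class = "surface_mesh")
  mesh$normals <- if (is.null(normals)) vertex_normals(mesh) else as.matrix(normals)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Area-weighted per-vertex normals
#'
#' Each vertex normal is the normalized sum of the (area-weighted) normals of
#' its incident faces; the cross-product face normal already carries the area
#' weight. Degenerate (zero-area) faces contribute nothing. Isolated vertices
#' (no incident face) get a zero normal and are flagged via the
#' `"isolated"` attribute so callers can exclude them from the source space.
#'
#' @param mesh a [surface_mesh()].
#' @return n x 3 matrix of unit normals (zero rows for isolated vertices),
#'   with attribute `isolated` (integer vertex indices).
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- matrix(0, nrow(v), 3)
  if (nrow(f) == 0) stop("mesh has no faces; normals undefined")
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- rowsum(fn[, c], group = f[, k], reorder = FALSE)
      n[as.integer(rownames(acc)), c] <- n[as.integer(rownames(acc)), c] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  isolated <- which(len == 0)
  ok <- len > 0
  n[ok, ] <- n[ok, ] / len[ok]
  attr(n, "isolated") <- isolated
  n
}

#' Read a surface mesh from disk
#'
#' Supports Wavefront OBJ (`v`/`f` records, polygonal faces triangulated by
#' fanning) and GIFTI surface files (see [read_gifti_surface()]). A JSON
#' sidecar `<path>.json` with a `units` field of `"mm"` triggers conversion
#' to meters, as does a GIFTI coordinate-system unit declaration.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"obj"` or `"gifti"`.
#' @return a [surface_mesh()].
#' @export
read_surface <- function(path, format = c("auto", "obj", "gifti")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti" else "obj"
  }
  mesh <- switch(format,
    obj = read_obj(path),
    gifti = read_gifti_surface(path)
  )
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (identical(meta$units, "mm"))
      mesh$vertices <- mesh$vertices / 1000
  }
  mesh
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0) stop("malformed OBJ: no vertex records in ", path)
  v <- suppressWarnings(
    t(vapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
             function(x) as.numeric(x[1:3]), numeric(3))))
  if (anyNA(v)) stop("malformed OBJ: non-numeric vertex coordinates")
  faces <- list()
  for (ln in fl) {
    toks <- strsplit(trimws(sub("^f", "", ln)), "\\s+")[[1]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[`, character(1), 1))
    if (anyNA(idx)) stop("malformed OBJ: bad face record '", ln, "'")
    if (length(idx) < 3) stop("malformed OBJ: face with fewer than 3 vertices")
    for (k in seq_len(length(idx) - 2))             # fan-triangulate polygons
      faces[[length(faces) + 1]] <- idx[c(1, k + 1, k + 2)]
  }
  f <- if (length(faces)) do.call(rbind, faces) else matrix(integer(), 0, 3)
  surface_mesh(v, f)
}

#' Write a surface mesh
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param format `"obj"` or `"gifti"` (by extension when `"auto"`).
#' @param role optional surface role (`"pial"`, `"white"`, `"scalp"`) written
#'   to the JSON sidecar together with `units: "m"`.
#' @export
write_surface <- function(mesh, path, format = c("auto", "obj", "gifti"),
                          role = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti" else "obj"
  if (format == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    if (nrow(mesh$faces))
      writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                         mesh$faces[, 3]), con)
  } else {
    write_gifti_surface(mesh, path)
  }
  meta <- list(units = "m")
  if (!is.null(role)) meta$role <- role
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Unit icosphere generator
#'
#' Recursively subdivided icosahedron with vertices projected to the unit
#' sphere; the standard synthetic stand-in for a closed cortical surface.
#'
#' @param subdivisions non-negative integer; vertex counts are 12, 42, 162,
#'   642, 2562, ...
#' @param radius sphere radius in meters.
#' @return a [surface_mesh()] with outward normals.
#' @export
icosphere <- function(subdivisions = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1]] <<- m
      idx <- nv + length(newv)
      midcache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  surface_mesh(v * radius, f)
}

mesh_edge_list <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Geodesic (graph shortest-path) distances within a surface
#'
#' Distances along mesh edges, the approximation used for patch smoothing and
#' functional-ROI neighborhoods. Exact surface geodesics are unnecessary at
#' the patch scales involved relative to typical edge lengths.
#'
#' @param mesh a [surface_mesh()].
#' @param from integer vertex indices (default all).
#' @param cutoff optional maximum distance; larger distances return `Inf`.
#' @return length(from) x n matrix of distances in meters.
#' @export
geodesic_distances <- function(mesh, from = seq_len(nrow(mesh$vertices)),
                               cutoff = NULL) {
  e <- mesh_edge_list(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w)
  if (igraph::vcount(g) < nrow(mesh$vertices))
    g <- igraph::add_vertices(g, nrow(mesh$vertices) - igraph::vcount(g))
  d <- igraph::distances(g, v = from, algorithm = "dijkstra")
  if (!is.null(cutoff)) d[d > cutoff] <- Inf
  d
}

#' Decimate a triangle mesh by iterative edge collapse
#'
#' Collapses the shortest admissible edge (link condition enforced so the
#' surface stays 2-manifold) to its midpoint until the vertex count is about
#' `n / factor`. When `partner` is given, the identical sequence of index
#' operations is applied to it so a pial/white vertex correspondence
#' survives decimation; partner collapse targets use the partner's own
#' midpoints.
#'
#' @param mesh a [surface_mesh()].
#' @param factor decimation factor (>= 1); `1` returns the input unchanged.
#' @param partner optional second [surface_mesh()] with identical
#'   connectivity to decimate jointly.
#' @return a [surface_mesh()], or `list(mesh, partner)` when `partner` is
#'   supplied.
#' @export
downsample_mesh <- function(mesh, factor, partner = NULL) {
  if (factor < 1) stop("factor must be >= 1")
  n0 <- nrow(mesh$vertices)
  target <- round(n0 / factor)
  if (target < 4) stop("decimation target below 4 vertices")
  if (factor == 1) {
    return(if (is.null(partner)) mesh else list(mesh = mesh, partner = partner))
  }
  if (!is.null(partner) && nrow(partner$vertices) != n0)
    stop("partner mesh must have the same vertex count")

  v <- mesh$vertices
  vp <- if (!is.null(partner)) partner$vertices else NULL
  f <- mesh$faces
  alive <- rep(TRUE, n0)
  nalive <- n0

  neighbors <- function(f, i) {
    rows <- which(f[, 1] == i | f[, 2] == i | f[, 3] == i)
    setdiff(unique(as.vector(f[rows, ])), i)
  }

  while (nalive > target) {
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    len <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
    ord <- order(len)
    collapsed <- FALSE
    for (k in ord) {
      a <- e[k, 1]; b <- e[k, 2]
      # link condition: shared neighbors of a manifold edge are exactly 2
      if (length(intersect(neighbors(f, a), neighbors(f, b))) != 2L) next
      v[a, ] <- (v[a, ] + v[b, ]) / 2
      if (!is.null(vp)) vp[a, ] <- (vp[a, ] + vp[b, ]) / 2
      f[f == b] <- a
      deg <- !(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])
      f <- f[deg, , drop = FALSE]
      alive[b] <- FALSE
      nalive <- nalive - 1
      collapsed <- TRUE
      break
    }
    if (!collapsed) break  # no admissible edge left
  }

  keep <- which(alive)
  remap <- integer(n0)
  remap[keep] <- seq_along(keep)
  out <- surface_mesh(v[keep, , drop = FALSE],
                      matrix(remap[f], ncol = 3))
  if (is.null(partner)) return(out)
  list(mesh = out,
       partner = surface_mesh(vp[keep, , drop = FALSE],
                              matrix(remap[f], ncol = 3)))
}
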