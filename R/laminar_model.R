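#' Paired two-surface laminar source space
#'
#' Binds a pial and a white-matter surface with index-based vertex
#' correspondence into a combined source space. The correspondence is
#' strictly positional: vertex i of the white surface pairs with vertex i of
#' the pial surface, as produced by the mesh generator (mirroring the
#' white-to-pial correspondence of FreeSurfer reconstructions). No geometric
#' nearest-neighbor fallback exists: silent re-matching would corrupt the
#' laminar pairing that every downstream statistic depends on.
#'
#' The combined source-space ordering is fixed: sources `1..N` are the white
#' (deep) surface, `N+1..2N` the pial (superficial) surface. A positive
#' laminar t-statistic therefore always means "pial".
#'
#' A scalp surface is built as the convex hull of the pial vertices (unless
#' supplied) and per-vertex scalp distances are computed as the Euclidean
#' distance to the nearest hull vertex.
#'
#' @param pial,white [surface_mesh()] objects with equal vertex counts.
#' @param scalp optional scalp [surface_mesh()]; default: pial convex hull.
#' @return object of class `laminar_model`: `pial`, `white`, `scalp`,
#'   `n` (vertices per surface), `separation` (per-pair distance, meters),
#'   `scalp_distance` (length `2N`, combined order).
#' @export
pair_laminar_vertices <- function(pial, white, scalp = NULL) {
  if (nrow(pial$vertices) != nrow(white$vertices))
    stop("pial and white vertex counts differ (",
         nrow(pial$vertices), " vs ", nrow(white$vertices),
         "); index correspondence is required")
  n <- nrow(pial$vertices)
  separation <- sqrt(rowSums((pial$vertices - white$vertices)^2))
  if (is.null(scalp)) {
    hull <- convex_hull3(pial$vertices)
    scalp <- surface_mesh(pial$vertices[hull$vertices, , drop = FALSE],
                          matrix(match(as.vector(hull$faces), hull$vertices),
                                 ncol = 3),
                          validate = TRUE)
  }
  model <- structure(list(pial = pial, white = white, scalp = scalp,
                          n = n, separation = separation,
                          scalp_distance = NULL),
                     class = "laminar_model")
  model$scalp_distance <- scalp_distance(model)
  model
}

#' @export
print.laminar_model <- function(x, ...) {
  cat(sprintf(
    "<laminar_model> %d vertex pairs (combined source space %d)\n  mean pial-white separation %.2f mm\n",
    x$n, 2 * x$n, 1000 * mean(x$separation)))
  invisible(x)
}

#' Distance from every source vertex to the scalp
#'
#' Euclidean distance from each vertex of both surfaces to the nearest
#' vertex of the scalp (convex hull) surface, in combined source order
#' (white block then pial block).
#'
#' @param model a `laminar_model`.
#' @return numeric vector of length `2 * model$n`, meters.
#' @export
scalp_distance <- function(model) {
  hv <- model$scalp$vertices
  nearest <- function(v) {
    # ||v - h||^2 = |v|^2 - 2 v.h + |h|^2, minimized over hull vertices
    cross <- v %*% t(hv)
    d2 <- outer(rowSums(v^2), rowSums(hv^2), "+") - 2 * cross
    sqrt(pmax(apply(d2, 1, min), 0))
  }
  c(nearest(model$white$vertices), nearest(model$pial$vertices))
}

#' Combined source-space positions and orientations
#'
#' @param model a `laminar_model`.
#' @return list with `positions` (2N x 3) and `orientations` (2N x 3, vertex
#'   normals), white block first.
#' @export
source_space <- function(model) {
  list(positions = rbind(model$white$vertices, model$pial$vertices),
       orientations = rbind(model$white$normals, model$pial$normals))
}

combined_surface <- function(model) {
  # factor tagging each combined-source index with its surface
  factor(rep(c("white", "pial"), each = model$n), levels = c("white", "pial"))
}
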