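# 3D convex hull (quickhull). Only hull vertex membership and the hull
# triangulation are needed (scalp-distance uses nearest hull *vertex*);
# numerics use a relative epsilon on the point-cloud scale.

#' Convex hull of a 3D point cloud
#'
#' Quickhull. Returns the indices of points on the hull and the hull's
#' triangular faces (indices into the original point set, outward-oriented).
#'
#' @param points n x 3 numeric matrix.
#' @return list with `vertices` (sorted integer indices) and `faces`
#'   (m x 3 integer matrix).
#' @export
convex_hull3 <- function(points) {
  p <- as.matrix(points)
  n <- nrow(p)
  if (n < 4) stop("convex hull needs at least 4 points")
  scale <- max(apply(p, 2, function(x) diff(range(x))))
  eps <- 1e-10 * max(scale, 1)

  # initial simplex from extreme points
  i1 <- which.min(p[, 1]); i2 <- which.max(p[, 1])
  if (sqrt(sum((p[i1, ] - p[i2, ])^2)) < eps) stop("degenerate point set")
  d <- p[i2, ] - p[i1, ]
  rej <- p - matrix(p[i1, ], n, 3, byrow = TRUE)
  rej <- rej - outer(drop(rej %*% d) / sum(d^2), d)
  i3 <- which.max(rowSums(rej^2))
  if (sqrt(sum(rej[i3, ]^2)) < eps) stop("degenerate (collinear) point set")
  nrm <- cross3(p[i2, ] - p[i1, ], p[i3, ] - p[i1, ])
  h <- drop((p - matrix(p[i1, ], n, 3, byrow = TRUE)) %*% nrm)
  i4 <- which.max(abs(h))
  if (abs(h[i4]) < eps * sqrt(sum(nrm^2))) stop("degenerate (coplanar) point set")

  faces <- if (h[i4] > 0) {
    rbind(c(i1, i3, i2), c(i1, i2, i4), c(i2, i3, i4), c(i3, i1, i4))
  } else {
    rbind(c(i1, i2, i3), c(i2, i1, i4), c(i3, i2, i4), c(i1, i3, i4))
  }

  face_plane <- function(fc) {
    nv <- cross3(p[fc[2], ] - p[fc[1], ], p[fc[3], ] - p[fc[1], ])
    list(n = nv, d = sum(nv * p[fc[1], ]))
  }
  planes <- apply(faces, 1, face_plane)

  outside <- function(plane) {
    s <- drop(p %*% plane$n) - plane$d
    which(s > eps * sqrt(sum(plane$n^2)))
  }
  out_sets <- lapply(planes, outside)

  repeat {
    sizes <- lengths(out_sets)
    if (all(sizes == 0)) break
    fi <- which(sizes > 0)[1]
    plane <- planes[[fi]]
    cand <- out_sets[[fi]]
    s <- drop(p[cand, , drop = FALSE] %*% plane$n) - plane$d
    apex <- cand[which.max(s)]

    # find all faces visible from apex
    vis <- vapply(planes, function(pl)
      sum(pl$n * p[apex, ]) - pl$d > eps * sqrt(sum(pl$n^2)), logical(1))
    vis_f <- faces[vis, , drop = FALSE]
    # horizon = edges of visible region appearing exactly once
    ed <- rbind(vis_f[, c(1, 2)], vis_f[, c(2, 3)], vis_f[, c(3, 1)])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    horizon <- ed[key %in% names(which(table(key) == 1)), , drop = FALSE]

    faces <- faces[!vis, , drop = FALSE]
    planes <- planes[!vis]
    out_sets <- out_sets[!vis]
    for (i in seq_len(nrow(horizon))) {
      fc <- c(horizon[i, 1], horizon[i, 2], apex)
      pl <- face_plane(fc)
      faces <- rbind(faces, fc)
      planes[[length(planes) + 1]] <- pl
      out_sets[[length(out_sets) + 1]] <- outside(pl)
    }
  }
  list(vertices = sort(unique(as.vector(faces))), faces = unname(faces))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
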