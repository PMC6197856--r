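#' MEG sensor array
#'
#' @param positions n x 3 coil positions (meters). For axial gradiometers
#'   this is the inner (pickup) coil; the reference coil sits `baseline`
#'   meters further along the coil orientation.
#' @param orientations n x 3 unit coil orientations.
#' @param type `"axial_gradiometer"` or `"magnetometer"` (recycled).
#' @param baseline gradiometer baseline in meters (ignored for
#'   magnetometers). Default 0.05 m, typical for axial gradiometer systems.
#' @param names channel names.
#' @return object of class `sensor_array`.
#' @export
sensor_array <- function(positions, orientations,
                         type = "axial_gradiometer", baseline = 0.05,
                         names = NULL) {
  positions <- as.matrix(positions)
  orientations <- as.matrix(orientations)
  len <- sqrt(rowSums(orientations^2))
  if (any(abs(len - 1) > 1e-6))
    orientations <- orientations / len
  n <- nrow(positions)
  type <- rep_len(type, n)
  if (any(type == "axial_gradiometer") && any(baseline <= 0))
    stop("gradiometer baseline must be > 0")
  structure(list(positions = positions, orientations = orientations,
                 type = type, baseline = rep_len(baseline, n),
                 names = if (is.null(names)) sprintf("CH%03d", seq_len(n)) else names),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d channels (%s)\n", nrow(x$positions),
              paste(unique(x$type), collapse = ", ")))
  invisible(x)
}

#' Read / write a sensor layout table
#'
#' CSV columns: `name,x,y,z,ox,oy,oz,type,baseline` (meters).
#' @param path CSV path.
#' @export
read_sensor_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  sensor_array(as.matrix(d[, c("x", "y", "z")]),
               as.matrix(d[, c("ox", "oy", "oz")]),
               type = d$type, baseline = d$baseline, names = d$name)
}

#' @rdname read_sensor_csv
#' @param sensors a [sensor_array()].
#' @export
write_sensor_csv <- function(sensors, path) {
  d <- data.frame(name = sensors$names,
                  x = sensors$positions[, 1], y = sensors$positions[, 2],
                  z = sensors$positions[, 3],
                  ox = sensors$orientations[, 1], oy = sensors$orientations[, 2],
                  oz = sensors$orientations[, 3],
                  type = sensors$type, baseline = sensors$baseline)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Magnetic field of a current dipole in a homogeneous conducting sphere
#'
#' Closed-form external field (the classical spherical-conductor solution):
#' exact, linear in the dipole moment, and silent for purely radial moments.
#' Stands in for realistic single-shell conductor models; the lead-field
#' builder accepts alternative field functions.
#'
#' @param dipole_position length-3, meters (inside the sphere).
#' @param dipole_moment length-3, A m.
#' @param sensor_points n x 3 field points, meters (outside the sphere).
#' @param sphere_center length-3, meters.
#' @return n x 3 matrix of field vectors in Tesla.
#' @export
dipole_field_sphere <- function(dipole_position, dipole_moment, sensor_points,
                                sphere_center = c(0, 0, 0)) {
  mu0_4pi <- 1e-7
  sensor_points <- matrix(as.numeric(sensor_points), ncol = 3)
  r0 <- as.numeric(dipole_position) - as.numeric(sphere_center)
  q <- as.numeric(dipole_moment)
  r <- sweep(sensor_points, 2, as.numeric(sphere_center))
  rn <- sqrt(rowSums(r^2))
  r0n <- sqrt(sum(r0^2))
  if (any(rn <= r0n))
    stop("sensor point inside (or not beyond) the dipole radius; field undefined")
  a <- r - matrix(r0, nrow(r), 3, byrow = TRUE)
  an <- sqrt(rowSums(a^2))
  if (any(an < 1e-12)) stop("sensor point coincides with the dipole")
  adotr <- rowSums(a * r)
  r0dotr <- drop(r %*% r0)
  FF <- an * (rn * an + rn^2 - r0dotr)
  gradF <- (an^2 / rn + adotr / an + 2 * an + 2 * rn) * r -
    outer(an + 2 * rn + adotr / an, r0)
  qxr0 <- cross3(q, r0)
  qxr0_dot_r <- drop(r %*% qxr0)
  B <- (FF * matrix(qxr0, nrow(r), 3, byrow = TRUE) - qxr0_dot_r * gradF) *
    (mu0_4pi / FF^2)
  # defined limit: dipole at center with any moment -> qxr0 = 0 -> B = 0
  B[!is.finite(B)] <- 0
  B
}

#' Least-squares sphere fit
#'
#' @param points n x 3 matrix.
#' @return list with `center` and `radius`.
#' @export
fit_sphere <- function(points) {
  p <- as.matrix(points)
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  list(center = center, radius = radius)
}

#' Build the lead field for a laminar model
#'
#' One source per combined-space vertex (white block then pial block),
#' oriented along the vertex normal with unit moment (1 A m). The conductor
#' sphere is fitted to the scalp vertices unless supplied. Axial gradiometer
#' channels measure the field component along the coil orientation at the
#' coil position minus the same component at the coil displaced by its
#' baseline along that orientation.
#'
#' @param model a `laminar_model`.
#' @param sensors a [sensor_array()].
#' @param sphere_center optional conductor sphere center; default from
#'   [fit_sphere()] on scalp vertices.
#' @param field_fun field evaluator with the signature of
#'   [dipole_field_sphere()].
#' @return object of class `lead_field`: matrix `L` (channels x 2N, Tesla
#'   per A m), `patch_fwhm` (0 for unsmoothed), `sphere`, `provenance`.
#' @export
build_lead_field <- function(model, sensors, sphere_center = NULL,
                             field_fun = dipole_field_sphere) {
  sph <- fit_sphere(model$scalp$vertices)
  if (!is.null(sphere_center)) sph$center <- sphere_center
  ss <- source_space(model)
  rad <- sqrt(rowSums(sweep(ss$positions, 2, sph$center)^2))
  bad <- which(rad >= sph$radius)
  if (length(bad))
    stop("source vertices outside the fitted conductor sphere: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  nch <- nrow(sensors$positions)
  nsrc <- nrow(ss$positions)
  grad <- sensors$type == "axial_gradiometer"
  outer_pos <- sensors$positions + sensors$baseline * sensors$orientations
  L <- matrix(0, nch, nsrc)
  for (i in seq_len(nsrc)) {
    B1 <- field_fun(ss$positions[i, ], ss$orientations[i, ],
                    sensors$positions, sph$center)
    b <- rowSums(B1 * sensors$orientations)
    if (any(grad)) {
      B2 <- field_fun(ss$positions[i, ], ss$orientations[i, ],
                      outer_pos, sph$center)
      b[grad] <- b[grad] - rowSums(B2 * sensors$orientations)[grad]
    }
    L[, i] <- b
  }
  structure(list(L = L, patch_fwhm = 0, sphere = sph,
                 provenance = list(model = "homogeneous sphere (closed form)",
                                   n_sources = nsrc, n_channels = nch)),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d channels x %d sources, patch FWHM %.1f mm\n",
              nrow(x$L), ncol(x$L), 1000 * x$patch_fwhm))
  invisible(x)
}

#' Per-source lead-field strength
#'
#' Root mean square over channels of each lead-field column.
#' @param lf a `lead_field` or plain matrix.
#' @return numeric vector, one value per source.
#' @export
leadfield_rms <- function(lf) {
  L <- if (inherits(lf, "lead_field")) lf$L else lf
  sqrt(colMeans(L^2))
}

#' Spatial-coherence patch smoothing of a lead field
#'
#' Replaces each source column by a Gaussian-weighted combination of
#' same-surface neighbor columns (weights from geodesic distance, normalized
#' to sum one). This implements extended coherent patches of activity
#' within the per-source prior: a diagonal prior over the smoothed basis is
#' an extended-patch covariance on the original source space. Smoothing is
#' strictly within-surface, so pial patches never bleed onto white and vice
#' versa.
#'
#' @param lf a `lead_field` built on `model`.
#' @param model the `laminar_model`.
#' @param fwhm patch full width at half maximum in meters; 0 = identity.
#' @return a smoothed `lead_field` (with `patch_fwhm` set and the smoothing
#'   weights retained as `smoother`).
#' @export
coherence_smooth <- function(lf, model, fwhm) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(lf)
  edges <- mesh_edge_list(model$pial)
  elen <- sqrt(rowSums((model$pial$vertices[edges[, 1], ] -
                        model$pial$vertices[edges[, 2], ])^2))
  if (fwhm < mean(elen) / 2)
    warning("patch FWHM below half the mean edge length; kernel under-resolved")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  cutoff <- 3 * sigma
  W_for <- function(mesh) {
    d <- geodesic_distances(mesh, cutoff = cutoff)
    w <- exp(-d^2 / (2 * sigma^2))
    w[!is.finite(w)] <- 0
    w / rowSums(w)
  }
  n <- model$n
  Ww <- W_for(model$white)
  Wp <- W_for(model$pial)
  L <- lf$L
  # smoothed column i = sum_j w_ij L_j  (within surface)
  Ls <- cbind(L[, 1:n, drop = FALSE] %*% t(Ww),
              L[, n + 1:n, drop = FALSE] %*% t(Wp))
  out <- lf
  out$L <- Ls
  out$patch_fwhm <- fwhm
  out$smoother <- list(white = Ww, pial = Wp)
  out
}

#' Randomly permute lead-field columns
#'
#' Destroys the correspondence between cortical geometry and sensor data;
#' the basis of the shuffled-forward-model control.
#'
#' @param lf a `lead_field`.
#' @param seed integer seed (reproducible permutation).
#' @return a `lead_field` with permuted columns; the permutation is stored
#'   as attribute `"permutation"`.
#' @export
shuffle_lead_fields <- function(lf, seed) {
  nsrc <- ncol(lf$L)
  set.seed(seed)
  perm <- sample.int(nsrc)
  out <- lf
  out$L <- lf$L[, perm, drop = FALSE]
  attr(out, "permutation") <- perm
  out
}

#' Simulate a rigid co-registration error
#'
#' Draws a rotation angle ~ Normal(mean_rot_deg, sd_rot_deg) about a
#' uniformly random axis through the head origin and a translation of
#' magnitude ~ Normal(mean_trans_mm, sd_trans_mm) along a uniformly random
#' direction, and applies the rigid transform to the whole sensor array
#' (equivalent to mis-registering the anatomy against the sensors).
#'
#' @param sensors a [sensor_array()].
#' @param mean_rot_deg,sd_rot_deg rotation angle moments, degrees.
#' @param mean_trans_mm,sd_trans_mm translation magnitude moments, mm.
#' @param seed integer seed.
#' @return a perturbed [sensor_array()]; the transform is stored as
#'   attribute `"transform"` (list `R`, `t`).
#' @export
perturb_coregistration <- function(sensors, mean_rot_deg = 10,
                                   sd_rot_deg = 2.5, mean_trans_mm = 10,
                                   sd_trans_mm = 2.5, seed = 1) {
  set.seed(seed)
  axis <- random_unit_vector()
  angle <- stats::rnorm(1, mean_rot_deg, sd_rot_deg) * pi / 180
  dir <- random_unit_vector()
  trans <- stats::rnorm(1, mean_trans_mm, sd_trans_mm) / 1000 * dir
  R <- rotation_matrix(axis, angle)
  out <- sensors
  out$positions <- sensors$positions %*% t(R) +
    matrix(trans, nrow(sensors$positions), 3, byrow = TRUE)
  out$orientations <- sensors$orientations %*% t(R)
  attr(out, "transform") <- list(R = R, t = trans, angle_deg = angle * 180 / pi,
                                 trans_mm = 1000 * sqrt(sum(trans^2)))
  out
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
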