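# Independent oracle: a from-scratch evaluation of the dipole-in-sphere
# closed form, written against the published formula with no shared code.
sphere_field_oracle <- function(r0, q, r) {
  a <- r - r0
  an <- sqrt(sum(a^2)); rn <- sqrt(sum(r^2))
  FF <- an * (rn * an + rn^2 - sum(r0 * r))
  gF <- (an^2 / rn + sum(a * r) / an + 2 * an + 2 * rn) * r -
    (an + 2 * rn + sum(a * r) / an) * r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  1e-7 / FF^2 * (FF * qxr0 - sum(qxr0 * r) * gF)
}

test_that("spherical-conductor field matches an independent closed form", {
  set.seed(2)
  for (i in 1:20) {
    r0 <- runif(3, -0.03, 0.03) + c(0, 0, 0.02)
    q <- rnorm(3)
    r <- c(0, 0, 0.12) + runif(3, -0.04, 0.04)
    got <- dipole_field_sphere(r0, q, rbind(r))
    want <- sphere_field_oracle(r0, q, r)
    expect_equal(drop(got), want, tolerance = 1e-10)
  }
})

test_that("radial dipoles are externally silent and the field is linear", {
  sensors <- icosphere(1, radius = 0.12)$vertices
  pos <- c(0.02, -0.01, 0.04)
  B <- dipole_field_sphere(pos, 3 * pos, sensors)
  expect_lt(max(abs(B)), 1e-20)

  qt <- c(0.02, 0.05, -0.01)             # has a tangential part
  B1 <- dipole_field_sphere(pos, qt, sensors)
  B7 <- dipole_field_sphere(pos, 7 * qt, sensors)
  expect_equal(B7, 7 * B1, tolerance = 1e-12)

  # dipole at the center: any moment is radial; defined zero limit
  B0 <- dipole_field_sphere(c(0, 0, 0), c(0, 0, 1), sensors)
  expect_equal(max(abs(B0)), 0)

  expect_error(dipole_field_sphere(c(0, 0, 0.1), qt, rbind(c(0, 0, 0.05))),
               "inside")
})

test_that("sphere fit recovers center and radius", {
  sph <- icosphere(2, radius = 0.083)
  pts <- sweep(sph$vertices, 2, c(0.01, -0.02, 0.005), "+")
  fit <- fit_sphere(pts)
  expect_equal(fit$center, c(0.01, -0.02, 0.005), tolerance = 1e-9)
  expect_equal(fit$radius, 0.083, tolerance = 1e-9)
})

test_that("lead field equals column-stacked dipole evaluations", {
  model <- small_model()
  sensors <- small_sensors()
  lf <- small_leadfield()
  ss <- source_space(model)
  set.seed(3)
  outer_pos <- sensors$positions + sensors$baseline * sensors$orientations
  for (i in sample(ncol(lf$L), 20)) {
    B1 <- dipole_field_sphere(ss$positions[i, ], ss$orientations[i, ],
                              sensors$positions, lf$sphere$center)
    B2 <- dipole_field_sphere(ss$positions[i, ], ss$orientations[i, ],
                              outer_pos, lf$sphere$center)
    col <- rowSums(B1 * sensors$orientations) -
      rowSums(B2 * sensors$orientations)
    expect_equal(lf$L[, i], col, tolerance = 1e-12)
  }
})

test_that("radial-normal sources on a smooth sphere have near-zero columns", {
  pial <- icosphere(2, radius = 0.070)
  white <- icosphere(2, radius = 0.067)
  # exact radial orientations (the discrete-mesh normals are radial only to
  # a fraction of a degree, which already leaks measurable field)
  pial$normals <- pial$vertices / 0.070
  white$normals <- white$vertices / 0.067
  model <- pair_laminar_vertices(pial, white,
                                 scalp = icosphere(1, radius = 0.08))
  lf <- build_lead_field(model, small_sensors())
  rms <- leadfield_rms(lf)
  # all normals are radial: every column is numerically silent relative to
  # a wrinkled model's tangential sources
  ref <- stats::median(leadfield_rms(small_leadfield()))
  expect_lt(max(rms), 1e-6 * ref)
})

test_that("superficial columns are stronger than deep ones under full sensor coverage", {
  model <- small_model()
  sensors <- make_sensor_array(80, cap_half_angle = 180)
  lf <- build_lead_field(model, sensors)
  rms <- leadfield_rms(lf)
  n <- model$n
  expect_gte(mean(rms[n + 1:n] >= rms[1:n]), 0.95)
})

test_that("lead-field RMS matches its column-wise definition", {
  m <- matrix(c(1, 2, 2, 4, 0, 3, 1, 1, 5, 2, 0, 1), 3, 4)
  expect_equal(leadfield_rms(m), sqrt(colMeans(m^2)))
})

test_that("rigid co-rotation of model and sensors leaves the lead field unchanged", {
  model <- small_model()
  sensors <- small_sensors()
  lf <- small_leadfield()
  R <- laminar:::rotation_matrix(c(0.2, -1, 0.5), 0.6)
  rot_mesh <- function(m) surface_mesh(m$vertices %*% t(R), m$faces)
  rmodel <- pair_laminar_vertices(rot_mesh(model$pial), rot_mesh(model$white),
                                  scalp = rot_mesh(model$scalp))
  rsensors <- sensor_array(sensors$positions %*% t(R),
                           sensors$orientations %*% t(R),
                           type = sensors$type, baseline = sensors$baseline)
  lf2 <- build_lead_field(rmodel, rsensors)
  expect_equal(lf2$L, lf$L, tolerance = 1e-6)
})

test_that("coherence smoothing: identity at zero, hand weights on a toy, correlation increase", {
  model <- small_model()
  lf <- small_leadfield()
  expect_identical(coherence_smooth(lf, model, 0), lf)

  lfs <- suppressWarnings(coherence_smooth(lf, model, 0.02))
  # nearest-neighbor column correlation strictly increases
  nn_cor <- function(L, mesh) {
    e <- laminar:::mesh_edge_list(mesh)
    mean(vapply(seq_len(nrow(e)), function(i)
      abs(stats::cor(L[, e[i, 1]], L[, e[i, 2]])), numeric(1)), na.rm = TRUE)
  }
  n <- model$n
  expect_gt(nn_cor(lfs$L[, n + 1:n], model$pial),
            nn_cor(lf$L[, n + 1:n], model$pial))

  # hand-computed two-column Gaussian weights
  d <- geodesic_distances(model$pial, from = 1)[1, ]
  sigma <- 0.02 / (2 * sqrt(2 * log(2)))
  w <- exp(-d^2 / (2 * sigma^2))
  w[d > 3 * sigma] <- 0
  w <- w / sum(w)
  expect_equal(lfs$L[, n + 1], drop(lf$L[, n + which(w > 0), drop = FALSE] %*%
                                    w[w > 0]), tolerance = 1e-12)

  # column sums conserved when all columns identical
  lfc <- lf
  lfc$L <- matrix(lf$L[, 1], nrow(lf$L), ncol(lf$L))
  lfc_s <- suppressWarnings(coherence_smooth(lfc, model, 0.02))
  expect_equal(lfc_s$L, lfc$L, tolerance = 1e-12)
})

test_that("lead-field shuffling is seeded, uniform and column-preserving", {
  lf <- small_leadfield()
  s1 <- shuffle_lead_fields(lf, 7)
  s2 <- shuffle_lead_fields(lf, 7)
  expect_identical(s1$L, s2$L)
  expect_equal(sort(leadfield_rms(s1)), sort(leadfield_rms(lf)))

  # uniformity over the 24 permutations of 4 columns
  toy <- list(L = matrix(1:8, 2, 4))
  class(toy) <- "lead_field"
  counts <- table(vapply(1:10000, function(s)
    paste(attr(shuffle_lead_fields(toy, s), "permutation"), collapse = ""),
    character(1)))
  expect_equal(length(counts), 24L)
  expected <- 10000 / 24
  sd24 <- sqrt(10000 * (1 / 24) * (23 / 24))
  expect_true(all(abs(counts - expected) <= 5 * sd24))
})

test_that("co-registration perturbation has the stated moments and is seeded", {
  sensors <- small_sensors()
  p1 <- perturb_coregistration(sensors, seed = 3)
  p2 <- perturb_coregistration(sensors, seed = 3)
  expect_identical(p1$positions, p2$positions)

  p0 <- perturb_coregistration(sensors, mean_rot_deg = 0, sd_rot_deg = 0,
                               mean_trans_mm = 0, sd_trans_mm = 0, seed = 1)
  expect_equal(p0$positions, sensors$positions, tolerance = 1e-12,
               ignore_attr = TRUE)

  angles <- vapply(1:10000, function(s)
    attr(perturb_coregistration(sensors, seed = s), "transform")$angle_deg,
    numeric(1))
  se <- 2.5 / sqrt(10000)
  expect_lt(abs(mean(angles) - 10), 3 * se)
})
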