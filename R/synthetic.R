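#' Two-layer spherical cortical model
#'
#' Concentric icosphere stand-in for a paired pial/white surface
#' reconstruction: the pial surface is an icosphere of the given radius, the
#' white surface the same mesh shrunk radially by `thickness`, so index
#' correspondence holds by construction and every pair separation equals
#' `thickness`. A smooth deterministic radial modulation (`wrinkle`, a
#' low-order angular harmonic mimicking gyrification) tilts the surface
#' normals away from the radial direction; without it every normal is
#' radial and -- radial dipoles being externally silent in a spherical
#' conductor -- the whole source space would be invisible to MEG. Set
#' `wrinkle = 0` for purely geometric work.
#'
#' @param radius pial sphere radius, meters.
#' @param thickness pial-white separation, meters (must be < radius).
#' @param subdivisions icosphere subdivisions (3 gives 642 vertices per
#'   surface).
#' @param wrinkle relative amplitude of the radial modulation (default 0.1).
#' @param scalp_offset scalp sphere offset beyond the pial radius, meters.
#' @return a `laminar_model`.
#' @export
make_two_layer_model <- function(radius = 0.07, thickness = 0.003,
                                 subdivisions = 3, wrinkle = 0.1,
                                 scalp_offset = 0.01) {
  if (thickness <= 0) stop("thickness must be > 0")
  if (thickness >= radius) stop("thickness must be smaller than the radius")
  base <- icosphere(subdivisions, radius = 1)
  u <- base$vertices                     # unit directions
  theta <- acos(pmin(pmax(u[, 3], -1), 1))
  phi <- atan2(u[, 2], u[, 1])
  g <- sin(3 * theta) * cos(2 * phi)
  r_pial <- radius * (1 + wrinkle * g)
  pial <- surface_mesh(u * r_pial, base$faces)
  # white surface displaced along the pial normal so paired normals stay
  # near-parallel and separation is exactly `thickness`
  white <- surface_mesh(pial$vertices - thickness * pial$normals, base$faces)
  scalp <- icosphere(max(subdivisions - 1, 1),
                     radius = radius * (1 + abs(wrinkle)) + scalp_offset)
  pair_laminar_vertices(pial, white, scalp = scalp)
}

#' Synthetic MEG helmet
#'
#' Quasi-uniform (Fibonacci lattice) coverage of a spherical cap with
#' radially oriented axial gradiometers; a configurable stand-in for a
#' whole-head gradiometer system.
#'
#' @param n number of channels (>= 10).
#' @param helmet_radius sphere radius of the coil layer, meters.
#' @param cap_half_angle angular cap coverage from the +z pole, degrees.
#' @param type channel type.
#' @param baseline gradiometer baseline, meters.
#' @return a [sensor_array()].
#' @export
make_sensor_array <- function(n = 130, helmet_radius = 0.09,
                              cap_half_angle = 120,
                              type = "axial_gradiometer", baseline = 0.05) {
  if (n < 10) stop("need at least 10 channels")
  zmin <- cos(cap_half_angle * pi / 180)
  i <- seq_len(n)
  z <- 1 - (i - 0.5) / n * (1 - zmin)    # uniform in z over the cap
  golden <- pi * (3 - sqrt(5))
  az <- golden * i
  rho <- sqrt(pmax(1 - z^2, 0))
  dirs <- cbind(rho * cos(az), rho * sin(az), z)
  sensor_array(dirs * helmet_radius, dirs, type = type, baseline = baseline)
}

#' Randomized task schedule with exact design counts
#'
#' Factorial congruence-by-coherence design: each block crosses coherence
#' level and motion direction in equal cells, with an exact (not sampled)
#' count of congruent trials split evenly over the cells; row order is then
#' randomized. Defaults give, per 180-trial block, 126 congruent trials and
#' 60 trials per coherence level with 30 leftward each.
#'
#' @param n_blocks number of blocks.
#' @param trials_per_block trials per block.
#' @param congruent_frac fraction of congruent trials.
#' @param coherence_levels number of coherence levels.
#' @param seed integer seed for the ordering (counts are seed-invariant).
#' @param error_rate probability that a trial is marked incorrect (default
#'   0: all correct).
#' @return data frame: `block`, `trial`, `congruent`, `coherence`,
#'   `direction`, `correct`.
#' @export
make_task_schedule <- function(n_blocks = 1, trials_per_block = 180,
                               congruent_frac = 0.7, coherence_levels = 3,
                               seed = 1, error_rate = 0) {
  ncell <- trials_per_block / (2 * coherence_levels)
  ncong <- congruent_frac * trials_per_block
  ncong_cell <- ncong / (2 * coherence_levels)
  if (abs(ncell - round(ncell)) > 1e-9 || abs(ncong_cell - round(ncong_cell)) > 1e-9)
    stop("design counts are not integers for these fractions")
  ncell <- as.integer(round(ncell)); ncong_cell <- as.integer(round(ncong_cell))
  lev <- paste0("coh", seq_len(coherence_levels))
  set.seed(seed)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    rows <- expand.grid(direction = c("left", "right"), coherence = lev,
                        stringsAsFactors = FALSE)
    d <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      data.frame(block = b,
                 congruent = rep(c(TRUE, FALSE),
                                 c(ncong_cell, ncell - ncong_cell)),
                 coherence = rows$coherence[i],
                 direction = rows$direction[i])
    }))
    d <- d[sample.int(nrow(d)), ]
    d$trial <- seq_len(nrow(d))
    d
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out$correct <- if (error_rate > 0)
    stats::runif(nrow(out)) >= error_rate else TRUE
  out[, c("block", "trial", "congruent", "coherence", "direction", "correct")]
}

#' Laminar source specification for the generator
#'
#' @param surface `"pial"` or `"white"`.
#' @param band frequency band of the induced oscillation, Hz.
#' @param modulation signed fractional power change inside `window`
#'   relative to the ongoing level (e.g. -0.3 = 30 percent decrease).
#' @param window time window of the modulation, s (relative to the epoch
#'   alignment event).
#' @param amplitude source current amplitude scale (arbitrary units; the
#'   sensor-level SNR is set separately).
#' @param patch_fwhm spatial FWHM of each coherent Gaussian patch, meters.
#' @param field_fwhm spatial FWHM of the field over which the source's
#'   generators are scattered, meters; `0` puts every generator at `vertex`.
#' @param n_generators number of quasi-independent generators: each carries
#'   its own band-limited stochastic carrier per trial (sharing the power
#'   envelope), emulating the partial spatial incoherence of real
#'   oscillatory fields. `1` gives a single fully coherent patch.
#' @param vertex center vertex (1..N per-surface index); `NULL` = chosen by
#'   the generator under its seed.
#' @param condition_effect optional list `(factor, level, delta)`: trials
#'   whose schedule column `factor` equals `level` get `modulation + delta`.
#' @return a `source_spec` list.
#' @export
source_spec <- function(surface, band, modulation, window, amplitude = 1,
                        patch_fwhm = 0.01, field_fwhm = 0,
                        n_generators = 1, vertex = NULL,
                        condition_effect = NULL) {
  stopifnot(surface %in% c("pial", "white"), patch_fwhm > 0,
            n_generators >= 1)
  structure(list(surface = surface, band = band, modulation = modulation,
                 window = window, amplitude = amplitude,
                 patch_fwhm = patch_fwhm, field_fwhm = field_fwhm,
                 n_generators = as.integer(n_generators), vertex = vertex,
                 condition_effect = condition_effect),
            class = "source_spec")
}

#' Default laminar source pair
#'
#' The canonical study condition: an ongoing alpha rhythm on the deep
#' (white) surface that desynchronizes strongly during the stimulus window
#' (classical alpha blocking, -60% band power at the source), and a weaker
#' superficial (pial) gamma source with a clear power burst (+200%, typical
#' of induced visual gamma at source level) shortly after stimulus onset.
#' @export
default_sources <- function() {
  list(alpha = source_spec("white", band = c(7, 13), modulation = -0.6,
                           window = c(0, 2), amplitude = 1),
       gamma = source_spec("pial", band = c(60, 90), modulation = 2,
                           window = c(0.25, 0.5), amplitude = 0.75))
}

raised_cosine_envelope <- function(time, window, fs, ramp = 0.1) {
  env <- numeric(length(time))
  inside <- time >= window[1] & time <= window[2]
  env[inside] <- 1
  nr <- round(ramp * fs)
  if (nr > 1) {
    idx <- which(inside)
    if (length(idx) > 2 * nr) {
      ramp_up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
      env[idx[seq_len(nr)]] <- ramp_up
      env[idx[length(idx) + 1 - seq_len(nr)]] <- ramp_up
    }
  }
  env
}

# 1/f ("pink") amplitude-spectrum Gaussian noise, unit variance per row
pink_noise <- function(nrow, ns, fs) {
  white <- matrix(stats::rnorm(nrow * ns), ns, nrow)
  F <- stats::mvfft(white)
  f <- c(1, seq_len(ns - 1))             # DC handled separately
  f <- pmin(f, ns - f + 1)               # fold to two-sided frequencies
  F <- F / sqrt(f)
  F[1, ] <- 0
  x <- Re(stats::mvfft(F, inverse = TRUE)) / ns
  x <- sweep(x, 2, apply(x, 2, stats::sd), "/")
  t(x)
}

band_limited_noise <- function(ns, fs, band, pad = 100) {
  drop(band_noise_matrix(ns, fs, band, 1))
}

# stationary Gaussian band noise, one column per realization, unit SD;
# spectrum shaped by the squared-magnitude Butterworth bandpass response
# (the spectral equivalent of forward-backward filtering white noise)
band_noise_matrix <- function(ns, fs, band, ncols) {
  bf <- signal::butter(4, pmin(band / (fs / 2), 0.999), type = "pass")
  k <- seq_len(ns) - 1
  f <- pmin(k, ns - k) * fs / ns         # two-sided frequency axis
  z <- exp(-2i * pi * f / fs)
  H2 <- Mod(vapply(z, function(zz) sum(bf$b * zz^(seq_along(bf$b) - 1)) /
                     sum(bf$a * zz^(seq_along(bf$a) - 1)), complex(1)))^2
  white <- matrix(stats::rnorm(ns * ncols), ns, ncols)
  x <- Re(stats::mvfft(stats::mvfft(white) * H2, inverse = TRUE)) / ns
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

#' Simulate a complete synthetic session
#'
#' Generates epoched sensor data for a two-layer model: each source is an
#' induced (non-phase-locked; fresh band-limited noise per trial, so the
#' trial-averaged evoked field is near zero) oscillation on one surface,
#' spread over a Gaussian geodesic patch, with its power modulated inside
#' its time window; sources are projected through the veridical lead field
#' and white sensor noise is added at the requested SNR
#' (`10*log10(P_signal / P_noise)` over channels, samples and trials).
#'
#' @param model a `laminar_model` (default [make_two_layer_model()]).
#' @param sensors a [sensor_array()] (default [make_sensor_array()]).
#' @param lf optional precomputed `lead_field` for `model`/`sensors`.
#' @param sources list of [source_spec()]s (default [default_sources()]).
#' @param n_trials number of trials; when `schedule` is given its row count
#'   wins.
#' @param schedule optional [make_task_schedule()] trial table.
#' @param fs sampling rate, Hz.
#' @param epoch epoch limits, s, relative to the alignment event.
#' @param snr_db sensor-level SNR in dB: the ratio of task-signal to added
#'   white sensor-noise power.
#' @param background ongoing ("brain-noise") activity level: distributed
#'   unmodulated dipole noise with a 1/f amplitude spectrum and the spatial
#'   covariance of the source space (`L L'`), scaled so its sensor power is
#'   `background` times the task-signal power. Real MEG records task
#'   modulations on top of such ongoing fields; without it the source space
#'   is silent outside the simulated patches, a degenerate condition no
#'   recording exhibits. Set 0 to disable.
#' @param seed integer seed (same seed, same session, bit for bit).
#' @return object of class `laminar_session`: `epochs` ([epoched_data()]),
#'   `truth` (ground-truth table), `model`, `sensors`, `lf`, `noise_sd`,
#'   `seed`.
#' @export
simulate_session <- function(model = make_two_layer_model(),
                             sensors = make_sensor_array(),
                             lf = NULL, sources = default_sources(),
                             n_trials = 100, schedule = NULL, fs = 250,
                             epoch = c(-1.5, 2.5), snr_db = 0,
                             background = 1, seed = 1) {
  set.seed(seed)
  if (is.null(lf)) lf <- build_lead_field(model, sensors)
  time <- seq(epoch[1], epoch[2], by = 1 / fs)
  ns <- length(time)
  if (is.null(schedule)) {
    schedule <- make_task_schedule(n_blocks = 1, seed = seed)
  }
  if (nrow(schedule) > n_trials)
    schedule <- schedule[sample.int(nrow(schedule), n_trials), , drop = FALSE]
  n_trials <- nrow(schedule)
  rownames(schedule) <- NULL
  nch <- nrow(sensors$positions)

  # assign center vertices: well separated, under the sensor cap, and on
  # cortex the array can actually see (the synthetic wrinkle has nodal
  # lines of near-silent sources that no real cortical region exhibits)
  n <- model$n
  rms <- leadfield_rms(lf)
  upper <- which(model$pial$vertices[, 3] > 0.25 * max(model$pial$vertices[, 3]))
  centers <- integer(0)
  for (i in seq_along(sources)) {
    if (!is.null(sources[[i]]$vertex)) {
      centers[i] <- sources[[i]]$vertex
      next
    }
    srms <- if (sources[[i]]$surface == "white") rms[seq_len(n)] else
      rms[n + seq_len(n)]
    visible <- upper[srms[upper] >= stats::median(srms[upper])]
    ok <- visible
    if (length(centers)) {
      far <- apply(as.matrix(stats::dist(rbind(
        model$pial$vertices[centers, , drop = FALSE],
        model$pial$vertices[visible, , drop = FALSE]
      )))[seq_along(centers), length(centers) + seq_along(visible),
          drop = FALSE], 2, min)
      ok <- visible[far > 0.03]
      if (!length(ok)) ok <- visible
    }
    centers[i] <- sample(ok, 1)
    sources[[i]]$vertex <- centers[i]
  }

  # per-source sensor patterns, one per quasi-independent generator
  gains <- lapply(sources, function(sp) {
    mesh <- if (sp$surface == "pial") model$pial else model$white
    d <- as.vector(geodesic_distances(mesh, from = sp$vertex))
    centers <- sp$vertex
    if (sp$n_generators > 1) {
      fsig <- max(sp$field_fwhm, 1e-6) / (2 * sqrt(2 * log(2)))
      wfield <- exp(-d^2 / (2 * fsig^2))
      wfield[!is.finite(wfield)] <- 0
      centers <- sample(n, sp$n_generators, prob = wfield)
    }
    idx <- if (sp$surface == "white") seq_len(n) else n + seq_len(n)
    sigma <- sp$patch_fwhm / (2 * sqrt(2 * log(2)))
    dgen <- geodesic_distances(mesh, from = centers)
    patterns <- vapply(seq_along(centers), function(k) {
      g <- exp(-dgen[k, ]^2 / (2 * sigma^2))
      g[!is.finite(g)] <- 0
      drop(lf$L[, idx, drop = FALSE] %*% g)
    }, numeric(nch))
    list(patterns = patterns, centers = centers)
  })

  signal <- array(0, c(n_trials, nch, ns))
  for (i in seq_along(sources)) {
    sp <- sources[[i]]
    ngen <- sp$n_generators
    env <- raised_cosine_envelope(time, sp$window, fs)
    S <- band_noise_matrix(ns, fs, sp$band, n_trials * ngen)
    for (tr in seq_len(n_trials)) {
      mod <- sp$modulation
      ce <- sp$condition_effect
      if (!is.null(ce) && identical(schedule[[ce$factor]][tr], ce$level))
        mod <- mod + ce$delta
      scale <- sp$amplitude * sqrt(pmax(1 + env * mod, 0)) / sqrt(ngen)
      cols <- (tr - 1) * ngen + seq_len(ngen)
      signal[tr, , ] <- signal[tr, , ] +
        gains[[i]]$patterns %*% t(S[, cols, drop = FALSE] * scale)
    }
  }
  p_sig <- mean(signal^2)
  if (p_sig <= 0) stop("zero signal power; target SNR unreachable")
  if (background > 0) {
    # ongoing dipole noise: spatial covariance L L', 1/f spectrum
    LL <- tcrossprod(lf$L)
    Ab <- chol(LL + diag(1e-9 * mean(diag(LL)), nch))
    P <- pink_noise(nch * n_trials, ns, fs)
    bgs <- vector("list", n_trials)
    for (tr in seq_len(n_trials))
      bgs[[tr]] <- crossprod(Ab, P[(tr - 1) * nch + seq_len(nch), ])
    bg_pow <- mean(vapply(bgs, function(b) mean(b^2), numeric(1)))
    sc <- sqrt(background * p_sig / bg_pow)
    for (tr in seq_len(n_trials))
      signal[tr, , ] <- signal[tr, , ] + bgs[[tr]] * sc
  }
  noise_sd <- sqrt(p_sig / 10^(snr_db / 10))
  data <- signal + array(stats::rnorm(length(signal), sd = noise_sd),
                         dim(signal))
  truth <- do.call(rbind, lapply(seq_along(sources), function(i) {
    sp <- sources[[i]]
    data.frame(source = names(sources)[i] %||% paste0("s", i),
               surface = sp$surface, vertex = sp$vertex,
               band_lo = sp$band[1], band_hi = sp$band[2],
               modulation = sp$modulation, window_lo = sp$window[1],
               window_hi = sp$window[2], amplitude = sp$amplitude,
               patch_fwhm = sp$patch_fwhm)
  }))
  structure(list(epochs = epoched_data(data, fs, epoch[1], trials = schedule),
                 truth = truth, model = model, sensors = sensors, lf = lf,
                 noise_sd = noise_sd, snr_db = snr_db, seed = seed,
                 signal_power = p_sig),
            class = "laminar_session")
}

#' @export
print.laminar_session <- function(x, ...) {
  d <- dim(x$epochs$data)
  cat(sprintf("<laminar_session> %d trials x %d channels x %d samples, SNR %g dB, seed %d\n",
              d[1], d[2], d[3], x$snr_db, x$seed))
  print(x$truth[, c("source", "surface", "vertex", "band_lo", "band_hi",
                    "modulation")])
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The packaged band/window signal definitions
#'
#' Six band-limited signals with their analysis and baseline windows and
#' laminar hypotheses, as shipped in `inst/extdata/signal_definitions.yaml`.
#'
#' @return data frame with one row per signal.
#' @export
signal_definitions <- function() {
  path <- system.file("extdata", "signal_definitions.yaml", package = "laminar")
  y <- yaml::read_yaml(path)
  num <- function(x) as.numeric(unlist(x))   # mixed int/real YAML sequences
  do.call(rbind, lapply(y$signals, function(s)
    data.frame(name = s$name, event = s$event,
               band_lo = num(s$band)[1], band_hi = num(s$band)[2],
               woi_lo = num(s$woi)[1], woi_hi = num(s$woi)[2],
               baseline_lo = num(s$baseline)[1],
               baseline_hi = num(s$baseline)[2],
               hypothesis = s$hypothesis)))
}
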