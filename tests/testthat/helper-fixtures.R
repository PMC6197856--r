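# Shared fixtures, built once per test run. Small scales: geometry tests use
# a 42- or 162-vertex sphere; statistical fixtures are generated in code.

fixture_env <- new.env()

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

small_model <- function() fixture("small_model", function()
  make_two_layer_model(subdivisions = 2))

small_sensors <- function() fixture("small_sensors", function()
  make_sensor_array(60))

small_leadfield <- function() fixture("small_lf", function()
  build_lead_field(small_model(), small_sensors()))

# a single triangle in the z = 0 plane
flat_triangle <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               rbind(c(1, 2, 3)))
}

# brute-force Wilcoxon signed-rank: enumerate all sign assignments
wilcoxon_brute <- function(d, null_value = 0) {
  d <- d - null_value
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.vector(signs %*% r)
  maxW <- n * (n + 1) / 2
  lower <- mean(Wnull <= min(W, maxW - W) + 1e-9)
  list(W = W, p = min(1, 2 * lower))
}
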