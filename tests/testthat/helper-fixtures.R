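# Shared fixtures, built once per test run.  Everything is generated in
# code from the phantom generator; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

toy_sheep_malleus <- function()
  cached_fixture("malleus_sheep", toy_ossicle("malleus", "sheep"))

toy_sheep_chain <- function()
  cached_fixture("chain_sheep", toy_ossicle("chain", "sheep"))

toy_sheep_stapes <- function()
  cached_fixture("stapes_sheep", toy_ossicle("stapes", "sheep"))

toy_sheep_incus <- function()
  cached_fixture("incus_sheep", toy_ossicle("incus", "sheep"))

voxel_sphere <- function()
  cached_fixture("sphere_r40",
    voxelize(phantom_spec(list(prim_sphere(c(0, 0, 0), 0.4)),
                          spacing = 0.01), density = 1))

# small random phantom for property tests (1-2 primitives, coarse grid)
random_phantom <- function(rng_seed) {
  set.seed(rng_seed)
  prims <- list(prim_sphere(stats::runif(3, -0.2, 0.2),
                            stats::runif(1, 0.15, 0.3)))
  if (stats::runif(1) > 0.5) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    ctr <- prims[[1]]$center + u * (prims[[1]]$r + 0.25)
    prims <- c(prims, list(prim_box(ctr, stats::runif(3, 0.08, 0.2))))
  }
  voxelize(phantom_spec(prims, spacing = 0.02), density = 2)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Rodrigues rotation about a unit axis
rotation_about_test <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}
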