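# Probabilistic environment generation and Monte Carlo volume validation.

test_that("obstacle-free limit gives an empty spheroid list and alpha of one", {
  env <- generate_environment(arena_spec(alpha = 1, vf_astro = 0), seed = 5,
                              n_points = 1e4)
  expect_equal(nrow(env$spheroids), 0)
  est <- estimate_volume_fractions(env, n_points = 1e4, seed = 2,
                                   include_cleft_obstacles = FALSE)
  expect_identical(est$alpha_hat, 1)
  expect_identical(est$vf_astro_hat, 0)
})

test_that("single-sphere environment recovers the analytic sphere volume", {
  r <- 0.3
  env <- sphere_env(0.8, 0, 0, r)
  est <- estimate_volume_fractions(env, n_points = 2e5, seed = 3,
                                   include_cleft_obstacles = FALSE)
  alpha_true <- 1 - (4 / 3) * pi * r^3 / 4^3
  expect_lt(abs(est$alpha_hat - alpha_true), 3 * est$se_alpha + 1e-12)
})

test_that("baseline generation hits both volume-fraction targets within tolerance", {
  spec <- arena_spec(alpha = 0.2, vf_astro = 0.1)
  env <- generate_environment(spec, seed = 7, n_points = 1e5)
  expect_lt(abs(env$alpha_measured - 0.2), spec$tolerance)
  expect_lt(abs(env$vf_astro_measured - 0.1), spec$tolerance)
  # independent re-estimate agrees
  est <- estimate_volume_fractions(env, n_points = 2e5, seed = 9)
  expect_lt(abs(est$alpha_hat - 0.2), 0.015)
  expect_lt(abs(est$vf_astro_hat - 0.1), 0.015)
})

test_that("identical seeds are bit-identical and different seeds differ", {
  spec <- arena_spec()
  a <- generate_environment(spec, seed = 11, n_points = 3e4)
  b <- generate_environment(spec, seed = 11, n_points = 3e4)
  c <- generate_environment(spec, seed = 12, n_points = 3e4)
  expect_identical(a$spheroids, b$spheroids)
  expect_false(isTRUE(all.equal(a$spheroids$x, c$spheroids$x)))
})

test_that("radii are uniform on the configured range and respect the cleft gap", {
  spec <- arena_spec()
  radii <- c()
  for (s in 1:4) {
    env <- generate_environment(spec, seed = 20 + s, n_points = 3e4)
    radii <- c(radii, env$spheroids$r)
    # exhaustive cleft-gap check: surface clearance from the capsule
    d <- capsule_axis_dist(env$spheroids$x, env$spheroids$y, env$spheroids$z,
                           hz = spec$cleft$height_nm / 2000)
    clearance <- d - env$spheroids$r - spec$cleft$apposition_nm / 2000
    expect_true(all(clearance >= spec$min_gap_nm / 1000 - 1e-12))
  }
  expect_gt(length(radii), 1e4)
  ks <- suppressWarnings(ks.test(radii, "punif", 0.05, 0.3))
  expect_gt(ks$p.value, 0.01)
})

test_that("unreachable targets fail with a diagnostic", {
  spec <- arena_spec(alpha = 0.2, vf_astro = 0.1)
  expect_error(generate_environment(spec, seed = 1, n_points = 2e4,
                                    max_spheres = 10),
               "not reached")
})

test_that("point classification follows deepest containment with index ties", {
  env <- sphere_env(x = c(0.5, 0.64), y = c(0, 0), z = c(0, 0),
                    r = c(0.1, 0.1), role = c("neuronal", "astroglial"))
  # far corner is extracellular; sphere centres belong to their spheres
  labs <- point_classification(env, rbind(c(1.9, 1.9, 1.9), c(0.5, 0, 0),
                                          c(0.64, 0, 0)))
  expect_equal(as.character(labs),
               c("extracellular", "neuronal", "astroglial"))
  # points in the overlap: owner is the sphere with deepest containment
  xs <- seq(0.545, 0.595, by = 0.01)
  labs <- point_classification(env, cbind(xs, 0, 0))
  depth1 <- 0.1 - abs(xs - 0.5)
  depth2 <- 0.1 - abs(xs - 0.64)
  oracle <- ifelse(depth1 >= depth2, "neuronal", "astroglial")
  expect_equal(as.character(labs), oracle)
  expect_error(point_classification(env, cbind(3, 0, 0)), "outside")
})

test_that("classification agrees with an explicit per-sphere containment oracle", {
  env <- generate_environment(arena_spec(), seed = 31, n_points = 3e4)
  pts <- with(list(), {
    set.seed(42)
    matrix(runif(300, -2, 2), ncol = 3)
  })
  labs <- point_classification(env, pts)
  sph <- env$spheroids
  oracle <- apply(pts, 1, function(p) {
    d <- sqrt((p[1] - sph$x)^2 + (p[2] - sph$y)^2 + (p[3] - sph$z)^2)
    depth <- sph$r - d
    if (capsule_axis_dist(p[1], p[2], p[3], 0.01) <= 0.125 &&
        abs(p[3]) >= 0.01 &&
        sqrt(p[1]^2 + p[2]^2 + (abs(p[3]) - 0.01)^2) <= 0.125)
      return("cleft_obstacle")
    if (all(depth <= 0)) return("extracellular")
    as.character(sph$role[which.max(depth)])
  })
  expect_equal(as.character(labs), oracle)
})

test_that("environment serialisation round-trips", {
  env <- generate_environment(arena_spec(), seed = 3, n_points = 3e4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_environment(env, path)
  back <- read_environment(path)
  expect_equal(back$spheroids$x, env$spheroids$x, tolerance = 1e-12)
  expect_equal(back$spheroids$r, env$spheroids$r, tolerance = 1e-12)
  expect_equal(as.character(back$spheroids$role),
               as.character(env$spheroids$role))
  expect_equal(back$alpha_measured, env$alpha_measured, tolerance = 1e-12)
  expect_equal(back$spec$edge_um, env$spec$edge_um)
})
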