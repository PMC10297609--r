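# Brownian stepping, mirror reflections, proximity and boundaries.

test_that("release fills the cleft cylinder uniformly", {
  p1 <- release_particles(cleft_spec(), n = 1, seed = 1)
  expect_equal(nrow(p1), 1)
  n <- 2e4
  p <- release_particles(cleft_spec(), n = n, seed = 2)
  r <- sqrt(p$x^2 + p$y^2)
  expect_true(all(r <= 0.060 + 1e-12))
  expect_true(all(abs(p$z) <= 0.010 + 1e-12))
  # uniform in the cylinder: r^2 / R^2 and z are both uniform
  expect_gt(suppressWarnings(ks.test(r^2 / 0.060^2, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test((p$z + 0.010) / 0.020, "punif"))$p.value,
            0.01)
})

test_that("free Brownian increments have the Einstein variance", {
  pos <- matrix(0, 3, 3)
  expect_identical(brownian_step(pos, D = 0, dt = 1, seed = 1), pos)
  n <- 1e5
  stepped <- brownian_step(matrix(0, n, 3), D = 0.5, dt = 1e-3, seed = 4)
  v <- apply(stepped, 2, var)
  # per-axis variance 2 D dt = 1e-3; chi-square spread ~ sqrt(2/n)
  expect_true(all(abs(v / 1e-3 - 1) < 5 * sqrt(2 / n)))
})

test_that("head-on reflection off a sphere preserves the radial line and distance", {
  env <- sphere_env(0, 0, 0, 0.1, alpha_target = 0.99)
  old <- rbind(c(0.2, 0, 0))
  prop <- rbind(c(0.05, 0, 0)) # would end 0.05 inside the surface
  out <- resolve_collisions(env, old, prop, include_cleft_obstacles = FALSE)
  expect_equal(unname(out[1, ]), c(0.15, 0, 0), tolerance = 1e-7)
  # a segment that misses every surface is unchanged
  out2 <- resolve_collisions(env, rbind(c(0.5, 0.5, 0.5)),
                             rbind(c(0.52, 0.5, 0.5)),
                             include_cleft_obstacles = FALSE)
  expect_equal(unname(out2[1, ]), c(0.52, 0.5, 0.5), tolerance = 1e-12)
})

test_that("oblique reflections preserve path length and leave particles outside", {
  env <- sphere_env(0, 0, 0, 0.1, alpha_target = 0.99)
  set.seed(8)
  n <- 200
  # random segments starting outside aimed near/through the sphere
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  old <- u * runif(n, 0.12, 0.2)
  prop <- old + matrix(rnorm(3 * n, sd = 0.05), ncol = 3)
  out <- resolve_collisions(env, old, prop, include_cleft_obstacles = FALSE)
  d_out <- sqrt(rowSums(out^2))
  expect_true(all(d_out >= 0.1 - 1e-9))
  # reflected endpoints stay within the original step length of the start
  step_len <- sqrt(rowSums((prop - old)^2))
  end_dist <- sqrt(rowSums((out - old)^2))
  expect_true(all(end_dist <= step_len + 1e-9))
})

test_that("astro proximity reports exact distances and contact flags", {
  env <- sphere_env(x = c(0.5, -0.5), y = c(0, 0), z = c(0, 0),
                    r = c(0.1, 0.1), role = c("astroglial", "neuronal"))
  pts <- rbind(c(0.604, 0, 0),  # 4 nm from the astro surface
               c(0.606, 0, 0),  # 6 nm away
               c(-0.604, 0, 0)) # 4 nm from a *neuronal* surface
  pr <- astro_proximity(env, pts, cutoff_nm = 5)
  expect_equal(pr$in_contact, c(TRUE, FALSE, FALSE))
  expect_equal(pr$distance_um[1], 0.004, tolerance = 1e-9)
  none <- astro_proximity(empty_env(), pts)
  expect_true(all(!none$in_contact))
})

test_that("boundary conditions conserve or flag particles", {
  pos <- rbind(c(2.1, 0, 0), c(-2.3, 1, -1), c(0.5, 0.5, 0.5))
  refl <- boundary_condition(pos, edge_um = 4, boundary = "reflective")
  expect_equal(unname(refl[1, 1]), 1.9)
  expect_equal(unname(refl[2, 1]), -1.7)
  expect_equal(unname(refl[3, ]), c(0.5, 0.5, 0.5))
  expect_true(all(abs(refl) <= 2))
  open <- boundary_condition(pos, edge_um = 4, boundary = "open")
  expect_equal(attr(open, "escaped"), c(TRUE, TRUE, FALSE))
})

test_that("particles are conserved and never end inside solids", {
  env <- generate_environment(arena_spec(), seed = 41, n_points = 5e4)
  run <- simulate_run(env, n_particles = 50, seed = 6,
                      diffusion = diffusion_spec(
                        t_end_ms = 0.2,
                        record_t_ms = seq(0.02, 0.2, by = 0.02)))
  counts <- dplyr::count(run$snapshots, t_ms)
  expect_true(all(counts$n == 50))
  free <- dplyr::filter(run$snapshots, status == "free")
  labs <- point_classification(env, free[c("x", "y", "z")])
  expect_true(all(labs %in% c("extracellular")))
})

test_that("obstacles reduce the effective diffusion coefficient", {
  d <- diffusion_spec(dt_ms = 2e-5, t_end_ms = 0.5,
                      record_t_ms = seq(0.1, 0.5, by = 0.1))
  # free reference in an obstacle-free arena
  run_free <- simulate_run(empty_env(), n_particles = 400, seed = 9,
                           diffusion = d, include_cleft_obstacles = FALSE,
                           transporter = transporter_spec(enabled = FALSE))
  env <- generate_environment(arena_spec(alpha = 0.2, vf_astro = 0),
                              seed = 55, n_points = 5e4)
  run_obs <- simulate_run(env, n_particles = 400, seed = 9, diffusion = d,
                          transporter = transporter_spec(enabled = FALSE))
  slope <- function(run) {
    msd <- run$snapshots |>
      dplyr::group_by(t_ms) |>
      dplyr::summarise(msd = mean(x^2 + y^2 + z^2))
    unname(coef(lm(msd ~ t_ms, data = msd))[2])
  }
  D_free <- slope(run_free) / 6
  D_obs <- slope(run_obs) / 6
  expect_gt(D_free, D_obs)
  expect_lt(D_obs / 0.5, 0.95) # tortuosity is a real slow-down
})

test_that("identical run seeds reproduce trajectories bit for bit", {
  env <- generate_environment(arena_spec(), seed = 77, n_points = 3e4)
  d <- diffusion_spec(t_end_ms = 0.05, record_t_ms = 0.05)
  a <- simulate_run(env, n_particles = 30, seed = 13, diffusion = d)
  b <- simulate_run(env, n_particles = 30, seed = 13, diffusion = d)
  expect_identical(a$snapshots, b$snapshots)
})
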