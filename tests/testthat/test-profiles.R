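# Shell binning, extracellular volumes, concentration conversion, averaging.

fake_ensemble <- function(x, y, z, status = "free") {
  tibble::tibble(x = x, y = y, z = z,
                 status = factor(status, levels = c("free", "bound",
                                                    "retained", "escaped")))
}

test_that("shell binning is half-open, exhaustive and conserving", {
  grid <- shell_grid(shell_width_nm = 20, max_radius_um = 0.2)
  one <- shell_counts(fake_ensemble(0.030, 0, 0), grid)
  expect_equal(one$free_count[one$r_lo_nm == 20], 1)
  expect_equal(sum(one$free_count), 1)
  origin <- shell_counts(fake_ensemble(rep(0, 5), rep(0, 5), rep(0, 5)), grid)
  expect_equal(origin$free_count[1], 5)
  set.seed(3)
  n <- 5000
  ens <- fake_ensemble(runif(n, -0.3, 0.3), runif(n, -0.3, 0.3),
                       runif(n, -0.3, 0.3),
                       status = sample(c("free", "bound"), n, replace = TRUE))
  cnt <- shell_counts(ens, grid)
  over <- attr(cnt, "overflow")
  expect_equal(sum(cnt$free_count) + over[["free"]] +
                 sum(cnt$bound_count) + over[["bound"]], n)
})

test_that("retained particles count as bound glutamate in shell tallies", {
  grid <- shell_grid(shell_width_nm = 20, max_radius_um = 0.1)
  ens <- fake_ensemble(c(0.01, 0.03, 0.05), 0, 0,
                       status = c("bound", "retained", "free"))
  cnt <- shell_counts(ens, grid)
  expect_equal(sum(cnt$bound_count), 2)
  expect_equal(sum(cnt$free_count), 1)
})

test_that("shell extracellular volumes match analytic limits", {
  grid <- shell_grid(shell_width_nm = 100, max_radius_um = 0.5)
  vols <- shell_ec_volumes(empty_env(), grid, n_points = 2e4, seed = 1)
  # no spheroids: extracellular volume equals the analytic shell volume
  # except for the small cleft capsule bite in the innermost shells
  outer <- vols[vols$r_lo_nm >= 200, ]
  expect_equal(outer$ec_vol_um3, outer$shell_vol_um3, tolerance = 1e-9)
  # a shell fully buried inside one neuronal sphere has no extracellular room
  env <- sphere_env(0, 0, 0, 0.45)
  buried <- shell_ec_volumes(env, grid, n_points = 2e4, seed = 2)
  expect_equal(buried$ec_vol_um3[buried$r_lo_nm == 200], 0, tolerance = 1e-12)
  # baseline far-field extracellular fraction is close to alpha
  base <- generate_environment(arena_spec(), seed = 8, n_points = 5e4)
  g2 <- shell_grid(shell_width_nm = 100, max_radius_um = 1.5)
  v2 <- shell_ec_volumes(base, g2, n_points = 3e4, seed = 3)
  far <- v2[v2$r_lo_nm >= 500, ]
  expect_lt(abs(mean(far$ec_frac) - 0.2), 0.03)
})

test_that("concentration conversion follows Avogadro arithmetic", {
  grid <- shell_grid(shell_width_nm = 20, max_radius_um = 0.04)
  cnt <- tibble::tibble(shell = 1:2, r_lo_nm = c(0, 20), r_hi_nm = c(20, 40),
                        free_count = c(0, 1), bound_count = c(0, 0))
  vols <- tibble::tibble(shell = 1:2, ec_vol_um3 = c(1e-4, 1e-4))
  conc <- to_concentration(cnt, vols, scale_factor = 3)
  expect_equal(conc$free_mM[1], 0)
  expect_equal(conc$free_mM[2], 1000 * 3 / (6.02214076e23 * 1e-19),
               tolerance = 1e-6)
  expect_equal(conc$free_mM[2], 0.0498, tolerance = 1e-3)
  # linear in the scale factor
  conc6 <- to_concentration(cnt, vols, scale_factor = 6)
  expect_equal(conc6$free_mM[2], 2 * conc$free_mM[2])
  # zero-volume shells with particles are flagged, not dropped
  vols0 <- tibble::tibble(shell = 1:2, ec_vol_um3 = c(1e-4, 0))
  expect_warning(flagged <- to_concentration(cnt, vols0), "zero extracellular")
  expect_true(flagged$flagged[2])
  expect_true(is.na(flagged$free_mM[2]))
})

test_that("run averaging gives the exact two-run closed form", {
  base <- tibble::tibble(t_ms = 1, shell = 1:3, r_lo_nm = c(0, 20, 40),
                         r_hi_nm = c(20, 40, 60),
                         free_count = 1:3, bound_count = 0:2,
                         ec_vol_um3 = 1e-4,
                         free_mM = c(1, 2, 3), bound_mM = c(0, 1, 2),
                         flagged = FALSE)
  same <- average_runs(list(base, base))
  expect_true(all(same$summary$sem_free_mM == 0))
  expect_equal(same$summary$mean_free_mM, base$free_mM)
  b2 <- dplyr::mutate(base, free_mM = c(3, 2, 1))
  two <- average_runs(list(base, b2))
  expect_equal(two$summary$mean_free_mM, c(2, 2, 2))
  expect_equal(two$summary$sem_free_mM, abs(base$free_mM - b2$free_mM) / 2)
  bad <- dplyr::mutate(base, shell = shell + 1)
  expect_error(average_runs(list(base, bad)), "mismatched")
  expect_identical(tidy(two), two$summary)
})

test_that("obstacle-free shell profile matches the point-source closed form", {
  d <- diffusion_spec(D_um2_ms = 0.5, dt_ms = 5e-4, t_end_ms = 1,
                      record_t_ms = 1)
  run <- simulate_run(empty_env(edge_um = 8), n_particles = 2e4, seed = 21,
                      diffusion = d, include_cleft_obstacles = FALSE,
                      transporter = transporter_spec(enabled = FALSE))
  grid <- shell_grid(shell_width_nm = 100, max_radius_um = 4)
  cnt <- shell_counts(dplyr::filter(run$snapshots, t_ms == 1), grid)
  # radial mass in [a, b): chi-square_3 law with per-axis variance 2 D t
  s2 <- 2 * 0.5 * 1
  p <- diff(pchisq(c(grid$r_lo, max(grid$r_hi))^2 / s2, df = 3))
  keep <- which(2e4 * p >= 5 & grid$r_hi <= 3.5)
  chisq <- sum((cnt$free_count[keep] - 2e4 * p[keep])^2 / (2e4 * p[keep]))
  expect_gt(pchisq(chisq, df = length(keep) - 1, lower.tail = FALSE), 1e-3)
})

test_that("psi calibration is self-consistent on its own output", {
  fac <- bound_profile_factory(n_runs = 1, n_particles = 120, t_eval_ms = 2,
                               grid = shell_grid(shell_width_nm = 40,
                                                 max_radius_um = 1),
                               ec_points = 5e3, seed = 70)
  ref <- fac(1)
  expect_gt(max(ref$signal), 0)
  fit <- fit_psi(ref, fac, psi_grid = c(0.5, 1, 2), t_eval_ms = 2)
  expect_equal(fit$best_psi, 1)
  expect_equal(min(fit$grid$sse), 0, tolerance = 1e-18)
  expect_identical(tidy(fit), fit$grid)
  expect_equal(glance(fit)$best_psi, 1)
  expect_error(fit_psi(ref[1:2, ], fac), "at least 3")
})
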