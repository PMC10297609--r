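# Orchestration: config validation, YAML round trip, determinism, pairing.

test_that("configs validate physical consistency", {
  expect_error(run_config(conditions = tibble::tibble(
    alpha = 0.9, vf_astro = 0.3, unbinding = TRUE)), "solid fraction")
  expect_error(run_config(diffusion = diffusion_spec(dt_ms = 1e-3)),
               "time step too coarse")
  cfg <- run_config(n_particles = 10, n_runs = 1)
  expect_s3_class(cfg, "run_config")
})

test_that("configurations round-trip through YAML losslessly", {
  cfg <- run_config(
    arena = arena_spec(alpha = 0.25, vf_astro = 0.05, r_max_nm = 250),
    transporter = transporter_spec(psi_ms = 0.7, p_unbind = 0.2),
    diffusion = diffusion_spec(dt_ms = 1e-5, t_end_ms = 5,
                               record_t_ms = c(1, 2, 5)),
    conditions = tibble::tibble(alpha = c(0.25, 0.1),
                                vf_astro = c(0.05, 0.05),
                                unbinding = c(TRUE, FALSE)),
    n_particles = 123, n_runs = 3, seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$arena, cfg$arena)
  expect_equal(back$transporter, cfg$transporter)
  expect_equal(back$diffusion, cfg$diffusion)
  expect_equal(back$conditions, cfg$conditions)
  expect_equal(back$n_particles, cfg$n_particles)
  expect_equal(back$seed, cfg$seed)
})

test_that("seed derivation is deterministic, bounded and index-sensitive", {
  s1 <- derive_seed(1, 2, 3)
  expect_identical(s1, derive_seed(1, 2, 3))
  expect_false(s1 == derive_seed(1, 3, 2))
  expect_false(s1 == derive_seed(2, 2, 3))
  many <- sapply(1:500, function(i) derive_seed(7, i, 1))
  expect_true(all(many >= 1 & many < 2^31))
  expect_equal(length(unique(many)), 500)
})

test_that("a smoke-scale experiment completes and conserves particles", {
  cfg <- run_config(n_particles = 10, n_runs = 1, seed = 3,
                    diffusion = diffusion_spec(t_end_ms = 0.1,
                                               record_t_ms = c(0.05, 0.1)),
                    ec_points = 2e3, env_points = 2e4)
  ex <- run_experiment(cfg)
  prof <- ex$results[[1]]$series$runs
  tot <- prof |>
    dplyr::group_by(t_ms) |>
    dplyr::summarise(n = sum(free_count + bound_count))
  expect_true(all(tot$n == 10))
})

test_that("identical master seeds give byte-identical aggregate outputs", {
  cfg <- run_config(n_particles = 15, n_runs = 2, seed = 8,
                    diffusion = diffusion_spec(t_end_ms = 0.1,
                                               record_t_ms = 0.1),
                    ec_points = 2e3, env_points = 2e4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_experiment(cfg, outdir = d1)
  run_experiment(cfg, outdir = d2)
  f1 <- list.files(d1, pattern = "csv$", full.names = TRUE)
  f2 <- list.files(d2, pattern = "csv$", full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
})

test_that("without astroglia the paired unbinding arms are identical", {
  cfg <- run_config(n_particles = 40, n_runs = 2, seed = 21,
                    conditions = tibble::tibble(alpha = 0.3, vf_astro = 0,
                                                unbinding = TRUE),
                    diffusion = diffusion_spec(t_end_ms = 0.2,
                                               record_t_ms = c(0.1, 0.2)),
                    ec_points = 2e3, env_points = 2e4)
  ex <- paired_conditions(cfg)
  expect_equal(nrow(ex$config$conditions), 2)
  on <- ex$results[[1]]$series$summary
  off <- ex$results[[2]]$series$summary
  expect_identical(on$mean_free_mM, off$mean_free_mM)
  expect_identical(on$mean_bound_mM, off$mean_bound_mM)
})

test_that("the unbinding contrast vanishes continuously as p_unbind goes to zero", {
  # shared seeds: arm differences shrink with p_unbind
  cfg0 <- run_config(n_particles = 150, n_runs = 2, seed = 31,
                     diffusion = diffusion_spec(t_end_ms = 1,
                                                record_t_ms = c(0.5, 1)),
                     ec_points = 5e3, env_points = 5e4)
  free_at_end <- function(p_unbind) {
    cfg <- cfg0
    cfg$transporter$p_unbind <- p_unbind
    res <- simulate_condition(cfg, alpha = 0.2, vf_astro = 0.1,
                              unbinding = TRUE, cond_index = 1)
    sum(dplyr::filter(res$series$runs, t_ms == 1)$free_count)
  }
  f0 <- free_at_end(0)
  f35 <- free_at_end(0.35)
  ref <- simulate_condition(cfg0, alpha = 0.2, vf_astro = 0.1,
                            unbinding = FALSE, cond_index = 1)
  f_off <- sum(dplyr::filter(ref$series$runs, t_ms == 1)$free_count)
  # p_unbind = 0 with unbinding "on" must equal the unbinding-off arm
  expect_identical(f0, f_off)
  expect_gte(f35, f0)
})
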