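# Experiment orchestration: run configuration, seeded multi-run simulation of
# conditions, paired unbinding-on/off contrasts, output bundles.

#' Build a run configuration
#'
#' Collects every module's parameters plus the experiment layout (conditions,
#' run counts, master seed). The defaults are the baseline hippocampal
#' configuration: 4 um arena, alpha = 0.2, vf_astro = 0.1, psi = 1 ms,
#' p_unbind = 0.35, 1000 particles.
#'
#' @param arena An [arena_spec()] (its `alpha`/`vf_astro` act as defaults for
#'   conditions that do not override them).
#' @param transporter A [transporter_spec()].
#' @param diffusion A [diffusion_spec()].
#' @param conditions A data frame with columns `alpha`, `vf_astro`,
#'   `unbinding` (logical); default: the single baseline condition with
#'   unbinding on.
#' @param n_particles Particles per run.
#' @param n_runs Environment realisations per condition.
#' @param scale_factor Molecule-count scaling for concentrations.
#' @param shell_width_nm Profile shell thickness.
#' @param ec_points Test points per shell-volume estimate.
#' @param env_points Internal test points per environment generation.
#' @param seed Master seed; all sub-stream seeds derive from it.
#' @return An object of class `run_config`.
#' @export
#' @examples
#' run_config(n_particles = 100, n_runs = 2)
run_config <- function(arena = arena_spec(),
                       transporter = transporter_spec(),
                       diffusion = diffusion_spec(),
                       conditions = NULL,
                       n_particles = 1000, n_runs = 10, scale_factor = 3,
                       shell_width_nm = 20, ec_points = 1e5,
                       env_points = 2e5, seed = 1) {
  if (is.null(conditions))
    conditions <- tibble::tibble(alpha = arena$alpha,
                                 vf_astro = arena$vf_astro, unbinding = TRUE)
  conditions <- tibble::as_tibble(conditions)
  stopifnot(all(c("alpha", "vf_astro", "unbinding") %in% names(conditions)),
            n_particles >= 1, n_runs >= 1)
  cfg <- structure(list(arena = arena, transporter = transporter,
                        diffusion = diffusion, conditions = conditions,
                        n_particles = n_particles, n_runs = n_runs,
                        scale_factor = scale_factor,
                        shell_width_nm = shell_width_nm,
                        ec_points = ec_points, env_points = env_points,
                        seed = seed),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Rejects physically inconsistent settings with actionable messages: solid
#' fractions exceeding the arena, a time step violating the proximity
#' resolution guard, or malformed condition tables.
#'
#' @param config A `run_config`.
#' @return `config`, invisibly.
#' @export
validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bad <- config$conditions$alpha + config$conditions$vf_astro > 1 |
    config$conditions$alpha <= 0 | config$conditions$vf_astro < 0
  if (any(bad))
    stop(sprintf(paste0("condition(s) %s imply a solid fraction above 1 or ",
                        "invalid fractions; require alpha > 0, vf_astro >= 0, ",
                        "alpha + vf_astro <= 1"),
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  check_resolution_guard(config$diffusion, config$transporter$cutoff_nm)
  invisible(config)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %d condition(s) x %d runs x %d particles, master seed %g\n",
    nrow(x$conditions), x$n_runs, x$n_particles, x$seed))
  print(x$conditions)
  invisible(x)
}

#' Read/write a run configuration as YAML
#'
#' Config keys follow a flat dotted scheme (`arena.edge_um`, `arena.alpha`,
#' `arena.vf_astro`, `arena.r_min_nm`, `arena.r_max_nm`, `arena.min_gap_nm`,
#' `cleft.width_nm`, `cleft.height_nm`, `cleft.apposition_nm`,
#' `diffusion.*`, `transporter.*`, `run.*`, `seed`, and a `conditions` list
#' of `{alpha, vf_astro, unbinding}` records). Configurations round-trip
#' losslessly.
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config`; for `write_run_config`,
#'   `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(lst, key, default) lst[[key]] %||% default
  ar <- y$arena %||% list()
  cl <- y$cleft %||% list()
  df <- y$diffusion %||% list()
  tr <- y$transporter %||% list()
  rn <- y$run %||% list()
  cleft <- cleft_spec(width_nm = pick(cl, "width_nm", 120),
                      height_nm = pick(cl, "height_nm", 20),
                      apposition_nm = pick(cl, "apposition_nm", 250))
  arena <- arena_spec(edge_um = pick(ar, "edge_um", 4),
                      alpha = pick(ar, "alpha", 0.2),
                      vf_astro = pick(ar, "vf_astro", 0.1),
                      r_min_nm = pick(ar, "r_min_nm", 50),
                      r_max_nm = pick(ar, "r_max_nm", 300),
                      cleft = cleft,
                      min_gap_nm = pick(ar, "min_gap_nm", 10),
                      tolerance = pick(ar, "tolerance", 0.01))
  transporter <- transporter_spec(
    psi_ms = pick(tr, "psi_ms", 1), p_unbind = pick(tr, "p_unbind", 0.35),
    unbind_mu_ms = pick(tr, "unbind_mu_ms", 4),
    unbind_sigma_ms = pick(tr, "unbind_sigma_ms", 2),
    cutoff_nm = pick(tr, "cutoff_nm", 5), enabled = pick(tr, "enabled", TRUE))
  diffusion <- diffusion_spec(
    D_um2_ms = pick(df, "D_um2_ms", 0.5), dt_ms = pick(df, "dt_ms", 2e-5),
    t_end_ms = pick(df, "t_end_ms", 10),
    record_t_ms = unlist(pick(df, "record_t_ms",
                              c(0.1, 0.5, 1, 2, 4, 6, 8, 10))),
    boundary = pick(df, "boundary", "reflective"))
  conditions <- if (!is.null(y$conditions))
    dplyr::bind_rows(lapply(y$conditions, tibble::as_tibble)) else NULL
  run_config(arena = arena, transporter = transporter, diffusion = diffusion,
             conditions = conditions,
             n_particles = pick(rn, "n_particles", 1000),
             n_runs = pick(rn, "n_runs", 10),
             scale_factor = pick(rn, "scale_factor", 3),
             shell_width_nm = pick(rn, "shell_width_nm", 20),
             ec_points = pick(rn, "ec_points", 1e5),
             env_points = pick(rn, "env_points", 2e5),
             seed = pick(y, "seed", 1))
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  a <- config$arena; cl <- a$cleft; d <- config$diffusion
  tr <- config$transporter
  y <- list(
    arena = list(edge_um = a$edge_um, alpha = a$alpha,
                 vf_astro = a$vf_astro, r_min_nm = a$r_min_nm,
                 r_max_nm = a$r_max_nm, min_gap_nm = a$min_gap_nm,
                 tolerance = a$tolerance),
    cleft = list(width_nm = cl$width_nm, height_nm = cl$height_nm,
                 apposition_nm = cl$apposition_nm),
    diffusion = list(D_um2_ms = d$D_um2_ms, dt_ms = d$dt_ms,
                     t_end_ms = d$t_end_ms,
                     record_t_ms = as.list(d$record_t_ms),
                     boundary = d$boundary),
    transporter = list(psi_ms = tr$psi_ms, p_unbind = tr$p_unbind,
                       unbind_mu_ms = tr$unbind_mu_ms,
                       unbind_sigma_ms = tr$unbind_sigma_ms,
                       cutoff_nm = tr$cutoff_nm, enabled = tr$enabled),
    run = list(n_particles = config$n_particles, n_runs = config$n_runs,
               scale_factor = config$scale_factor,
               shell_width_nm = config$shell_width_nm,
               ec_points = config$ec_points, env_points = config$env_points),
    conditions = lapply(seq_len(nrow(config$conditions)), function(i)
      as.list(config$conditions[i, ])),
    seed = config$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Simulate one condition: fresh environments, runs, averaged profiles
#'
#' The workhorse behind [run_experiment()]: for each of `n_runs`
#' realisations, generates a fresh environment at the condition's
#' `(alpha, vf_astro)`, simulates particle dynamics, and computes the
#' per-run shell profile; then averages across runs. Sub-stream seeds
#' derive from `(seed, cond_index, run_index, module)`, and the unbinding
#' flag does not enter seed derivation, so paired conditions share
#' environments and per-particle diffusion noise.
#'
#' @param config A `run_config`.
#' @param alpha,vf_astro Condition volume fractions.
#' @param unbinding Logical: transporter unbinding on (`p_unbind` from the
#'   config) or off (`p_unbind = 0`).
#' @param cond_index Condition index used in seed derivation.
#' @return A list: `series` (a `glu_profile_series`), `envs` (per-run
#'   measured fractions), `counters` (per-run tallies).
#' @export
simulate_condition <- function(config, alpha, vf_astro, unbinding = TRUE,
                               cond_index = 1) {
  stopifnot(inherits(config, "run_config"))
  a <- config$arena
  spec <- arena_spec(edge_um = a$edge_um, alpha = alpha, vf_astro = vf_astro,
                     r_min_nm = a$r_min_nm, r_max_nm = a$r_max_nm,
                     cleft = a$cleft, min_gap_nm = a$min_gap_nm,
                     tolerance = a$tolerance)
  tr <- config$transporter
  if (!unbinding) tr$p_unbind <- 0
  # shells reach the arena's corner radius so every particle is binned and
  # the per-time conservation invariant holds exactly
  grid <- shell_grid(config$shell_width_nm,
                     max_radius_um = a$edge_um * sqrt(3) / 2)
  envs <- vector("list", config$n_runs)
  runs <- vector("list", config$n_runs)
  profiles <- vector("list", config$n_runs)
  for (i in seq_len(config$n_runs)) {
    env <- generate_environment(spec,
                                seed = derive_seed(config$seed, cond_index, i, 1),
                                n_points = config$env_points)
    run <- simulate_run(env, n_particles = config$n_particles,
                        seed = derive_seed(config$seed, cond_index, i, 2),
                        transporter = tr, diffusion = config$diffusion)
    profiles[[i]] <- run_profile(run, env, grid,
                                 n_points = config$ec_points,
                                 seed = derive_seed(config$seed, cond_index, i, 3),
                                 scale_factor = config$scale_factor)
    envs[[i]] <- tibble::tibble(run = i, alpha_measured = env$alpha_measured,
                                vf_astro_measured = env$vf_astro_measured,
                                n_spheroids = nrow(env$spheroids))
    runs[[i]] <- dplyr::mutate(run$counters, run = i)
  }
  series <- if (config$n_runs >= 2) average_runs(profiles) else {
    one <- dplyr::mutate(profiles[[1]], run = 1L)
    structure(list(
      runs = one,
      summary = dplyr::mutate(
        one, r_mid_nm = (.data$r_lo_nm + .data$r_hi_nm) / 2,
        mean_free_mM = .data$free_mM, sem_free_mM = NA_real_,
        mean_bound_mM = .data$bound_mM, sem_bound_mM = NA_real_,
        n_runs = 1L),
      n_runs = 1L), class = "glu_profile_series")
  }
  list(series = series, envs = dplyr::bind_rows(envs),
       counters = dplyr::bind_rows(runs))
}

#' Run a full experiment over all configured conditions
#'
#' For each condition x run: a fresh environment, the full simulation, and
#' shell profiles; per-condition aggregates; and a manifest of the seeds
#' used. Identical config and master seed give bit-identical outputs. When
#' `outdir` is given, per-run and aggregated profile CSVs plus the manifest
#' (YAML) are written there.
#'
#' @param config A `run_config`.
#' @param outdir Optional output directory.
#' @return An object of class `glu_experiment`: per-condition results and a
#'   manifest tibble.
#' @export
#' @examples
#' cfg <- run_config(n_particles = 10, n_runs = 1,
#'                   diffusion = diffusion_spec(dt_ms = 2e-4, t_end_ms = 0.1,
#'                                              record_t_ms = 0.1))
#' ex <- run_experiment(cfg)
run_experiment <- function(config, outdir = NULL) {
  validate_run_config(config)
  t0 <- Sys.time()
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  results <- vector("list", nrow(config$conditions))
  for (ci in seq_len(nrow(config$conditions))) {
    cond <- config$conditions[ci, ]
    res <- simulate_condition(config, alpha = cond$alpha,
                              vf_astro = cond$vf_astro,
                              unbinding = cond$unbinding, cond_index = ci)
    res$condition <- cond
    if (!is.null(outdir)) {
      tag <- sprintf("cond%02d_a%03.0f_vf%03.0f_%s", ci, cond$alpha * 100,
                     cond$vf_astro * 100,
                     if (cond$unbinding) "unbind" else "nounbind")
      write_profiles(res$series,
                     runs_path = file.path(outdir, paste0(tag, "_runs.csv")),
                     summary_path = file.path(outdir, paste0(tag, "_mean.csv")))
    }
    results[[ci]] <- res
  }
  manifest <- tidyr::crossing(condition = seq_len(nrow(config$conditions)),
                              run = seq_len(config$n_runs)) |>
    dplyr::mutate(
      env_seed = purrr::map2_dbl(.data$condition, .data$run,
                                 ~derive_seed(config$seed, .x, .y, 1)),
      particle_seed = purrr::map2_dbl(.data$condition, .data$run,
                                      ~derive_seed(config$seed, .x, .y, 2)))
  ex <- structure(list(config = config, results = results,
                       manifest = manifest,
                       wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs"))),
                  class = "glu_experiment")
  if (!is.null(outdir)) {
    write_run_config(config, file.path(outdir, "config.yaml"))
    yaml::write_yaml(list(wall_time_s = ex$wall_time_s,
                          n_conditions = nrow(config$conditions),
                          n_runs = config$n_runs,
                          master_seed = config$seed),
                     file.path(outdir, "manifest.yaml"))
  }
  ex
}

#' @export
print.glu_experiment <- function(x, ...) {
  cat(sprintf("<glu_experiment> %d condition(s), %d runs each, %.1f s\n",
              nrow(x$config$conditions), x$config$n_runs, x$wall_time_s))
  invisible(x)
}

#' Paired unbinding-on/off experiment
#'
#' Duplicates each configured `(alpha, vf_astro)` condition into an
#' unbinding-on and an unbinding-off arm. Both arms use identical
#' environments and per-particle diffusion streams (seeds derive from the
#' condition pair index, not the unbinding flag), so the contrast between
#' arms is variance-reduced.
#'
#' @param config A `run_config`; its `conditions` rows define the pairs (the
#'   `unbinding` column is ignored).
#' @return A `glu_experiment` whose conditions alternate on/off per pair,
#'   with a `pair` column in `$config$conditions`.
#' @export
paired_conditions <- function(config) {
  stopifnot(inherits(config, "run_config"))
  base <- dplyr::distinct(config$conditions[c("alpha", "vf_astro")])
  paired <- base |>
    dplyr::mutate(pair = dplyr::row_number()) |>
    tidyr::crossing(unbinding = c(TRUE, FALSE)) |>
    dplyr::arrange(.data$pair, dplyr::desc(.data$unbinding))
  cfg <- config
  cfg$conditions <- paired
  results <- vector("list", nrow(paired))
  for (k in seq_len(nrow(paired))) {
    row <- paired[k, ]
    # seed index = pair index, shared across the two arms
    res <- simulate_condition(cfg, alpha = row$alpha, vf_astro = row$vf_astro,
                              unbinding = row$unbinding,
                              cond_index = row$pair)
    res$condition <- row
    results[[k]] <- res
  }
  structure(list(config = cfg, results = results,
                 manifest = NULL, wall_time_s = NA_real_),
            class = "glu_experiment")
}
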