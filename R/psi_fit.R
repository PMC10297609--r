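# Calibration of the transporter binding time constant psi against a
# reference spatial profile of bound glutamate.

#' Simulation factory for bound-glutamate spatial profiles
#'
#' Returns a function of `psi` that simulates `n_runs` fresh environment
#' realisations plus particle dynamics and yields the across-run mean
#' bound-glutamate profile at `t_eval_ms`, as a two-column tibble
#' (`distance_nm`, `signal`). Used by [fit_psi()] and to generate synthetic
#' reference profiles.
#'
#' @param spec An [arena_spec()].
#' @param transporter Template [transporter_spec()]; its `psi_ms` is
#'   overridden by the factory argument.
#' @param diffusion A [diffusion_spec()]; must record `t_eval_ms`.
#' @param grid A [shell_grid()].
#' @param n_runs,n_particles Simulation scale per psi evaluation.
#' @param t_eval_ms Snapshot time of the profile (ms).
#' @param ec_points Test points for shell volume estimation.
#' @param seed Integer seed; run seeds are derived per (psi-independent) run
#'   index so different psi values see identical environments.
#' @return `function(psi) -> tibble(distance_nm, signal)`.
#' @export
bound_profile_factory <- function(spec = arena_spec(),
                                  transporter = transporter_spec(),
                                  diffusion = NULL, grid = shell_grid(),
                                  n_runs = 2, n_particles = 200,
                                  t_eval_ms = 4, ec_points = 2e4, seed = 1) {
  if (is.null(diffusion))
    diffusion <- diffusion_spec(t_end_ms = t_eval_ms, record_t_ms = t_eval_ms)
  if (!any(abs(diffusion$record_t_ms - t_eval_ms) < 1e-9))
    stop("diffusion spec does not record t_eval_ms", call. = FALSE)
  force(list(spec, transporter, grid, n_runs, n_particles, ec_points, seed))
  function(psi) {
    tr <- transporter
    tr$psi_ms <- psi
    profs <- purrr::map(seq_len(n_runs), function(i) {
      env <- generate_environment(spec, seed = derive_seed(seed, i, 1))
      run <- simulate_run(env, n_particles = n_particles,
                          seed = derive_seed(seed, i, 2),
                          transporter = tr, diffusion = diffusion)
      run_profile(run, env, grid, n_points = ec_points,
                  seed = derive_seed(seed, i, 3))
    })
    ser <- if (n_runs >= 2) average_runs(profs)$summary else
      dplyr::mutate(profs[[1]],
                    r_mid_nm = (.data$r_lo_nm + .data$r_hi_nm) / 2,
                    mean_bound_mM = .data$bound_mM)
    d <- dplyr::filter(ser, abs(.data$t_ms - t_eval_ms) < 1e-9)
    tibble::tibble(distance_nm = d$r_mid_nm,
                   signal = ifelse(is.na(d$mean_bound_mM), 0, d$mean_bound_mM))
  }
}

#' Synthetic reference profile of bound glutamate
#'
#' Generates a stand-in for an experimentally imaged glutamate-sensor spatial
#' profile by simulating the bound-glutamate profile at `t_eval_ms` under a
#' known `psi`. Being simulation-derived, it is a synthetic reference: it
#' supports calibration tests and demonstrations, not comparison with real
#' imaging data.
#'
#' @param psi True binding time constant used to generate the reference (ms).
#' @inheritParams bound_profile_factory
#' @param ... Passed to [bound_profile_factory()].
#' @return A tibble (`distance_nm`, `signal`), peak-normalised.
#' @export
synthetic_reference_profile <- function(psi = 1, seed = 100, ...) {
  prof <- bound_profile_factory(seed = seed, ...)(psi)
  peak <- max(prof$signal)
  if (peak > 0) prof$signal <- prof$signal / peak
  prof
}

#' Calibrate psi against a reference bound-glutamate profile
#'
#' Grid search: for each candidate `psi`, the factory simulates the
#' bound-glutamate spatial profile at the evaluation time; both the simulated
#' and the reference profile are normalised to unit peak (only profile shape
#' is comparable between a fluorescence readout and a concentration), and the
#' sum of squared differences over the overlapping distance range is
#' minimised.
#'
#' @param reference A two-column data frame (`distance_nm`, `signal`), at
#'   least 3 points.
#' @param sim_factory A `function(psi) -> tibble(distance_nm, signal)`, e.g.
#'   from [bound_profile_factory()].
#' @param psi_grid Candidate psi values (ms), within (0, Inf); the standard
#'   calibration range is 0.1 to 10 ms.
#' @param t_eval_ms Evaluation time, carried for reporting.
#' @return An object of class `psi_fit` with `best_psi`, the discrepancy
#'   curve, and the matched profiles at the optimum.
#' @export
fit_psi <- function(reference, sim_factory,
                    psi_grid = c(0.1, 0.2, 0.5, 1, 2, 5, 10),
                    t_eval_ms = 4) {
  stopifnot(is.function(sim_factory), all(psi_grid > 0))
  reference <- tibble::as_tibble(reference)
  if (!all(c("distance_nm", "signal") %in% names(reference)))
    stop("reference needs columns distance_nm and signal", call. = FALSE)
  if (nrow(reference) < 3)
    stop("reference profile needs at least 3 points", call. = FALSE)
  ref <- reference
  ref$signal <- ref$signal / max(ref$signal)

  evals <- purrr::map(psi_grid, function(psi) {
    sim <- sim_factory(psi)
    lo <- max(min(ref$distance_nm), min(sim$distance_nm))
    hi <- min(max(ref$distance_nm), max(sim$distance_nm))
    if (hi <= lo)
      stop("reference and simulated profiles have no overlapping distance range",
           call. = FALSE)
    keep <- ref$distance_nm >= lo & ref$distance_nm <= hi
    peak <- max(sim$signal)
    simn <- if (peak > 0) sim$signal / peak else sim$signal
    pred <- stats::approx(sim$distance_nm, simn, xout = ref$distance_nm[keep])$y
    list(sse = sum((pred - ref$signal[keep])^2), sim = sim)
  })
  sse <- purrr::map_dbl(evals, "sse")
  best <- which.min(sse)
  structure(list(
    best_psi = psi_grid[best],
    grid = tibble::tibble(psi = psi_grid, sse = sse),
    reference = ref, t_eval_ms = t_eval_ms,
    best_profile = evals[[best]]$sim), class = "psi_fit")
}

#' @export
print.psi_fit <- function(x, ...) {
  cat(sprintf("<psi_fit> best psi = %g ms over grid [%g, %g] ms (%d points)\n",
              x$best_psi, min(x$grid$psi), max(x$grid$psi), nrow(x$grid)))
  invisible(x)
}

#' @rdname fit_psi
#' @param x A `psi_fit`.
#' @param ... Unused.
#' @export
tidy.psi_fit <- function(x, ...) x$grid

#' @rdname fit_psi
#' @export
glance.psi_fit <- function(x, ...) {
  tibble::tibble(best_psi = x$best_psi, min_sse = min(x$grid$sse),
                 n_grid = nrow(x$grid), t_eval_ms = x$t_eval_ms)
}

#' Plot the psi calibration discrepancy curve
#'
#' @param object A `psi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psi_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$psi, y = .data$sse)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_psi, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(psi ~ "(ms)"),
                  y = "sum of squared differences") +
    ggplot2::theme_minimal()
}
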