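# Concentric-shell concentration profiles: shell binning, Monte Carlo
# extracellular shell volumes, conversion to millimolar, run averaging.

#' Concentric shell grid centred at the release site
#'
#' @param shell_width_nm Shell thickness (nm).
#' @param max_radius_um Outer radius covered (default: arena half-width of the
#'   standard 4 um arena). Shell boundaries are `r_k = k * shell_width`,
#'   half-open `[r_k, r_k+1)`.
#' @return An object of class `shell_grid`.
#' @export
#' @examples
#' shell_grid()
shell_grid <- function(shell_width_nm = 20, max_radius_um = 2) {
  stopifnot(shell_width_nm > 0, max_radius_um > 0)
  w <- shell_width_nm / 1000
  n <- ceiling(max_radius_um / w)
  structure(list(shell_width_nm = shell_width_nm, n_shells = n,
                 r_lo = (seq_len(n) - 1) * w, r_hi = seq_len(n) * w),
            class = "shell_grid")
}

#' @export
print.shell_grid <- function(x, ...) {
  cat(sprintf("<shell_grid> %d shells of %g nm up to %g um\n",
              x$n_shells, x$shell_width_nm, max(x$r_hi)))
  invisible(x)
}

#' Tally free and bound particles per shell
#'
#' Assigns every non-escaped particle to exactly one shell by its Euclidean
#' distance from the release site. Particles beyond the outermost shell are
#' reported in the `overflow` attribute so that totals remain auditable.
#' Bound tallies include retained (translocation-fate) particles: both remain
#' physically transporter-bound for the duration of a run.
#'
#' @param ensemble A tibble with `x`, `y`, `z` (um) and `status`.
#' @param grid A [shell_grid()].
#' @return A tibble with `shell`, `r_lo_nm`, `r_hi_nm`, `free_count`,
#'   `bound_count`.
#' @export
#' @examples
#' shell_counts(release_particles(cleft_spec(), 10, seed = 1), shell_grid())
shell_counts <- function(ensemble, grid) {
  stopifnot(inherits(grid, "shell_grid"),
            all(c("x", "y", "z", "status") %in% names(ensemble)))
  w <- grid$shell_width_nm / 1000
  r <- sqrt(ensemble$x^2 + ensemble$y^2 + ensemble$z^2)
  idx <- pmin(floor(r / w), grid$n_shells) + 1L # n_shells + 1 = overflow
  free <- tabulate(idx[ensemble$status == "free"], nbins = grid$n_shells + 1L)
  bound <- tabulate(idx[ensemble$status %in% c("bound", "retained")],
                    nbins = grid$n_shells + 1L)
  out <- tibble::tibble(
    shell = seq_len(grid$n_shells),
    r_lo_nm = grid$r_lo * 1000, r_hi_nm = grid$r_hi * 1000,
    free_count = free[seq_len(grid$n_shells)],
    bound_count = bound[seq_len(grid$n_shells)])
  attr(out, "overflow") <- c(free = free[grid$n_shells + 1L],
                             bound = bound[grid$n_shells + 1L])
  out
}

#' Monte Carlo extracellular volume of each shell
#'
#' For every shell, samples points uniformly within the analytic spherical
#' shell and classifies them against the environment; the extracellular
#' volume is the analytic shell volume times the fraction of points that are
#' extracellular and inside the arena (shells are thereby clipped to the
#' arena automatically).
#'
#' @param env A `glu_env`.
#' @param grid A [shell_grid()].
#' @param n_points Total number of test points, spread evenly over shells.
#' @param seed Integer seed.
#' @return A tibble with `shell`, `r_lo_nm`, `r_hi_nm`, `shell_vol_um3`
#'   (analytic), `ec_frac`, `ec_vol_um3`.
#' @export
shell_ec_volumes <- function(env, grid, n_points = 1e5, seed = 1) {
  stopifnot(inherits(env, "glu_env"), inherits(grid, "shell_grid"))
  m_shell <- max(20L, ceiling(n_points / grid$n_shells))
  half <- env$spec$edge_um / 2
  g <- env_geometry(env)
  vol <- (4 / 3) * pi * (grid$r_hi^3 - grid$r_lo^3)
  ec_frac <- numeric(grid$n_shells)
  with_seed(seed, {
    for (k in seq_len(grid$n_shells)) {
      u <- runif(m_shell)
      r <- (grid$r_lo[k]^3 + u * (grid$r_hi[k]^3 - grid$r_lo[k]^3))^(1 / 3)
      # uniform directions
      zc <- runif(m_shell, -1, 1)
      th <- runif(m_shell, 0, 2 * pi)
      s <- sqrt(1 - zc^2)
      pts <- cbind(r * s * cos(th), r * s * sin(th), r * zc)
      inside <- abs(pts[, 1]) <= half & abs(pts[, 2]) <= half &
        abs(pts[, 3]) <= half
      if (!any(inside)) { ec_frac[k] <- 0; next }
      lab <- cpp_classify_points(g$spheres, g$role, pts[inside, , drop = FALSE],
                                 g$half, g$cap_R, g$cap_hz, g$capsule)
      ec_frac[k] <- sum(lab == 0L) / m_shell
    }
  })
  tibble::tibble(shell = seq_len(grid$n_shells),
                 r_lo_nm = grid$r_lo * 1000, r_hi_nm = grid$r_hi * 1000,
                 shell_vol_um3 = vol, ec_frac = ec_frac,
                 ec_vol_um3 = vol * ec_frac)
}

#' Convert shell counts to absolute concentrations
#'
#' `conc_mM = scale_factor * count / (N_A * ec_volume)`, with volumes in um^3
#' converted to litres. The default `scale_factor = 3` maps 1000 simulated
#' particles onto the ~3000 glutamate molecules of an average synaptic
#' vesicle; transporter supply is treated as non-saturating, so
#' concentrations scale linearly with molecule count. Shells with zero
#' extracellular volume but non-zero counts are flagged (`conc = NA`), never
#' silently dropped.
#'
#' @param counts Output of [shell_counts()].
#' @param ec_volumes Output of [shell_ec_volumes()].
#' @param scale_factor Linear molecule-count scaling.
#' @return The joined tibble with `free_mM`, `bound_mM` and logical
#'   `flagged`.
#' @export
to_concentration <- function(counts, ec_volumes, scale_factor = 3) {
  stopifnot(nrow(counts) == nrow(ec_volumes), scale_factor > 0)
  out <- dplyr::left_join(counts,
                          dplyr::select(ec_volumes, "shell", "ec_vol_um3"),
                          by = "shell")
  zero <- out$ec_vol_um3 <= 0
  conc <- function(n) ifelse(zero, ifelse(n > 0, NA_real_, 0),
                             scale_factor * n / (out$ec_vol_um3 * MM_DENOM))
  out$free_mM <- conc(out$free_count)
  out$bound_mM <- conc(out$bound_count)
  out$flagged <- zero & (out$free_count + out$bound_count > 0)
  if (any(out$flagged))
    warning(sprintf("%d shell(s) with particles but zero extracellular volume",
                    sum(out$flagged)), call. = FALSE)
  out
}

#' Full concentration profile of one run
#'
#' Applies [shell_counts()] at every recorded time of a run and converts to
#' millimolar with the run environment's Monte Carlo shell volumes.
#'
#' @param run A `glu_run`.
#' @param env The `glu_env` the run was simulated in.
#' @param grid A [shell_grid()].
#' @param n_points Test points for [shell_ec_volumes()].
#' @param seed Seed for the volume estimate.
#' @param scale_factor See [to_concentration()].
#' @return A tibble with one row per time x shell.
#' @export
run_profile <- function(run, env, grid = shell_grid(), n_points = 1e5,
                        seed = 1, scale_factor = 3) {
  stopifnot(inherits(run, "glu_run"))
  vols <- shell_ec_volumes(env, grid, n_points = n_points, seed = seed)
  run$snapshots |>
    dplyr::group_by(.data$t_ms) |>
    dplyr::group_modify(function(d, key) {
      suppressWarnings(to_concentration(shell_counts(d, grid), vols,
                                        scale_factor = scale_factor))
    }) |>
    dplyr::ungroup()
}

#' Average concentration profiles across runs
#'
#' Pointwise mean and standard error of the mean, per time and shell, across
#' independent runs (each with its own environment realisation).
#'
#' @param profiles A list of per-run profile tibbles (identical grids and
#'   time points), as returned by [run_profile()].
#' @return An object of class `glu_profile_series`: `runs` (row-bound per-run
#'   profiles with a `run` column) and `summary` (mean +/- SEM).
#' @export
average_runs <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2)
  key0 <- profiles[[1]][c("t_ms", "shell")]
  for (p in profiles[-1])
    if (!identical(p[c("t_ms", "shell")], key0))
      stop("profiles have mismatched grids or time points", call. = FALSE)
  runs <- dplyr::bind_rows(profiles, .id = "run") |>
    dplyr::mutate(run = as.integer(.data$run))
  summary <- runs |>
    dplyr::group_by(.data$t_ms, .data$shell, .data$r_lo_nm, .data$r_hi_nm) |>
    dplyr::summarise(
      mean_free_mM = mean(.data$free_mM), sem_free_mM = stats::sd(.data$free_mM) / sqrt(dplyr::n()),
      mean_bound_mM = mean(.data$bound_mM), sem_bound_mM = stats::sd(.data$bound_mM) / sqrt(dplyr::n()),
      n_runs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(r_mid_nm = (.data$r_lo_nm + .data$r_hi_nm) / 2)
  structure(list(runs = runs, summary = summary,
                 n_runs = length(profiles)),
            class = "glu_profile_series")
}

#' @export
print.glu_profile_series <- function(x, ...) {
  cat(sprintf("<glu_profile_series> %d runs, %d time points, %d shells\n",
              x$n_runs, length(unique(x$summary$t_ms)),
              length(unique(x$summary$shell))))
  invisible(x)
}

#' @rdname average_runs
#' @param x A `glu_profile_series`.
#' @param ... Unused.
#' @export
tidy.glu_profile_series <- function(x, ...) x$summary

#' Plot averaged free/bound concentration profiles
#'
#' @param object A `glu_profile_series`.
#' @param what `"free"` or `"bound"` glutamate.
#' @param ... Unused.
#' @return A ggplot object: concentration vs distance, one panel-free curve
#'   per recorded time, mean with SEM ribbon.
#' @export
autoplot.glu_profile_series <- function(object, what = c("free", "bound"),
                                        ...) {
  what <- match.arg(what)
  d <- object$summary
  d$mu <- if (what == "free") d$mean_free_mM else d$mean_bound_mM
  d$se <- if (what == "free") d$sem_free_mM else d$sem_bound_mM
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r_mid_nm / 1000, y = .data$mu,
                                  colour = factor(.data$t_ms),
                                  fill = factor(.data$t_ms))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mu - .data$se,
                                      ymax = .data$mu + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from release site (µm)",
                  y = sprintf("%s glutamate (mM)", what),
                  colour = "t (ms)", fill = "t (ms)") +
    ggplot2::theme_minimal()
}

#' Write per-run and aggregated profile CSVs
#'
#' @param series A `glu_profile_series`.
#' @param runs_path,summary_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_profiles <- function(series, runs_path = NULL, summary_path = NULL) {
  stopifnot(inherits(series, "glu_profile_series"))
  if (!is.null(runs_path)) {
    cols <- c("run", "t_ms", "r_lo_nm", "r_hi_nm", "free_mM", "bound_mM",
              "free_count", "bound_count", "ec_vol_um3")
    utils::write.csv(as.data.frame(series$runs[cols]), runs_path,
                     row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    cols <- c("t_ms", "r_mid_nm", "mean_free_mM", "sem_free_mM",
              "mean_bound_mM", "sem_bound_mM")
    utils::write.csv(as.data.frame(series$summary[cols]), summary_path,
                     row.names = FALSE)
  }
  invisible(c(runs_path, summary_path))
}
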