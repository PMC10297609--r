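# Brownian dynamics surfaces: particle release, free steps, mirror-reflection
# collision resolution, astroglial proximity, arena boundaries, and the full
# compiled simulation driver.

#' Release glutamate particles into the synaptic cleft
#'
#' Places `n` free particles uniformly inside the release cylinder (diameter
#' `width_nm`, height `height_nm`) at the arena centre, the instant of
#' vesicular release.
#'
#' @param cleft A [cleft_spec()].
#' @param n Number of particles.
#' @param seed Integer seed.
#' @return A tibble with `id`, `x`, `y`, `z` (um) and `status = "free"`.
#' @export
#' @examples
#' release_particles(cleft_spec(), n = 5, seed = 1)
release_particles <- function(cleft, n, seed = 1) {
  stopifnot(inherits(cleft, "cleft_spec"), n >= 1)
  R <- cleft$width_nm / 2000
  hz <- cleft$height_nm / 2000
  with_seed(seed, {
    r <- R * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    tibble::tibble(id = seq_len(n),
                   x = r * cos(th), y = r * sin(th),
                   z = runif(n, -hz, hz),
                   status = factor("free", levels = status_levels))
  })
}

#' Propose free Brownian displacements
#'
#' Adds an independent zero-mean Gaussian increment of variance `2 * D * dt`
#' to every coordinate. No interaction with obstacles: pair with
#' [resolve_collisions()] to obtain valid positions.
#'
#' @param positions n x 3 matrix or data frame with `x`, `y`, `z` (um).
#' @param D Diffusion coefficient (um^2/ms).
#' @param dt Time step (ms).
#' @param seed Optional integer seed.
#' @return An n x 3 matrix of proposed positions.
#' @export
#' @examples
#' brownian_step(matrix(0, 2, 3), D = 0.5, dt = 1e-3, seed = 1)
brownian_step <- function(positions, D, dt, seed = NULL) {
  stopifnot(dt > 0, D >= 0)
  pos <- as_position_matrix(positions)
  draw <- function() pos + matrix(rnorm(length(pos), sd = sqrt(2 * D * dt)),
                                  ncol = 3)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Resolve particle-obstacle collisions by mirror reflection
#'
#' Each step segment crossing a spheroid surface, a cleft-obstacle surface or
#' an arena wall is reflected elastically about the tangent plane at the
#' crossing point, iteratively (up to 8 reflections), so path length is
#' preserved per reflection. Astroglial spheroids reflect exactly like
#' neuronal ones; binding is handled separately by the proximity hazard.
#'
#' @param env A `glu_env`.
#' @param old_positions,proposed_positions n x 3 matrices (um); old positions
#'   must be valid (outside all solids).
#' @param boundary `"reflective"` or `"open"` arena walls.
#' @param include_cleft_obstacles Include the two hemispheric synaptic
#'   obstacles as reflecting solids.
#' @return An n x 3 matrix of corrected positions with attribute `escaped`
#'   (logical, open boundary only). Errors if any reflection cascade fails to
#'   converge, which signals a too-large time step.
#' @export
resolve_collisions <- function(env, old_positions, proposed_positions,
                               boundary = c("reflective", "open"),
                               include_cleft_obstacles = TRUE) {
  stopifnot(inherits(env, "glu_env"))
  boundary <- match.arg(boundary)
  old <- as_position_matrix(old_positions)
  prop <- as_position_matrix(proposed_positions)
  stopifnot(nrow(old) == nrow(prop))
  g <- env_geometry(env, include_cleft = include_cleft_obstacles)
  res <- cpp_resolve_collisions(g$spheres, g$role, old, prop, g$half,
                                g$cap_R, g$cap_hz, g$capsule,
                                boundary == "open")
  bad <- !res$converged & !res$escaped
  if (any(bad))
    stop(sprintf(paste0("mirror reflection failed to converge for %d ",
                        "particle(s); the time step is too large for this ",
                        "geometry"), sum(bad)), call. = FALSE)
  out <- res$positions
  colnames(out) <- c("x", "y", "z")
  attr(out, "escaped") <- as.logical(res$escaped)
  out
}

#' Proximity of particles to astroglial surfaces
#'
#' @param env A `glu_env`.
#' @param positions n x 3 matrix or data frame (um).
#' @param cutoff_nm Contact cutoff (nm).
#' @return A tibble with the exact `distance_um` to the nearest astroglial
#'   surface (Inf if the environment has none) and logical `in_contact`.
#' @export
astro_proximity <- function(env, positions, cutoff_nm = 5) {
  stopifnot(inherits(env, "glu_env"), cutoff_nm > 0)
  pts <- as_position_matrix(positions)
  g <- env_geometry(env)
  d <- cpp_nearest_astro_dist(g$spheres, g$role, pts, g$half)
  tibble::tibble(distance_um = d, in_contact = d <= cutoff_nm / 1000)
}

#' Apply the arena boundary condition to raw positions
#'
#' Reflective walls fold coordinates back into the arena (mirror images of
#' period `2 * edge`); open boundaries leave positions untouched and flag
#' particles outside the arena as escaped.
#'
#' @param positions n x 3 matrix or data frame (um).
#' @param edge_um Arena edge length (um).
#' @param boundary `"reflective"` or `"open"`.
#' @return An n x 3 matrix with attribute `escaped` (logical).
#' @export
boundary_condition <- function(positions, edge_um,
                               boundary = c("reflective", "open")) {
  boundary <- match.arg(boundary)
  pos <- as_position_matrix(positions)
  half <- edge_um / 2
  if (boundary == "reflective") {
    fold <- function(v) {
      # triangle wave of period 4 * half mapping R onto [-half, half]
      u <- (v + half) %% (4 * half)
      pmin(u, 4 * half - u) - half
    }
    out <- apply(pos, 2, fold)
    if (!is.matrix(out)) out <- matrix(out, ncol = 3)
    attr(out, "escaped") <- rep(FALSE, nrow(pos))
    out
  } else {
    esc <- apply(abs(pos) > half, 1, any)
    attr(pos, "escaped") <- esc
    pos
  }
}

#' Simulate one full release-diffusion-binding run
#'
#' Releases `n_particles` into the cleft and advances them by Brownian steps
#' with mirror reflections off all surfaces. While a particle dwells within
#' the transporter cutoff of an astroglial surface, a contact clock
#' accumulates and binding is sampled with the per-step hazard
#' `1 - exp(-dt / psi)`, so the cumulative binding probability after contact
#' time `t` is exactly `1 - exp(-t / psi)`; the clock resets once the
#' particle departs beyond the cutoff. Each binding event is assigned the
#' unbinding fate with probability `p_unbind` (release after a
#' cumulative-Gaussian delay, at the binding position) or else retained for
#' the rest of the run (translocation outlasts the simulated window).
#'
#' @param env A `glu_env`.
#' @param n_particles Number of released particles.
#' @param seed Integer seed for the particle streams (each particle has its
#'   own counter-derived sub-stream, so paired conditions share diffusion
#'   noise).
#' @param transporter A [transporter_spec()].
#' @param diffusion A [diffusion_spec()].
#' @param include_cleft_obstacles Include the hemispheric synaptic obstacles.
#' @return An object of class `glu_run`: `snapshots` (tibble `t_ms`, `id`,
#'   `x`, `y`, `z`, `status`), `release` (initial positions), `counters`
#'   (binding/release/escape/rejected-move tallies) and the parameters used.
#' @export
#' @examples
#' env <- generate_environment(arena_spec(), seed = 1, n_points = 2e4)
#' run <- simulate_run(env, n_particles = 20, seed = 1,
#'                     diffusion = diffusion_spec(dt_ms = 2e-4, t_end_ms = 0.1,
#'                                                record_t_ms = c(0.05, 0.1)))
#' dplyr::count(run$snapshots, t_ms, status)
simulate_run <- function(env, n_particles = 1000, seed = 1,
                         transporter = transporter_spec(),
                         diffusion = diffusion_spec(),
                         include_cleft_obstacles = TRUE) {
  stopifnot(inherits(env, "glu_env"), inherits(transporter, "transporter_spec"),
            inherits(diffusion, "diffusion_spec"), n_particles >= 1)
  has_astro <- any(env$spheroids$role == "astroglial")
  if (transporter$enabled && has_astro)
    check_resolution_guard(diffusion, transporter$cutoff_nm)
  g <- env_geometry(env, include_cleft = include_cleft_obstacles)
  res <- cpp_simulate(
    spheres = g$spheres, role = g$role, half = g$half,
    cap_R = g$cap_R, cap_hz = g$cap_hz, capsule = g$capsule,
    n_particles = as.integer(n_particles),
    release_R = env$spec$cleft$width_nm / 2000,
    release_hz = env$spec$cleft$height_nm / 2000,
    D = diffusion$D_um2_ms, dt = diffusion$dt_ms,
    t_end = diffusion$t_end_ms, record_t = diffusion$record_t_ms,
    psi = transporter$psi_ms, p_unbind = transporter$p_unbind,
    unbind_mu = transporter$unbind_mu_ms,
    unbind_sigma = transporter$unbind_sigma_ms,
    cutoff = transporter$cutoff_nm / 1000,
    binding_enabled = transporter$enabled,
    open_boundary = diffusion$boundary == "open",
    seed = as.double(seed))

  n_rec <- length(res$times)
  snapshots <- purrr::map_dfr(seq_len(n_rec), function(k) {
    m <- res$positions[[k]]
    tibble::tibble(t_ms = res$times[k], id = seq_len(n_particles),
                   x = m[, 1], y = m[, 2], z = m[, 3],
                   status = status_factor(res$status[, k]))
  })
  structure(list(snapshots = snapshots,
                 counters = tibble::as_tibble(res$counters),
                 n_particles = n_particles, seed = seed,
                 transporter = transporter, diffusion = diffusion,
                 env_alpha = env$alpha_measured,
                 env_vf_astro = env$vf_astro_measured),
            class = "glu_run")
}

#' @export
print.glu_run <- function(x, ...) {
  cat(sprintf(
    "<glu_run> %d particles, %d snapshots over %g ms\n",
    x$n_particles, length(unique(x$snapshots$t_ms)), x$diffusion$t_end_ms))
  cat(sprintf("  binding events: %d; releases: %d; rejected moves: %d; escaped: %d\n",
              x$counters$n_bind_events, x$counters$n_release_events,
              x$counters$n_rejected_moves, x$counters$n_escaped))
  invisible(x)
}
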