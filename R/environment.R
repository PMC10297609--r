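# Probabilistic synaptic environment: sphere scatter, role assignment,
# Monte Carlo volume-fraction validation, point classification, serialisation.

#' Generate a probabilistic synaptic environment
#'
#' Scatters overlapping spheroids (uniform radii) over the cubic arena,
#' rejecting any that intrude within `min_gap_nm` of the cleft volume, until a
#' running Monte Carlo estimate of the extracellular volume fraction first
#' reaches the target `alpha`. Each spheroid is then labelled astroglial or
#' neuronal: an initial Bernoulli draw at probability `vf_astro / (1 - alpha)`
#' is refined by greedy label flips against the measured astroglial share, so
#' that both measured fractions land within tolerance of their targets. The
#' whole procedure is repeated anew for every realisation.
#'
#' @param spec An [arena_spec()].
#' @param seed Integer seed; realisations are bit-identical for a given seed.
#' @param n_points Number of internal Monte Carlo test points used for the
#'   running volume-fraction estimates.
#' @param max_spheres Placement budget before failing with a diagnostic
#'   (default: ten times the expected number needed).
#' @return An object of class `glu_env`: the spec, a tibble of spheroids
#'   (`x`, `y`, `z`, `r` in um, `role`), measured fractions, and the seed.
#' @export
#' @examples
#' env <- generate_environment(arena_spec(), seed = 1, n_points = 2e4)
#' env$alpha_measured
generate_environment <- function(spec, seed, n_points = 2e5,
                                 max_spheres = NULL) {
  stopifnot(inherits(spec, "arena_spec"), n_points >= 1)
  # expected sphere count for a Boolean (Poisson) sphere model:
  # alpha = exp(-n * vbar / V)
  vbar <- mean_sphere_volume(spec$r_min_nm / 1000, spec$r_max_nm / 1000)
  v_arena <- spec$edge_um^3
  n_expected <- if (spec$alpha < 1) log(1 / spec$alpha) * v_arena / vbar else 0
  if (is.null(max_spheres)) max_spheres <- ceiling(10 * n_expected) + 1000

  res <- cpp_generate_environment(
    edge = spec$edge_um, alpha_target = spec$alpha,
    vf_target = spec$vf_astro,
    r_min = spec$r_min_nm / 1000, r_max = spec$r_max_nm / 1000,
    cap_R = spec$cleft$apposition_nm / 2000,
    cap_hz = spec$cleft$height_nm / 2000,
    min_gap = spec$min_gap_nm / 1000,
    n_points = as.integer(n_points), role_tol = spec$tolerance / 5,
    max_spheres = as.integer(max_spheres), seed = as.double(seed))

  spheroids <- tibble::tibble(
    x = res$spheres[, 1], y = res$spheres[, 2], z = res$spheres[, 3],
    r = res$spheres[, 4],
    role = factor(ifelse(res$role == 1L, "astroglial", "neuronal"),
                  levels = c("neuronal", "astroglial")))
  structure(list(spec = spec, spheroids = spheroids,
                 alpha_measured = res$alpha_hat,
                 vf_astro_measured = res$vf_astro_hat,
                 n_points = res$n_points, seed_used = seed),
            class = "glu_env")
}

mean_sphere_volume <- function(r_min, r_max) {
  # E[(4/3) pi R^3] for R ~ U(r_min, r_max)
  (4 / 3) * pi * (r_max^4 - r_min^4) / (4 * (r_max - r_min))
}

env_geometry <- function(env, include_cleft = TRUE) {
  sph <- env$spheroids
  list(spheres = cbind(sph$x, sph$y, sph$z, sph$r),
       role = as.integer(sph$role == "astroglial"),
       half = env$spec$edge_um / 2,
       cap_R = env$spec$cleft$apposition_nm / 2000,
       cap_hz = env$spec$cleft$height_nm / 2000,
       capsule = include_cleft)
}

#' Estimate volume fractions by Monte Carlo test points
#'
#' Distributes `n_points` uniform test points over the arena and classifies
#' each against the environment. The extracellular fraction is the share of
#' points outside all spheroids and cleft obstacles; the astroglial fraction
#' is the share inside at least one astroglial spheroid, with overlaps
#' resolved by deepest containment (see [point_classification()]).
#'
#' @param env A `glu_env`.
#' @param n_points Number of test points.
#' @param seed Integer seed for the test-point draw.
#' @param include_cleft_obstacles Count the hemispheric synaptic obstacles as
#'   occupied volume (default); `FALSE` gives the pure spheroid packing.
#' @return A one-row tibble with `alpha_hat`, `vf_astro_hat`, their binomial
#'   standard errors and `n_points`.
#' @export
#' @examples
#' env <- generate_environment(arena_spec(), seed = 1, n_points = 2e4)
#' estimate_volume_fractions(env, n_points = 1e4, seed = 2)
estimate_volume_fractions <- function(env, n_points = 1e6, seed = 1,
                                      include_cleft_obstacles = TRUE) {
  stopifnot(inherits(env, "glu_env"), n_points >= 1)
  half <- env$spec$edge_um / 2
  pts <- with_seed(seed,
                   matrix(runif(3 * n_points, -half, half), ncol = 3))
  g <- env_geometry(env, include_cleft = include_cleft_obstacles)
  lab <- cpp_classify_points(g$spheres, g$role, pts, g$half,
                             g$cap_R, g$cap_hz, g$capsule)
  alpha_hat <- mean(lab == 0L)
  vf_hat <- mean(lab == 2L)
  tibble::tibble(
    alpha_hat = alpha_hat,
    vf_astro_hat = vf_hat,
    se_alpha = sqrt(alpha_hat * (1 - alpha_hat) / n_points),
    se_vf_astro = sqrt(vf_hat * (1 - vf_hat) / n_points),
    n_points = n_points)
}

#' Classify points against an environment
#'
#' Labels each position as extracellular, neuronal, astroglial, or cleft
#' obstacle. A point inside several overlapping spheroids belongs to the one
#' whose surface is farthest away inside (deepest containment); ties break to
#' the lowest spheroid index. The same rule is used for test points, shell
#' volumes and collision bookkeeping, so labels are consistent everywhere.
#'
#' @param env A `glu_env`.
#' @param positions An n x 3 matrix or a data frame with `x`, `y`, `z`
#'   columns (um, arena-centred coordinates).
#' @return A factor with levels `extracellular`, `neuronal`, `astroglial`,
#'   `cleft_obstacle`.
#' @export
#' @examples
#' env <- generate_environment(arena_spec(), seed = 1, n_points = 2e4)
#' point_classification(env, cbind(1.9, 1.9, 1.9))
point_classification <- function(env, positions) {
  stopifnot(inherits(env, "glu_env"))
  pts <- as_position_matrix(positions)
  half <- env$spec$edge_um / 2
  if (any(abs(pts) > half + 1e-12))
    stop("positions outside the arena", call. = FALSE)
  g <- env_geometry(env)
  lab <- cpp_classify_points(g$spheres, g$role, pts, g$half,
                             g$cap_R, g$cap_hz, g$capsule)
  factor(c("extracellular", "neuronal", "astroglial", "cleft_obstacle")[lab + 1L],
         levels = c("extracellular", "neuronal", "astroglial", "cleft_obstacle"))
}

#' @export
print.glu_env <- function(x, ...) {
  cat(sprintf(
    paste0("<glu_env> %d spheroids (%d astroglial) in a %g um cube\n",
           "  alpha: measured %.4f (target %g); vf_astro: measured %.4f (target %g)\n"),
    nrow(x$spheroids), sum(x$spheroids$role == "astroglial"),
    x$spec$edge_um, x$alpha_measured, x$spec$alpha,
    x$vf_astro_measured, x$spec$vf_astro))
  invisible(x)
}

#' Write an environment realisation to CSV
#'
#' One row per spheroid (`x`, `y`, `z`, `r` in um, `role`), preceded by
#' commented header lines recording the spec and the measured fractions.
#'
#' @param env A `glu_env`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_environment <- function(env, path) {
  stopifnot(inherits(env, "glu_env"))
  s <- env$spec
  hdr <- c(
    sprintf("# edge_um=%.15g", s$edge_um),
    sprintf("# alpha_target=%.15g", s$alpha),
    sprintf("# vf_astro_target=%.15g", s$vf_astro),
    sprintf("# r_min_nm=%.15g", s$r_min_nm),
    sprintf("# r_max_nm=%.15g", s$r_max_nm),
    sprintf("# cleft_width_nm=%.15g", s$cleft$width_nm),
    sprintf("# cleft_height_nm=%.15g", s$cleft$height_nm),
    sprintf("# cleft_apposition_nm=%.15g", s$cleft$apposition_nm),
    sprintf("# min_gap_nm=%.15g", s$min_gap_nm),
    sprintf("# tolerance=%.15g", s$tolerance),
    sprintf("# alpha_measured=%.15g", env$alpha_measured),
    sprintf("# vf_astro_measured=%.15g", env$vf_astro_measured),
    sprintf("# seed_used=%.15g", env$seed_used))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(env$spheroids), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an environment realisation written by [write_environment()]
#'
#' @param path File path.
#' @return A `glu_env`.
#' @export
read_environment <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# *", "", hdr), "=", fixed = TRUE))
  vals <- setNames(as.numeric(kv[, 2]), kv[, 1])
  spec <- arena_spec(
    edge_um = vals[["edge_um"]], alpha = vals[["alpha_target"]],
    vf_astro = vals[["vf_astro_target"]], r_min_nm = vals[["r_min_nm"]],
    r_max_nm = vals[["r_max_nm"]],
    cleft = cleft_spec(vals[["cleft_width_nm"]], vals[["cleft_height_nm"]],
                       vals[["cleft_apposition_nm"]]),
    min_gap_nm = vals[["min_gap_nm"]], tolerance = vals[["tolerance"]])
  sph <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  spheroids <- tibble::tibble(
    x = sph$x, y = sph$y, z = sph$z, r = sph$r,
    role = factor(sph$role, levels = c("neuronal", "astroglial")))
  structure(list(spec = spec, spheroids = spheroids,
                 alpha_measured = vals[["alpha_measured"]],
                 vf_astro_measured = vals[["vf_astro_measured"]],
                 n_points = NA_real_, seed_used = vals[["seed_used"]]),
            class = "glu_env")
}

#' Plot a cross-section of an environment realisation
#'
#' Draws the circles in which spheroids intersect a plane of constant `z`,
#' coloured by role, with the synaptic apposition marked at the centre.
#'
#' @param object A `glu_env`.
#' @param z_um Section height (um).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glu_env <- function(object, z_um = 0, ...) {
  sph <- object$spheroids
  cut <- sph[abs(sph$z - z_um) < sph$r, ]
  if (nrow(cut)) {
    cut$rc <- sqrt(cut$r^2 - (cut$z - z_um)^2)
    theta <- seq(0, 2 * pi, length.out = 60)
    circles <- purrr::pmap_dfr(
      list(cut$x, cut$y, cut$rc, seq_len(nrow(cut)), as.character(cut$role)),
      function(x0, y0, rc, id, role)
        tibble::tibble(id = id, role = role,
                       x = x0 + rc * cos(theta), y = y0 + rc * sin(theta)))
  } else {
    circles <- tibble::tibble(id = integer(), role = character(),
                              x = numeric(), y = numeric())
  }
  half <- object$spec$edge_um / 2
  capR <- object$spec$cleft$apposition_nm / 2000
  ring <- tibble::tibble(x = capR * cos(seq(0, 2 * pi, length.out = 90)),
                         y = capR * sin(seq(0, 2 * pi, length.out = 90)))
  ggplot2::ggplot(circles, ggplot2::aes(x = .data$x, y = .data$y,
                                        group = .data$id,
                                        colour = .data$role)) +
    ggplot2::geom_path(linewidth = 0.2, alpha = 0.7) +
    ggplot2::geom_path(data = ring, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "black", linetype = 2) +
    ggplot2::coord_equal(xlim = c(-half, half), ylim = c(-half, half)) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("Neuropil section at z = %g µm", z_um),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
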