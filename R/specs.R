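# Parameter containers for the arena, cleft, diffusion and transporter models.
# All lengths are user-facing in nm where the underlying scale is nanometric
# (radii, cleft, shells) and in um for the arena; internal computation is in
# um and ms throughout.

#' Synaptic cleft geometry
#'
#' The release zone is a cylinder at the arena centre; the synaptic apposition
#' (pre- and postsynaptic elements) is modelled as two solid hemispheric
#' obstacles of diameter `apposition_nm` flanking the cleft void, so the
#' cleft itself is the disc-shaped extracellular gap between them.
#'
#' @param width_nm Release-zone cylinder diameter (nm).
#' @param height_nm Cleft height (nm); the gap between the two hemispheres.
#' @param apposition_nm Diameter of the synaptic apposition (nm).
#' @return An object of class `cleft_spec`.
#' @export
#' @examples
#' cleft_spec()
cleft_spec <- function(width_nm = 120, height_nm = 20, apposition_nm = 250) {
  stopifnot(height_nm > 0, width_nm > 0, apposition_nm > 0)
  if (!(height_nm < width_nm && width_nm <= apposition_nm))
    stop("cleft requires height_nm < width_nm <= apposition_nm", call. = FALSE)
  structure(list(width_nm = width_nm, height_nm = height_nm,
                 apposition_nm = apposition_nm),
            class = "cleft_spec")
}

#' Arena specification for a probabilistic synaptic environment
#'
#' Describes the cubic simulation arena and the targets used when scattering
#' overlapping neuronal/astroglial spheroids: the extracellular volume
#' fraction `alpha`, the astroglial volume fraction `vf_astro`, and the
#' uniform radius range of the spheroids.
#'
#' @param edge_um Arena edge length (um).
#' @param alpha Target extracellular volume fraction, in (0, 1].
#' @param vf_astro Target astroglial volume fraction, in \[0, 1).
#' @param r_min_nm,r_max_nm Spheroid radius range (nm), drawn uniformly.
#' @param cleft A [cleft_spec()].
#' @param min_gap_nm Minimum gap between any spheroid surface and the cleft
#'   volume (nm).
#' @param tolerance Acceptable deviation of measured volume fractions from
#'   their targets.
#' @return An object of class `arena_spec`.
#' @export
#' @examples
#' arena_spec(alpha = 0.2, vf_astro = 0.1)
arena_spec <- function(edge_um = 4, alpha = 0.2, vf_astro = 0.1,
                       r_min_nm = 50, r_max_nm = 300,
                       cleft = cleft_spec(), min_gap_nm = 10,
                       tolerance = 0.01) {
  stopifnot(inherits(cleft, "cleft_spec"),
            alpha > 0, alpha <= 1, vf_astro >= 0, vf_astro < 1,
            r_min_nm > 0, min_gap_nm >= 0, tolerance > 0)
  if (alpha + vf_astro > 1)
    stop("alpha + vf_astro must not exceed 1", call. = FALSE)
  if (!(r_min_nm < r_max_nm))
    stop("r_min_nm must be smaller than r_max_nm", call. = FALSE)
  if (!(edge_um * 1000 > 2 * r_max_nm))
    stop("arena edge must exceed twice the maximum spheroid radius",
         call. = FALSE)
  structure(list(edge_um = edge_um, alpha = alpha, vf_astro = vf_astro,
                 r_min_nm = r_min_nm, r_max_nm = r_max_nm, cleft = cleft,
                 min_gap_nm = min_gap_nm, tolerance = tolerance),
            class = "arena_spec")
}

#' Glutamate transporter binding/unbinding parameters
#'
#' The binding hazard treats a particle dwelling within `cutoff_nm` of an
#' astroglial surface as binding with cumulative probability
#' `1 - exp(-t / psi_ms)` in continuous contact time `t`. Each binding event
#' is then released back into the extracellular space with probability
#' `p_unbind` after a delay following a cumulative-Gaussian schedule
#' (`unbind_mu_ms`, `unbind_sigma_ms`), or else retained (transporter
#' translocation, which outlasts the simulated window).
#'
#' @param psi_ms Binding time constant Psi (ms).
#' @param p_unbind Per-event probability of unbinding rather than
#'   translocation.
#' @param unbind_mu_ms Median unbinding delay (ms).
#' @param unbind_sigma_ms Spread of the unbinding delay (ms).
#' @param cutoff_nm Proximity cutoff for transporter contact (nm).
#' @param enabled Logical; `FALSE` disables binding entirely (equivalent to a
#'   transporter-free astroglial surface).
#' @return An object of class `transporter_spec`.
#' @export
#' @examples
#' transporter_spec()
transporter_spec <- function(psi_ms = 1, p_unbind = 0.35, unbind_mu_ms = 4,
                             unbind_sigma_ms = 2, cutoff_nm = 5,
                             enabled = TRUE) {
  stopifnot(psi_ms > 0, p_unbind >= 0, p_unbind <= 1, unbind_sigma_ms > 0,
            unbind_mu_ms >= 0, cutoff_nm > 0, is.logical(enabled))
  structure(list(psi_ms = psi_ms, p_unbind = p_unbind,
                 unbind_mu_ms = unbind_mu_ms, unbind_sigma_ms = unbind_sigma_ms,
                 cutoff_nm = cutoff_nm, enabled = enabled),
            class = "transporter_spec")
}

#' Brownian diffusion parameters
#'
#' @param D_um2_ms Free diffusion coefficient (um^2/ms).
#' @param dt_ms Time step (ms). The default gives an rms 3D step of about
#'   7.7 nm, comparable to the 5 nm transporter proximity shell.
#' @param t_end_ms Total simulated time (ms).
#' @param record_t_ms Times (ms) at which particle snapshots are recorded.
#' @param boundary Arena-edge behaviour: `"reflective"` walls (default) or
#'   `"open"` (particles leaving the arena are flagged escaped).
#' @return An object of class `diffusion_spec`.
#' @export
#' @examples
#' diffusion_spec()
diffusion_spec <- function(D_um2_ms = 0.5, dt_ms = 2e-5, t_end_ms = 10,
                           record_t_ms = c(0.1, 0.5, 1, 2, 4, 6, 8, 10),
                           boundary = c("reflective", "open")) {
  boundary <- match.arg(boundary)
  stopifnot(D_um2_ms >= 0, dt_ms > 0, t_end_ms > 0,
            all(record_t_ms >= 0))
  record_t_ms <- sort(unique(pmin(record_t_ms, t_end_ms)))
  structure(list(D_um2_ms = D_um2_ms, dt_ms = dt_ms, t_end_ms = t_end_ms,
                 record_t_ms = record_t_ms, boundary = boundary),
            class = "diffusion_spec")
}

# resolution guard: rms step must stay comparable to the proximity shell
check_resolution_guard <- function(diffusion, cutoff_nm) {
  rms_nm <- sqrt(6 * diffusion$D_um2_ms * diffusion$dt_ms) * 1000
  if (rms_nm > 2 * cutoff_nm)
    stop(sprintf(paste0(
      "time step too coarse: rms 3D step %.1f nm exceeds twice the %.0f nm ",
      "proximity cutoff; reduce dt_ms below %.2e"),
      rms_nm, cutoff_nm,
      (2 * cutoff_nm / 1000)^2 / (6 * diffusion$D_um2_ms)), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf(
    "<arena_spec> %g um cube; alpha = %g, vf_astro = %g; radii U(%g, %g) nm\n",
    x$edge_um, x$alpha, x$vf_astro, x$r_min_nm, x$r_max_nm))
  invisible(x)
}

#' @export
print.cleft_spec <- function(x, ...) {
  cat(sprintf(
    "<cleft_spec> release %g nm wide, %g nm high; apposition %g nm\n",
    x$width_nm, x$height_nm, x$apposition_nm))
  invisible(x)
}

#' @export
print.transporter_spec <- function(x, ...) {
  cat(sprintf(
    "<transporter_spec> psi = %g ms, p_unbind = %g, delay ~ S(%g, %g) ms, cutoff %g nm%s\n",
    x$psi_ms, x$p_unbind, x$unbind_mu_ms, x$unbind_sigma_ms, x$cutoff_nm,
    if (x$enabled) "" else " [disabled]"))
  invisible(x)
}

#' @export
print.diffusion_spec <- function(x, ...) {
  cat(sprintf(
    "<diffusion_spec> D = %g um^2/ms, dt = %g ms, t_end = %g ms, %s walls\n",
    x$D_um2_ms, x$dt_ms, x$t_end_ms, x$boundary))
  invisible(x)
}
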