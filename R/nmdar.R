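# Five-state NMDA receptor kinetics driven by a simulated free-glutamate
# concentration time course, integrated with deSolve.

#' Five-state NMDA receptor kinetic scheme
#'
#' Standard two-binding-step scheme: unbound `U`, single-bound `C1`,
#' double-bound `C2`, desensitised `D` and open `O`, with glutamate-dependent
#' transitions `U -> C1 -> C2` (rate `kon * [glu]`) and first-order
#' transitions otherwise. Rate constants are configuration values loaded from
#' a CSV parameter file (see `inst/extdata/nmdar_5state.csv` for the shipped
#' published set) so they can be swapped without code changes.
#'
#' @param file Path to a parameter CSV with columns `parameter`, `value`
#'   (`kon` in per-mM-per-ms; `koff`, `kd`, `kr`, `ko`, `kc` in per-ms).
#' @return An object of class `nmdar_scheme`.
#' @export
#' @examples
#' nmdar_scheme()
nmdar_scheme <- function(file = system.file("extdata", "nmdar_5state.csv",
                                            package = "gluspill")) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("kon", "koff", "kd", "kr", "ko", "kc")
  if (!all(need %in% tab$parameter))
    stop("scheme file must define: ", paste(need, collapse = ", "),
         call. = FALSE)
  rates <- setNames(tab$value[match(need, tab$parameter)], need)
  if (any(rates < 0)) stop("all rates must be non-negative", call. = FALSE)
  structure(list(rates = as.list(rates), source = file,
                 states = c("U", "C1", "C2", "D", "O")),
            class = "nmdar_scheme")
}

#' @export
print.nmdar_scheme <- function(x, ...) {
  r <- x$rates
  cat(sprintf(paste0(
    "<nmdar_scheme> U <-> C1 <-> C2 <-> {D, O}\n",
    "  kon %g /mM/ms, koff %g /ms, kd %g /ms, kr %g /ms, ko %g /ms, kc %g /ms\n"),
    r$kon, r$koff, r$kd, r$kr, r$ko, r$kc))
  invisible(x)
}

# generator matrix (columns sum to zero) at a fixed glutamate concentration
nmdar_generator <- function(scheme, glu_mM) {
  r <- scheme$rates
  b <- r$kon * glu_mM
  # states U, C1, C2, D, O; Q[i, j] = rate j -> i
  Q <- matrix(0, 5, 5, dimnames = list(scheme$states, scheme$states))
  Q["C1", "U"] <- b
  Q["U", "C1"] <- r$koff
  Q["C2", "C1"] <- b
  Q["C1", "C2"] <- r$koff
  Q["D", "C2"] <- r$kd
  Q["C2", "D"] <- r$kr
  Q["O", "C2"] <- r$ko
  Q["C2", "O"] <- r$kc
  diag(Q) <- -colSums(Q)
  Q
}

#' Stationary occupancy at constant glutamate
#'
#' Null-space solution of the fixed-rate generator, independent of the ODE
#' integrator; used as an equilibrium cross-check.
#'
#' @param scheme An [nmdar_scheme()].
#' @param glu_mM Constant glutamate concentration (mM).
#' @return Named numeric vector of stationary state occupancies.
#' @export
nmdar_stationary <- function(scheme, glu_mM) {
  Q <- nmdar_generator(scheme, glu_mM)
  ns <- svd(Q)$v[, 5]
  p <- ns / sum(ns)
  setNames(pmax(p, 0) / sum(pmax(p, 0)), scheme$states)
}

#' Integrate NMDA receptor kinetics under a glutamate transient
#'
#' Solves the linear (in state) ODE system with time-varying glutamate,
#' starting from all receptors unbound, at relative and absolute tolerance
#' `tol`. The concentration input is linearly interpolated and extended past
#' its last sample with zero (default) or its last value, so slow unbinding
#' over hundreds of milliseconds can be followed from a ~10 ms transient.
#'
#' @param scheme An [nmdar_scheme()].
#' @param glu A data frame with `t_ms` and `glu_mM` (non-negative).
#' @param t_max_ms Integration window end (ms).
#' @param dt_out_ms Output grid spacing (ms).
#' @param tol Integrator tolerance (both relative and absolute).
#' @param extend How to extend the transient past its last sample: `"zero"`
#'   or `"last"`.
#' @return An object of class `nmdar_traj`: tibble with `t_ms`, the five
#'   state occupancies, `open` (= O) and `double_occ` (= C2 + D + O, all
#'   doubly liganded states).
#' @export
#' @examples
#' glu <- tibble::tibble(t_ms = c(0, 1, 2), glu_mM = c(0, 1, 0))
#' traj <- simulate_nmdar(nmdar_scheme(), glu, t_max_ms = 50)
#' max(traj$open)
simulate_nmdar <- function(scheme, glu, t_max_ms = 300, dt_out_ms = 0.1,
                           tol = 1e-8, extend = c("zero", "last")) {
  stopifnot(inherits(scheme, "nmdar_scheme"),
            all(c("t_ms", "glu_mM") %in% names(glu)))
  extend <- match.arg(extend)
  if (any(glu$glu_mM < 0)) stop("glutamate must be non-negative", call. = FALSE)
  glu <- glu[order(glu$t_ms), ]
  yend <- if (extend == "zero") 0 else glu$glu_mM[nrow(glu)]
  glu_fun <- approxfun(glu$t_ms, glu$glu_mM, rule = 2,
                       yleft = glu$glu_mM[1], yright = yend)
  r <- scheme$rates
  deriv <- function(t, y, parms) {
    b <- r$kon * glu_fun(t)
    U <- y[1]; C1 <- y[2]; C2 <- y[3]; D <- y[4]; O <- y[5]
    dU <- r$koff * C1 - b * U
    dC1 <- b * U + r$koff * C2 - (r$koff + b) * C1
    dC2 <- b * C1 + r$kr * D + r$kc * O - (r$koff + r$kd + r$ko) * C2
    dD <- r$kd * C2 - r$kr * D
    dO <- r$ko * C2 - r$kc * O
    list(c(dU, dC1, dC2, dD, dO))
  }
  times <- seq(0, t_max_ms, by = dt_out_ms)
  sol <- deSolve::ode(y = c(U = 1, C1 = 0, C2 = 0, D = 0, O = 0),
                      times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = tol, atol = tol)
  if (attr(sol, "istate")[1] < 0)
    stop("NMDAR ODE integration failed for the supplied transient",
         call. = FALSE)
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "t_ms"
  out$open <- out$O
  out$double_occ <- out$C2 + out$D + out$O
  drift <- max(abs(rowSums(out[, c("U", "C1", "C2", "D", "O")]) - 1))
  structure(out, class = c("nmdar_traj", class(out)),
            conservation_error = drift)
}

#' Activation and tagging metrics of a receptor trajectory
#'
#' Peak open probability, peak double occupancy, and the tag duration: the
#' length of the maximal contiguous interval over which double occupancy
#' stays at or above `threshold_fraction` of its own peak. Doubly occupied
#' ("tagged") receptors open upon depolarisation without further glutamate,
#' so tag duration measures how long a synapse's neighbourhood stays primed.
#'
#' @param traj An `nmdar_traj`.
#' @param threshold_fraction Fraction of the peak double occupancy defining
#'   the tagged interval, in (0, 1).
#' @return A one-row tibble: `peak_open`, `t_peak_open_ms`, `peak_double`,
#'   `tag_duration_ms`.
#' @export
activation_metrics <- function(traj, threshold_fraction = 0.05) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1,
            all(c("t_ms", "open", "double_occ") %in% names(traj)))
  peak_open <- max(traj$open)
  peak_double <- max(traj$double_occ)
  if (peak_double <= 0) {
    tag <- 0
  } else {
    above <- traj$double_occ >= threshold_fraction * peak_double
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    spans <- ifelse(runs$values,
                    traj$t_ms[ends] - traj$t_ms[starts], 0)
    tag <- max(spans)
  }
  tibble::tibble(peak_open = peak_open,
                 t_peak_open_ms = traj$t_ms[which.max(traj$open)],
                 peak_double = peak_double,
                 tag_duration_ms = tag)
}

#' Extract a glutamate time course at a given distance
#'
#' Pulls the mean free-glutamate concentration time course at the shell whose
#' midpoint is nearest to `distance_um` from an averaged profile series, with
#' a zero-concentration sample prepended at t = 0.
#'
#' @param series A `glu_profile_series`.
#' @param distance_um Distance from the release site (um).
#' @return A tibble (`t_ms`, `glu_mM`) with attribute `distance_um` (the
#'   shell midpoint actually used).
#' @export
glu_timecourse <- function(series, distance_um) {
  stopifnot(inherits(series, "glu_profile_series"))
  mids <- unique(series$summary$r_mid_nm)
  pick <- mids[which.min(abs(mids - distance_um * 1000))]
  d <- dplyr::filter(series$summary, .data$r_mid_nm == pick) |>
    dplyr::arrange(.data$t_ms)
  out <- tibble::tibble(
    t_ms = c(0, d$t_ms),
    glu_mM = c(0, ifelse(is.na(d$mean_free_mM), 0, d$mean_free_mM)))
  attr(out, "distance_um") <- pick / 1000
  out
}

#' Distance-time map of NMDA receptor activation
#'
#' For each requested distance, extracts the free-glutamate transient from
#' the averaged profile series, integrates the receptor scheme, and collects
#' occupancies and metrics into a tidy map.
#'
#' @param series A `glu_profile_series`.
#' @param scheme An [nmdar_scheme()].
#' @param distances_um Distances from the release site (um); matched to
#'   nearest shell midpoints.
#' @param t_max_ms,dt_out_ms,tol Passed to [simulate_nmdar()].
#' @param threshold_fraction Passed to [activation_metrics()].
#' @return An object of class `glu_activation_map`: `map` (tibble
#'   `distance_um`, `t_ms`, `open_prob`, `double_occ`) and `metrics` (one row
#'   per distance).
#' @export
activation_map <- function(series, scheme, distances_um = c(0.25, 0.5, 1),
                           t_max_ms = 300, dt_out_ms = 0.1, tol = 1e-8,
                           threshold_fraction = 0.05) {
  stopifnot(inherits(series, "glu_profile_series"))
  mids <- unique(series$summary$r_mid_nm) / 1000
  if (any(distances_um > max(mids) + 1e-9) || any(distances_um < 0))
    stop("requested distance outside the shell grid", call. = FALSE)
  parts <- purrr::map(distances_um, function(d) {
    glu <- glu_timecourse(series, d)
    traj <- simulate_nmdar(scheme, glu, t_max_ms = t_max_ms,
                           dt_out_ms = dt_out_ms, tol = tol)
    list(map = tibble::tibble(distance_um = attr(glu, "distance_um"),
                              t_ms = traj$t_ms, open_prob = traj$open,
                              double_occ = traj$double_occ),
         metrics = dplyr::mutate(
           activation_metrics(traj, threshold_fraction),
           distance_um = attr(glu, "distance_um"), .before = 1))
  })
  structure(list(map = purrr::map_dfr(parts, "map"),
                 metrics = purrr::map_dfr(parts, "metrics")),
            class = "glu_activation_map")
}

#' @export
print.glu_activation_map <- function(x, ...) {
  cat("<glu_activation_map>\n")
  print(x$metrics)
  invisible(x)
}

#' @rdname activation_map
#' @param x A `glu_activation_map`.
#' @param ... Unused.
#' @export
tidy.glu_activation_map <- function(x, ...) x$map

#' @rdname activation_map
#' @export
glance.glu_activation_map <- function(x, ...) x$metrics

#' Plot an NMDAR activation map
#'
#' @param object A `glu_activation_map`.
#' @param what `"open_prob"` or `"double_occ"`.
#' @param ... Unused.
#' @return A ggplot object (time course per distance).
#' @export
autoplot.glu_activation_map <- function(object,
                                        what = c("open_prob", "double_occ"),
                                        ...) {
  what <- match.arg(what)
  d <- object$map
  d$y <- d[[what]]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_ms, y = .data$y,
                                  colour = factor(.data$distance_um))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)",
                  y = if (what == "open_prob") "open probability"
                      else "double occupancy",
                  colour = "distance (µm)") +
    ggplot2::theme_minimal()
}
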