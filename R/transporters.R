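# Transporter binding hazard, fate assignment, unbinding schedule. These
# tibble-level operations define the stochastic model; the compiled run loop
# applies the same formulas per step.

#' Cumulative transporter binding probability
#'
#' Classical first-order lifetime expression: a particle that has remained in
#' continuous contact with an astroglial surface for `t_contact` ms has bound
#' with probability `1 - exp(-t_contact / psi)`. `psi` lumps transporter
#' affinity, surface density, and surface proximity into one time constant.
#'
#' @param t_contact Continuous contact time (ms), non-negative.
#' @param psi Binding time constant (ms).
#' @return Probability in `[0, 1)`.
#' @export
#' @examples
#' binding_probability(1, psi = 1) # 1 - exp(-1)
binding_probability <- function(t_contact, psi) {
  stopifnot(psi > 0)
  if (any(t_contact < 0)) stop("t_contact must be non-negative", call. = FALSE)
  1 - exp(-t_contact / psi)
}

#' Cumulative-Gaussian unbinding release schedule
#'
#' The S-function governing when a bound glutamate molecule that will unbind
#' is released back into the extracellular space: a cumulative Gaussian in
#' time since binding, crossing 0.5 at `mu` ms with spread `sigma` ms.
#'
#' @param t Time since binding (ms).
#' @param mu Median release delay (ms).
#' @param sigma Spread (ms).
#' @return The release-schedule CDF evaluated at `t`.
#' @export
#' @examples
#' unbind_release_cdf(4) # 0.5
unbind_release_cdf <- function(t, mu = 4, sigma = 2) {
  stopifnot(sigma > 0)
  pnorm((t - mu) / sigma)
}

#' Create an empty transporter book
#'
#' Per-particle bookkeeping of the proximity contact clock, binding time,
#' fate, and scheduled release time.
#'
#' @param n Number of particles.
#' @return A tibble with one row per particle.
#' @export
transporter_book <- function(n) {
  stopifnot(n >= 1)
  tibble::tibble(id = seq_len(n), contact_clock = 0, bound = FALSE,
                 bind_time = NA_real_,
                 fate = factor(NA_character_,
                               levels = c("will_unbind", "will_translocate")),
                 scheduled_release_time = NA_real_)
}

#' Advance contact clocks and sample binding events
#'
#' Clocks of particles in contact advance by `dt`; clocks of particles that
#' departed beyond the cutoff reset to zero. Binding is sampled for each
#' in-contact unbound particle with the incremental hazard
#' `1 - exp(-dt / psi)`, so the cumulative binding probability after
#' continuous contact time `t` equals `1 - exp(-t / psi)` exactly, for any
#' step size.
#'
#' @param book A [transporter_book()].
#' @param proximity_flags Logical vector: particle within cutoff this step.
#' @param dt Time step (ms).
#' @param psi Binding time constant (ms).
#' @param t_now Current system time (ms), recorded as `bind_time` for new
#'   binding events.
#' @param seed Optional integer seed.
#' @return The updated book, with attribute `newly_bound` (particle ids).
#' @export
update_and_sample_binding <- function(book, proximity_flags, dt, psi,
                                      t_now = NA_real_, seed = NULL) {
  stopifnot(dt > 0, psi > 0, nrow(book) == length(proximity_flags))
  run <- function() {
    eligible <- !book$bound
    book$contact_clock[eligible & proximity_flags] <-
      book$contact_clock[eligible & proximity_flags] + dt
    book$contact_clock[eligible & !proximity_flags] <- 0
    hazard <- 1 - exp(-dt / psi)
    candidates <- which(eligible & proximity_flags)
    hit <- candidates[runif(length(candidates)) < hazard]
    book$bound[hit] <- TRUE
    book$bind_time[hit] <- t_now
    attr(book, "newly_bound") <- book$id[hit]
    book
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Assign binding fates and schedule unbinding releases
#'
#' Every binding event is independently assigned the `will_unbind` fate with
#' probability `spec$p_unbind` (otherwise `will_translocate`, keeping the
#' particle retained for the rest of the run). Unbinding delays follow the
#' cumulative-Gaussian schedule of [unbind_release_cdf()]: a Gaussian draw
#' with mean `unbind_mu_ms` and sd `unbind_sigma_ms`, left-censored at zero,
#' which preserves the schedule's crossing of 0.5 at the median delay.
#'
#' @param bound_ids Particle ids of new binding events.
#' @param bind_times Binding times (ms), recycled to length of `bound_ids`.
#' @param spec A [transporter_spec()].
#' @param seed Optional integer seed.
#' @return A tibble with `id`, `bind_time`, `fate`, `scheduled_release_time`
#'   (NA for translocating particles).
#' @export
#' @examples
#' assign_fate_and_schedule(1:5, 0, transporter_spec(), seed = 1)
assign_fate_and_schedule <- function(bound_ids, bind_times, spec, seed = NULL) {
  stopifnot(inherits(spec, "transporter_spec"))
  n <- length(bound_ids)
  bind_times <- rep_len(bind_times, n)
  run <- function() {
    unbind <- runif(n) < spec$p_unbind
    delay <- pmax(0, rnorm(n, spec$unbind_mu_ms, spec$unbind_sigma_ms))
    tibble::tibble(
      id = bound_ids, bind_time = bind_times,
      fate = factor(ifelse(unbind, "will_unbind", "will_translocate"),
                    levels = c("will_unbind", "will_translocate")),
      scheduled_release_time = ifelse(unbind, bind_times + delay, NA_real_))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Release bound particles whose scheduled time has come
#'
#' Particles with the `will_unbind` fate and a scheduled release time at or
#' before `t_now` become free again at their binding position, with contact
#' clock reset, eligible for repeated binding.
#'
#' @param book A fate-annotated book (as produced by merging
#'   [assign_fate_and_schedule()] into a [transporter_book()]).
#' @param ensemble A tibble with `id` and `status` columns.
#' @param t_now Current system time (ms).
#' @return A list with the updated `book` and `ensemble`.
#' @export
release_due <- function(book, ensemble, t_now) {
  due <- !is.na(book$scheduled_release_time) & book$bound &
    book$fate == "will_unbind" & book$scheduled_release_time <= t_now
  ids <- book$id[due]
  book$bound[due] <- FALSE
  book$contact_clock[due] <- 0
  book$bind_time[due] <- NA_real_
  book$fate[due] <- NA
  book$scheduled_release_time[due] <- NA_real_
  sel <- ensemble$id %in% ids
  if (any(sel)) ensemble$status[sel] <- factor("free", levels = status_levels)
  list(book = book, ensemble = ensemble, released = ids)
}
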