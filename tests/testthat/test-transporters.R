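# First-order binding hazard, fate assignment, unbinding schedule.

test_that("binding probability follows the first-order lifetime expression", {
  expect_identical(binding_probability(0, psi = 1), 0)
  expect_equal(binding_probability(1, psi = 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(binding_probability(2, psi = 4), 1 - exp(-0.5), tolerance = 1e-12)
  t <- seq(0, 5, by = 0.1)
  expect_true(all(diff(binding_probability(t, psi = 1)) > 0))
  expect_error(binding_probability(-0.1, psi = 1), "non-negative")
})

test_that("release schedule is a cumulative Gaussian crossing 0.5 at the median", {
  expect_identical(unbind_release_cdf(4, mu = 4, sigma = 2), 0.5)
  expect_equal(unbind_release_cdf(2, mu = 4, sigma = 2), pnorm(-1),
               tolerance = 1e-12)
  expect_equal(unbind_release_cdf(6, mu = 4, sigma = 2), pnorm(1),
               tolerance = 1e-12)
})

test_that("hazard sampling reproduces the exponential waiting time, step-size free", {
  n <- 2e4
  psi <- 1
  bind_times <- function(dt, seed) {
    book <- transporter_book(n)
    tb <- rep(NA_real_, n)
    set.seed(seed)
    for (s in seq_len(round(3 / dt))) {
      book <- update_and_sample_binding(book, rep(TRUE, n), dt, psi,
                                        t_now = s * dt)
      tb[attr(book, "newly_bound")] <- s * dt
    }
    tb
  }
  coarse <- bind_times(0.02, seed = 1)
  fine <- bind_times(0.01, seed = 2)
  for (tt in c(0.5, 1, 2)) {
    target <- 1 - exp(-tt / psi)
    se <- sqrt(target * (1 - target) / n)
    expect_lt(abs(mean(!is.na(coarse) & coarse <= tt) - target), 4 * se)
    expect_lt(abs(mean(!is.na(fine) & fine <= tt) - target), 4 * se)
  }
})

test_that("the contact clock resets when a particle departs and restarts on return", {
  book <- transporter_book(1)
  book <- update_and_sample_binding(book, TRUE, dt = 0.25, psi = 1e9,
                                    t_now = 0.25, seed = 1)
  book <- update_and_sample_binding(book, TRUE, dt = 0.25, psi = 1e9,
                                    t_now = 0.5, seed = 2)
  expect_equal(book$contact_clock, 0.5)
  book <- update_and_sample_binding(book, FALSE, dt = 0.25, psi = 1e9,
                                    t_now = 0.75, seed = 3)
  expect_equal(book$contact_clock, 0)
  book <- update_and_sample_binding(book, TRUE, dt = 0.25, psi = 1e9,
                                    t_now = 1, seed = 4)
  expect_equal(book$contact_clock, 0.25)
})

test_that("fates are Bernoulli at p_unbind and delays follow the S-function", {
  spec <- transporter_spec()
  none <- assign_fate_and_schedule(1:100, 0, transporter_spec(p_unbind = 0),
                                   seed = 1)
  expect_true(all(none$fate == "will_translocate"))
  expect_true(all(is.na(none$scheduled_release_time)))

  n <- 1e5
  fates <- assign_fate_and_schedule(seq_len(n), 0, spec, seed = 2)
  frac <- mean(fates$fate == "will_unbind")
  se <- sqrt(0.35 * 0.65 / n)
  expect_lt(abs(frac - 0.35), 3 * se)
  delays <- fates$scheduled_release_time[fates$fate == "will_unbind"]
  m <- length(delays)
  # empirical CDF matches the cumulative-Gaussian schedule
  expect_lt(abs(mean(delays <= 4) - 0.5), 4 / sqrt(m))
  expect_lt(abs(mean(delays <= 2) - pnorm(-1)), 4 / sqrt(m))
  expect_true(all(delays >= 0))
})

test_that("scheduled releases free particles at the right time, repeatably", {
  book <- transporter_book(3)
  book$bound <- c(TRUE, TRUE, FALSE)
  book$bind_time <- c(1, 1, NA)
  book$fate[1:2] <- "will_unbind"
  book$scheduled_release_time <- c(5, 8, NA)
  ens <- tibble::tibble(id = 1:3,
                        status = factor(c("bound", "bound", "free"),
                                        levels = c("free", "bound",
                                                   "retained", "escaped")))
  r1 <- release_due(book, ens, t_now = 4.9)
  expect_equal(r1$released, integer(0))
  r2 <- release_due(book, ens, t_now = 5)
  expect_equal(r2$released, 1L)
  expect_equal(as.character(r2$ensemble$status), c("free", "bound", "free"))
  expect_equal(r2$book$contact_clock[1], 0)
  expect_false(r2$book$bound[1])
})

test_that("fate draws across bind-release cycles are independent", {
  n <- 4e3
  spec <- transporter_spec()
  cyc1 <- assign_fate_and_schedule(seq_len(n), 0, spec, seed = 5)
  cyc2 <- assign_fate_and_schedule(seq_len(n), 5, spec, seed = 6)
  tab <- table(cyc1$fate, cyc2$fate)
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
})

test_that("with unbinding disabled the bound pool never shrinks in a full run", {
  env <- generate_environment(arena_spec(), seed = 91, n_points = 5e4)
  run <- simulate_run(env, n_particles = 300, seed = 14,
                      transporter = transporter_spec(p_unbind = 0),
                      diffusion = diffusion_spec(
                        t_end_ms = 1.5, record_t_ms = seq(0.25, 1.5, by = 0.25)))
  bound_t <- run$snapshots |>
    dplyr::group_by(t_ms) |>
    dplyr::summarise(n_bound = sum(status %in% c("bound", "retained")))
  expect_true(all(diff(bound_t$n_bound) >= 0))
  expect_equal(run$counters$n_release_events, 0)
})
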