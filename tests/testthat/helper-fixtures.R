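# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small session used across module tests: 12 units, 30 trials/condition
small_bundle <- function() {
  fixture("small_bundle", function() {
    cohort <- ground_truth_cohort(n_units = 12, seed = 42)
    trials <- condition_table(trials_per_condition = 30, order_seed = 42)
    suppressWarnings(simulate_session(cohort, trials, seed = 42))
  })
}

small_metrics <- function() {
  fixture("small_metrics", function() unit_metrics(small_bundle()))
}

# the acceptance cohort: 200 units, 70 trials/condition, fixed seed
acceptance_bundle <- function() {
  fixture("acceptance_bundle", function() {
    cohort <- ground_truth_cohort(n_units = 200, seed = 1)
    trials <- condition_table(trials_per_condition = 70, order_seed = 1)
    suppressWarnings(simulate_session(cohort, trials, seed = 1))
  })
}

acceptance_metrics <- function() {
  fixture("acceptance_metrics", function() unit_metrics(acceptance_bundle()))
}

# von Mises sampler (Best & Fisher), used as an independent oracle for
# circular-CI coverage tests
rvonmises_deg <- function(n, mu_deg, kappa) {
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  (out * 180 / pi) %% 360
}

circ_diff_deg <- function(a, b) ((a - b + 180) %% 360) - 180
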