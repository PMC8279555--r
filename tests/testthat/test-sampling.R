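beta298 <- 1 / kT(298.15)

test_that("Metropolis acceptance handles the limiting cases exactly", {
  expect_true(metropolis_accept(0, beta298, u = 0.999999))
  expect_true(metropolis_accept(-5, beta298, u = 0.999999))
  expect_false(metropolis_accept(1e10, beta298, u = 0))
  st <- metropolis_step("a", "b", beta298, u = 0.9999,
                        energy = function(s) if (s == "a") 0 else 1e9)
  expect_identical(st$state, "a")        # rejected -> prior state
  expect_false(st$accepted)
  st2 <- metropolis_step("a", "b", beta298, u = 0.5,
                         energy = function(s) 0)
  expect_true(st2$accepted)
})

test_that("two-state chain reaches the Boltzmann occupancy ratio", {
  dE <- kT(298.15) * log(2)              # ratio should be 2:1
  energy <- function(s) if (s == 1) 0 else dE
  set.seed(42)
  state <- 1
  n <- 4e4
  visits <- integer(2)
  for (i in seq_len(n)) {
    st <- metropolis_step(state, 3 - state, beta298, energy)
    state <- st$state
    visits[state] <- visits[state] + 1
  }
  p1 <- visits[1] / n
  se <- sqrt(p1 * (1 - p1) / n) * 3      # crude iid bound; chain mixes fast
  expect_lt(abs(p1 - 2 / 3), 3 * se + 0.01)
})

test_that("three-state toy chain satisfies detailed balance in distribution", {
  E <- c(0, 1.7, 4.1)
  pexp <- exp(-beta298 * E) / sum(exp(-beta298 * E))
  set.seed(17)
  state <- 1L
  n <- 6e4
  visits <- integer(3)
  for (i in seq_len(n)) {
    prop <- sample.int(3, 1)
    st <- metropolis_step(state, prop, beta298, function(s) E[s])
    state <- st$state
    visits[state] <- visits[state] + 1
  }
  phat <- visits / n
  for (s in 1:3) {
    se <- sqrt(pexp[s] * (1 - pexp[s]) / n)
    expect_lt(abs(phat[s] - pexp[s]), 3 * se + 0.01)
  }
})

test_that("umbrella run with zero-strength bias equals the unbiased run", {
  top <- chain_topology(8)
  sch <- window_schedule(6, k = 0, equilibration = 500, production = 3000)
  h <- run_umbrella_windows(top, schedule = sch,
                            mc = mc_config(seed = 12, stride = 5),
                            breaks = seq(0, 10, 0.1))
  plain <- run_mc(top, config = mc_config(seed = 12, stride = 5,
                                          n_steps = 3000),
                  equilibration = 500)
  expect_equal(as.numeric(h$counts),
               chainpmf:::.bin_counts(plain$r_ee, h$breaks))
})

test_that("window centres reproduce the configured 0.5 A spacing exactly", {
  sch <- window_schedule(seq(4, 14, by = 0.5))
  expect_equal(unique(round(sch$spacing, 12)), 0.5)
  top <- chain_topology(11)
  h <- run_umbrella_windows(top, schedule = window_schedule(
    seq(8, 12, 0.5), equilibration = 200, production = 1000),
    mc = mc_config(seed = 2))
  expect_equal(h$bias_r0, seq(8, 12, 0.5))
  expect_equal(unique(h$bias_k), 50)
})

test_that("biased window sampling matches the quadratic-completion mean", {
  # true PMF 0.5 kappa r^2 plus window bias: Gaussian with known mean
  kappa <- 8; k <- 50; r0 <- 1.5
  h <- harmonic_umbrella_fixture(kappa, centers = r0, k = k,
                                 n_per_window = 20000, seed = 33)
  m_expect <- r0 * k / (kappa + k)
  sd_true <- sqrt(kT(298.15) / (kappa + k))
  counts <- h$counts[1, ]
  m_obs <- sum(h$mids * counts) / sum(counts)
  expect_lt(abs(m_obs - m_expect),
            3 * sd_true / sqrt(sum(counts)) + 0.03)  # + half-bin slack
})

test_that("replica exchange decision is exact in the limiting cases", {
  b1 <- 1 / kT(298.15); b2 <- 1 / kT(400)
  expect_true(remd_exchange_decision(5, 5, b1, b2, u = 0.999999))
  expect_true(remd_exchange_decision(3, 9, b1, b1, u = 0.999999))
  # downhill-in-(beta, E) swaps always accepted
  expect_true(remd_exchange_decision(10, 2, b1, b2, u = 0.999999))
})

test_that("empirical swap rate matches the quadrature oracle", {
  T1 <- 298.15; T2 <- 400
  b1 <- 1 / kT(T1); b2 <- 1 / kT(T2)
  kappa <- 20
  set.seed(6)
  n <- 2e4
  E1 <- 0.5 * kappa * rnorm(n, 0, sqrt(kT(T1) / kappa))^2
  E2 <- 0.5 * kappa * rnorm(n, 0, sqrt(kT(T2) / kappa))^2
  acc <- mean(vapply(seq_len(n), function(i)
    remd_exchange_decision(E1[i], E2[i], b1, b2), logical(1)))
  oracle <- oracle_swap_rate(T1, T2)
  expect_lt(abs(acc - oracle), 3 * sqrt(oracle * (1 - oracle) / n) + 0.01)
})

test_that("single-temperature replica run collapses to plain umbrella sampling", {
  top <- chain_topology(8)
  sch <- window_schedule(seq(4, 9, 0.5), equilibration = 500,
                         production = 2000)
  h1 <- run_umbrella_windows(top, schedule = sch,
                             mc = mc_config(seed = 5, stride = 10))
  r1 <- run_remd_umbrella(top, schedule = sch,
                          remd = remd_config(298.15, 200, seed = 5),
                          mc = mc_config(stride = 10))
  expect_equal(h1$counts, r1$histograms[[1]]$counts)
  expect_equal(h1$breaks, r1$histograms[[1]]$breaks)
})

test_that("replica-exchange marginals match independent single-T runs", {
  top <- chain_topology(8)
  sch <- window_schedule(7, k = 0, equilibration = 1000, production = 20000)
  temps <- c(298.15, 400)
  res <- run_remd_umbrella(top, schedule = sch,
                           remd = remd_config(temps, 250, seed = 9),
                           mc = mc_config(stride = 5))
  for (i in seq_along(temps)) {
    solo <- run_mc(top, config = mc_config(temperature = temps[i], seed = 100 + i,
                                           stride = 5, n_steps = 20000),
                   equilibration = 1000)
    hm <- res$histograms[[i]]
    m_remd <- sum(hm$mids * hm$counts[1, ]) / sum(hm$counts[1, ])
    m_solo <- mean(solo$r_ee)
    se <- sqrt(block_se(solo$r_ee)^2 + block_se(solo$r_ee)^2)
    expect_lt(abs(m_remd - m_solo), 4 * se + 0.05)
  }
  expect_true(res$swap_acceptance >= 0 && res$swap_acceptance <= 1)
})

test_that("fixed seeds give bit-identical histograms", {
  top <- chain_topology(9)
  sch <- window_schedule(seq(5, 9, 1), equilibration = 200, production = 1000)
  h1 <- run_umbrella_windows(top, schedule = sch, mc = mc_config(seed = 77))
  h2 <- run_umbrella_windows(top, schedule = sch, mc = mc_config(seed = 77))
  expect_identical(h1$counts, h2$counts)
  expect_identical(h1$r_rep, h2$r_rep)
})

test_that("larger maximum step size never increases the acceptance rate", {
  top <- chain_topology(11)
  steps <- c(5, 20, 60, 120)
  acc <- matrix(NA_real_, 10, length(steps))
  for (s in 1:10) {
    for (j in seq_along(steps)) {
      run <- run_mc(top, config = mc_config(seed = 1000 + s, n_steps = 4000,
                                            max_step = steps[j], p_pivot = 0))
      acc[s, j] <- run$acceptance
    }
  }
  mean_acc <- colMeans(acc)
  expect_true(all(diff(mean_acc) <= 1e-9))
})

test_that("schedules and configs validate their invariants", {
  expect_error(window_schedule(c(5, 5, 6)), "strictly increasing")
  expect_error(window_schedule(numeric(0)), "at least one")
  expect_error(mc_config(temperature = -1), "positive")
  expect_error(remd_config(c(400, 300)), "strictly increasing")
  expect_equal(length(remd_ladder()), 10)
  expect_equal(remd_ladder()[1], 298.15)
  expect_equal(remd_ladder()[10], 500)
})

test_that("empty windows are reported by name", {
  top <- chain_topology(8)
  # grid that cannot contain any sample of the window at r0 = 6
  sch <- window_schedule(6, equilibration = 100, production = 500)
  expect_error(
    run_umbrella_windows(top, schedule = sch, mc = mc_config(seed = 3),
                         breaks = seq(50, 60, 0.1)),
    "window 1")
})
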