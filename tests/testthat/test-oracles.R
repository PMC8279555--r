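test_that("single-dihedral RIS trans population has its closed form", {
  for (Tt in c(250, 298.15, 400)) {
    mod <- ris_model(1, eps_g = 2.9)
    L <- ris_enumerate(mod, Tt)
    expect_equal(L$trans_fraction,
                 1 / (1 + 2 * exp(-2.9 / kT(Tt))), tolerance = 1e-12)
  }
})

test_that("excluded pentane pairs carry exactly zero weight", {
  mod <- ris_model(3, exclude_pentane = TRUE)
  L <- ris_enumerate(mod, 298.15)
  st <- L$states
  # decode base-3 states and find adjacent g+g-/g-g+ pairs
  digits <- t(vapply(seq_along(st$energy) - 1, function(s) {
    d <- integer(3)
    for (i in 1:3) { d[i] <- as.integer(s %% 3); s <- s %/% 3 }
    d
  }, integer(3)))
  pent <- (digits[, 1] == 1 & digits[, 2] == 2) |
    (digits[, 1] == 2 & digits[, 2] == 1) |
    (digits[, 2] == 1 & digits[, 3] == 2) |
    (digits[, 2] == 2 & digits[, 3] == 1)
  expect_true(all(is.infinite(st$energy[pent])))
  expect_true(all(is.finite(st$energy[!pent])))
  # weights: P sums to 1 per temperature even with exclusions
  expect_equal(rowSums(L$P), 1, tolerance = 1e-12)
})

test_that("enumeration probabilities normalise and G is min-anchored", {
  mod <- ris_model(6)
  L <- ris_enumerate(mod, c(298.15, 400))
  expect_equal(unname(rowSums(L$P)), c(1, 1), tolerance = 1e-12)
  expect_equal(apply(L$G, 1, min, na.rm = TRUE), c(0, 0))
  expect_error(ris_model(13), "1..12")
})

test_that("enumeration obeys Gibbs-Helmholtz finite differences", {
  # -T^2 d(G_raw/T)/dT must equal the Boltzmann mean energy per bin
  mod <- ris_model(5)
  T0 <- 350
  dT <- 0.25
  L <- ris_enumerate(mod, c(T0 - dT, T0, T0 + dT), bin_width = 0.1)
  st <- L$states
  w <- breaks <- L$breaks
  bin <- pmin(pmax(floor((st$r_ee - breaks[1]) / diff(breaks[1:2])) + 1, 1),
              length(breaks) - 1)
  kt <- kT(T0)
  wts <- exp(-st$energy / kt)
  num <- rowsum(wts * st$energy, bin)
  den <- rowsum(wts, bin)
  Hbin <- rep(NA_real_, length(L$mids))
  Hbin[as.integer(rownames(num))] <- num / den
  # gauge: G_raw includes +kT ln Z whose derivative is the mean total energy
  Z <- sum(wts)
  Emean <- sum(wts * st$energy) / Z
  Hfd <- -T0^2 * (L$G_raw[3, ] / (T0 + dT) - L$G_raw[1, ] / (T0 - dT)) /
    (2 * dT)
  ok <- is.finite(Hfd)
  expect_lt(max(abs(Hfd[ok] - (Hbin[ok] - Emean))), 1e-3)
})

test_that("unbiased harmonic fixture samples N(0, kT/kappa)", {
  kappa <- 10
  h <- harmonic_umbrella_fixture(kappa, centers = 0, k = 0,
                                 n_per_window = 30000, seed = 2)
  counts <- h$counts[1, ]
  mu <- sum(h$mids * counts) / sum(counts)
  v <- sum(h$mids^2 * counts) / sum(counts) - mu^2
  expect_lt(abs(mu), 3 * sqrt(kT(298.15) / kappa / 30000) + 0.01)
  expect_equal(v, kT(298.15) / kappa, tolerance = 0.05)
})

test_that("two-cluster fixture honours its weights and degenerate limits", {
  c1 <- rep(180, 4); c2 <- rep(60, 4)
  all_one <- two_cluster_dihedral_fixture(4, rbind(c1, c2), weights = c(1, 0),
                                          n = 200, seed = 1)
  expect_true(all(attr(all_one, "labels") == 1))
  expect_true(all(abs(all_one$angles - 180) < 60 |
                    abs(all_one$angles + 180) < 60))
  frozen <- two_cluster_dihedral_fixture(4, rbind(c1, c2),
                                         spreads = c(0, 0),
                                         weights = c(0.5, 0.5), n = 100,
                                         seed = 2)
  expect_equal(nrow(unique(frozen$angles)), 2)
  mixed <- two_cluster_dihedral_fixture(4, rbind(c1, c2),
                                        weights = c(0.7, 0.3), n = 5000,
                                        seed = 3)
  phat <- mean(attr(mixed, "labels") == 1)
  expect_lt(abs(phat - 0.7), 3 * sqrt(0.7 * 0.3 / 5000))
  expect_error(two_cluster_dihedral_fixture(4, rbind(c1, c2),
                                            weights = c(0.6, 0.6)),
               "sum to 1")
})

test_that("sampled RIS chain agrees with enumeration across temperatures", {
  mod <- ris_model(6)
  for (Tt in c(298.15, 450)) {
    L <- ris_enumerate(mod, Tt)
    run <- run_ris_mc(mod, temperature = Tt, n_steps = 2e5, stride = 2,
                      seed = round(Tt))
    se <- block_se(run$r_ee^2)
    expect_lt(abs(mean(run$r_ee^2) - L$rms_ree^2), 3 * se)
    tf <- 1 - mean(run$n_gauche) / mod$m
    expect_lt(abs(tf - L$trans_fraction), 3 * block_se(1 - run$n_gauche / mod$m))
  }
})

test_that("scenario configs are deterministic and validated", {
  cfg1 <- confined_chain_scenario(11, seed = 5)
  cfg2 <- confined_chain_scenario(11, seed = 5)
  expect_identical(cfg1, cfg2)
  p1 <- tempfile(fileext = ".yml"); p2 <- tempfile(fileext = ".yml")
  write_config(cfg1, p1); write_config(cfg2, p2)
  expect_identical(readLines(p1), readLines(p2))   # byte-for-byte
  expect_silent(validate_config(cfg1))
  bad <- cfg1; bad$extra_section <- list(a = 1)
  expect_error(validate_config(bad), "unknown config section")
  bad2 <- cfg1; bad2$wham$typo <- 1
  expect_error(validate_config(bad2), "unknown key")
  expect_error(confined_chain_scenario(3), "4..30")
})

test_that("free-chain scenario keeps its PMF minimum below full extension", {
  cfg <- confined_chain_scenario(11, cavity = NULL, seed = 3)
  cfg$umbrella$equilibration <- 2000
  cfg$umbrella$production <- 15000
  res <- run_scenario(cfg)
  expect_gt(nrow(res$minima), 0)
  expect_lt(res$minima$r[1], all_trans_length(chain_topology(11)))
  expect_true(as.character(res$dominant$motif) %in%
                c("linear", "hairpin", "chicane"))
})
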