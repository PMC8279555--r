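ladder <- remd_ladder()

test_that("temperature-independent surfaces give zero entropy", {
  G <- matrix(rep(c(1.2, 0.4, 2.5), each = length(ladder)), nrow = length(ladder))
  th <- fit_gibbs_helmholtz(multi_temperature_pmf(ladder, 1:3, G))
  expect_equal(th$A, c(1.2, 0.4, 2.5), tolerance = 1e-10)
  expect_equal(th$B, rep(0, 3), tolerance = 1e-10)
  expect_equal(th$C, rep(0, 3), tolerance = 1e-10)
  expect_equal(th$H, th$G, tolerance = 1e-10)
  expect_equal(th$minus_TS, rep(0, 3), tolerance = 1e-10)
})

test_that("noiseless synthetic coefficients are recovered to 1e-9", {
  set.seed(4)
  nb <- 12
  A <- rnorm(nb, 2, 1); B <- rnorm(nb, 0, 0.02); C <- rnorm(nb, 0, 0.02)
  G <- t(vapply(ladder, function(Tt)
    A + B * (Tt - 298.15) + C * Tt * log(Tt / 298.15), numeric(nb)))
  th <- fit_gibbs_helmholtz(multi_temperature_pmf(ladder, seq_len(nb), G))
  expect_lt(max(abs(th$A - A)), 1e-9)
  expect_lt(max(abs(th$B - B)), 1e-9)
  expect_lt(max(abs(th$C - C)), 1e-9)
  expect_lt(max(th$residual_rms), 1e-9)
})

test_that("the thermodynamic identities hold at and away from T0", {
  set.seed(5)
  A <- rnorm(6); B <- rnorm(6, 0, 0.01); C <- rnorm(6, 0, 0.01)
  th <- thermo_profile(1:6, A, B, C, T0 = 298.15)
  # printed T0 identities
  expect_equal(th$G, A)
  expect_equal(th$H, A - (B + C) * 298.15)
  expect_equal(th$minus_TS, (B + C) * 298.15)
  he0 <- enthalpy_entropy(th, 298.15)
  expect_equal(he0$H, th$H, tolerance = 1e-12)
  expect_equal(he0$minus_TS, th$minus_TS, tolerance = 1e-12)
  # G = H - TS at every fitted temperature to 1e-9
  for (Tt in ladder) {
    he <- enthalpy_entropy(th, Tt)
    model_G <- A + B * (Tt - 298.15) + C * Tt * log(Tt / 298.15)
    expect_lt(max(abs(he$G - model_G)), 1e-9)
  }
  # heat capacity dH/dT = -C, constant in T
  dT <- 1e-3
  for (Tt in c(310, 420)) {
    cp <- (enthalpy_entropy(th, Tt + dT)$H -
             enthalpy_entropy(th, Tt - dT)$H) / (2 * dT)
    expect_equal(cp, -C, tolerance = 1e-6)
  }
  expect_error(enthalpy_entropy(th, -5), "positive")
})

test_that("degenerate designs are refused", {
  G <- matrix(rnorm(6), 2, 3)
  expect_error(fit_gibbs_helmholtz(multi_temperature_pmf(c(300, 350), 1:3, G)),
               class = "chainpmf_numeric_error")
  G3 <- matrix(rnorm(9), 3, 3)
  expect_error(
    fit_gibbs_helmholtz(multi_temperature_pmf(c(300, 350, 350), 1:3, G3)),
    "duplicate")
})

test_that("a uniform shift at one temperature moves C uniformly across bins", {
  set.seed(6)
  nb <- 8
  A <- rnorm(nb); B <- rnorm(nb, 0, 0.01); C <- rnorm(nb, 0, 0.01)
  G <- t(vapply(ladder, function(Tt)
    A + B * (Tt - 298.15) + C * Tt * log(Tt / 298.15), numeric(nb)))
  th0 <- fit_gibbs_helmholtz(multi_temperature_pmf(ladder, seq_len(nb), G))
  G2 <- G
  G2[4, ] <- G2[4, ] + 2.5                       # constant shift at one T
  th1 <- fit_gibbs_helmholtz(multi_temperature_pmf(ladder, seq_len(nb), G2))
  dC <- th1$C - th0$C
  expect_lt(max(abs(dC - dC[1])), 1e-9)          # same shift for every bin
  dA <- th1$A - th0$A
  expect_lt(max(abs(dA - dA[1])), 1e-9)
})

test_that("H(T0) noise amplification matches exact OLS error propagation", {
  # H(T0) = A - T0 (B + C) is the Gibbs-Helmholtz intercept; over this
  # ladder its standard error is |c' (X'X)^{-1} c|^{1/2} sigma with
  # c = (1, -T0, -T0) -- about 6.6 sigma.  The fitted estimator should
  # attain (not beat, not exceed) that analytic bound.
  T0 <- 298.15
  X <- cbind(1, ladder - T0, ladder * log(ladder / T0))
  cvec <- c(1, -T0, -T0)
  mult <- sqrt(drop(t(cvec) %*% solve(crossprod(X)) %*% cvec))
  sigma <- 0.05
  set.seed(9)
  errs <- replicate(200, {
    A <- rnorm(1, 2, 1); B <- rnorm(1, 0, 0.02); C <- rnorm(1, 0, 0.02)
    G <- A + B * (ladder - T0) + C * ladder * log(ladder / T0) +
      rnorm(length(ladder), 0, sigma)
    th <- fit_gibbs_helmholtz(multi_temperature_pmf(ladder, 1, matrix(G)))
    abs(th$H - (A - (B + C) * T0))
  })
  analytic_median <- 0.6745 * mult * sigma
  expect_lt(median(errs), 1.5 * analytic_median)
  expect_gt(median(errs), 0.4 * analytic_median)
})

test_that("a fourth, quadratic term is not supported by 3-term data", {
  set.seed(10)
  A <- 1.3; B <- 0.01; C <- -0.02
  G <- A + B * (ladder - 298.15) + C * ladder * log(ladder / 298.15)
  X <- cbind(1, ladder - 298.15, ladder * log(ladder / 298.15),
             (ladder - 298.15)^2)
  fit <- lm.fit(X, G)
  expect_lt(abs(fit$coefficients[4]), 1e-10)
})

test_that("fit matches the finite-difference enthalpy on enumerated surfaces", {
  mod <- ris_model(6)
  L <- ris_enumerate(mod, ladder, bin_width = 0.1)
  ref <- max(which(is.finite(L$G_raw[1, ])))   # all-trans bin fixes the gauge
  Grel <- L$G_raw - L$G_raw[, ref]
  th <- fit_gibbs_helmholtz(multi_temperature_pmf(ladder, L$mids, Grel))
  dT <- 0.5
  Lp <- ris_enumerate(mod, c(298.15 - dT, 298.15 + dT), bin_width = 0.1)
  Gp <- Lp$G_raw - Lp$G_raw[, ref]
  Hfd <- -298.15^2 * (Gp[2, ] / (298.15 + dT) -
                        Gp[1, ] / (298.15 - dT)) / (2 * dT)
  well <- L$P[1, ] >= 1e-3
  expect_lt(max(abs(th$H[well] - Hfd[well]), na.rm = TRUE), 0.1)
})

test_that("the WHAM + fit pipeline reproduces enumeration-derived H and -TS", {
  mod <- ris_model(6)
  temps <- ladder
  L <- ris_enumerate(mod, temps, bin_width = 0.1)
  sch <- window_schedule(seq(3, 9.6, by = 0.6), k = 5, equilibration = 3000,
                         production = 1200000)
  hists <- lapply(temps, function(Tt)
    run_ris_umbrella(mod, sch, temperature = Tt, breaks = L$breaks,
                     stride = 2, seed = 40 + round(Tt)))
  res <- decompose_pmf_pipeline(hists)
  # exact reference: fit the same model to min-anchored enumeration surfaces
  th_exact <- fit_gibbs_helmholtz(multi_temperature_pmf(temps, L$mids, L$G))
  ok <- is.finite(res$profile$H) & is.finite(th_exact$H) &
    apply(L$P >= 2e-3, 2, all)
  expect_gt(sum(ok), 10)
  expect_lt(sqrt(mean((res$profile$H[ok] - th_exact$H[ok])^2)), 0.2)
  expect_lt(sqrt(mean((res$profile$minus_TS[ok] - th_exact$minus_TS[ok])^2)),
            0.2)
})

test_that("errors from pipeline stages carry the stage name", {
  counts <- rbind(c(50, 0, 0, 0, 0), c(0, 0, 0, 0, 40))
  h <- biased_histogram_set(counts, seq(0, 5), c(10, 10), c(0.5, 4.5), 300)
  err <- tryCatch(decompose_pmf_pipeline(list(h, h, h)),
                  error = function(e) e)
  expect_match(conditionMessage(err), "WHAM stage")
})
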