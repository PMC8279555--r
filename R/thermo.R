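#' Multi-temperature PMF container
#'
#' @param temperatures temperature list in K (>= 3 for fitting; all
#'   positive, no duplicates).
#' @param r common distance grid in Angstrom.
#' @param G temperatures x bins matrix of free energies in kJ/mol (NA
#'   allowed on unpopulated bins).
#' @param sigma optional matrix of per-point uncertainties (same shape).
#' @return object of class `multi_temperature_pmf`.
#' @export
multi_temperature_pmf <- function(temperatures, r, G, sigma = NULL) {
  temperatures <- as.numeric(temperatures)
  G <- as.matrix(G)
  if (any(temperatures <= 0)) stop("temperatures must be positive")
  if (nrow(G) != length(temperatures) || ncol(G) != length(r))
    stop("G must be temperatures x bins")
  if (!is.null(sigma)) {
    sigma <- as.matrix(sigma)
    if (!all(dim(sigma) == dim(G))) stop("sigma must match G")
  }
  structure(list(temperatures = temperatures, r = as.numeric(r), G = G,
                 sigma = sigma),
            class = "multi_temperature_pmf")
}

#' Thermodynamic decomposition profile
#'
#' Holds the per-bin coefficients of the constant-heat-capacity form
#' `G(T, r) = A(r) + B(r) (T - T0) + C(r) T ln(T/T0)` and the derived
#' G, H and -TS profiles at the reference temperature.  At `T0` the
#' identities `G = A`, `H = A - (B + C) T0` and `-T0 S = (B + C) T0`
#' hold exactly, and `G = H - T S` holds at every temperature by
#' construction.  The heat capacity `dH/dT = -C` is constant in T.
#'
#' @param r distance grid in Angstrom.
#' @param A,B,C coefficient arrays (kJ/mol, kJ/(mol K), kJ/(mol K)).
#' @param T0 reference temperature in K.
#' @param residual_rms per-bin fit residual RMS in kJ/mol.
#' @return object of class `thermo_profile` with derived `G`, `H`,
#'   `minus_TS` at `T0`.
#' @export
thermo_profile <- function(r, A, B, C, T0 = 298.15, residual_rms = NULL) {
  stopifnot(length(A) == length(r), length(B) == length(r),
            length(C) == length(r))
  structure(list(r = as.numeric(r), A = as.numeric(A), B = as.numeric(B),
                 C = as.numeric(C), T0 = T0,
                 G = as.numeric(A),
                 H = A - (B + C) * T0,
                 minus_TS = (B + C) * T0,
                 residual_rms = residual_rms),
            class = "thermo_profile")
}

#' @export
print.thermo_profile <- function(x, ...) {
  ok <- is.finite(x$G)
  cat(sprintf(
    "thermo_profile: %d/%d bins, T0 = %.2f K\n", sum(ok), length(x$r), x$T0))
  if (any(ok)) {
    ig <- which.min(x$G); ih <- which.min(x$H)
    cat(sprintf("  G minimum at r = %.2f A; H minimum at r = %.2f A\n",
                x$r[ig], x$r[ih]))
  }
  invisible(x)
}

#' @export
plot.thermo_profile <- function(x, ...) {
  rng <- range(c(x$G, x$H, x$minus_TS), finite = TRUE)
  plot(x$r, x$G, type = "l", ylim = rng, xlab = "r_ee (Angstrom)",
       ylab = "kJ/mol", ...)
  graphics::lines(x$r, x$H, lty = 2)
  graphics::lines(x$r, x$minus_TS, lty = 3)
  graphics::legend("topleft", legend = c("G", "H", "-TS"), lty = 1:3,
                   bty = "n")
  invisible(x)
}

#' Fit the constant-heat-capacity Gibbs-Helmholtz form
#'
#' Per-bin least squares of `G(T) = A + B (T - T0) + C T ln(T/T0)` over
#' the supplied temperatures (weighted by `1/sigma^2` when uncertainties
#' are present).  This three-parameter family is the general solution of a
#' temperature-independent interaction heat capacity; adding higher-order
#' terms does not change the T0 identities.
#'
#' @param multiT a [multi_temperature_pmf()] with >= 3 temperatures.
#' @param T0 reference temperature in K.
#' @return a [thermo_profile()]; bins with fewer than 3 finite
#'   temperatures get NA coefficients.
#' @export
fit_gibbs_helmholtz <- function(multiT, T0 = 298.15) {
  stopifnot(inherits(multiT, "multi_temperature_pmf"))
  Tv <- multiT$temperatures
  if (length(Tv) < 3)
    stop_numeric(">= 3 temperatures required (3 free coefficients per bin)")
  if (anyDuplicated(Tv))
    stop_numeric("duplicate temperatures make the design rank-deficient")
  X <- cbind(1, Tv - T0, Tv * log(Tv / T0))
  nb <- ncol(multiT$G)
  A <- B <- C <- rms <- rep(NA_real_, nb)
  for (j in seq_len(nb)) {
    y <- multiT$G[, j]
    ok <- is.finite(y)
    if (sum(ok) < 3) next
    Xj <- X[ok, , drop = FALSE]
    yj <- y[ok]
    if (!is.null(multiT$sigma)) {
      wj <- 1 / multiT$sigma[ok, j]^2
      wj[!is.finite(wj)] <- 0
      sw <- sqrt(wj)
      fit <- lm.fit(Xj * sw, yj * sw)
    } else {
      fit <- lm.fit(Xj, yj)
    }
    if (fit$rank < 3) next
    A[j] <- fit$coefficients[1]
    B[j] <- fit$coefficients[2]
    C[j] <- fit$coefficients[3]
    res <- yj - Xj %*% fit$coefficients
    rms[j] <- sqrt(mean(res^2))
  }
  thermo_profile(multiT$r, A, B, C, T0 = T0, residual_rms = rms)
}

#' Enthalpy and entropy profiles at a temperature
#'
#' From the fitted coefficients: `S(T) = -B - C (1 + ln(T/T0))` and
#' `H(T) = A - B T0 - C T`, so that `G(T) = H(T) - T S(T)` is an exact
#' identity of the functional form.
#'
#' @param profile a [thermo_profile()].
#' @param T temperature in K (> 0).
#' @return list with `H`, `minus_TS`, `G` (all kJ/mol) and `T`.
#' @export
enthalpy_entropy <- function(profile, T = profile$T0) {
  stopifnot(inherits(profile, "thermo_profile"))
  if (T <= 0) stop("T must be positive")
  S <- -profile$B - profile$C * (1 + log(T / profile$T0))
  H <- profile$A - profile$B * profile$T0 - profile$C * T
  list(H = H, minus_TS = -T * S, G = H - T * S, T = T)
}

#' WHAM + Gibbs-Helmholtz pipeline over a temperature set
#'
#' Solves WHAM for each per-temperature histogram set (all must share one
#' bin grid), min-anchors each PMF, and fits the constant-heat-capacity
#' form.
#'
#' @param histogram_sets list of [biased_histogram_set()], one per
#'   temperature.
#' @param T0 reference temperature in K.
#' @param ... passed on to [wham_solve()].
#' @return list with `profile` (a [thermo_profile()]), `pmfs` (per-T
#'   [pmf_profile()]s) and `multiT` (the fitted surface).
#' @export
decompose_pmf_pipeline <- function(histogram_sets, T0 = 298.15, ...) {
  if (inherits(histogram_sets, "biased_histogram_set"))
    histogram_sets <- list(histogram_sets)
  temps <- vapply(histogram_sets, function(h) h$temperature, numeric(1))
  pmfs <- vector("list", length(histogram_sets))
  for (i in seq_along(histogram_sets)) {
    pmfs[[i]] <- tryCatch(
      align_pmf(wham_solve(histogram_sets[[i]], ...)),
      error = function(e) stop_numeric(
        sprintf("WHAM stage failed at T = %.2f K: %s", temps[i],
                conditionMessage(e))))
  }
  r <- pmfs[[1]]$r
  for (p in pmfs)
    if (length(p$r) != length(r) || any(abs(p$r - r) > 1e-9))
      stop_numeric("fit stage: per-temperature PMFs are not on a shared grid")
  G <- do.call(rbind, lapply(pmfs, function(p) p$G))
  multiT <- multi_temperature_pmf(temps, r, G)
  profile <- fit_gibbs_helmholtz(multiT, T0 = T0)
  list(profile = profile, pmfs = pmfs, multiT = multiT)
}
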