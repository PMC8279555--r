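#' PMF profile
#'
#' Free energy G(r) on a distance grid, together with the per-window free
#' energies and convergence diagnostics produced by [wham_solve()].
#'
#' @param r bin centres in Angstrom.
#' @param G free energy in kJ/mol (NA on bins with no counts).
#' @param temperature temperature in K.
#' @param F per-window free energies in kJ/mol.
#' @param iterations iterations used.
#' @param max_dF final maximum |change in F| in kJ/mol.
#' @param counts aggregate counts per bin.
#' @param stderr optional per-bin standard error in kJ/mol.
#' @return object of class `pmf_profile`.
#' @export
pmf_profile <- function(r, G, temperature, F = numeric(0), iterations = 0L,
                        max_dF = NA_real_, counts = NULL, stderr = NULL) {
  stopifnot(length(r) == length(G))
  structure(list(r = as.numeric(r), G = as.numeric(G),
                 temperature = temperature, F = F,
                 iterations = as.integer(iterations), max_dF = max_dF,
                 counts = counts, stderr = stderr),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- is.finite(x$G)
  cat(sprintf(
    "pmf_profile: %d/%d populated bins on [%.2f, %.2f] A, T = %.2f K\n",
    sum(ok), length(x$G), min(x$r), max(x$r), x$temperature))
  if (any(ok)) {
    i <- which.min(x$G)
    cat(sprintf("  minimum %.3f kJ/mol at r = %.2f A (%d WHAM iterations, max|dF| = %.2e)\n",
                x$G[i], x$r[i], x$iterations, x$max_dF))
  }
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  plot(x$r, x$G, type = "l", xlab = "r_ee (Angstrom)",
       ylab = "G (kJ/mol)", ...)
  invisible(x)
}

# connectivity of the window-overlap graph; returns component id per window
.overlap_components <- function(counts) {
  nw <- nrow(counts)
  occ <- counts > 0
  comp <- rep(NA_integer_, nw)
  cid <- 0L
  for (s in seq_len(nw)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in seq_len(nw)) {
        if (is.na(comp[j]) && any(occ[i, ] & occ[j, ])) {
          comp[j] <- cid
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

#' Solve WHAM for the unbiased PMF
#'
#' Self-consistent iteration of the weighted histogram analysis method:
#' `P(r) = sum_i n_i(r) / sum_i N_i exp(beta (F_i - U_i(r)))` with
#' `exp(-beta F_i) = sum_r P(r) exp(-beta U_i(r))`, iterated until the
#' largest change in any window free energy falls below `tolerance`.
#' The returned G(r) = -kT ln P(r) is anchored so its minimum is 0; bins
#' with zero aggregate counts are reported as `NA`, never interpolated.
#'
#' @param histograms a [biased_histogram_set()].
#' @param tolerance convergence tolerance on max |dF_i| in kJ/mol.
#' @param max_iterations iteration cap.
#' @return a [pmf_profile()].
#' @export
wham_solve <- function(histograms, tolerance = 1e-6, max_iterations = 1e5) {
  stopifnot(inherits(histograms, "biased_histogram_set"))
  comp <- .overlap_components(histograms$counts)
  if (max(comp) > 1) {
    groups <- split(seq_along(comp), comp)
    stop_numeric("window overlap graph is disconnected; components: ",
                 paste(vapply(groups, function(g)
                   paste0("{", paste(g, collapse = ","), "}"), character(1)),
                   collapse = " "))
  }
  kt <- kT(histograms$temperature)
  beta <- 1 / kt
  # bias energies are evaluated at the per-bin representative coordinate
  # (mean of the samples in the bin) when available; the profile itself is
  # reported on the uniform bin-centre grid
  r <- if (!is.null(histograms$r_rep)) histograms$r_rep else histograms$mids
  n_tot <- colSums(histograms$counts)
  occupied <- n_tot > 0
  N <- histograms$N
  # bias energy of every window at every bin centre
  off <- if (!is.null(histograms$bias_offset)) histograms$bias_offset
         else rep(0, length(N))
  U <- outer(seq_along(N), seq_along(r), function(i, j)
    0.5 * histograms$bias_k[i] * (r[j] - histograms$bias_r0[i])^2 + off[i])
  Fw <- rep(0, length(N))
  lognT <- log(n_tot[occupied])
  logN <- log(N)
  bU <- beta * U[, occupied, drop = FALSE]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # log denominator per occupied bin: logsumexp over windows
    A <- (logN + beta * Fw) - bU            # windows x bins
    mx <- apply(A, 2, max)
    logden <- mx + log(colSums(exp(sweep(A, 2, mx))))
    logP <- lognT - logden
    # window free energies from the new P
    B <- sweep(-bU, 2, logP, "+")           # windows x bins
    mb <- apply(B, 1, max)
    Fw_new <- -kt * (mb + log(rowSums(exp(B - mb))))
    Fw_new <- Fw_new - Fw_new[1]
    dF <- max(abs(Fw_new - Fw))
    Fw <- Fw_new
    if (dF < tolerance) break
    if (iter >= max_iterations)
      stop_numeric(sprintf(
        "WHAM did not converge in %d iterations (max |dF| = %.3e kJ/mol)",
        as.integer(max_iterations), dF))
  }
  G <- rep(NA_real_, length(r))
  G[occupied] <- -kt * logP
  G <- G - min(G, na.rm = TRUE)
  pmf_profile(histograms$mids, G, histograms$temperature, F = Fw,
              iterations = iter, max_dF = dF, counts = n_tot)
}

#' Anchor a PMF at zero
#'
#' Shifts the profile so its global minimum is exactly 0; the shape is
#' unchanged and the operation is idempotent.
#'
#' @param profile a [pmf_profile()].
#' @return the aligned [pmf_profile()].
#' @export
align_pmf <- function(profile) {
  stopifnot(inherits(profile, "pmf_profile"))
  if (!any(is.finite(profile$G))) stop("profile has no finite values")
  profile$G <- profile$G - min(profile$G, na.rm = TRUE)
  profile
}

#' Locate local PMF minima
#'
#' Interior local minima on the uniform grid, filtered by topographic
#' prominence (the height of the lowest barrier separating a minimum from
#' any deeper one; the global minimum has infinite prominence).  Results
#' are ordered by G, so the first entry is the primary minimum.
#'
#' @param profile a [pmf_profile()].
#' @param prominence minimum prominence in kJ/mol.
#' @return data frame with columns `r`, `G`, `prominence`.
#' @export
find_minima <- function(profile, prominence = 0) {
  stopifnot(inherits(profile, "pmf_profile"))
  G <- profile$G
  r <- profile$r
  n <- length(G)
  idx <- integer(0)
  for (i in seq(2, n - 1)) {
    if (!is.finite(G[i]) || !is.finite(G[i - 1]) || !is.finite(G[i + 1])) next
    if (G[i] <= G[i - 1] && G[i] <= G[i + 1] &&
        (G[i] < G[i - 1] || G[i] < G[i + 1]))
      idx <- c(idx, i)
  }
  if (!length(idx))
    return(data.frame(r = numeric(0), G = numeric(0), prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    side <- function(path) {
      hi <- -Inf
      for (j in path) {
        if (!is.finite(G[j])) break   # gap in support acts as a wall
        if (G[j] < G[i]) return(hi)   # reached deeper ground
        hi <- max(hi, G[j])
      }
      Inf                             # no deeper minimum this side
    }
    key <- min(side(rev(seq_len(i - 1))), side(seq(i + 1, n)))
    key - G[i]
  }, numeric(1))
  keep <- prom >= prominence
  out <- data.frame(r = r[idx[keep]], G = G[idx[keep]],
                    prominence = prom[keep])
  out[order(out$G), , drop = FALSE]
}

#' Bayesian-bootstrap uncertainty for a WHAM PMF
#'
#' Re-solves WHAM under Dirichlet(1) window weights and reports the
#' per-bin standard deviation of the aligned profiles.
#'
#' @param histograms a [biased_histogram_set()].
#' @param n_boot number of resamples.
#' @param seed optional integer seed.
#' @param ... passed on to [wham_solve()].
#' @return a [pmf_profile()] with the `stderr` field filled in.
#' @export
wham_bootstrap <- function(histograms, n_boot = 50, seed = NULL, ...) {
  base <- wham_solve(histograms, ...)
  if (!is.null(seed)) set.seed(seed)
  nw <- nrow(histograms$counts)
  mat <- matrix(NA_real_, n_boot, length(base$G))
  for (b in seq_len(n_boot)) {
    w <- -log(runif(nw))
    w <- w / sum(w) * nw                 # Dirichlet(1) scaled to mean 1
    h <- histograms
    h$counts <- histograms$counts * w
    h$N <- rowSums(h$counts)
    g <- tryCatch(wham_solve(h, ...)$G, error = function(e) NULL)
    if (!is.null(g)) mat[b, ] <- g
  }
  base$stderr <- apply(mat, 2, stats::sd, na.rm = TRUE)
  base
}
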