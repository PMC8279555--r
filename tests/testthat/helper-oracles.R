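# Independent oracles used across the suite.  Each re-derives a quantity by
# a different route than the package implementation.

# --- explicit rotation-matrix chain builder -------------------------------
# Start from the closed-form planar all-trans zigzag, then apply each
# dihedral as an explicit Rodrigues rotation of the chain tail about the
# corresponding bond axis.  Shares no code with the NeRF builder.
oracle_build_chain <- function(dihedrals, n, l = 1.53, theta = 112.7) {
  half <- theta / 2 * pi / 180
  p <- l * sin(half)
  q <- l * cos(half)
  xyz <- cbind((seq_len(n) - 1) * p, q * (seq_len(n) %% 2 == 0), 0)
  rot_about <- function(pts, origin, axis, angle) {
    a <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
    t(R %*% (t(pts) - origin) + origin)
  }
  for (k in seq_along(dihedrals)) {
    # dihedral k involves atoms k, k+1, k+2, k+3; rotate tail k+3..n
    cur <- oracle_dihedral(xyz[k, ], xyz[k + 1, ], xyz[k + 2, ], xyz[k + 3, ])
    delta <- (dihedrals[k] - cur) * pi / 180
    axis <- xyz[k + 1, ] - xyz[k + 2, ]   # sense chosen to match IUPAC sign
    tail_idx <- (k + 3):n
    xyz[tail_idx, ] <- rot_about(xyz[tail_idx, , drop = FALSE],
                                 xyz[k + 2, ], axis, delta)
  }
  xyz
}

oracle_dihedral <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  phi <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  phi
}

# --- naive textbook WHAM (probability-space fixed point) ------------------
oracle_wham <- function(counts, breaks, bias_k, bias_r0, temperature,
                        tol = 1e-12, maxit = 2e5, r = NULL) {
  kt <- chainpmf::kT(temperature)
  if (is.null(r)) r <- (head(breaks, -1) + tail(breaks, -1)) / 2
  nw <- nrow(counts)
  U <- matrix(0, nw, length(r))
  for (i in seq_len(nw)) U[i, ] <- 0.5 * bias_k[i] * (r - bias_r0[i])^2
  N <- rowSums(counts)
  f <- rep(1, nw)                        # f_i = exp(+F_i / kT)
  ntot <- colSums(counts)
  P <- rep(0, length(r))
  for (it in seq_len(maxit)) {
    den <- colSums(N * f * exp(-U / kt)) # sum_i N_i f_i e^{-beta U_i}
    P <- ifelse(den > 0, ntot / den, 0)
    f_new <- vapply(seq_len(nw), function(i) 1 / sum(P * exp(-U[i, ] / kt)),
                    numeric(1))
    f_new <- f_new / f_new[1]
    if (max(abs(log(f_new) - log(f))) < tol / kt) { f <- f_new; break }
    f <- f_new
  }
  G <- -kt * log(P / sum(P))
  G <- G - min(G[is.finite(G)])
  G[!is.finite(G)] <- NA
  list(G = G, F = kt * log(f), P = P / sum(P))
}

# --- analytic union volume of two spheres ---------------------------------
oracle_two_sphere_union <- function(r1, r2, d) {
  v <- 4 / 3 * pi * (r1^3 + r2^3)
  if (d >= r1 + r2) return(v)
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
  v - lens
}

# --- block standard error for correlated samples --------------------------
block_se <- function(x, nblocks = 20) {
  n <- length(x)
  bs <- floor(n / nblocks)
  means <- vapply(seq_len(nblocks),
                  function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                  numeric(1))
  stats::sd(means) / sqrt(nblocks)
}

# --- replica swap acceptance by 2-D quadrature ----------------------------
# Both replicas sample U = 0.5 kappa x^2, so E ~ (kT/2) chi^2_1.
oracle_swap_rate <- function(T_i, T_j, nq = 400) {
  kB <- 8.31446261815324e-3
  bi <- 1 / (kB * T_i); bj <- 1 / (kB * T_j)
  # E = z^2/(2 beta) with z standard normal
  zs <- seq(-6, 6, length.out = nq)
  wz <- stats::dnorm(zs); wz <- wz / sum(wz)
  Ei <- zs^2 / (2 * bi)
  Ej <- zs^2 / (2 * bj)
  acc <- outer(Ei, Ej, function(a, b) pmin(1, exp((bi - bj) * (a - b))))
  sum(wz * (acc %*% wz))
}

# --- eigenpairs of a small matrix via the characteristic polynomial -------
# Faddeev-LeVerrier coefficients + polyroot + null-space eigenvectors.
oracle_eigen_small <- function(A) {
  n <- nrow(A)
  coefs <- numeric(n + 1)
  coefs[n + 1] <- 1                      # lambda^n
  M <- diag(n)
  cs <- numeric(n)
  for (k in seq_len(n)) {
    M <- A %*% M
    cs[k] <- -sum(diag(M)) / k
    coefs[n + 1 - k] <- cs[k]
    M <- M + diag(cs[k], n)
  }
  lam <- sort(Re(polyroot(coefs)), decreasing = TRUE)
  vecs <- sapply(lam, function(l) {
    s <- svd(A - diag(l, n))
    v <- s$v[, n]
    i <- which.max(abs(v))
    if (v[i] < 0) -v else v
  })
  list(values = lam, vectors = vecs)
}

# small standard alkane helpers used in many tests
all_trans <- function(top) rep(180, top$n_dihedrals)
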