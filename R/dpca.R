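#' Dihedral trajectory
#'
#' Time-ordered frames of backbone dihedrals with optional frame weights.
#'
#' @param angles frames x m matrix of dihedrals in degrees (wrapped to
#'   (-180, 180]).
#' @param weights nonnegative frame weights (default uniform).
#' @return object of class `dihedral_trajectory`.
#' @export
dihedral_trajectory <- function(angles, weights = NULL) {
  angles <- as.matrix(angles)
  storage.mode(angles) <- "double"
  angles[] <- wrap_angle(angles)
  if (is.null(weights)) weights <- rep(1, nrow(angles))
  if (length(weights) != nrow(angles)) stop("one weight per frame required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  structure(list(angles = angles, weights = as.numeric(weights)),
            class = "dihedral_trajectory")
}

#' @export
print.dihedral_trajectory <- function(x, ...) {
  cat(sprintf("dihedral_trajectory: %d frames x %d dihedrals\n",
              nrow(x$angles), ncol(x$angles)))
  invisible(x)
}

#' Circular (cos, sin) embedding of dihedrals
#'
#' Maps each dihedral phi_k to the pair (cos phi_k, sin phi_k), removing
#' angular periodicity before PCA.  Columns are ordered cos1, sin1, cos2,
#' sin2, ...
#'
#' @param trajectory a [dihedral_trajectory()] or an angle matrix.
#' @return frames x 2m numeric matrix with values in `[-1, 1]`.
#' @export
circular_embed <- function(trajectory) {
  ang <- if (inherits(trajectory, "dihedral_trajectory")) trajectory$angles
         else as.matrix(trajectory)
  rad <- ang * pi / 180
  m <- ncol(rad)
  out <- matrix(0, nrow(rad), 2 * m)
  out[, seq(1, 2 * m, by = 2)] <- cos(rad)
  out[, seq(2, 2 * m, by = 2)] <- sin(rad)
  colnames(out) <- paste0(rep(c("cos", "sin"), m), rep(seq_len(m), each = 2))
  out
}

#' Top-two dihedral principal components
#'
#' Eigendecomposition of the (weighted) covariance matrix of the
#' circularly embedded dihedrals; the two eigenvectors with the greatest
#' variance define the projection plane.  The sign of each eigenvector is
#' fixed so its largest-magnitude loading is positive.
#'
#' @param x a [dihedral_trajectory()] (embedded internally) or an
#'   already-embedded matrix.
#' @param weights frame weights (taken from the trajectory if present).
#' @return object of class `pca_result` with `mean`, `eigenvalues`
#'   (descending, all of them), `vectors` (2m x 2), `projections`
#'   (frames x 2) and `total_variance`.  When `x` was a trajectory it is
#'   kept in `$trajectory` for [dominant_conformation()].
#' @export
top2_pca <- function(x, weights = NULL) {
  traj <- NULL
  if (inherits(x, "dihedral_trajectory")) {
    traj <- x
    if (is.null(weights)) weights <- x$weights
    x <- circular_embed(x)
  }
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 frames for PCA")
  if (ncol(x) < 2) stop("need >= 2 columns for PCA")
  if (is.null(weights)) weights <- rep(1, nrow(x))
  cw <- cov.wt(x, wt = weights / sum(weights), method = "ML")
  ev <- eigen(cw$cov, symmetric = TRUE)
  total <- sum(diag(cw$cov))
  if (total <= 0) stop("zero total variance: no conformational spread")
  vecs <- ev$vectors[, 1:2, drop = FALSE]
  for (k in 1:2) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  centred <- sweep(x, 2, cw$center)
  structure(list(mean = cw$center, eigenvalues = pmax(ev$values, 0),
                 vectors = vecs, projections = centred %*% vecs,
                 total_variance = total, weights = weights,
                 trajectory = traj),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  frac <- sum(x$eigenvalues[1:2]) / x$total_variance
  cat(sprintf(
    "pca_result: %d frames, top-2 variance fraction %.3f (lambda = %.4f, %.4f)\n",
    nrow(x$projections), frac, x$eigenvalues[1], x$eigenvalues[2]))
  invisible(x)
}

#' Dominant conformation from the PC-plane probability maximum
#'
#' Histograms the frame projections on a `bins` x `bins` grid, locates the
#' mode bin (weighted by frame weights), and returns the frame whose
#' projection lies closest (Euclidean, in the PC plane) to the mode bin
#' centre.  Ties break to the lowest frame index.
#'
#' @param pca a `pca_result` from [top2_pca()].
#' @param bins histogram bins per axis.
#' @return list with `frame` (index), `pc` (its projection), `mode_center`
#'   (PC coordinates of the mode bin) and, when the trajectory is
#'   available, `dihedrals`.
#' @export
dominant_conformation <- function(pca, bins = 50) {
  stopifnot(inherits(pca, "pca_result"))
  P <- pca$projections
  n <- nrow(P)
  if (n < 1) stop("need at least one frame")
  w <- pca$weights
  if (n == 1) {
    best <- 1L
    center <- P[1, ]
  } else {
    rng1 <- range(P[, 1]); rng2 <- range(P[, 2])
    pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
    rng1 <- pad(rng1); rng2 <- pad(rng2)
    b1 <- seq(rng1[1], rng1[2], length.out = bins + 1)
    b2 <- seq(rng2[1], rng2[2], length.out = bins + 1)
    i1 <- pmin(pmax(findInterval(P[, 1], b1, all.inside = TRUE), 1), bins)
    i2 <- pmin(pmax(findInterval(P[, 2], b2, all.inside = TRUE), 1), bins)
    H <- matrix(0, bins, bins)
    for (f in seq_len(n)) H[i1[f], i2[f]] <- H[i1[f], i2[f]] + w[f]
    mode_idx <- which(H == max(H), arr.ind = TRUE)[1, ]   # ties: lowest index
    center <- c((b1[mode_idx[1]] + b1[mode_idx[1] + 1]) / 2,
                (b2[mode_idx[2]] + b2[mode_idx[2] + 1]) / 2)
    d2 <- (P[, 1] - center[1])^2 + (P[, 2] - center[2])^2
    best <- which.min(d2)                                  # ties: lowest index
  }
  out <- list(frame = best, pc = P[best, ], mode_center = center)
  if (!is.null(pca$trajectory))
    out$dihedrals <- pca$trajectory$angles[best, ]
  out
}

#' Classify a conformation into linear / hairpin / chicane motifs
#'
#' Coarse direction vectors are taken over successive 3-bond segments of
#' the backbone; their components along the chain's principal axis define
#' a sign sequence.  A turn is a sign reversal that persists for at least
#' 2 segments (single-segment flickers are smoothed away).  0 turns is
#' linear (the extended and helical families, which are not distinguished),
#' 1 turn a hairpin, 2 or more a chicane.  An end-to-end consistency flag
#' is attached: linear chains are expected to have `r_ee` above
#' `linear_frac` of the all-trans length, hairpins below `hairpin_frac`.
#'
#' @param conformation a `conformation`, or a dihedral vector with
#'   `topology` supplied.
#' @param topology a [chain_topology()] (when `conformation` is a bare
#'   dihedral vector).
#' @param segment_bonds bonds per direction segment.
#' @param persistence segments a new direction must persist to count.
#' @param linear_frac,hairpin_frac r_ee / all-trans thresholds for the
#'   consistency check.
#' @return character label with attributes `turns`, `r_ee` and
#'   `consistent` (logical or NA for chicane).
#' @export
classify_motif <- function(conformation, topology = NULL, segment_bonds = 3,
                           persistence = 2, linear_frac = 0.75,
                           hairpin_frac = 0.5) {
  if (!inherits(conformation, "conformation")) {
    stopifnot(inherits(topology, "chain_topology"))
    conformation <- build_cartesian(topology, conformation)
  }
  coords <- align_to_cavity(conformation$coords)   # principal axis -> z
  n <- nrow(coords)
  n_seg <- floor((n - 1) / segment_bonds)
  if (n_seg < 3)
    stop("chain too short: need at least 3 direction segments")
  starts <- seq(1, by = segment_bonds, length.out = n_seg)
  axial <- coords[starts + segment_bonds, 3] - coords[starts, 3]
  sgn <- sign(axial)
  sgn[sgn == 0] <- 1
  # run-length encode; absorb runs shorter than `persistence` into the
  # preceding direction, then count the surviving reversals
  rl <- rle(sgn)
  vals <- rl$values
  lens <- rl$lengths
  i <- 2
  while (i <= length(vals)) {
    if (lens[i] < persistence) {
      vals[i] <- vals[i - 1]
      rl2 <- rle(rep(vals, lens))
      vals <- rl2$values; lens <- rl2$lengths
      i <- 2
    } else i <- i + 1
  }
  turns <- max(length(vals) - 1, 0)
  label <- if (turns == 0) "linear" else if (turns == 1) "hairpin" else "chicane"
  ree <- end_to_end(conformation)
  at <- all_trans_length(conformation$topology)
  consistent <- switch(label,
    linear = ree > linear_frac * at,
    hairpin = ree < hairpin_frac * at,
    chicane = NA)
  structure(label, turns = turns, r_ee = ree, consistent = consistent)
}
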