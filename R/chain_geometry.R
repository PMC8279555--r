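#' Chain topology
#'
#' Describes the internal-coordinate geometry of an n-alkane backbone:
#' number of carbons, C-C bond length and C-C-C angle, and (optionally)
#' the C-H geometry used when hydrogens are materialised for volume
#' calculations.  A chain of `n_carbons` carbons has `n_carbons - 3`
#' backbone dihedrals.
#'
#' @param n_carbons number of backbone carbons (>= 2).
#' @param bond_length C-C bond length in Angstrom.
#' @param bond_angle C-C-C angle in degrees.
#' @param with_hydrogens if `TRUE`, [build_cartesian()] also places
#'   hydrogens at tetrahedral positions (needed only for van der Waals
#'   volumes).
#' @param ch_bond C-H bond length in Angstrom.
#' @return an object of class `chain_topology`.
#' @examples
#' top <- chain_topology(11)
#' all_trans_length(top)
#' @export
chain_topology <- function(n_carbons, bond_length = 1.53, bond_angle = 112.7,
                           with_hydrogens = FALSE, ch_bond = 1.09) {
  n_carbons <- as.integer(n_carbons)
  if (n_carbons < 2) stop("n_carbons must be >= 2")
  if (bond_length <= 0) stop("bond_length must be positive")
  if (bond_angle <= 0 || bond_angle >= 180) stop("bond_angle must be in (0, 180)")
  if (ch_bond <= 0) stop("ch_bond must be positive")
  structure(list(n_carbons = n_carbons, bond_length = bond_length,
                 bond_angle = bond_angle, with_hydrogens = isTRUE(with_hydrogens),
                 ch_bond = ch_bond, n_dihedrals = max(n_carbons - 3L, 0L)),
            class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf("chain_topology: C%d  (l = %.3f A, theta = %.2f deg, %d dihedrals%s)\n",
              x$n_carbons, x$bond_length, x$bond_angle, x$n_dihedrals,
              if (x$with_hydrogens) ", all-atom" else ""))
  invisible(x)
}

#' Van der Waals radii set
#'
#' Named element -> radius map used by [vdw_volume()].  The default is the
#' Bondi set for alkanes (C 1.70 A, H 1.20 A).
#'
#' @param radii named numeric vector of radii in Angstrom; all positive.
#' @return an object of class `radii_set`.
#' @export
radii_set <- function(radii = c(C = 1.70, H = 1.20)) {
  if (is.null(names(radii)) || any(!nzchar(names(radii))))
    stop("radii must be a named vector (element -> radius)")
  if (any(radii <= 0)) stop("all radii must be positive")
  structure(as.list(radii), class = "radii_set")
}

#' @rdname radii_set
#' @export
bondi_radii <- function() radii_set(c(C = 1.70, H = 1.20))

#' Build Cartesian coordinates from dihedrals
#'
#' Places the backbone carbons from internal coordinates (fixed bond
#' length, fixed bond angle, supplied dihedrals; IUPAC sign convention with
#' trans = 180 deg).  If the topology has `with_hydrogens = TRUE`,
#' hydrogens are added at tetrahedral positions (two per CH2, three per
#' terminal CH3).
#'
#' @param topology a [chain_topology()].
#' @param dihedrals numeric vector of `n_carbons - 3` angles in degrees on
#'   (-180, 180].
#' @return an object of class `conformation` with elements `topology`,
#'   `dihedrals`, `coords` (backbone n x 3 matrix) and, for all-atom
#'   topologies, `atoms` (data frame with `element`, `x`, `y`, `z`).
#' @examples
#' conf <- build_cartesian(chain_topology(11), rep(180, 8))
#' end_to_end(conf)
#' @export
build_cartesian <- function(topology, dihedrals = numeric(0)) {
  stopifnot(inherits(topology, "chain_topology"))
  dihedrals <- as.numeric(dihedrals)
  if (length(dihedrals) != topology$n_dihedrals)
    stop(sprintf("expected %d dihedrals for a C%d chain, got %d",
                 topology$n_dihedrals, topology$n_carbons, length(dihedrals)))
  dihedrals <- wrap_angle(dihedrals)
  coords <- build_chain_cpp(dihedrals, topology$n_carbons,
                            topology$bond_length, topology$bond_angle)
  conf <- structure(list(topology = topology, dihedrals = dihedrals,
                         coords = coords, atoms = NULL),
                    class = "conformation")
  if (topology$with_hydrogens) conf$atoms <- add_hydrogens(coords, topology)
  conf
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("conformation: C%d, r_ee = %.3f A, gauche fraction %.3f\n",
              x$topology$n_carbons, end_to_end(x),
              classify_dihedrals(x$dihedrals)$gauche_fraction))
  invisible(x)
}

# tetrahedral hydrogen placement on a backbone carbon skeleton; returns an
# all-atom data frame (element, x, y, z).  Methyl hydrogens are staggered
# with respect to the adjacent backbone bond.
add_hydrogens <- function(coords, topology) {
  n <- nrow(coords)
  lch <- topology$ch_bond
  tet <- 109.471220634491 * pi / 180
  rows <- list()
  rows[[1]] <- data.frame(element = rep("C", n), x = coords[, 1],
                          y = coords[, 2], z = coords[, 3])
  unitv <- function(v) v / sqrt(sum(v^2))
  for (i in seq_len(n)) {
    Ci <- coords[i, ]
    if (i > 1 && i < n) {                         # CH2
      u <- unitv(coords[i - 1, ] - Ci)
      v <- unitv(coords[i + 1, ] - Ci)
      bis <- unitv(-(u + v))
      nrm <- unitv(pracma_cross(u, v))
      half <- (107.8 / 2) * pi / 180              # H-C-H half angle
      h1 <- Ci + lch * (bis * cos(half) + nrm * sin(half))
      h2 <- Ci + lch * (bis * cos(half) - nrm * sin(half))
      rows[[length(rows) + 1L]] <- data.frame(element = c("H", "H"),
        x = c(h1[1], h2[1]), y = c(h1[2], h2[2]), z = c(h1[3], h2[3]))
    } else {                                      # terminal CH3
      j <- if (i == 1) 2L else n - 1L
      b <- unitv(coords[j, ] - Ci)                # towards bonded neighbour
      # reference perpendicular: use next-next backbone atom when available
      k <- if (i == 1) min(3L, n) else max(n - 2L, 1L)
      ref <- coords[k, ] - Ci
      e1 <- ref - sum(ref * b) * b
      if (sqrt(sum(e1^2)) < 1e-8) e1 <- pracma_cross(b, c(0, 0, 1))
      e1 <- unitv(e1)
      e2 <- unitv(pracma_cross(b, e1))
      for (ph in c(60, 180, 300) * pi / 180) {    # staggered methyl
        d <- b * cos(tet) + sin(tet) * (e1 * cos(ph) + e2 * sin(ph))
        h <- Ci + lch * d
        rows[[length(rows) + 1L]] <- data.frame(element = "H",
          x = h[1], y = h[2], z = h[3])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# 3-vector cross product (kept local; no dependency needed for one line)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Measure backbone dihedrals from coordinates
#'
#' @param coords n x 3 matrix of backbone positions (n >= 4).
#' @return dihedral angles in degrees on (-180, 180].
#' @export
measure_dihedrals <- function(coords) {
  coords <- as_coords(coords)
  measure_dihedrals_cpp(coords)
}

as_coords <- function(x) {
  if (inherits(x, "conformation")) return(x$coords)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3) stop("coordinates must be an n x 3 matrix")
  x
}

#' End-to-end distance
#'
#' Euclidean distance between the first and last backbone carbons.
#'
#' @param x a `conformation` or an n x 3 coordinate matrix (n >= 2).
#' @return distance in Angstrom.
#' @export
end_to_end <- function(x) {
  coords <- as_coords(x)
  if (nrow(coords) < 2) stop("need at least 2 backbone sites")
  sqrt(sum((coords[nrow(coords), ] - coords[1, ])^2))
}

#' All-trans end-to-end length (closed form)
#'
#' For `m = n_carbons - 1` bonds in a planar zigzag with bond length `l`
#' and bond angle `theta`, the terminal separation is `m * p` for even `m`
#' and `sqrt((m p)^2 + q^2)` for odd `m`, with `p = l sin(theta/2)` and
#' `q = l cos(theta/2)`.
#'
#' @param topology a [chain_topology()].
#' @return length in Angstrom.
#' @export
all_trans_length <- function(topology) {
  stopifnot(inherits(topology, "chain_topology"))
  m <- topology$n_carbons - 1L
  half <- topology$bond_angle / 2 * pi / 180
  p <- topology$bond_length * sin(half)
  q <- topology$bond_length * cos(half)
  if (m %% 2 == 0) m * p else sqrt((m * p)^2 + q^2)
}

#' Classify dihedrals into trans / gauche states
#'
#' trans (`t`) for |phi| >= 120 deg, `g+` for 0 <= phi < 120 (an exact 0
#' is labelled `g+` as the documented tie-break), `g-` for -120 < phi < 0.
#'
#' @param dihedrals angles in degrees on (-180, 180].
#' @return list with `labels` (character vector) and `gauche_fraction`.
#' @examples
#' classify_dihedrals(c(180, 60, -60, 170))$gauche_fraction  # 0.5
#' @export
classify_dihedrals <- function(dihedrals) {
  phi <- wrap_angle(as.numeric(dihedrals))
  labels <- ifelse(abs(phi) >= 120, "t", ifelse(phi >= 0, "g+", "g-"))
  list(labels = labels,
       gauche_fraction = if (length(phi)) mean(labels != "t") else 0)
}

#' Root-mean-square end-to-end distance
#'
#' Computes `sqrt(sum(w r^2) / sum(w))` over an ensemble.
#'
#' @param r_ee numeric vector of end-to-end distances, or a list of
#'   `conformation` objects.
#' @param weights nonnegative weights, not all zero (default uniform).
#' @return RMS distance in Angstrom.
#' @export
rms_end_to_end <- function(r_ee, weights = NULL) {
  if (is.list(r_ee)) r_ee <- vapply(r_ee, end_to_end, numeric(1))
  r_ee <- as.numeric(r_ee)
  if (is.null(weights)) weights <- rep(1, length(r_ee))
  if (length(weights) != length(r_ee)) stop("weights length mismatch")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) == 0) stop("weights must not all be zero")
  sqrt(sum(weights * r_ee^2) / sum(weights))
}

#' Union-of-spheres van der Waals volume by Monte Carlo integration
#'
#' Samples uniform points in the bounding box of the atomic spheres and
#' estimates the union volume from the hit fraction.  The standard error is
#' the binomial error of the hit fraction scaled by the box volume.
#'
#' @param atoms a `conformation` built with hydrogens, a data frame with
#'   columns `element`, `x`, `y`, `z`, or an n x 3 matrix (all carbon).
#' @param radii a [radii_set()]; default Bondi.
#' @param n_points number of Monte Carlo points (>= 1e5).
#' @param seed optional integer seed for reproducibility.
#' @return list with `volume`, `stderr` (both Angstrom^3), `n_points` and
#'   `box_volume`.
#' @examples
#' \donttest{
#' conf <- build_cartesian(chain_topology(20, with_hydrogens = TRUE), rep(180, 17))
#' vdw_volume(conf, n_points = 1e5, seed = 1)$volume  # ~350 A^3
#' }
#' @export
vdw_volume <- function(atoms, radii = bondi_radii(), n_points = 1e6,
                       seed = NULL) {
  stopifnot(inherits(radii, "radii_set"))
  if (inherits(atoms, "conformation")) {
    atoms <- if (!is.null(atoms$atoms)) atoms$atoms else atoms$coords
  }
  if (is.matrix(atoms)) {
    atoms <- data.frame(element = "C", x = atoms[, 1], y = atoms[, 2],
                        z = atoms[, 3])
  }
  if (nrow(atoms) == 0) stop("empty coordinates")
  if (n_points < 1e5) stop("n_points must be >= 1e5")
  missing_el <- setdiff(unique(atoms$element), names(radii))
  if (length(missing_el))
    stop("no radius for element(s): ", paste(missing_el, collapse = ", "))
  r <- unlist(radii)[atoms$element]
  centers <- as.matrix(atoms[, c("x", "y", "z")])
  storage.mode(centers) <- "double"
  lo <- apply(centers - r, 2, min)
  hi <- apply(centers + r, 2, max)
  box <- prod(hi - lo)
  if (!is.null(seed)) set.seed(seed)
  hits <- mc_volume_hits_cpp(centers, as.numeric(r), lo, hi,
                             as.integer(n_points))
  f <- hits / n_points
  list(volume = box * f,
       stderr = box * sqrt(f * (1 - f) / n_points),
       n_points = n_points, box_volume = box)
}

#' Packing fraction of a guest in a cavity
#'
#' @param guest_volume guest van der Waals volume in Angstrom^3 (a number
#'   or the result of [vdw_volume()]).
#' @param cavity_volume cavity interior volume in Angstrom^3; the default
#'   740 is the interior of the sealed octa-acid cavitand dimer.
#' @return dimensionless ratio.
#' @export
packing_fraction <- function(guest_volume, cavity_volume = 740) {
  if (is.list(guest_volume)) guest_volume <- guest_volume$volume
  if (!is.numeric(guest_volume) || guest_volume <= 0)
    stop("guest_volume must be positive")
  if (!is.numeric(cavity_volume) || cavity_volume <= 0)
    stop("cavity_volume must be positive")
  guest_volume / cavity_volume
}

#' Align coordinates to the cavity frame
#'
#' Centres the coordinates on their centroid and rotates the principal
#' gyration axis onto z (the cavity axis).  This is the placement the
#' sampler applies before evaluating the confinement term: the guest is
#' free to translate and orient inside the host, so the cavity is taken to
#' co-align with the guest's long axis.
#'
#' @param coords n x 3 matrix or `conformation`.
#' @return aligned n x 3 matrix.
#' @export
align_to_cavity <- function(coords) {
  align_principal_cpp(as_coords(coords))
}
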