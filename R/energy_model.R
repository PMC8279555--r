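#' Coarse-grained chain potential parameters
#'
#' One united-atom interaction site per carbon.  The torsion term is a
#' cosine polynomial `sum_k c_k cos^k(phi - 180)`; the default
#' coefficients are the classic Ryckaert-Bellemans butane constants, which
#' put the global minimum at trans (energy 0), the gauche states
#' 2.93 kJ/mol above trans and the trans-gauche barrier at 12.3 kJ/mol.
#' Nonbonded sites interact through a 12-6 Lennard-Jones potential with
#' pairs separated by `excl_depth` or fewer bonds excluded (no 1-4
#' scaling).
#'
#' @param torsion numeric length-6 coefficient vector c0..c5 in kJ/mol.
#' @param lj_epsilon Lennard-Jones well depth in kJ/mol.
#' @param lj_sigma Lennard-Jones diameter in Angstrom.
#' @param excl_depth bonded exclusion depth (>= 3): pairs separated by this
#'   many bonds or fewer are excluded from the LJ sum.
#' @return object of class `potential_params`.
#' @export
potential_params <- function(torsion = c(9.279, 12.156, -13.120, -3.060,
                                         26.240, -31.495),
                             lj_epsilon = 0.40, lj_sigma = 3.95,
                             excl_depth = 3L) {
  if (length(torsion) != 6) stop("torsion must have 6 coefficients c0..c5")
  if (lj_sigma <= 0) stop("lj_sigma must be positive")
  excl_depth <- as.integer(excl_depth)
  if (excl_depth < 3) stop("excl_depth must be >= 3")
  structure(list(torsion = as.numeric(torsion), lj_epsilon = lj_epsilon,
                 lj_sigma = lj_sigma, excl_depth = excl_depth),
            class = "potential_params")
}

#' Soft prolate-ellipsoid cavity wall
#'
#' Stand-in for the sealed cavitand dimer interior: a site at scaled
#' radius `s = sqrt((x^2 + y^2)/a^2 + z^2/c^2)` (axis along z, centred at
#' the origin) pays `k * max(0, s - 1)^2`.  Defaults give a pocket 8 A
#' across and a total interior length of 13 A.
#'
#' @param a radial semi-axis in Angstrom.
#' @param c axial semi-axis in Angstrom.
#' @param k wall stiffness in kJ/mol per squared reduced unit.
#' @return object of class `cavity_wall`.
#' @export
cavity_wall <- function(a = 4.0, c = 6.5, k = 50) {
  if (a <= 0 || c <= 0 || k <= 0) stop("a, c and k must be positive")
  structure(list(a = a, c = c, k = k), class = "cavity_wall")
}

#' Harmonic umbrella bias on the end-to-end distance
#'
#' @param k force constant in kJ/(mol Angstrom^2), >= 0.
#' @param r0 bias centre in Angstrom.
#' @return object of class `umbrella_bias`.
#' @export
umbrella_bias <- function(k = 50, r0) {
  if (k < 0) stop("force constant must be nonnegative")
  stopifnot(is.numeric(r0), length(r0) == 1)
  structure(list(k = k, r0 = r0), class = "umbrella_bias")
}

#' Torsion energy
#'
#' `U(phi) = sum_k c_k cos^k(phi - 180)`, periodic with period 360 deg and
#' (with default coefficients) minimum 0 at trans.
#'
#' @param phi dihedral angle(s) in degrees.
#' @param params a [potential_params()].
#' @return energy in kJ/mol (vectorised over `phi`).
#' @examples
#' p <- potential_params()
#' torsion_energy(180, p)                       # 0
#' torsion_energy(60, p) - torsion_energy(180, p)  # gauche penalty ~2.93
#' @export
torsion_energy <- function(phi, params = potential_params()) {
  stopifnot(inherits(params, "potential_params"))
  torsion_energy_cpp(as.numeric(phi), params$torsion)
}

#' Intramolecular Lennard-Jones energy
#'
#' Sum of `4 eps [(sigma/r)^12 - (sigma/r)^6]` over site pairs separated by
#' more than `excl_depth` bonds.
#'
#' @param coords n x 3 matrix or `conformation` (backbone sites).
#' @param params a [potential_params()].
#' @return energy in kJ/mol.
#' @export
intramolecular_lj <- function(coords, params = potential_params()) {
  stopifnot(inherits(params, "potential_params"))
  lj_energy_cpp(as_coords(coords), params$lj_epsilon, params$lj_sigma,
                params$excl_depth)
}

#' Confinement energy
#'
#' Evaluates the soft-wall penalty on the coordinates as given (wall axis
#' along z, centred at the origin); no alignment is applied.  Use
#' [align_to_cavity()] first to reproduce the sampler's placement.
#'
#' @param coords n x 3 matrix or `conformation`.
#' @param wall a [cavity_wall()].
#' @return energy in kJ/mol; exactly 0 when every site has `s <= 1`.
#' @export
confinement_energy <- function(coords, wall) {
  stopifnot(inherits(wall, "cavity_wall"))
  confinement_energy_cpp(as_coords(coords), wall$a, wall$c, wall$k)
}

#' Umbrella bias energy
#'
#' @param r_ee end-to-end distance(s) in Angstrom, >= 0.
#' @param bias an [umbrella_bias()].
#' @return `0.5 k (r_ee - r0)^2` in kJ/mol.
#' @export
bias_energy <- function(r_ee, bias) {
  stopifnot(inherits(bias, "umbrella_bias"))
  if (any(r_ee < 0)) stop("r_ee must be nonnegative")
  0.5 * bias$k * (r_ee - bias$r0)^2
}

#' Total chain energy
#'
#' Sum of the active terms: torsion, intramolecular Lennard-Jones,
#' confinement (on the cavity-aligned coordinates) and umbrella bias.
#' Omitting `wall` or `bias` equals passing a zero-strength version.
#'
#' @param conformation a `conformation`, or a numeric dihedral vector when
#'   `topology` is supplied.
#' @param params a [potential_params()].
#' @param wall optional [cavity_wall()].
#' @param bias optional [umbrella_bias()].
#' @param topology needed only when `conformation` is a bare dihedral
#'   vector.
#' @return energy in kJ/mol.
#' @export
total_energy <- function(conformation, params = potential_params(),
                         wall = NULL, bias = NULL, topology = NULL) {
  if (!inherits(conformation, "conformation")) {
    stopifnot(inherits(topology, "chain_topology"))
    conformation <- build_cartesian(topology, conformation)
  }
  top <- conformation$topology
  res <- chain_energy_cpp(conformation$dihedrals, top$n_carbons,
                          top$bond_length, top$bond_angle, params$torsion,
                          params$lj_epsilon, params$lj_sigma,
                          params$excl_depth, use_lj = TRUE,
                          use_wall = !is.null(wall),
                          wall_a = if (is.null(wall)) 1 else wall$a,
                          wall_c = if (is.null(wall)) 1 else wall$c,
                          wall_k = if (is.null(wall)) 0 else wall$k,
                          use_bias = !is.null(bias),
                          bias_k = if (is.null(bias)) 0 else bias$k,
                          bias_r0 = if (is.null(bias)) 0 else bias$r0)
  res$energy
}
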