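#' Rotational-isomeric-state chain model
#'
#' Discrete chain with dihedral states trans = 180, gauche+ = 60 and
#' gauche- = -60 deg.  Each gauche dihedral costs `eps_g`; adjacent
#' g+g- / g-g+ pairs (the pentane effect) cost an extra `eps_pent`.  With
#' `exclude_pentane = TRUE` such pairs are forbidden outright.  All `3^m`
#' states are enumerable, so every ensemble observable is exact.
#'
#' @param m number of dihedrals (1..12).
#' @param eps_g gauche penalty in kJ/mol.
#' @param eps_pent pentane-pair penalty in kJ/mol.
#' @param topology chain geometry; defaults to a C(m+3) chain with
#'   standard alkane geometry.
#' @param exclude_pentane forbid adjacent g+g-/g-g+ pairs entirely.
#' @return object of class `ris_model`.
#' @export
ris_model <- function(m, eps_g = 2.9, eps_pent = 8,
                      topology = chain_topology(m + 3),
                      exclude_pentane = FALSE) {
  m <- as.integer(m)
  if (m < 1 || m > 12) stop("m must be in 1..12 (3^m states are enumerated)")
  stopifnot(inherits(topology, "chain_topology"))
  if (topology$n_dihedrals != m) stop("topology must have m dihedrals")
  structure(list(m = m, eps_g = eps_g,
                 eps_pent = if (exclude_pentane) Inf else eps_pent,
                 topology = topology,
                 exclude_pentane = isTRUE(exclude_pentane)),
            class = "ris_model")
}

#' RIS state energies (exported for samplers and tests)
#'
#' @param states integer vector/matrix of states (0 = t, 1 = g+, 2 = g-).
#' @param model a [ris_model()].
#' @return energy (or vector of energies) in kJ/mol.
#' @export
ris_energy <- function(states, model) {
  stopifnot(inherits(model, "ris_model"))
  f <- function(st) {
    e <- model$eps_g * sum(st != 0)
    if (length(st) > 1) {
      a <- st[-length(st)]; b <- st[-1]
      np <- sum((a == 1 & b == 2) | (a == 2 & b == 1))
      if (np > 0) e <- e + model$eps_pent * np
    }
    e
  }
  if (is.matrix(states)) apply(states, 1, f) else f(as.integer(states))
}

#' Exact multi-temperature landscape by full RIS enumeration
#'
#' Enumerates all `3^m` states, Boltzmann-weights their end-to-end
#' distances into bins, and returns exact free-energy surfaces plus exact
#' trans fractions and RMS end-to-end distances at each temperature.
#'
#' @param model a [ris_model()].
#' @param temperatures temperatures in K.
#' @param breaks bin edges in Angstrom, or `NULL` to cover the chain with
#'   `bin_width` bins.
#' @param bin_width bin width when `breaks` is `NULL`.
#' @return object of class `exact_landscape`: `temperatures`, `breaks`,
#'   `mids`, `P` (T x bins, rows sum to 1), `G` (min-anchored per T),
#'   `G_raw` (`-kT ln P`, unanchored -- use this for temperature
#'   derivatives), `trans_fraction`, `rms_ree`, and the per-state tables
#'   in `states`.
#' @export
ris_enumerate <- function(model, temperatures = 298.15, breaks = NULL,
                          bin_width = 0.1) {
  stopifnot(inherits(model, "ris_model"))
  top <- model$topology
  eps_pent <- if (is.finite(model$eps_pent)) model$eps_pent else 1e9
  st <- ris_enumerate_cpp(model$m, top$bond_length, top$bond_angle,
                          model$eps_g, eps_pent)
  if (!is.finite(model$eps_pent)) st$energy[st$energy >= 1e9] <- Inf
  if (is.null(breaks)) {
    lo <- floor(min(st$r_ee) / bin_width) * bin_width - bin_width
    hi <- ceiling(max(st$r_ee) / bin_width) * bin_width + bin_width
    breaks <- seq(lo, hi, by = bin_width)
  }
  nb <- length(breaks) - 1
  w <- breaks[2] - breaks[1]
  bin <- pmin(pmax(floor((st$r_ee - breaks[1]) / w) + 1, 1), nb)
  temperatures <- as.numeric(temperatures)
  nt <- length(temperatures)
  P <- matrix(0, nt, nb)
  trans_fraction <- rms_ree <- numeric(nt)
  m <- model$m
  for (i in seq_len(nt)) {
    kt <- kT(temperatures[i])
    lw <- -st$energy / kt
    lw <- lw - max(lw)
    wts <- exp(lw)
    wts <- wts / sum(wts)
    agg <- rowsum(wts, bin)
    Pj <- numeric(nb)
    Pj[as.integer(rownames(agg))] <- agg
    P[i, ] <- Pj
    trans_fraction[i] <- sum(wts * (m - st$n_gauche) / m)
    rms_ree[i] <- sqrt(sum(wts * st$r_ee^2))
  }
  G_raw <- -outer(kT(temperatures), rep(1, nb)) * log(P)
  G_raw[!is.finite(G_raw)] <- NA_real_
  G <- G_raw - apply(G_raw, 1, min, na.rm = TRUE)
  structure(list(temperatures = temperatures, breaks = breaks,
                 mids = (head(breaks, -1) + tail(breaks, -1)) / 2,
                 P = P, G = G, G_raw = G_raw,
                 trans_fraction = trans_fraction, rms_ree = rms_ree,
                 states = st, model = model),
            class = "exact_landscape")
}

#' @export
print.exact_landscape <- function(x, ...) {
  cat(sprintf(
    "exact_landscape: RIS m = %d (%d states), %d temperature(s), %d bins\n",
    x$model$m, length(x$states$energy), length(x$temperatures),
    length(x$mids)))
  invisible(x)
}

#' Metropolis sampling of the RIS chain
#'
#' Discrete-state Metropolis MC on the [ris_model()], optionally under a
#' harmonic umbrella bias on the end-to-end distance.  Because the exact
#' distribution is available from [ris_enumerate()], this is the
#' sampler-validation workhorse.
#'
#' @param model a [ris_model()].
#' @param temperature temperature in K.
#' @param n_steps MC steps.
#' @param stride sampling stride.
#' @param bias optional [umbrella_bias()].
#' @param start integer start state (0 = t, 1 = g+, 2 = g-); default
#'   all-trans.
#' @param seed optional integer seed.
#' @param save_frames keep sampled state frames?
#' @return list with `r_ee`, `n_gauche`, `acceptance`, `final_state` and
#'   optionally `frames`.
#' @export
run_ris_mc <- function(model, temperature = 298.15, n_steps = 1e5,
                       stride = 1, bias = NULL, start = NULL, seed = NULL,
                       save_frames = FALSE) {
  stopifnot(inherits(model, "ris_model"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start)) start <- rep(0L, model$m)
  top <- model$topology
  eps_pent <- if (is.finite(model$eps_pent)) model$eps_pent else 1e9
  ris_mc_cpp(as.integer(start), top$bond_length, top$bond_angle, model$eps_g,
             eps_pent, temperature, as.integer(n_steps), as.integer(stride),
             save_frames, use_bias = !is.null(bias),
             bias_k = if (is.null(bias)) 0 else bias$k,
             bias_r0 = if (is.null(bias)) 0 else bias$r0)
}

#' Umbrella windows over the RIS chain
#'
#' Runs [run_ris_mc()] per window of the schedule and histograms r_ee on a
#' shared grid; the output feeds [wham_solve()] and can be checked bin by
#' bin against [ris_enumerate()].
#'
#' @param model a [ris_model()].
#' @param schedule a [window_schedule()].
#' @param temperature temperature in K.
#' @param stride sampling stride.
#' @param breaks optional explicit bin edges.
#' @param bin_width bin width when `breaks` is `NULL`.
#' @param seed optional integer seed.
#' @return a [biased_histogram_set()].
#' @export
run_ris_umbrella <- function(model, schedule, temperature = 298.15,
                             stride = 1, breaks = NULL, bin_width = 0.1,
                             seed = NULL) {
  stopifnot(inherits(model, "ris_model"), inherits(schedule, "window_schedule"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(breaks)) breaks <- .default_grid(schedule$centers, bin_width)
  nw <- length(schedule$centers)
  nb <- length(breaks) - 1
  counts <- matrix(0, nw, nb)
  rsums <- matrix(0, nw, nb)
  state <- rep(0L, model$m)
  for (w in order(schedule$centers, decreasing = TRUE)) {
    bias <- umbrella_bias(schedule$k, schedule$centers[w])
    if (schedule$equilibration > 0) {
      eq <- run_ris_mc(model, temperature, schedule$equilibration, stride = 0,
                       bias = bias, start = state)
      state <- eq$final_state
    }
    run <- run_ris_mc(model, temperature, schedule$production, stride = stride,
                      bias = bias, start = state)
    state <- run$final_state
    bs <- .bin_stats(run$r_ee, breaks)
    counts[w, ] <- bs$counts
    rsums[w, ] <- bs$sums
    if (sum(counts[w, ]) == 0)
      stop_numeric(sprintf("window %d (r0 = %.3f A) produced zero samples",
                           w, schedule$centers[w]))
  }
  tot <- colSums(counts)
  biased_histogram_set(counts, breaks, rep(schedule$k, nw), schedule$centers,
                       temperature, meta = list(seed = seed, model = "RIS"),
                       r_rep = ifelse(tot > 0, colSums(rsums) / tot, NA))
}

#' Analytic harmonic umbrella fixture
#'
#' Exact-sampling fixture for WHAM: the unbiased coordinate lives on the
#' quadratic PMF `0.5 kappa r^2`, so window `i` with bias
#' `0.5 k (r - r0_i)^2` samples a Gaussian with mean `r0_i k / (kappa + k)`
#' and variance `kT / (kappa + k)` -- drawn here directly with `rnorm`.
#' The true PMF is attached as attribute `"true_pmf"`.
#'
#' @param kappa curvature of the true PMF in kJ/(mol Angstrom^2), > 0.
#' @param centers window bias centres in Angstrom.
#' @param k bias force constant in kJ/(mol Angstrom^2).
#' @param temperature temperature in K.
#' @param n_per_window samples per window.
#' @param seed optional integer seed.
#' @param bin_width histogram bin width.
#' @return a [biased_histogram_set()] with attribute `true_pmf`
#'   (a function of r).
#' @export
harmonic_umbrella_fixture <- function(kappa, centers = seq(-3, 3, by = 0.5),
                                      k = 50, temperature = 298.15,
                                      n_per_window = 20000, seed = NULL,
                                      bin_width = 0.1) {
  if (kappa <= 0) stop("kappa must be positive")
  if (!is.null(seed)) set.seed(seed)
  kt <- kT(temperature)
  mean_i <- centers * k / (kappa + k)
  sd_i <- sqrt(kt / (kappa + k))
  lo <- floor((min(mean_i) - 5 * sd_i) / bin_width) * bin_width
  hi <- ceiling((max(mean_i) + 5 * sd_i) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  nb <- length(breaks) - 1
  counts <- matrix(0, length(centers), nb)
  rsums <- matrix(0, length(centers), nb)
  for (i in seq_along(centers)) {
    bs <- .bin_stats(rnorm(n_per_window, mean_i[i], sd_i), breaks)
    counts[i, ] <- bs$counts
    rsums[i, ] <- bs$sums
  }
  tot <- colSums(counts)
  out <- biased_histogram_set(counts, breaks, rep(k, length(centers)),
                              centers, temperature,
                              meta = list(seed = seed, kappa = kappa,
                                          n_per_window = n_per_window),
                              r_rep = ifelse(tot > 0, colSums(rsums) / tot, NA))
  attr(out, "true_pmf") <- function(r) 0.5 * kappa * r^2
  out
}

#' Two-cluster dihedral trajectory fixture
#'
#' Frames are drawn from a mixture of wrapped Gaussians around two
#' dihedral centres; the component labels are kept as attribute
#' `"labels"` for validation.
#'
#' @param m number of dihedrals.
#' @param centers 2 x m matrix (or list of two length-m vectors) of
#'   cluster centres in degrees.
#' @param spreads per-cluster angular standard deviations in degrees.
#' @param weights mixture weights, summing to 1.
#' @param n number of frames.
#' @param seed optional integer seed.
#' @return a [dihedral_trajectory()] with attribute `labels`.
#' @export
two_cluster_dihedral_fixture <- function(m, centers, spreads = c(10, 10),
                                         weights = c(0.5, 0.5), n = 1000,
                                         seed = NULL) {
  if (is.list(centers)) centers <- do.call(rbind, centers)
  centers <- as.matrix(centers)
  if (nrow(centers) != 2 || ncol(centers) != m)
    stop("centers must be 2 x m")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(2, n, replace = TRUE, prob = weights)
  ang <- matrix(0, n, m)
  for (f in seq_len(n))
    ang[f, ] <- wrap_angle(rnorm(m, centers[comp[f], ], spreads[comp[f]]))
  out <- dihedral_trajectory(ang)
  attr(out, "labels") <- comp
  out
}

#' Ready-to-run configuration for a confined-chain study
#'
#' Emits the complete configuration for the full pipeline (umbrella
#' sampler, WHAM, Gibbs-Helmholtz fit, DPCA) for one chain length inside
#' (or outside) the cavity.  Identical arguments give identical
#' configurations.
#'
#' @param n_carbons chain length (4..30).
#' @param cavity a [cavity_wall()] or `NULL` for a free chain.
#' @param schedule optional [window_schedule()]; the default spans contact
#'   (about 4 A) to beyond full extension in 0.5 A increments.
#' @param temperatures sampling temperatures in K (one for a plain run,
#'   a ladder for replica exchange).
#' @param seed global seed.
#' @return a `run_config` list with sections `chain`, `potential`,
#'   `cavity`, `umbrella`, `remd`, `wham`, `thermo`, `dpca`, `output` and
#'   a global `seed`.
#' @export
confined_chain_scenario <- function(n_carbons, cavity = cavity_wall(),
                                    schedule = NULL, temperatures = 298.15,
                                    seed = 1) {
  n_carbons <- as.integer(n_carbons)
  if (n_carbons < 4 || n_carbons > 30) stop("n_carbons must be in 4..30")
  top <- chain_topology(n_carbons)
  if (is.null(schedule)) {
    hi <- all_trans_length(top) + 0.6
    schedule <- window_schedule(seq(4, hi, by = 0.5))
  }
  cfg <- list(
    chain = list(n_carbons = n_carbons, bond_length = top$bond_length,
                 bond_angle = top$bond_angle),
    potential = unclass(potential_params()),
    cavity = if (is.null(cavity)) NULL else unclass(cavity),
    umbrella = list(centers = schedule$centers, k = schedule$k,
                    equilibration = schedule$equilibration,
                    production = schedule$production),
    remd = list(temperatures = as.numeric(temperatures),
                exchange_interval = 200L),
    wham = list(bin_width = 0.1, tolerance = 1e-6, max_iterations = 1e5),
    thermo = list(T0 = 298.15),
    dpca = list(bins = 50L, n_frames = 10000L),
    output = list(directory = "."),
    seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

.config_sections <- c("chain", "potential", "cavity", "umbrella", "remd",
                      "wham", "thermo", "dpca", "output", "seed")

#' Validate a run configuration
#'
#' Rejects unknown sections or unknown keys within a section.
#'
#' @param config a `run_config` (or plain list with the same sections).
#' @return the config, invisibly, on success.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), .config_sections)
  if (length(unknown))
    stop_usage("unknown config section(s): ", paste(unknown, collapse = ", "))
  known_keys <- list(
    chain = c("n_carbons", "bond_length", "bond_angle"),
    potential = c("torsion", "lj_epsilon", "lj_sigma", "excl_depth"),
    cavity = c("a", "c", "k"),
    umbrella = c("centers", "k", "equilibration", "production"),
    remd = c("temperatures", "exchange_interval"),
    wham = c("bin_width", "tolerance", "max_iterations"),
    thermo = c("T0"),
    dpca = c("bins", "n_frames"),
    output = c("directory"))
  for (s in intersect(names(config), names(known_keys))) {
    bad <- setdiff(names(config[[s]]), known_keys[[s]])
    if (length(bad))
      stop_usage(sprintf("unknown key(s) in [%s]: %s", s,
                         paste(bad, collapse = ", ")))
  }
  invisible(config)
}

#' Execute a run configuration
#'
#' Runs the umbrella sampler (with replica exchange when the config lists
#' several temperatures), solves WHAM per temperature, fits the
#' Gibbs-Helmholtz decomposition when three or more temperatures are
#' available, and extracts the dominant conformation of the window closest
#' to the primary PMF minimum by DPCA.  When `output_dir` is set, results
#' and the resolved configuration are written beside each other.
#'
#' @param config a `run_config` from [confined_chain_scenario()].
#' @param output_dir optional output directory.
#' @param mc an [mc_config()] carrying move parameters.
#' @return list with `histograms`, `pmf` (at the first temperature),
#'   `minima`, optionally `thermo`, and `dominant` (DPCA result).
#' @export
run_scenario <- function(config, output_dir = NULL, mc = mc_config()) {
  validate_config(config)
  set.seed(config$seed)
  top <- chain_topology(config$chain$n_carbons, config$chain$bond_length,
                        config$chain$bond_angle)
  params <- do.call(potential_params, config$potential)
  wall <- if (is.null(config$cavity)) NULL else do.call(cavity_wall, config$cavity)
  schedule <- window_schedule(config$umbrella$centers, config$umbrella$k,
                              config$umbrella$equilibration,
                              config$umbrella$production)
  temps <- config$remd$temperatures
  mc$seed <- NULL
  if (length(temps) >= 2) {
    remd <- remd_config(temps, config$remd$exchange_interval)
    res <- run_remd_umbrella(top, params, schedule, remd, mc, wall = wall,
                             bin_width = config$wham$bin_width)
    hists <- res$histograms
  } else {
    mc$temperature <- temps[1]
    hists <- list(run_umbrella_windows(top, params, schedule, mc, wall = wall,
                                       bin_width = config$wham$bin_width,
                                       save_dihedrals = FALSE))
  }
  pmfs <- lapply(hists, function(h)
    align_pmf(wham_solve(h, config$wham$tolerance,
                         config$wham$max_iterations)))
  out <- list(histograms = hists, pmf = pmfs[[1]],
              minima = find_minima(pmfs[[1]]))
  if (length(temps) >= 3)
    out$thermo <- decompose_pmf_pipeline(hists, T0 = config$thermo$T0,
                                         tolerance = config$wham$tolerance,
                                         max_iterations = config$wham$max_iterations)$profile
  # DPCA on the window nearest the primary minimum (first temperature)
  if (nrow(out$minima) > 0) {
    w <- which.min(abs(schedule$centers - out$minima$r[1]))
    mc1 <- mc
    mc1$temperature <- temps[1]
    run <- run_mc(top, params, within_steps(mc1, schedule$production), wall,
                  umbrella_bias(schedule$k, schedule$centers[w]),
                  equilibration = schedule$equilibration, save_frames = TRUE)
    traj <- dihedral_trajectory(run$frames)
    pca <- top2_pca(traj)
    dom <- dominant_conformation(pca, bins = config$dpca$bins)
    dom$motif <- classify_motif(dom$dihedrals, top)
    out$dominant <- dom
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(output_dir, "config.yml"))
    write_pmf(out$pmf, file.path(output_dir, "pmf.tsv"))
    for (i in seq_along(hists))
      write_histograms(hists[[i]],
                       file.path(output_dir, sprintf("histograms_T%03d.tsv", i)))
    if (!is.null(out$thermo))
      write_thermo(out$thermo, file.path(output_dir, "thermo.tsv"))
  }
  out
}

within_steps <- function(mc, n_steps) {
  mc$n_steps <- as.integer(n_steps)
  mc
}
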