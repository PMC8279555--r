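#' Monte Carlo sampler configuration
#'
#' Canonical Metropolis Monte Carlo in torsion space.  The move set mixes
#' single-dihedral perturbations of at most `max_step` degrees with
#' torsion-space pivots (one dihedral redrawn uniformly, rotating the whole
#' tail), chosen with probability `p_pivot`.
#'
#' @param temperature temperature in K.
#' @param n_steps production steps.
#' @param max_step maximum single-dihedral perturbation in degrees.
#' @param p_pivot probability of a pivot move.
#' @param stride sampling stride (one sample every `stride` steps).
#' @param seed optional integer seed.
#' @return object of class `mc_config`.
#' @export
mc_config <- function(temperature = 298.15, n_steps = 10000, max_step = 30,
                      p_pivot = 0.2, stride = 10, seed = NULL) {
  if (temperature <= 0) stop("temperature must be positive")
  if (n_steps <= 0) stop("n_steps must be positive")
  if (p_pivot < 0 || p_pivot > 1) stop("p_pivot must be in [0, 1]")
  structure(list(temperature = temperature, n_steps = as.integer(n_steps),
                 max_step = max_step, p_pivot = p_pivot,
                 stride = as.integer(stride), seed = seed),
            class = "mc_config")
}

#' Umbrella window schedule
#'
#' @param centers strictly increasing bias centres in Angstrom; typically
#'   evenly spaced in 0.5 A (single temperature) or 0.32 A (replica
#'   exchange) increments.
#' @param k umbrella force constant in kJ/(mol Angstrom^2).
#' @param equilibration per-window equilibration steps.
#' @param production per-window production steps.
#' @return object of class `window_schedule`.
#' @examples
#' window_schedule(seq(4, 14, by = 0.5))
#' @export
window_schedule <- function(centers, k = 50, equilibration = 2000,
                            production = 10000) {
  centers <- as.numeric(centers)
  if (length(centers) < 1) stop("need at least one window centre")
  if (length(centers) > 1 && any(diff(centers) <= 0))
    stop("window centres must be strictly increasing")
  if (k < 0) stop("force constant must be nonnegative")
  structure(list(centers = centers, k = k,
                 equilibration = as.integer(equilibration),
                 production = as.integer(production),
                 spacing = if (length(centers) > 1) diff(centers) else numeric(0)),
            class = "window_schedule")
}

#' Replica-exchange configuration
#'
#' @param temperatures strictly increasing ladder in K (>= 2 replicas);
#'   the default is the ten-temperature ladder used throughout the
#'   package, [remd_ladder()].
#' @param exchange_interval MC steps between exchange attempts.
#' @param seed optional integer seed.
#' @return object of class `remd_config`.
#' @export
remd_config <- function(temperatures = remd_ladder(),
                        exchange_interval = 200, seed = NULL) {
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 1) stop("need at least 1 replica")
  if (any(diff(temperatures) <= 0))
    stop("temperature ladder must be strictly increasing")
  # a single-temperature "ladder" degenerates to plain umbrella sampling;
  # exchanges require >= 2 replicas
  structure(list(temperatures = temperatures,
                 exchange_interval = as.integer(exchange_interval),
                 seed = seed),
            class = "remd_config")
}

#' Default replica-exchange temperature ladder
#'
#' Ten temperatures from 298.15 to 500 K spaced for roughly uniform
#' exchange acceptance.
#'
#' @return numeric vector of 10 temperatures in K.
#' @export
remd_ladder <- function() {
  c(298.15, 317.79, 338.46, 360.20, 383.13, 407.22, 432.55, 459.21,
    487.29, 500)
}

#' Metropolis acceptance
#'
#' @param delta_e energy change in kJ/mol.
#' @param beta inverse temperature 1/kT in mol/kJ.
#' @param u uniform variate on `[0, 1)`.
#' @return logical: accept the proposal?
#' @export
metropolis_accept <- function(delta_e, beta, u = runif(1)) {
  u < pmin(1, exp(-beta * delta_e))
}

#' Single Metropolis step
#'
#' Accepts the proposal with probability `min(1, exp(-beta dE))`; a
#' rejected proposal returns the prior state.
#'
#' @param current current state (any R object `energy` accepts).
#' @param proposal proposed state.
#' @param beta inverse temperature 1/kT in mol/kJ.
#' @param energy function mapping a state to its energy in kJ/mol.
#' @param u uniform variate on `[0, 1)`.
#' @return list with `state`, `energy` and logical `accepted`.
#' @export
metropolis_step <- function(current, proposal, beta, energy, u = runif(1)) {
  e0 <- energy(current)
  e1 <- energy(proposal)
  if (metropolis_accept(e1 - e0, beta, u)) {
    list(state = proposal, energy = e1, accepted = TRUE)
  } else {
    list(state = current, energy = e0, accepted = FALSE)
  }
}

#' Replica-exchange swap decision
#'
#' Accepts the swap with probability
#' `min(1, exp((beta_i - beta_j) (E_i - E_j)))`.
#'
#' @param e_i,e_j potential energies of the two replicas in kJ/mol.
#' @param beta_i,beta_j inverse temperatures in mol/kJ.
#' @param u uniform variate on `[0, 1)`.
#' @return logical: swap?
#' @export
remd_exchange_decision <- function(e_i, e_j, beta_i, beta_j, u = runif(1)) {
  u < min(1, exp((beta_i - beta_j) * (e_i - e_j)))
}

#' Run plain Metropolis Monte Carlo on a chain
#'
#' @param topology a [chain_topology()].
#' @param params a [potential_params()].
#' @param config an [mc_config()].
#' @param wall optional [cavity_wall()].
#' @param bias optional [umbrella_bias()].
#' @param start starting dihedrals (default all-trans).
#' @param equilibration discarded steps before production.
#' @param save_frames keep sampled dihedral frames?
#' @return list with `r_ee`, `energy`, `acceptance`, `final_dihedrals` and
#'   (optionally) `frames`.
#' @export
run_mc <- function(topology, params = potential_params(), config = mc_config(),
                   wall = NULL, bias = NULL, start = NULL,
                   equilibration = 0, save_frames = FALSE) {
  stopifnot(inherits(topology, "chain_topology"))
  if (is.null(start)) start <- rep(180, topology$n_dihedrals)
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- as.numeric(start)
  if (equilibration > 0) {
    eq <- .mc_chunk(state, topology, params, config, wall, bias,
                    n_steps = equilibration, stride = 0L, save_frames = FALSE)
    state <- eq$final_dihedrals
  }
  out <- .mc_chunk(state, topology, params, config, wall, bias,
                   n_steps = config$n_steps, stride = config$stride,
                   save_frames = save_frames)
  out
}

.mc_chunk <- function(start, topology, params, config, wall, bias, n_steps,
                      stride, save_frames) {
  mc_chain_cpp(as.numeric(start), topology$n_carbons, topology$bond_length,
               topology$bond_angle, params$torsion, params$lj_epsilon,
               params$lj_sigma, params$excl_depth, use_lj = TRUE,
               use_wall = !is.null(wall),
               wall_a = if (is.null(wall)) 1 else wall$a,
               wall_c = if (is.null(wall)) 1 else wall$c,
               wall_k = if (is.null(wall)) 0 else wall$k,
               use_bias = !is.null(bias),
               bias_k = if (is.null(bias)) 0 else bias$k,
               bias_r0 = if (is.null(bias)) 0 else bias$r0,
               temperature = config$temperature, n_steps = as.integer(n_steps),
               max_step = config$max_step, p_pivot = config$p_pivot,
               stride = as.integer(stride), save_frames = save_frames)
}

#' Biased histogram set
#'
#' Per-window counts of the end-to-end coordinate on a shared uniform bin
#' grid, with the bias parameters of every window.  This is the input
#' contract of [wham_solve()].
#'
#' @param counts windows x bins matrix of nonnegative counts.
#' @param breaks uniform bin edges (length bins + 1) in Angstrom.
#' @param bias_k per-window force constants in kJ/(mol Angstrom^2).
#' @param bias_r0 per-window bias centres in Angstrom.
#' @param temperature temperature in K.
#' @param meta optional list of provenance (seed, steps, ...).
#' @param r_rep optional representative coordinate per bin (defaults to
#'   the bin centres); samplers fill in the per-bin mean coordinate, which
#'   removes the bin-centre approximation in the WHAM bias energies.
#' @param bias_offset optional per-window additive constant on the bias
#'   potential in kJ/mol (physically irrelevant; the WHAM output is
#'   invariant to it).
#' @return object of class `biased_histogram_set`.
#' @export
biased_histogram_set <- function(counts, breaks, bias_k, bias_r0,
                                 temperature, meta = list(), r_rep = NULL,
                                 bias_offset = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  widths <- diff(breaks)
  if (any(abs(widths - widths[1]) > 1e-9 * widths[1]))
    stop("bins must be uniform")
  if (ncol(counts) != length(breaks) - 1)
    stop("counts columns must match bins")
  if (length(bias_k) != nrow(counts) || length(bias_r0) != nrow(counts))
    stop("one bias (k, r0) per window required")
  if (temperature <= 0) stop("temperature must be positive")
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  if (is.null(r_rep)) r_rep <- mids
  if (length(r_rep) != ncol(counts)) stop("one r_rep per bin required")
  r_rep <- ifelse(is.finite(r_rep), r_rep, mids)
  if (is.null(bias_offset)) bias_offset <- rep(0, nrow(counts))
  if (length(bias_offset) != nrow(counts))
    stop("one bias_offset per window required")
  structure(list(counts = counts, breaks = as.numeric(breaks),
                 mids = mids, r_rep = as.numeric(r_rep),
                 bias_offset = as.numeric(bias_offset),
                 N = rowSums(counts), bias_k = as.numeric(bias_k),
                 bias_r0 = as.numeric(bias_r0), temperature = temperature,
                 meta = meta),
            class = "biased_histogram_set")
}

#' @export
print.biased_histogram_set <- function(x, ...) {
  cat(sprintf(
    "biased_histogram_set: %d windows, %d bins on [%.2f, %.2f] A, T = %.2f K, %d samples\n",
    nrow(x$counts), ncol(x$counts), min(x$breaks), max(x$breaks),
    x$temperature, sum(x$N)))
  invisible(x)
}

# default shared grid: generous padding around the window centres
.default_grid <- function(centers, bin_width, pad = 2.5) {
  lo <- floor((min(centers) - pad) / bin_width) * bin_width
  hi <- ceiling((max(centers) + pad) / bin_width) * bin_width
  seq(lo, hi, by = bin_width)
}

.bin_counts <- function(x, breaks) {
  # drop samples outside the grid; uniform bins allow direct indexing
  w <- breaks[2] - breaks[1]
  idx <- floor((x - breaks[1]) / w) + 1
  idx <- idx[idx >= 1 & idx <= length(breaks) - 1]
  tabulate(idx, nbins = length(breaks) - 1)
}

# counts plus per-bin coordinate sums (for the representative-point grid)
.bin_stats <- function(x, breaks) {
  w <- breaks[2] - breaks[1]
  nb <- length(breaks) - 1
  idx <- floor((x - breaks[1]) / w) + 1
  keep <- idx >= 1 & idx <= nb
  idx <- idx[keep]
  sums <- numeric(nb)
  if (length(idx)) {
    agg <- rowsum(x[keep], idx)
    sums[as.integer(rownames(agg))] <- agg
  }
  list(counts = tabulate(idx, nbins = nb), sums = sums)
}

#' Run a series of umbrella windows
#'
#' Samples each window with Metropolis MC under its harmonic bias and
#' histograms the end-to-end distance on a shared grid.  Windows are
#' visited from the most extended centre downwards, each warm-started from
#' the final state of the previous one (the first starts all-trans).
#'
#' @param topology a [chain_topology()].
#' @param params a [potential_params()].
#' @param schedule a [window_schedule()].
#' @param mc an [mc_config()] (its `n_steps` is ignored; the schedule's
#'   per-window `equilibration`/`production` are used).
#' @param wall optional [cavity_wall()].
#' @param bin_width histogram bin width in Angstrom.
#' @param breaks optional explicit bin edges (overrides `bin_width`).
#' @param save_dihedrals `FALSE`, `TRUE` (all windows) or integer window
#'   indices: keep sampled dihedral frames for DPCA.
#' @return a [biased_histogram_set()]; when frames were kept, they are
#'   attached as attribute `"dihedral_frames"` (a list of
#'   [dihedral_trajectory()] keyed by window index).
#' @export
run_umbrella_windows <- function(topology, params = potential_params(),
                                 schedule, mc = mc_config(), wall = NULL,
                                 bin_width = 0.1, breaks = NULL,
                                 save_dihedrals = FALSE) {
  stopifnot(inherits(schedule, "window_schedule"))
  if (!is.null(mc$seed)) set.seed(mc$seed)
  if (is.null(breaks)) breaks <- .default_grid(schedule$centers, bin_width)
  nw <- length(schedule$centers)
  nb <- length(breaks) - 1
  counts <- matrix(0, nw, nb)
  rsums <- matrix(0, nw, nb)
  keep <- if (isTRUE(save_dihedrals)) seq_len(nw)
          else if (is.numeric(save_dihedrals)) as.integer(save_dihedrals)
          else integer(0)
  frames <- list()
  order_desc <- order(schedule$centers, decreasing = TRUE)
  state <- rep(180, topology$n_dihedrals)
  for (w in order_desc) {
    bias <- umbrella_bias(schedule$k, schedule$centers[w])
    if (schedule$equilibration > 0) {
      eq <- .mc_chunk(state, topology, params, mc, wall, bias,
                      schedule$equilibration, 0L, FALSE)
      state <- eq$final_dihedrals
    }
    run <- .mc_chunk(state, topology, params, mc, wall, bias,
                     schedule$production, mc$stride, w %in% keep)
    state <- run$final_dihedrals
    if (length(run$r_ee) == 0)
      stop_numeric(sprintf("window %d (r0 = %.3f A) produced zero samples",
                           w, schedule$centers[w]))
    bs <- .bin_stats(run$r_ee, breaks)
    counts[w, ] <- bs$counts
    rsums[w, ] <- bs$sums
    if (sum(counts[w, ]) == 0)
      stop_numeric(sprintf(
        "window %d (r0 = %.3f A): all samples fell outside the bin grid",
        w, schedule$centers[w]))
    if (w %in% keep)
      frames[[as.character(w)]] <- dihedral_trajectory(run$frames)
  }
  for (w in seq_len(nw - 1)) {
    if (!any(counts[w, ] > 0 & counts[w + 1, ] > 0))
      warning(sprintf("windows %d and %d share no occupied bins", w, w + 1))
  }
  tot <- colSums(counts)
  out <- biased_histogram_set(counts, breaks, rep(schedule$k, nw),
                              schedule$centers, mc$temperature,
                              meta = list(seed = mc$seed,
                                          equilibration = schedule$equilibration,
                                          production = schedule$production,
                                          stride = mc$stride),
                              r_rep = ifelse(tot > 0, colSums(rsums) / tot, NA))
  if (length(frames)) attr(out, "dihedral_frames") <- frames
  out
}

#' Umbrella sampling with replica exchange over a temperature ladder
#'
#' For each window, one replica runs at every ladder temperature under the
#' same bias; after every `exchange_interval` production steps a randomly
#' chosen adjacent temperature pair attempts a configuration swap with the
#' standard replica-exchange criterion on total potential energies.
#'
#' @inheritParams run_umbrella_windows
#' @param remd an [remd_config()].
#' @param mc an [mc_config()] supplying the move parameters and stride
#'   (its `temperature` and `n_steps` are ignored).
#' @return list with `histograms` (a [biased_histogram_set()] per ladder
#'   temperature, named by temperature), `swap_acceptance` and `swap_log`
#'   (data frame of attempts).
#' @export
run_remd_umbrella <- function(topology, params = potential_params(), schedule,
                              remd = remd_config(), mc = mc_config(),
                              wall = NULL, bin_width = 0.1, breaks = NULL) {
  stopifnot(inherits(schedule, "window_schedule"),
            inherits(remd, "remd_config"))
  if (!is.null(remd$seed)) set.seed(remd$seed)
  if (is.null(breaks)) breaks <- .default_grid(schedule$centers, bin_width)
  temps <- remd$temperatures
  nt <- length(temps)
  nw <- length(schedule$centers)
  nb <- length(breaks) - 1
  counts <- lapply(seq_len(nt), function(i) matrix(0, nw, nb))
  rsums <- lapply(seq_len(nt), function(i) matrix(0, nw, nb))
  betas <- 1 / (.kB * temps)
  log_rows <- list()
  n_attempt <- 0L
  n_swap <- 0L
  order_desc <- order(schedule$centers, decreasing = TRUE)
  states <- lapply(seq_len(nt), function(i) rep(180, topology$n_dihedrals))
  for (w in order_desc) {
    bias <- umbrella_bias(schedule$k, schedule$centers[w])
    cfgs <- lapply(temps, function(tt) {
      c0 <- mc; c0$temperature <- tt; c0
    })
    for (i in seq_len(nt)) {
      if (schedule$equilibration > 0) {
        eq <- .mc_chunk(states[[i]], topology, params, cfgs[[i]], wall, bias,
                        schedule$equilibration, 0L, FALSE)
        states[[i]] <- eq$final_dihedrals
      }
    }
    samples <- lapply(seq_len(nt), function(i) numeric(0))
    energies <- numeric(nt)
    remaining <- schedule$production
    while (remaining > 0) {
      chunk <- min(remd$exchange_interval, remaining)
      for (i in seq_len(nt)) {
        run <- .mc_chunk(states[[i]], topology, params, cfgs[[i]], wall, bias,
                         chunk, mc$stride, FALSE)
        states[[i]] <- run$final_dihedrals
        energies[i] <- run$final_energy
        samples[[i]] <- c(samples[[i]], run$r_ee)
      }
      remaining <- remaining - chunk
      if (remaining > 0 && nt >= 2) {
        i <- sample.int(nt - 1, 1)
        ok <- remd_exchange_decision(energies[i], energies[i + 1],
                                     betas[i], betas[i + 1])
        n_attempt <- n_attempt + 1L
        if (ok) {
          tmp <- states[[i]]; states[[i]] <- states[[i + 1]]; states[[i + 1]] <- tmp
          n_swap <- n_swap + 1L
        }
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(window = w, pair_low = i, accepted = ok)
      }
    }
    for (i in seq_len(nt)) {
      if (length(samples[[i]]) == 0)
        stop_numeric(sprintf("window %d at T = %.2f K produced zero samples",
                             w, temps[i]))
      bs <- .bin_stats(samples[[i]], breaks)
      counts[[i]][w, ] <- bs$counts
      rsums[[i]][w, ] <- bs$sums
      if (sum(counts[[i]][w, ]) == 0)
        stop_numeric(sprintf(
          "window %d at T = %.2f K: all samples outside the bin grid",
          w, temps[i]))
    }
  }
  hists <- lapply(seq_len(nt), function(i) {
    tot <- colSums(counts[[i]])
    biased_histogram_set(counts[[i]], breaks, rep(schedule$k, nw),
                         schedule$centers, temps[i],
                         meta = list(seed = remd$seed, ladder = temps,
                                     production = schedule$production),
                         r_rep = ifelse(tot > 0, colSums(rsums[[i]]) / tot, NA))
  })
  names(hists) <- format(temps)
  list(histograms = hists,
       swap_acceptance = if (n_attempt > 0) n_swap / n_attempt else NA_real_,
       swap_log = if (length(log_rows)) do.call(rbind, log_rows)
                  else data.frame(window = integer(), pair_low = integer(),
                                  accepted = logical()))
}
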