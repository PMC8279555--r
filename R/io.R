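# File formats.  Every tabular file carries a "# key: value" metadata
# header so it is self-describing; floats are written with 17 significant
# digits so write -> read is an identity to better than 1e-12 relative.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_meta <- function(con, meta) {
  for (key in names(meta)) {
    val <- meta[[key]]
    if (is.null(val)) next
    writeLines(sprintf("# %s: %s", key,
                       paste(fmt_char(val), collapse = " ")), con)
  }
}

fmt_char <- function(v) if (is.numeric(v)) fmt_num(v) else as.character(v)

.read_meta <- function(lines) {
  hdr <- grep("^#", lines)
  meta <- list()
  for (i in hdr) {
    mm <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(mm) != 3)
      stop(sprintf("malformed metadata header at line %d: '%s'", i, lines[i]))
    meta[[trimws(mm[2])]] <- trimws(mm[3])
  }
  meta
}

.meta_num <- function(meta, key, default = NA_real_) {
  if (is.null(meta[[key]])) return(default)
  suppressWarnings(as.numeric(strsplit(meta[[key]], "\\s+")[[1]]))
}

#' Write / read XYZ trajectories
#'
#' Standard XYZ: atom count line, comment line, then `element x y z` per
#' site; frames are concatenated for trajectories.
#'
#' @param x a `conformation`, an n x 3 matrix, a data frame with columns
#'   `element`, `x`, `y`, `z`, or a list of any of these (one per frame).
#' @param path file path.
#' @param comment comment line (recycled over frames).
#' @return `write_xyz` returns the path invisibly; `read_xyz` returns a
#'   list of data frames (`element`, `x`, `y`, `z`), one per frame.
#' @export
write_xyz <- function(x, path, comment = "chainpmf") {
  frames <- if (is.list(x) && !is.data.frame(x) && !inherits(x, "conformation"))
    x else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    if (inherits(fr, "conformation"))
      fr <- if (!is.null(fr$atoms)) fr$atoms else fr$coords
    if (is.matrix(fr))
      fr <- data.frame(element = "C", x = fr[, 1], y = fr[, 2], z = fr[, 3])
    writeLines(as.character(nrow(fr)), con)
    writeLines(comment[1], con)
    writeLines(sprintf("%s %s %s %s", fr$element, fmt_num(fr$x),
                       fmt_num(fr$y), fmt_num(fr$z)), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("malformed XYZ atom count at line %d", i))
    if (i + 1 + n > length(lines))
      stop(sprintf("truncated XYZ frame starting at line %d", i))
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad))
      stop(sprintf("malformed XYZ coordinate at line %d", i + 1 + bad[1]))
    frames[[length(frames) + 1L]] <- data.frame(
      element = vapply(parts, `[`, character(1), 1),
      x = as.numeric(vapply(parts, `[`, character(1), 2)),
      y = as.numeric(vapply(parts, `[`, character(1), 3)),
      z = as.numeric(vapply(parts, `[`, character(1), 4)))
    i <- i + 2 + n
  }
  frames
}

#' Write / read biased histogram sets as TSV
#'
#' Columns `window_index`, `bias_center_A`, `bias_k`, `bin_left_A`,
#' `bin_right_A`, `count` under a metadata header (temperature, seed,
#' steps).  Row order is immaterial on read.
#'
#' @param hist a [biased_histogram_set()].
#' @param path file path.
#' @return `write_histograms` returns the path invisibly;
#'   `read_histograms` a [biased_histogram_set()].
#' @export
write_histograms <- function(hist, path) {
  stopifnot(inherits(hist, "biased_histogram_set"))
  con <- file(path, "w")
  on.exit(close(con))
  .write_meta(con, c(list(temperature = hist$temperature,
                          grid_lo = hist$breaks[1],
                          grid_hi = hist$breaks[length(hist$breaks)],
                          grid_bins = ncol(hist$counts)), hist$meta))
  writeLines(paste(c("window_index", "bias_center_A", "bias_k", "bin_left_A",
                     "bin_right_A", "count", "bin_r_mean"), collapse = "\t"),
             con)
  for (w in seq_len(nrow(hist$counts))) {
    keep <- which(hist$counts[w, ] > 0)
    if (!length(keep)) keep <- 1L   # keep the window visible even if empty
    writeLines(paste(w, fmt_num(hist$bias_r0[w]), fmt_num(hist$bias_k[w]),
                     fmt_num(hist$breaks[keep]), fmt_num(hist$breaks[keep + 1]),
                     fmt_num(hist$counts[w, keep]),
                     fmt_num(hist$r_rep[keep]), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_histograms
#' @export
read_histograms <- function(path) {
  lines <- readLines(path)
  meta <- .read_meta(lines)
  if (is.null(meta$temperature))
    stop("histogram TSV is missing the 'temperature' metadata header")
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = paste(body, collapse = "\n"), header = TRUE,
                   sep = "\t")
  if (!is.null(meta$grid_lo)) {
    lo <- .meta_num(meta, "grid_lo")
    hi <- .meta_num(meta, "grid_hi")
    nb <- as.integer(.meta_num(meta, "grid_bins"))
  } else {
    w0 <- stats::median(df$bin_right_A - df$bin_left_A)
    lo <- min(df$bin_left_A)
    hi <- max(df$bin_right_A)
    nb <- round((hi - lo) / w0)
  }
  w <- (hi - lo) / nb
  breaks <- seq(lo, hi, length.out = nb + 1)
  wins <- sort(unique(df$window_index))
  counts <- matrix(0, length(wins), nb)
  r_rep <- rep(NA_real_, nb)
  k <- r0 <- numeric(length(wins))
  for (i in seq_along(wins)) {
    sub <- df[df$window_index == wins[i], ]
    k[i] <- sub$bias_k[1]
    r0[i] <- sub$bias_center_A[1]
    idx <- round((sub$bin_left_A - lo) / w) + 1
    counts[i, idx] <- sub$count
    if (!is.null(sub$bin_r_mean)) r_rep[idx] <- sub$bin_r_mean
  }
  drop_keys <- c("temperature", "grid_lo", "grid_hi", "grid_bins")
  biased_histogram_set(counts, breaks, k, r0,
                       temperature = .meta_num(meta, "temperature"),
                       meta = meta[setdiff(names(meta), drop_keys)],
                       r_rep = r_rep)
}

#' Write / read PMF profiles as TSV
#'
#' Columns `r_A`, `G_kJmol` and (when present) `stderr_kJmol`, under a
#' metadata header (temperature, n_windows, tolerance, iterations).
#'
#' @param profile a [pmf_profile()].
#' @param path file path.
#' @return `write_pmf` returns the path invisibly; `read_pmf` a
#'   [pmf_profile()].
#' @export
write_pmf <- function(profile, path) {
  stopifnot(inherits(profile, "pmf_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  .write_meta(con, list(temperature = profile$temperature,
                        n_windows = length(profile$F),
                        iterations = profile$iterations,
                        max_dF = profile$max_dF))
  has_se <- !is.null(profile$stderr)
  hdr <- c("r_A", "G_kJmol", if (has_se) "stderr_kJmol")
  writeLines(paste(hdr, collapse = "\t"), con)
  if (has_se) {
    writeLines(paste(fmt_num(profile$r), fmt_num(profile$G),
                     fmt_num(profile$stderr), sep = "\t"), con)
  } else {
    writeLines(paste(fmt_num(profile$r), fmt_num(profile$G), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  lines <- readLines(path)
  meta <- .read_meta(lines)
  if (is.null(meta$temperature))
    stop("PMF TSV is missing the 'temperature' metadata header")
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = paste(body, collapse = "\n"), header = TRUE,
                   sep = "\t")
  pmf_profile(df$r_A, df$G_kJmol, temperature = .meta_num(meta, "temperature"),
              iterations = .meta_num(meta, "iterations", 0),
              max_dF = .meta_num(meta, "max_dF"),
              stderr = df$stderr_kJmol)
}

#' Write / read thermodynamic profiles as TSV
#'
#' Columns `r_A`, `G_kJmol`, `H_kJmol`, `minus_TS_kJmol`, `A`, `B`, `C`,
#' `residual_rms` under a metadata header (`T0`).
#'
#' @param profile a [thermo_profile()].
#' @param path file path.
#' @return `write_thermo` returns the path invisibly; `read_thermo` a
#'   [thermo_profile()].
#' @export
write_thermo <- function(profile, path) {
  stopifnot(inherits(profile, "thermo_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  .write_meta(con, list(T0 = profile$T0))
  writeLines(paste(c("r_A", "G_kJmol", "H_kJmol", "minus_TS_kJmol", "A", "B",
                     "C", "residual_rms"), collapse = "\t"), con)
  rr <- if (is.null(profile$residual_rms)) rep(NA_real_, length(profile$r))
        else profile$residual_rms
  writeLines(paste(fmt_num(profile$r), fmt_num(profile$G), fmt_num(profile$H),
                   fmt_num(profile$minus_TS), fmt_num(profile$A),
                   fmt_num(profile$B), fmt_num(profile$C), fmt_num(rr),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_thermo
#' @export
read_thermo <- function(path) {
  lines <- readLines(path)
  meta <- .read_meta(lines)
  if (is.null(meta$T0))
    stop("thermo TSV is missing the 'T0' metadata header")
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = paste(body, collapse = "\n"), header = TRUE,
                   sep = "\t")
  thermo_profile(df$r_A, df$A, df$B, df$C, T0 = .meta_num(meta, "T0"),
                 residual_rms = df$residual_rms)
}

#' Write / read dihedral trajectories as CSV
#'
#' Columns `frame`, `phi1` .. `phim`.
#'
#' @param trajectory a [dihedral_trajectory()].
#' @param path file path.
#' @return `write_dihedral_csv` returns the path invisibly;
#'   `read_dihedral_csv` a [dihedral_trajectory()].
#' @export
write_dihedral_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "dihedral_trajectory"))
  m <- ncol(trajectory$angles)
  df <- data.frame(frame = seq_len(nrow(trajectory$angles)))
  for (j in seq_len(m)) df[[paste0("phi", j)]] <- fmt_num(trajectory$angles[, j])
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dihedral_csv
#' @export
read_dihedral_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",")
  phi_cols <- grep("^phi", names(df), value = TRUE)
  if (!length(phi_cols)) stop("no phi columns found in dihedral CSV")
  dihedral_trajectory(as.matrix(df[, phi_cols, drop = FALSE]))
}

#' Write / read run configurations (YAML)
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `write_config` returns the path invisibly; `read_config` a
#'   validated `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- structure(cfg, class = "run_config")
  validate_config(cfg)
  cfg
}
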