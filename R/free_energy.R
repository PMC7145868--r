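# Boltzmann constant in kJ/mol/K; energies are kJ/mol throughout.
KB_KJ_MOL_K <- 0.0083144621

#' Construct an umbrella window
#'
#' @param center restraint target, nm.
#' @param force_constant harmonic force constant, kJ/mol/nm^2 (> 0).
#' @param samples reaction-coordinate samples, nm.
#' @param times optional sample times, ps.
#' @return object of class `mt_window`.
#' @export
mt_window <- function(center, force_constant, samples, times = NULL) {
  if (force_constant <= 0) stop("force constant must be positive")
  if (length(samples) < 1) stop("window needs at least one sample")
  if (any(!is.finite(samples))) stop("window samples must be finite")
  structure(list(center = as.numeric(center),
                 force_constant = as.numeric(force_constant),
                 samples = as.numeric(samples),
                 times = if (is.null(times)) NULL else as.numeric(times)),
            class = "mt_window")
}

#' Construct an umbrella window set
#'
#' @param windows list of [mt_window()]s; centres must be strictly
#'   increasing (the list is sorted by centre).
#' @param temperature simulation temperature, K.
#' @return object of class `mt_window_set`.
#' @export
mt_window_set <- function(windows, temperature = 303) {
  if (length(windows) < 1) stop("need at least one window")
  ctr <- vapply(windows, `[[`, numeric(1), "center")
  windows <- windows[order(ctr)]
  ctr <- sort(ctr)
  if (any(diff(ctr) <= 0)) stop("window centres must be strictly increasing")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(windows = windows, temperature = as.numeric(temperature)),
            class = "mt_window_set")
}

#' @export
print.mt_window_set <- function(x, ...) {
  ctr <- vapply(x$windows, `[[`, numeric(1), "center")
  ns <- vapply(x$windows, function(w) length(w$samples), numeric(1))
  cat(sprintf("<mt_window_set> %d windows, centres %.3f..%.3f nm, %g-%g samples each, T = %g K\n",
              length(x$windows), min(ctr), max(ctr), min(ns), max(ns),
              x$temperature))
  invisible(x)
}

#' Reaction coordinate: COM-COM distance between two groups
#'
#' Distance between the centres of mass of two selections (e.g. the EcfT
#' subunit and the bottom of the S-component), minimum image applied to the
#' COM difference. Groups are assumed whole (unwrapped).
#'
#' @param frame an [mt_frame()].
#' @param ecf_t_sel,s_bottom_sel the two selections.
#' @param masses optional mass table, see [center_of_mass()].
#' @return distance in nm.
#' @export
reaction_coordinate <- function(frame, ecf_t_sel, s_bottom_sel, masses = NULL) {
  a <- center_of_mass(frame, ecf_t_sel, masses)
  b <- center_of_mass(frame, s_bottom_sel, masses)
  minimum_image_distance(a, b, frame$box)
}

#' Validate an umbrella window set
#'
#' Reports per-window sample counts, mean-vs-centre deviations and
#' adjacent-window histogram overlaps; errors if any adjacent pair shares
#' no occupied bin (WHAM would be disconnected there).
#'
#' @param ws an [mt_window_set()].
#' @param bin_width histogram bin width, nm.
#' @return object of class `mt_window_report`: list with `windows` (data
#'   frame) and `overlaps` (shared occupied bins per adjacent pair).
#' @export
validate_windows <- function(ws, bin_width = 0.02) {
  W <- length(ws$windows)
  df <- data.frame(
    center = vapply(ws$windows, `[[`, numeric(1), "center"),
    force_constant = vapply(ws$windows, `[[`, numeric(1), "force_constant"),
    n = vapply(ws$windows, function(w) length(w$samples), numeric(1)),
    mean = vapply(ws$windows, function(w) mean(w$samples), numeric(1)),
    sd = vapply(ws$windows, function(w)
      if (length(w$samples) > 1) stats::sd(w$samples) else 0, numeric(1)))
  df$deviation <- df$mean - df$center
  if (W == 1) {
    warning("single umbrella window: the PMF shape is restraint-dominated")
    return(structure(list(windows = df, overlaps = numeric(0)),
                     class = "mt_window_report"))
  }
  edges <- wham_bin_edges(ws, bin_width)
  occ <- lapply(ws$windows, function(w)
    unique(findInterval(w$samples, edges, rightmost.closed = TRUE)))
  overlaps <- vapply(seq_len(W - 1), function(i)
    length(intersect(occ[[i]], occ[[i + 1]])), numeric(1))
  if (any(overlaps == 0)) {
    i <- which(overlaps == 0)[1]
    stop(sprintf("windows %d (centre %.3f) and %d (centre %.3f) share no occupied bins",
                 i, df$center[i], i + 1, df$center[i + 1]))
  }
  structure(list(windows = df, overlaps = overlaps), class = "mt_window_report")
}

#' @export
print.mt_window_report <- function(x, ...) {
  cat(sprintf("<mt_window_report> %d windows; max |mean-centre| = %.3f nm; min adjacent overlap = %s bins\n",
              nrow(x$windows), max(abs(x$windows$deviation)),
              if (length(x$overlaps)) min(x$overlaps) else "NA"))
  invisible(x)
}

wham_bin_edges <- function(ws, bin_width) {
  all_s <- unlist(lapply(ws$windows, `[[`, "samples"))
  lo <- floor(min(all_s) / bin_width) * bin_width
  hi <- ceiling(max(all_s) / bin_width) * bin_width
  seq(lo, hi + bin_width / 2, by = bin_width)
}

wham_histograms <- function(ws, edges) {
  nb <- length(edges) - 1
  matrix(vapply(ws$windows, function(w) {
    idx <- findInterval(w$samples, edges, rightmost.closed = TRUE)
    tabulate(idx, nbins = nb)
  }, numeric(nb)), nrow = length(ws$windows), ncol = nb, byrow = TRUE)
}

# Core self-consistent WHAM solve on pre-binned counts.
# H: W x J counts, centers: bin centres, ci/Ki: window parameters.
# Returns list(g, p, iterations, converged, residual); g = f_i / kT.
wham_core <- function(H, centers, ci, Ki, kT, tol, max_iter,
                      g_init = NULL, accelerate = TRUE) {
  W <- nrow(H); J <- ncol(H)
  n_i <- rowSums(H); N_j <- colSums(H)
  # log-bias matrix, W x J
  logB <- -0.5 * outer(Ki, rep(1, J)) * (outer(ci, centers, "-")^2) / kT
  B <- exp(logB)
  g <- if (is.null(g_init)) numeric(W) else g_init
  occ <- N_j > 0
  if (accelerate) {
    # convex log-likelihood in the reduced offsets; gradient is the WHAM
    # stationarity condition, so the minimiser is the WHAM fixed point
    obj <- function(g) {
      w <- n_i * exp(g)
      denom <- as.vector(t(B) %*% w)
      sum(N_j[occ] * log(denom[occ])) - sum(n_i * g)
    }
    grad <- function(g) {
      w <- n_i * exp(g)
      denom <- as.vector(t(B) %*% w)
      p <- ifelse(occ, N_j / denom, 0)
      w * as.vector(B %*% p) - n_i
    }
    opt <- stats::optim(g, obj, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    g <- opt$par - opt$par[1]
  }
  it <- 0L; resid <- Inf
  repeat {
    w <- n_i * exp(g)
    denom <- as.vector(t(B) %*% w)
    p <- ifelse(occ, N_j / denom, 0)
    p <- p / sum(p)
    Z <- as.vector(B %*% p)
    g_new <- -log(Z)
    g_new <- g_new - g_new[1]
    resid <- max(abs(g_new - g)) * kT
    g <- g_new
    it <- it + 1L
    if (resid < tol) break
    if (it >= max_iter)
      return(list(g = g, p = p, iterations = it, converged = FALSE,
                  residual = resid))
  }
  w <- n_i * exp(g)
  denom <- as.vector(t(B) %*% w)
  p <- ifelse(occ, N_j / denom, 0)
  p <- p / sum(p)
  list(g = g, p = p, iterations = it, converged = TRUE, residual = resid)
}

#' Weighted histogram analysis method (WHAM)
#'
#' Self-consistent solution of the WHAM equations for the unbiased
#' probability p(x) and per-window free-energy offsets f_i under harmonic
#' biases U_i(x) = K/2 (x - c_i)^2. The solve minimises the convex WHAM
#' log-likelihood (BFGS) and then polishes with the standard fixed-point
#' iteration until max |delta f_i| < `tol`; plain fixed-point iteration
#' (`accelerate = FALSE`) reaches the same fixed point. The free energy is
#' -kT ln p(x), anchored to zero at the profile minimum by default. Bins
#' inside the sampled range that received no samples are carried as NA.
#'
#' @param ws an [mt_window_set()].
#' @param bin_width histogram bin width, nm.
#' @param tol convergence tolerance on the window offsets, kJ/mol.
#' @param max_iter maximum fixed-point iterations.
#' @param anchor `"min"` (default), `"left"` or `"right"`: where the
#'   profile is set to zero.
#' @param radial_correction if TRUE, add the 2 kT ln(x) Jacobian correction
#'   for a radial distance coordinate (off by default).
#' @param accelerate use the convex-objective acceleration before the
#'   fixed-point polish.
#' @param g_init optional warm start for the reduced offsets f_i/kT.
#' @return object of class `mt_pmf` with `bin_centers` (nm), `free_energy`
#'   (kJ/mol), `errors` (NA until [bootstrap_pmf()]), `n_samples` per bin,
#'   `window_offsets` (f_i, kJ/mol), `temperature`, `iterations`.
#' @export
wham <- function(ws, bin_width = 0.02, tol = 1e-7, max_iter = 1e6,
                 anchor = c("min", "left", "right"),
                 radial_correction = FALSE, accelerate = TRUE, g_init = NULL) {
  anchor <- match.arg(anchor)
  invisible(validate_windows(ws, bin_width))
  kT <- KB_KJ_MOL_K * ws$temperature
  edges <- wham_bin_edges(ws, bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  H <- wham_histograms(ws, edges)
  ci <- vapply(ws$windows, `[[`, numeric(1), "center")
  Ki <- vapply(ws$windows, `[[`, numeric(1), "force_constant")
  sol <- wham_core(H, centers, ci, Ki, kT, tol, max_iter, g_init, accelerate)
  if (!sol$converged)
    stop(sprintf("WHAM did not converge in %d iterations (last residual %.3g kJ/mol)",
                 as.integer(max_iter), sol$residual))
  F <- ifelse(sol$p > 0, -kT * log(sol$p), NA_real_)
  if (radial_correction) F <- F + 2 * kT * log(centers)
  F <- anchor_profile(F, anchor)
  structure(list(bin_centers = centers, free_energy = F,
                 errors = rep(NA_real_, length(F)),
                 n_samples = colSums(H),
                 window_offsets = kT * sol$g,
                 reference = which.min(replace(F, is.na(F), Inf)),
                 temperature = ws$temperature, bin_width = bin_width,
                 anchor = anchor, iterations = sol$iterations,
                 bin_edges = edges),
            class = "mt_pmf")
}

anchor_profile <- function(F, anchor) {
  fin <- which(is.finite(F))
  ref <- switch(anchor, min = fin[which.min(F[fin])],
                left = fin[1], right = fin[length(fin)])
  F - F[ref]
}

#' @export
print.mt_pmf <- function(x, ...) {
  fin <- is.finite(x$free_energy)
  cat(sprintf("<mt_pmf> %d bins over %.3f..%.3f nm (width %.3g nm), T = %g K\n",
              length(x$bin_centers), min(x$bin_centers), max(x$bin_centers),
              x$bin_width, x$temperature))
  cat(sprintf("  free energy range %.2f..%.2f kJ/mol (anchored at %s); %d iterations\n",
              min(x$free_energy[fin]), max(x$free_energy[fin]), x$anchor,
              x$iterations))
  if (any(is.finite(x$errors)))
    cat(sprintf("  bootstrap errors: median %.3f kJ/mol\n",
                stats::median(x$errors[is.finite(x$errors)])))
  invisible(x)
}

#' @export
plot.mt_pmf <- function(x, ...) {
  graphics::plot(x$bin_centers, x$free_energy, type = "l",
                 xlab = "reaction coordinate (nm)",
                 ylab = "free energy (kJ/mol)", ...)
  if (any(is.finite(x$errors))) {
    ok <- is.finite(x$errors) & is.finite(x$free_energy)
    graphics::arrows(x$bin_centers[ok], x$free_energy[ok] - x$errors[ok],
                     x$bin_centers[ok], x$free_energy[ok] + x$errors[ok],
                     angle = 90, code = 3, length = 0.02)
  }
  invisible(x)
}

# Integrated autocorrelation time of a series (sum of acf until first
# non-positive lag), used to set the moving-block length.
integrated_act <- function(x) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(1)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  neg <- which(ac <= 0)
  if (length(neg)) ac <- ac[seq_len(neg[1] - 1)]
  max(1, 1 + 2 * sum(ac))
}

moving_block_resample <- function(x, block) {
  n <- length(x)
  block <- min(max(1L, as.integer(ceiling(block))), n)
  nb <- ceiling(n / block)
  starts <- sample.int(n - block + 1L, nb, replace = TRUE)
  out <- unlist(lapply(starts, function(s) x[s:(s + block - 1L)]))
  out[seq_len(n)]
}

#' Bootstrap errors for a WHAM profile
#'
#' Moving-block bootstrap: each window's sample series is resampled with
#' replacement in contiguous blocks (block length from the integrated
#' autocorrelation time of that window, minimum 1 — equal to 1 for
#' independent samples), WHAM is re-solved per replicate (warm-started from
#' the full-set offsets), and the per-bin standard deviation of the
#' anchored free energies is attached to the profile. Deterministic for a
#' fixed seed. Non-convergent replicates are dropped; more than 10 percent
#' dropped is an error.
#'
#' @param ws an [mt_window_set()].
#' @param profile the full-set [wham()] result for `ws` (recomputed when NULL).
#' @param n_boot number of bootstrap replicates.
#' @param block block length, or `"auto"` for the autocorrelation estimate.
#' @param seed RNG seed.
#' @param bin_width,tol,max_iter,anchor,radial_correction as in [wham()].
#' @return the `mt_pmf` with `errors` filled (bootstrap SD, kJ/mol) and
#'   attributes `block_lengths` and `n_dropped`.
#' @export
bootstrap_pmf <- function(ws, profile = NULL, n_boot = 200, block = "auto",
                          seed = 1, bin_width = 0.02, tol = 1e-7,
                          max_iter = 1e6, anchor = "min",
                          radial_correction = FALSE) {
  if (is.null(profile))
    profile <- wham(ws, bin_width, tol, max_iter, anchor, radial_correction)
  set.seed(seed)
  kT <- KB_KJ_MOL_K * ws$temperature
  edges <- profile$bin_edges
  centers <- profile$bin_centers
  ci <- vapply(ws$windows, `[[`, numeric(1), "center")
  Ki <- vapply(ws$windows, `[[`, numeric(1), "force_constant")
  g_full <- profile$window_offsets / kT
  blocks <- vapply(ws$windows, function(w) {
    if (identical(block, "auto")) integrated_act(w$samples) else as.numeric(block)
  }, numeric(1))
  boots <- matrix(NA_real_, n_boot, length(centers))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    H <- matrix(vapply(seq_along(ws$windows), function(i) {
      s <- moving_block_resample(ws$windows[[i]]$samples, blocks[i])
      tabulate(findInterval(s, edges, rightmost.closed = TRUE),
               nbins = length(centers))
    }, numeric(length(centers))), nrow = length(ws$windows),
    ncol = length(centers), byrow = TRUE)
    sol <- wham_core(H, centers, ci, Ki, kT, tol, max_iter, g_init = g_full)
    if (!sol$converged) { dropped <- dropped + 1L; next }
    F <- ifelse(sol$p > 0, -kT * log(sol$p), NA_real_)
    if (radial_correction) F <- F + 2 * kT * log(centers)
    boots[b, ] <- anchor_profile(F, profile$anchor)
  }
  if (dropped > 0.1 * n_boot)
    stop(dropped, " of ", n_boot, " bootstrap replicates failed to converge")
  errors <- apply(boots, 2, stats::sd, na.rm = TRUE)
  profile$errors <- errors
  attr(profile, "block_lengths") <- blocks
  attr(profile, "n_dropped") <- dropped
  attr(profile, "n_boot") <- n_boot
  profile
}

#' Write an umbrella window to a two-column file
#'
#' File dialect: a metadata header line
#' `# umbrella_window center=<nm> force_constant=<kJ/mol/nm^2>` followed by
#' whitespace rows `time coordinate`.
#'
#' @param window an [mt_window()].
#' @param path output path.
#' @export
write_window <- function(window, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# umbrella_window center=%.6g force_constant=%.6g",
                     window$center, window$force_constant), con)
  tm <- if (is.null(window$times)) seq_along(window$samples) else window$times
  writeLines(sprintf("%.6g %.8g", tm, window$samples), con)
  invisible(path)
}

#' Read an umbrella window file
#' @param path window file in the [write_window()] dialect.
#' @return an [mt_window()].
#' @export
read_window <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*umbrella_window", lines, value = TRUE)
  if (length(hdr) == 0)
    stop("window file ", path, " lacks the '# umbrella_window' metadata header")
  get_meta <- function(key) {
    m <- regmatches(hdr[1], regexec(paste0(key, "=([-0-9.eE+]+)"), hdr[1]))[[1]]
    if (length(m) < 2) stop("window header lacks ", key, " in ", path)
    as.numeric(m[2])
  }
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- matrix(suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+")))),
              ncol = 2, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric sample row in ", path)
  mt_window(get_meta("center"), get_meta("force_constant"),
            samples = m[, 2], times = m[, 1])
}

#' Read an umbrella window set from a manifest
#'
#' The manifest is a TSV with a `path` column (window files, relative to
#' the manifest location); optional `center` and `force_constant` columns
#' override the file headers.
#'
#' @param manifest_path manifest TSV.
#' @param temperature temperature, K.
#' @return an [mt_window_set()].
#' @export
read_windows <- function(manifest_path, temperature = 303) {
  man <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!"path" %in% names(man)) stop("manifest needs a 'path' column")
  base <- dirname(manifest_path)
  windows <- lapply(seq_len(nrow(man)), function(i) {
    w <- read_window(file.path(base, man$path[i]))
    if ("center" %in% names(man)) w$center <- man$center[i]
    if ("force_constant" %in% names(man)) w$force_constant <- man$force_constant[i]
    w
  })
  mt_window_set(windows, temperature)
}

#' Write an umbrella window set (files plus manifest)
#' @param ws an [mt_window_set()].
#' @param dir output directory (created if missing).
#' @return path of the manifest file.
#' @export
write_windows <- function(ws, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sprintf("window_%03d.dat", seq_along(ws$windows))
  for (i in seq_along(ws$windows))
    write_window(ws$windows[[i]], file.path(dir, paths[i]))
  man <- file.path(dir, "manifest.tsv")
  utils::write.table(data.frame(path = paths), man, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(man)
}

#' Write a PMF profile as TSV
#' @param profile an `mt_pmf`.
#' @param path output path.
#' @export
write_pmf <- function(profile, path) {
  con <- file(path, "w")
  writeLines(c("# potential of mean force: bin_center (nm), free_energy (kJ/mol), error (kJ/mol, bootstrap SD), n_samples",
               sprintf("# temperature_K=%g bin_width_nm=%g anchor=%s",
                       profile$temperature, profile$bin_width, profile$anchor)),
             con)
  utils::write.table(data.frame(bin_center = profile$bin_centers,
                                free_energy = profile$free_energy,
                                error = profile$errors,
                                n_samples = profile$n_samples),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
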