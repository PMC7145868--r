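#' Tilt-angle series for one replica
#'
#' @param times numeric vector of times (ps), strictly increasing.
#' @param angles numeric vector of tilt angles (degrees) in \[0, 180\].
#' @param replica_id replica label.
#' @return object of class `mt_tilt_series`.
#' @export
mt_tilt_series <- function(times, angles, replica_id = "replica") {
  if (length(times) != length(angles)) stop("times and angles differ in length")
  if (length(times) == 0) stop("empty tilt series")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(angles < 0 | angles > 180)) stop("angles must lie in [0, 180] degrees")
  structure(list(replica_id = replica_id, times = as.numeric(times),
                 angles = as.numeric(angles)), class = "mt_tilt_series")
}

#' @export
print.mt_tilt_series <- function(x, ...) {
  cat(sprintf("<mt_tilt_series> '%s': %d frames, angle %.1f-%.1f deg\n",
              x$replica_id, length(x$times), min(x$angles), max(x$angles)))
  invisible(x)
}

#' Principal axis of a helix selection
#'
#' Returns the unit principal axis (largest-variance direction) of the
#' selected particles, sign-oriented from the centroid of the N-terminal
#' half (first half in residue order) toward the centroid of the C-terminal
#' half, so that tilt angles beyond 90 degrees are meaningful. The
#' `endpoints` method instead uses the vector between the two half
#' centroids directly.
#'
#' @param frame an [mt_frame()].
#' @param helix_sel selection of the helix backbone particles (>= 3).
#' @param method `"principal"` (default) or `"endpoints"`.
#' @return unit length-3 vector.
#' @export
helix_axis <- function(frame, helix_sel, method = c("principal", "endpoints")) {
  method <- match.arg(method)
  rows <- sel_rows(frame, helix_sel)
  if (length(rows) < 3) stop("helix selection needs at least 3 particles")
  a <- frame$atoms[rows, ]
  a <- a[order(a$resid, a$index), ]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  nh <- floor(nrow(xyz) / 2)
  ref <- colMeans(xyz[(nrow(xyz) - nh + 1):nrow(xyz), , drop = FALSE]) -
    colMeans(xyz[1:nh, , drop = FALSE])
  if (method == "endpoints") {
    nr <- sqrt(sum(ref^2))
    if (nr < 1e-12) stop("degenerate helix selection: coincident half centroids")
    return(ref / nr)
  }
  cv <- stats::cov(xyz)
  if (sum(diag(cv)) < 1e-20) stop("degenerate helix selection: zero-variance cloud")
  eg <- eigen(cv, symmetric = TRUE)
  ax <- eg$vectors[, 1]
  if (sum(ax * ref) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Tilt angle between an axis and the bilayer normal
#'
#' Angle in degrees between two vectors, in \[0, 180\] (not folded to
#' \[0, 90\]: an inverted helix reads 180).
#'
#' @param axis length-3 vector (need not be unit).
#' @param normal bilayer normal; defaults to the laboratory +z axis.
#' @return angle in degrees.
#' @export
tilt_angle <- function(axis, normal = c(0, 0, 1)) {
  na <- sqrt(sum(axis^2)); nn <- sqrt(sum(normal^2))
  if (na < 1e-12 || nn < 1e-12) stop("zero vector has no direction")
  cosv <- sum(axis * normal) / (na * nn)
  cosv <- min(1, max(-1, cosv))
  acos(cosv) * 180 / pi
}

#' Classify a tilt angle as toppled
#'
#' The toppled orientation is defined by helix 5 lying roughly in the
#' membrane plane: tilt angle between 75 and 125 degrees, bounds inclusive.
#'
#' @param angle tilt angle(s), degrees in \[0, 180\].
#' @param band lower/upper band edges, degrees.
#' @return logical vector.
#' @export
classify_toppled <- function(angle, band = c(75, 125)) {
  if (any(angle < 0 | angle > 180)) stop("angles must lie in [0, 180]")
  angle >= band[1] & angle <= band[2]
}

#' Per-replica toppled-state stability
#'
#' A replica counts as a stable toppled orientation when it spends strictly
#' more than `threshold` (default 50 percent) of its frames in the toppled
#' band.
#'
#' @param series an [mt_tilt_series()].
#' @param band toppled band, degrees.
#' @param threshold stability threshold on the toppled time fraction.
#' @return list with `toppled_fraction` and logical `is_stable_toppled`.
#' @export
replica_stability <- function(series, band = c(75, 125), threshold = 0.5) {
  if (!inherits(series, "mt_tilt_series")) stop("series must be an mt_tilt_series")
  frac <- mean(classify_toppled(series$angles, band))
  list(toppled_fraction = frac, is_stable_toppled = frac > threshold)
}

#' Replica-stability summary for one condition
#'
#' Aggregates [replica_stability()] over replicas of one membrane/protein
#' condition and attaches a binomial standard deviation on the stable
#' fraction, sd = sqrt(p(1-p)/n) with p the stable fraction (multiply by n
#' for the count scale).
#'
#' @param replicas list of [mt_tilt_series()].
#' @param label condition label.
#' @param band,threshold passed to [replica_stability()].
#' @param sd_scale `"fraction"` (default) or `"count"`.
#' @return object of class `mt_stability` with fields `condition_label`,
#'   `n_replicas`, `n_stable`, `stable_fraction`, `sd`,
#'   `per_replica_toppled_fraction`.
#' @export
stability_summary <- function(replicas, label = "condition", band = c(75, 125),
                              threshold = 0.5, sd_scale = c("fraction", "count")) {
  sd_scale <- match.arg(sd_scale)
  if (length(replicas) < 1) stop("need at least one replica")
  st <- lapply(replicas, replica_stability, band = band, threshold = threshold)
  fracs <- vapply(st, `[[`, numeric(1), "toppled_fraction")
  stable <- vapply(st, `[[`, logical(1), "is_stable_toppled")
  n <- length(replicas)
  p <- mean(stable)
  sd <- sqrt(p * (1 - p) / n)
  if (sd_scale == "count") sd <- sd * n
  structure(list(condition_label = label, n_replicas = n, n_stable = sum(stable),
                 stable_fraction = p, sd = sd, sd_scale = sd_scale,
                 per_replica_toppled_fraction = unname(fracs)),
            class = "mt_stability")
}

#' @export
print.mt_stability <- function(x, ...) {
  cat(sprintf("<mt_stability> '%s': %d/%d replicas stable toppled (fraction %.3f, binomial sd %.3f on %s scale)\n",
              x$condition_label, x$n_stable, x$n_replicas, x$stable_fraction,
              x$sd, x$sd_scale))
  invisible(x)
}

#' Tilt-angle series from a trajectory
#'
#' @param frames list of [mt_frame()]s.
#' @param helix_sel helix selection.
#' @param normal bilayer normal (default +z).
#' @param method axis method, see [helix_axis()].
#' @param replica_id label for the series.
#' @return an [mt_tilt_series()].
#' @export
tilt_series <- function(frames, helix_sel, normal = c(0, 0, 1),
                        method = "principal", replica_id = "replica") {
  if (length(frames) == 0) stop("no frames")
  ang <- vapply(frames, function(fr)
    tilt_angle(helix_axis(fr, helix_sel, method), normal), numeric(1))
  tms <- vapply(frames, `[[`, numeric(1), "time")
  if (any(diff(tms) <= 0)) tms <- seq_along(frames)
  mt_tilt_series(tms, ang, replica_id)
}

#' Tilt angle binned along a reaction coordinate
#'
#' Mean and standard deviation of the helix tilt angle in bins of a
#' reaction coordinate (for tilt-vs-separation profiles along a
#' dissociation pathway). Bins with no frames are reported as NA, never 0.
#'
#' @param angles tilt angles per frame, degrees.
#' @param rc reaction-coordinate value per frame, nm.
#' @param breaks bin edges, nm.
#' @return data frame with `bin_lo`, `bin_hi`, `bin_center`, `mean_angle`,
#'   `sd_angle`, `n`.
#' @export
tilt_vs_coordinate <- function(angles, rc, breaks) {
  if (length(angles) != length(rc)) stop("angles and rc differ in length")
  bin <- cut(rc, breaks = breaks, include.lowest = TRUE)
  if (all(is.na(bin))) stop("no frames fall inside the bins")
  nb <- length(breaks) - 1
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1])
  out$bin_center <- (out$bin_lo + out$bin_hi) / 2
  out$mean_angle <- NA_real_; out$sd_angle <- NA_real_; out$n <- 0L
  for (b in seq_len(nb)) {
    in_b <- !is.na(bin) & as.integer(bin) == b
    n <- sum(in_b)
    out$n[b] <- n
    if (n > 0) {
      out$mean_angle[b] <- mean(angles[in_b])
      out$sd_angle[b] <- if (n > 1) stats::sd(angles[in_b]) else 0
    }
  }
  out
}
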