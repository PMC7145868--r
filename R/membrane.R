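# Bivariate monomial basis of total degree <= degree: columns x^i * y^j.
poly_exponents <- function(degree = 4) {
  ex <- NULL
  for (d in 0:degree) for (i in d:0) ex <- rbind(ex, c(i, d - i))
  colnames(ex) <- c("i", "j")
  ex
}

poly_design <- function(x, y, exponents) {
  X <- matrix(0, length(x), nrow(exponents))
  for (k in seq_len(nrow(exponents)))
    X[, k] <- x^exponents[k, 1] * y^exponents[k, 2]
  X
}

#' Assign lipids to leaflets
#'
#' The bilayer midplane is the median z of all phosphate beads; each lipid
#' goes to the upper or lower leaflet by the sign of its (phosphate-bead
#' averaged) z relative to the midplane. Lipids whose averaged phosphate z
#' lies within `dead_zone` of the midplane are excluded. Cardiolipin's two
#' phosphates are averaged so the molecule is assigned once.
#'
#' @param frame an [mt_frame()].
#' @param topo an [mt_topology()].
#' @param dead_zone half-width of the midplane exclusion zone, nm.
#' @return object of class `mt_leaflets`: data frame (`resid`, `lipid_type`,
#'   `z`, `leaflet` in upper/lower/excluded) with attribute `midplane_z`.
#' @export
assign_leaflets <- function(frame, topo, dead_zone = 0.5) {
  pb <- lipid_bead_rows(frame, topo, "phosphate")
  if (nrow(pb) == 0)
    stop("no phosphate beads matched the topology map (types: ",
         paste(topo$lipid_type, collapse = ", "), ")")
  z <- frame$atoms$z[pb$row]
  # midplane: overall mean refined once to the midpoint of the two sides
  # (a plain bead-level median lands inside a leaflet whenever bead counts
  # are unbalanced, e.g. through two-phosphate cardiolipin)
  mid <- mean(z)
  if (any(z > mid) && any(z <= mid))
    mid <- (mean(z[z > mid]) + mean(z[z <= mid])) / 2
  per <- stats::aggregate(list(z = z), by = list(resid = pb$resid), FUN = mean)
  per$lipid_type <- pb$lipid_type[match(per$resid, pb$resid)]
  dz <- per$z - mid
  per$leaflet <- ifelse(abs(dz) <= dead_zone, "excluded",
                        ifelse(dz > 0, "upper", "lower"))
  attr(per, "midplane_z") <- mid
  class(per) <- c("mt_leaflets", "data.frame")
  per
}

#' Fit a polynomial surface to one leaflet
#'
#' Least-squares fit of z(x, y) to phosphate-bead positions over the full
#' bivariate monomial basis of total degree 4 (15 terms), the surface model
#' used for thickness and curvature maps. The `radial4` basis restricts to
#' radially symmetric terms 1, r^2, r^4 (coefficients are still stored on
#' the bivariate basis).
#'
#' @param points data frame or matrix with columns/cols x, y, z (nm),
#'   pre-centered on the analysis patch (e.g. the protein centre of mass).
#' @param degree total polynomial degree (default 4).
#' @param basis `"bivariate4"` or `"radial4"`.
#' @param leaflet optional leaflet label carried through.
#' @return object of class `mt_surface_fit` with `coefficients` (named by
#'   monomial), `exponents`, `fit_rms` (nm), `domain` (x/y ranges), `n_points`.
#' @export
fit_leaflet_surface <- function(points, degree = 4,
                                basis = c("bivariate4", "radial4"),
                                leaflet = NA_character_) {
  basis <- match.arg(basis)
  pts <- as.data.frame(points)
  if (!all(c("x", "y", "z") %in% names(pts))) {
    pts <- as.data.frame(as.matrix(points))
    names(pts)[1:3] <- c("x", "y", "z")
  }
  ex <- poly_exponents(degree)
  if (basis == "radial4") {
    if (degree != 4) stop("radial4 basis is defined for degree 4")
    need <- 3
  } else need <- nrow(ex)
  if (nrow(pts) < need)
    stop("need at least ", need, " points for the ", basis,
         " basis, got ", nrow(pts), "; enlarge the patch")
  if (basis == "bivariate4" || basis != "radial4") {
    X <- poly_design(pts$x, pts$y, ex)
  }
  if (basis == "radial4") {
    u <- pts$x^2 + pts$y^2
    Xr <- cbind(1, u, u^2)
    qrX <- qr(Xr)
    if (qrX$rank < ncol(Xr))
      stop("rank-deficient surface fit design; use a larger patch with more spread")
    cr <- qr.coef(qrX, pts$z)
    co <- stats::setNames(numeric(nrow(ex)),
                          paste0("x", ex[, 1], "y", ex[, 2]))
    co["x0y0"] <- cr[1]
    co["x2y0"] <- co["x0y2"] <- cr[2]
    co["x4y0"] <- co["x0y4"] <- cr[3]
    co["x2y2"] <- 2 * cr[3]
    resid <- pts$z - as.vector(Xr %*% cr)
  } else {
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop("rank-deficient surface fit design (collinear points?); use a larger patch")
    co <- qr.coef(qrX, pts$z)
    names(co) <- paste0("x", ex[, 1], "y", ex[, 2])
    resid <- pts$z - as.vector(X %*% co)
  }
  structure(list(coefficients = co, exponents = ex, degree = degree,
                 basis = basis, leaflet = leaflet,
                 fit_rms = sqrt(mean(resid^2)),
                 domain = list(x = range(pts$x), y = range(pts$y)),
                 n_points = nrow(pts)),
            class = "mt_surface_fit")
}

#' @export
print.mt_surface_fit <- function(x, ...) {
  cat(sprintf("<mt_surface_fit> degree-%d %s surface%s: %d points, rms %.4f nm\n",
              x$degree, x$basis,
              if (is.na(x$leaflet)) "" else paste0(" (", x$leaflet, " leaflet)"),
              x$n_points, x$fit_rms))
  invisible(x)
}

#' Evaluate a fitted surface
#' @param object an `mt_surface_fit`.
#' @param x,y coordinates (nm), recycled together.
#' @param ... unused.
#' @return surface height z (nm).
#' @export
predict.mt_surface_fit <- function(object, x, y, ...) {
  as.vector(poly_design(x, y, object$exponents) %*% object$coefficients)
}

# Analytic value and partial derivatives of the fitted polynomial.
surface_derivs <- function(fit, x, y) {
  ex <- fit$exponents; co <- fit$coefficients
  dmat <- function(di, dj) {
    v <- numeric(length(x))
    for (k in seq_len(nrow(ex))) {
      i <- ex[k, 1]; j <- ex[k, 2]
      if (i < di || j < dj || co[k] == 0) next
      fac <- prod(seq(i, by = -1, length.out = di)) *
             prod(seq(j, by = -1, length.out = dj))
      v <- v + co[k] * fac * x^(i - di) * y^(j - dj)
    }
    v
  }
  list(z = dmat(0, 0), zx = dmat(1, 0), zy = dmat(0, 1),
       zxx = dmat(2, 0), zxy = dmat(1, 1), zyy = dmat(0, 2))
}

# Mean curvature of a Monge patch z(x, y) from analytic derivatives.
monge_mean_curvature <- function(d) {
  ((1 + d$zy^2) * d$zxx - 2 * d$zx * d$zy * d$zxy + (1 + d$zx^2) * d$zyy) /
    (2 * (1 + d$zx^2 + d$zy^2)^1.5)
}

#' Construct a 2-D analysis grid
#' @param half_width patch half-width, nm (patch spans \[-hw, hw\] in x and y).
#' @param spacing grid cell edge, nm.
#' @return list with `x_edges`, `y_edges`, `x_centers`, `y_centers`.
#' @export
mt_grid <- function(half_width = 4, spacing = 0.2) {
  e <- seq(-half_width, half_width, by = spacing)
  list(x_edges = e, y_edges = e,
       x_centers = (e[-1] + e[-length(e)]) / 2,
       y_centers = (e[-1] + e[-length(e)]) / 2)
}

new_grid_map <- function(grid, values, what, units, n_frames = 1L, mask = NULL) {
  if (is.null(mask))
    mask <- matrix(FALSE, length(grid$x_centers), length(grid$y_centers))
  values[mask] <- NA_real_
  structure(list(x_edges = grid$x_edges, y_edges = grid$y_edges,
                 x_centers = grid$x_centers, y_centers = grid$y_centers,
                 values = values, what = what, units = units,
                 n_frames_averaged = as.integer(n_frames),
                 protein_footprint_mask = mask),
            class = "mt_grid_map")
}

#' @export
print.mt_grid_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<mt_grid_map> %s (%s): %d x %d cells, %d frame(s), range %.4g..%.4g\n",
              x$what, x$units, length(x$x_centers), length(x$y_centers),
              x$n_frames_averaged,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
plot.mt_grid_map <- function(x, ...) {
  graphics::image(x$x_centers, x$y_centers, x$values,
                  xlab = "x (nm)", ylab = "y (nm)",
                  main = sprintf("%s (%s)", x$what, x$units), ...)
  invisible(x)
}

#' Membrane thickness map from two leaflet fits
#'
#' Thickness is the upper-minus-lower surface separation evaluated at grid
#' cell centres. Negative values (upper below lower) are reported as-is
#' with a warning.
#'
#' @param upper,lower `mt_surface_fit`s for the two leaflets.
#' @param grid an [mt_grid()].
#' @param mask optional logical mask matrix (TRUE = masked, reported NA).
#' @return an `mt_grid_map` of thickness in nm.
#' @export
thickness_map <- function(upper, lower, grid, mask = NULL) {
  check_grid_domain(upper, grid); check_grid_domain(lower, grid)
  g <- expand.grid(x = grid$x_centers, y = grid$y_centers)
  th <- predict(upper, g$x, g$y) - predict(lower, g$x, g$y)
  if (any(th < 0, na.rm = TRUE))
    warning("negative thickness in map: upper surface below lower surface somewhere")
  v <- matrix(th, length(grid$x_centers), length(grid$y_centers))
  new_grid_map(grid, v, "thickness", "nm", mask = mask)
}

check_grid_domain <- function(fit, grid) {
  gx <- range(grid$x_centers); gy <- range(grid$y_centers)
  dx <- fit$domain$x; dy <- fit$domain$y
  tol <- 0.5  # allow mild extrapolation beyond the outermost data point
  if (gx[1] < dx[1] - tol || gx[2] > dx[2] + tol ||
      gy[1] < dy[1] - tol || gy[2] > dy[2] + tol)
    stop("grid extends outside the fitted surface domain")
  invisible(TRUE)
}

#' Mean-curvature map of one leaflet surface
#'
#' Monge-patch mean curvature H from analytic derivatives of the fitted
#' polynomial, H = \[(1+z_y^2) z_xx - 2 z_x z_y z_xy + (1+z_x^2) z_yy\] /
#' \[2 (1+z_x^2+z_y^2)^(3/2)\], in 1/nm.
#'
#' @param fit an `mt_surface_fit`.
#' @param grid an [mt_grid()].
#' @param mask optional logical mask matrix.
#' @return an `mt_grid_map` of mean curvature in 1/nm.
#' @export
mean_curvature_map <- function(fit, grid, mask = NULL) {
  check_grid_domain(fit, grid)
  g <- expand.grid(x = grid$x_centers, y = grid$y_centers)
  H <- monge_mean_curvature(surface_derivs(fit, g$x, g$y))
  v <- matrix(H, length(grid$x_centers), length(grid$y_centers))
  new_grid_map(grid, v, "mean_curvature", "1/nm", mask = mask)
}

#' Protein footprint mask on a grid
#'
#' Marks grid cells whose centre lies within `pad` of the (x, y) projection
#' of any protein particle (minimum image in the box plane). Masked cells
#' are excluded from surface-fit input and carried as NA in maps.
#'
#' @param frame an [mt_frame()].
#' @param protein_sel protein selection (or NULL for an empty mask).
#' @param grid an [mt_grid()].
#' @param pad mask radius around each particle, nm.
#' @param center length-2 (x, y) origin of the grid in frame coordinates.
#' @param box box edges (for the in-plane minimum image); defaults to frame box.
#' @return logical matrix (TRUE = masked), dim n_x x n_y.
#' @export
protein_footprint <- function(frame, protein_sel, grid, pad = 0.3,
                              center = c(0, 0), box = NULL) {
  nx <- length(grid$x_centers); ny <- length(grid$y_centers)
  mask <- matrix(FALSE, nx, ny)
  if (is.null(protein_sel)) return(mask)
  rows <- sel_rows(frame, protein_sel)
  if (length(rows) == 0) return(mask)
  if (is.null(box)) box <- frame$box
  px <- frame$atoms$x[rows] - center[1]
  py <- frame$atoms$y[rows] - center[2]
  px <- px - box[1] * round(px / box[1])
  py <- py - box[2] * round(py / box[2])
  g <- expand.grid(x = grid$x_centers, y = grid$y_centers)
  dx <- outer(g$x, px, "-"); dy <- outer(g$y, py, "-")
  dx <- dx - box[1] * round(dx / box[1]); dy <- dy - box[2] * round(dy / box[2])
  near <- sqrt(dx^2 + dy^2) <= pad
  mask[matrix(apply(near, 1, any), nx, ny)] <- TRUE
  mask
}

#' Frame-averaged membrane thickness and curvature maps
#'
#' For each frame: centre coordinates on the protein centre of mass (or the
#' box centre), assign leaflets, fit a degree-4 polynomial surface to the
#' phosphate beads of each leaflet inside the analysis patch, and evaluate
#' thickness and per-leaflet mean curvature on the grid. Maps are averaged
#' over frames cell-wise; cells under the protein footprint are masked.
#'
#' @param frames list of [mt_frame()]s.
#' @param topo an [mt_topology()].
#' @param protein_sel optional protein selection (centres the patch and
#'   defines the footprint mask).
#' @param grid an [mt_grid()]; default 4 nm half-width, 0.2 nm cells.
#' @param center explicit length-2 patch centre (x, y, nm), used when
#'   `protein_sel` is NULL; default box centre.
#' @param what `"both"`, `"thickness"` or `"curvature"`.
#' @param dead_zone leaflet dead-zone half-width, nm.
#' @param pad footprint pad, nm.
#' @param basis surface basis, see [fit_leaflet_surface()].
#' @return list of `mt_grid_map`s: `thickness`, `curvature_upper`,
#'   `curvature_lower` (subset according to `what`).
#' @export
membrane_maps <- function(frames, topo, protein_sel = NULL, grid = mt_grid(),
                          center = NULL, what = c("both", "thickness", "curvature"),
                          dead_zone = 0.5, pad = 0.3, basis = "bivariate4") {
  what <- match.arg(what)
  if (length(frames) == 0) stop("no frames")
  nx <- length(grid$x_centers); ny <- length(grid$y_centers)
  acc <- list(thickness = matrix(0, nx, ny), curvature_upper = matrix(0, nx, ny),
              curvature_lower = matrix(0, nx, ny))
  mask_count <- matrix(0, nx, ny)
  for (fr in frames) {
    ctr <- if (!is.null(protein_sel)) {
      center_of_mass(fr, protein_sel)[1:2]
    } else if (!is.null(center)) center else fr$box[1:2] / 2
    mask <- protein_footprint(fr, protein_sel, grid, pad = pad, center = ctr,
                              box = fr$box)
    mask_count <- mask_count + mask
    lf <- assign_leaflets(fr, topo, dead_zone = dead_zone)
    pb <- lipid_bead_rows(fr, topo, "phosphate")
    pb$leaflet <- lf$leaflet[match(pb$resid, lf$resid)]
    px <- fr$atoms$x[pb$row] - ctr[1]; py <- fr$atoms$y[pb$row] - ctr[2]
    px <- px - fr$box[1] * round(px / fr$box[1])
    py <- py - fr$box[2] * round(py / fr$box[2])
    pz <- fr$atoms$z[pb$row]
    hwx <- range(grid$x_edges); hwy <- range(grid$y_edges)
    inpatch <- px >= hwx[1] & px <= hwx[2] & py >= hwy[1] & py <= hwy[2]
    if (any(mask)) {
      ix <- findInterval(px, grid$x_edges, rightmost.closed = TRUE)
      iy <- findInterval(py, grid$y_edges, rightmost.closed = TRUE)
      inside <- inpatch & ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
      masked_bead <- inside & mask[cbind(pmax(1, pmin(nx, ix)), pmax(1, pmin(ny, iy)))]
      inpatch <- inpatch & !masked_bead
    }
    fits <- list()
    for (leaf in c("upper", "lower")) {
      keep <- inpatch & pb$leaflet == leaf
      if (sum(keep) < 15)
        stop("too few ", leaf, "-leaflet phosphates in the analysis patch (",
             sum(keep), "); enlarge the patch or check the footprint mask")
      fits[[leaf]] <- fit_leaflet_surface(
        data.frame(x = px[keep], y = py[keep], z = pz[keep]),
        basis = basis, leaflet = leaf)
    }
    g <- expand.grid(x = grid$x_centers, y = grid$y_centers)
    if (what != "curvature") {
      th <- predict(fits$upper, g$x, g$y) - predict(fits$lower, g$x, g$y)
      acc$thickness <- acc$thickness + matrix(th, nx, ny)
    }
    if (what != "thickness") {
      acc$curvature_upper <- acc$curvature_upper +
        matrix(monge_mean_curvature(surface_derivs(fits$upper, g$x, g$y)), nx, ny)
      acc$curvature_lower <- acc$curvature_lower +
        matrix(monge_mean_curvature(surface_derivs(fits$lower, g$x, g$y)), nx, ny)
    }
  }
  nf <- length(frames)
  mask <- mask_count / nf > 0.5
  out <- list()
  if (what != "curvature")
    out$thickness <- new_grid_map(grid, acc$thickness / nf, "thickness", "nm",
                                  n_frames = nf, mask = mask)
  if (what != "thickness") {
    out$curvature_upper <- new_grid_map(grid, acc$curvature_upper / nf,
                                        "mean_curvature_upper", "1/nm",
                                        n_frames = nf, mask = mask)
    out$curvature_lower <- new_grid_map(grid, acc$curvature_lower / nf,
                                        "mean_curvature_lower", "1/nm",
                                        n_frames = nf, mask = mask)
  }
  out
}

#' Write a grid map as TSV
#'
#' Writes the value matrix with commented header lines naming the quantity,
#' units and the grid edges, plus a companion `.mask.tsv` when the map has
#' any masked cell.
#'
#' @param map an `mt_grid_map`.
#' @param path output path.
#' @export
write_grid_map <- function(map, path) {
  con <- file(path, "w")
  writeLines(c(sprintf("# %s (%s), %d frame(s) averaged; rows = x, cols = y; NA = masked",
                       map$what, map$units, map$n_frames_averaged),
               paste0("# x_edges_nm\t", paste(signif(map$x_edges, 8), collapse = "\t")),
               paste0("# y_edges_nm\t", paste(signif(map$y_edges, 8), collapse = "\t"))),
             con)
  utils::write.table(map$values, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  if (any(map$protein_footprint_mask)) {
    mp <- sub("\\.tsv$", "", path)
    utils::write.table(map$protein_footprint_mask * 1L, paste0(mp, ".mask.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
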