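#' Residue-lipid headgroup contacts in one frame
#'
#' A protein residue and a lipid molecule are in contact when any particle
#' of the residue lies within `cutoff` (minimum image) of any headgroup
#' bead of that lipid. Each (residue, lipid) pair is counted at most once
#' per frame; a cardiolipin contacting through both headgroup phosphates is
#' still one molecule.
#'
#' @param frame an [mt_frame()].
#' @param protein_sel selection of protein particles.
#' @param topo an [mt_topology()].
#' @param cutoff contact cutoff, nm (default 0.7).
#' @return data frame with `residue_id`, `lipid_id` (lipid resid),
#'   `lipid_type`, one row per contacting pair.
#' @export
lipid_contacts <- function(frame, protein_sel, topo, cutoff = 0.7) {
  if (cutoff <= 0) stop("cutoff must be positive")
  hb <- lipid_bead_rows(frame, topo, "headgroup")
  if (nrow(hb) == 0) stop("no headgroup beads resolvable from the topology map")
  prow <- sel_rows(frame, protein_sel)
  P <- as.matrix(frame$atoms[prow, c("x", "y", "z")])
  L <- as.matrix(frame$atoms[hb$row, c("x", "y", "z")])
  D <- min_image_cross(P, L, frame$box)
  hit <- which(D <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(data.frame(residue_id = integer(0), lipid_id = integer(0),
                      lipid_type = character(0), stringsAsFactors = FALSE))
  pairs <- data.frame(residue_id = frame$atoms$resid[prow][hit[, 1]],
                      lipid_id = hb$resid[hit[, 2]],
                      lipid_type = hb$lipid_type[hit[, 2]],
                      stringsAsFactors = FALSE)
  unique(pairs)
}

#' Annular-shell lipid census over a trajectory
#'
#' Per frame, a lipid molecule is in the annular shell when it has at least
#' one headgroup contact with any protein residue (cutoff rule of
#' [lipid_contacts()]). Bulk composition is the per-type lipid count of the
#' whole system.
#'
#' @param frames list of [mt_frame()]s.
#' @param protein_sel protein selection.
#' @param topo an [mt_topology()].
#' @param cutoff contact cutoff, nm.
#' @return object of class `mt_shell_census`: list with `shell_counts`
#'   (frames x types matrix), `bulk_counts` (named vector), `cutoff`.
#' @export
shell_census <- function(frames, protein_sel, topo, cutoff = 0.7) {
  if (length(frames) == 0) stop("need at least one frame")
  types <- sort(unique(topo$lipid_type))
  mol <- lipid_molecules(frames[[1]], topo)
  bulk <- table(factor(mol$lipid_type, levels = types))
  counts <- matrix(0L, length(frames), length(types),
                   dimnames = list(NULL, types))
  for (f in seq_along(frames)) {
    ct <- lipid_contacts(frames[[f]], protein_sel, topo, cutoff)
    if (nrow(ct)) {
      shell <- unique(ct[, c("lipid_id", "lipid_type")])
      tb <- table(factor(shell$lipid_type, levels = types))
      counts[f, ] <- as.integer(tb)
    }
  }
  structure(list(shell_counts = counts,
                 bulk_counts = stats::setNames(as.integer(bulk), types),
                 cutoff = cutoff, n_frames = length(frames)),
            class = "mt_shell_census")
}

#' @export
print.mt_shell_census <- function(x, ...) {
  cat(sprintf("<mt_shell_census> %d frames, cutoff %.2f nm\n", x$n_frames, x$cutoff))
  cat("  bulk:", paste(names(x$bulk_counts), x$bulk_counts, sep = "=", collapse = " "), "\n")
  cat("  mean shell:", paste(colnames(x$shell_counts),
                             round(colMeans(x$shell_counts), 2),
                             sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Depletion-enrichment index per lipid type
#'
#' For lipid type L the D-E index is ratio(L)_shell / ratio(L)_bulk, where
#' ratio(L)_shell is the fraction of shell lipids that are of type L and
#' ratio(L)_bulk the same fraction in the whole system. 1 means neutral
#' mixing, above 1 enrichment at the protein. The default estimator
#' averages the per-frame shell ratio over frames (frames with an empty
#' shell are skipped and counted); the pooled estimator sums shell counts
#' over frames first.
#'
#' @param census an `mt_shell_census`.
#' @param estimator `"perframe"` (default) or `"pooled"`.
#' @return object of class `mt_de_result`: data frame with `lipid_type`,
#'   `de_index`, `se` (standard error over frames), `n_frames`; per-frame
#'   shell ratios in attribute `per_frame_ratios`.
#' @export
de_index <- function(census, estimator = c("perframe", "pooled")) {
  estimator <- match.arg(estimator)
  types <- colnames(census$shell_counts)
  bulk <- census$bulk_counts[types]
  if (any(bulk == 0))
    stop("lipid type(s) absent from bulk: ",
         paste(types[bulk == 0], collapse = ", "))
  bulk_ratio <- bulk / sum(bulk)
  tot <- rowSums(census$shell_counts)
  occ <- tot > 0
  if (!any(occ)) stop("all frames have an empty annular shell")
  n_skip <- sum(!occ)
  if (n_skip > 0)
    message(n_skip, " frame(s) with empty shell skipped in D-E averaging")
  ratios <- census$shell_counts[occ, , drop = FALSE] / tot[occ]
  if (estimator == "perframe") {
    de <- colMeans(ratios) / bulk_ratio
    se <- apply(ratios, 2, stats::sd) / sqrt(nrow(ratios)) / bulk_ratio
  } else {
    pooled <- colSums(census$shell_counts[occ, , drop = FALSE])
    de <- (pooled / sum(pooled)) / bulk_ratio
    se <- apply(ratios, 2, stats::sd) / sqrt(nrow(ratios)) / bulk_ratio
  }
  out <- data.frame(lipid_type = types, de_index = as.numeric(de),
                    se = as.numeric(se), n_frames = sum(occ),
                    stringsAsFactors = FALSE)
  attr(out, "per_frame_ratios") <- ratios
  attr(out, "estimator") <- estimator
  attr(out, "bulk_ratio") <- bulk_ratio
  class(out) <- c("mt_de_result", "data.frame")
  out
}

#' Per-residue lipid contact occupancy
#'
#' Fraction of frames in which each protein residue has at least one
#' headgroup contact with a lipid of each type; also records, per frame,
#' the set of residues co-contacting each individual lipid molecule (for
#' binding-site grouping).
#'
#' @param frames list of [mt_frame()]s.
#' @param protein_sel protein selection.
#' @param topo an [mt_topology()].
#' @param cutoff contact cutoff, nm.
#' @return object of class `mt_contact_profile`: list with `occupancy`
#'   (residues x types matrix of fractions), `residues`, `cosets` (per
#'   frame, list of residue vectors keyed by "type:lipid_id"), `n_frames`.
#' @export
residue_contact_profile <- function(frames, protein_sel, topo, cutoff = 0.7) {
  if (length(frames) == 0) stop("need at least one frame")
  types <- sort(unique(topo$lipid_type))
  res_ids <- sort(unique(frames[[1]]$atoms$resid[
    sel_rows(frames[[1]], protein_sel)]))
  hits <- matrix(0L, length(res_ids), length(types),
                 dimnames = list(res_ids, types))
  cosets <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    ct <- lipid_contacts(frames[[f]], protein_sel, topo, cutoff)
    if (nrow(ct)) {
      per <- unique(ct[, c("residue_id", "lipid_type")])
      hits[cbind(match(per$residue_id, res_ids), match(per$lipid_type, types))] <-
        hits[cbind(match(per$residue_id, res_ids), match(per$lipid_type, types))] + 1L
      key <- paste(ct$lipid_type, ct$lipid_id, sep = ":")
      cosets[[f]] <- split(ct$residue_id, key)
    } else cosets[[f]] <- list()
  }
  structure(list(occupancy = hits / length(frames), residues = res_ids,
                 types = types, cosets = cosets, cutoff = cutoff,
                 n_frames = length(frames)),
            class = "mt_contact_profile")
}

#' @export
print.mt_contact_profile <- function(x, ...) {
  cat(sprintf("<mt_contact_profile> %d residues x %d lipid types over %d frames (cutoff %.2f nm)\n",
              length(x$residues), length(x$types), x$n_frames, x$cutoff))
  invisible(x)
}

#' Group residues into lipid-binding sites
#'
#' Single-linkage grouping of residues that are frequently in contact with
#' the same individual lipid molecule: two residues join the same site when
#' the fraction of frames in which some single lipid of the given type
#' touches both is at least `min_cofreq`.
#'
#' @param profile an `mt_contact_profile`.
#' @param lipid_type lipid type to analyse.
#' @param min_cofreq minimum co-contact frequency (fraction of frames).
#' @return list of integer vectors of residue ids (sites with >= 2 residues).
#' @export
binding_sites <- function(profile, lipid_type, min_cofreq = 0.2) {
  res <- profile$residues
  n <- length(res)
  co <- matrix(0, n, n, dimnames = list(res, res))
  for (f in seq_len(profile$n_frames)) {
    sets <- profile$cosets[[f]]
    sets <- sets[grepl(paste0("^", lipid_type, ":"), names(sets))]
    seen <- matrix(FALSE, n, n)
    for (s in sets) {
      i <- match(unique(s), res)
      if (length(i) >= 2) {
        pr <- t(utils::combn(sort(i), 2))
        seen[pr] <- TRUE
      }
    }
    co <- co + seen
  }
  co <- co / profile$n_frames
  adj <- co >= min_cofreq
  adj <- adj | t(adj)
  comp <- rep(0L, n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (comp[v] == 0L) {
          comp[v] <- cur
          queue <- c(queue, which(adj[v, ] & comp == 0L))
        }
      }
    }
  }
  sites <- split(res, comp)
  Filter(function(s) length(s) >= 2, unname(sites))
}

#' Headgroup density map for one lipid type
#'
#' 2-D histogram of headgroup-bead (x, y) positions in patch-centred
#' coordinates, normalised to counts per nm^2 per frame.
#'
#' @param frames list of [mt_frame()]s.
#' @param topo an [mt_topology()].
#' @param lipid_type lipid type to map.
#' @param grid an [mt_grid()].
#' @param protein_sel optional selection for the patch centre (protein
#'   centre of mass); default box centre.
#' @return an `mt_grid_map` of density in 1/nm^2/frame.
#' @export
headgroup_density_map <- function(frames, topo, lipid_type, grid = mt_grid(),
                                  protein_sel = NULL) {
  if (length(frames) == 0) stop("need at least one frame")
  nx <- length(grid$x_centers); ny <- length(grid$y_centers)
  counts <- matrix(0, nx, ny)
  n_beads <- 0
  for (fr in frames) {
    ctr <- if (!is.null(protein_sel)) center_of_mass(fr, protein_sel)[1:2]
           else fr$box[1:2] / 2
    hb <- lipid_bead_rows(fr, topo, "headgroup")
    hb <- hb[hb$lipid_type == lipid_type, , drop = FALSE]
    n_beads <- n_beads + nrow(hb)
    if (nrow(hb) == 0) next
    px <- fr$atoms$x[hb$row] - ctr[1]; py <- fr$atoms$y[hb$row] - ctr[2]
    px <- px - fr$box[1] * round(px / fr$box[1])
    py <- py - fr$box[2] * round(py / fr$box[2])
    ix <- findInterval(px, grid$x_edges, rightmost.closed = TRUE)
    iy <- findInterval(py, grid$y_edges, rightmost.closed = TRUE)
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    if (any(ok)) {
      tb <- table(factor(ix[ok], levels = 1:nx), factor(iy[ok], levels = 1:ny))
      counts <- counts + as.matrix(tb)
    }
  }
  if (n_beads == 0)
    warning("no headgroup beads of type '", lipid_type, "' found; density map is all zero")
  cell_area <- diff(grid$x_edges)[1] * diff(grid$y_edges)[1]
  new_grid_map(grid, counts / cell_area / length(frames),
               paste0("headgroup_density_", lipid_type), "1/nm^2/frame",
               n_frames = length(frames))
}
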