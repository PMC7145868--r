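#' Construct a coordinate frame
#'
#' A frame holds an ordered set of labelled particles together with the
#' orthorhombic box edges and a time stamp. All coordinates are in nm,
#' times in ps. Particle order is assumed stable across the frames of one
#' trajectory.
#'
#' @param atoms data frame with columns `index` (integer, unique),
#'   `name` (bead/atom name), `resname`, `resid` (integer),
#'   `chain` (molecule/chain id, character), `x`, `y`, `z` (nm).
#' @param box numeric length-3 vector of box edge lengths (nm), all > 0.
#' @param time frame time in ps.
#' @return An object of class `mt_frame`.
#' @export
mt_frame <- function(atoms, box, time = 0) {
  required <- c("index", "name", "resname", "resid", "chain", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(box) || length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three finite positive edge lengths (nm)")
  if (anyDuplicated(atoms$index))
    stop("particle indices must be unique within a frame")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz)))
    stop("particle positions must be finite")
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 box = as.numeric(box), time = as.numeric(time)),
            class = "mt_frame")
}

#' @export
print.mt_frame <- function(x, ...) {
  cat(sprintf("<mt_frame> %d particles, box %.3f x %.3f x %.3f nm, t = %g ps\n",
              nrow(x$atoms), x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

#' Number of particles in a frame
#' @param frame an `mt_frame`.
#' @return integer count.
#' @export
n_particles <- function(frame) nrow(frame$atoms)

#' Define a named selection of particles
#'
#' Selections name groups of particles by their `index` ids (1-based, as in
#' the common MD index-file convention) and are resolved against each frame
#' they are applied to.
#'
#' @param indices integer vector of particle index ids (non-empty).
#' @param name group name.
#' @return An object of class `mt_selection`.
#' @export
mt_selection <- function(indices, name = "group") {
  indices <- unique(as.integer(indices))
  if (length(indices) == 0) stop("selection '", name, "' is empty")
  structure(list(name = name, indices = indices), class = "mt_selection")
}

#' @export
print.mt_selection <- function(x, ...) {
  cat(sprintf("<mt_selection> '%s': %d particles\n", x$name, length(x$indices)))
  invisible(x)
}

# Resolve a selection to row positions in a frame's atom table.
sel_rows <- function(frame, sel) {
  if (inherits(sel, "mt_selection")) idx <- sel$indices else idx <- as.integer(sel)
  rows <- match(idx, frame$atoms$index)
  if (anyNA(rows)) {
    bad <- idx[is.na(rows)]
    stop("selection ", if (inherits(sel, "mt_selection")) paste0("'", sel$name, "' "),
         "does not resolve: missing particle index ", bad[1])
  }
  rows
}

#' Select particles by residue ranges
#'
#' Implements a residue-range mini-language, e.g. `"resid 69-75,127-133"`
#' (comma-separated ranges or single ids after the keyword `resid`).
#'
#' @param frame an `mt_frame`.
#' @param expr selection expression string.
#' @param name name for the resulting selection.
#' @return An `mt_selection` of all particles whose `resid` falls in range.
#' @export
select_resid <- function(frame, expr, name = expr) {
  expr <- trimws(expr)
  if (!grepl("^resid\\s+", expr))
    stop("selection expression must start with 'resid': got '", expr, "'")
  spec <- sub("^resid\\s+", "", expr)
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  ids <- integer(0)
  for (p in parts) {
    p <- trimws(p)
    if (grepl("^\\d+-\\d+$", p)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      ids <- c(ids, seq(ab[1], ab[2]))
    } else if (grepl("^\\d+$", p)) {
      ids <- c(ids, as.integer(p))
    } else stop("cannot parse residue range '", p, "'")
  }
  hit <- frame$atoms$resid %in% ids
  if (!any(hit)) stop("no particles match '", expr, "'")
  mt_selection(frame$atoms$index[hit], name = name)
}

#' Minimum-image distance under an orthorhombic box
#'
#' @param a,b numeric length-3 positions (nm).
#' @param box numeric length-3 box edges (nm), all > 0.
#' @return Euclidean distance (nm) between the closest periodic images.
#' @export
minimum_image_distance <- function(a, b, box) {
  if (any(box <= 0)) stop("box edges must be positive")
  d <- a - b
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# Vectorised minimum-image displacement: rows of A minus vector b.
min_image_disp <- function(A, b, box) {
  d <- sweep(A, 2, b)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# All minimum-image distances between rows of A (n x 3) and rows of B (m x 3):
# returns n x m matrix. Plain vectorised all-pairs; exact by construction.
min_image_cross <- function(A, B, box) {
  n <- nrow(A); m <- nrow(B)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Centre of mass of a selection
#'
#' Mass-weighted mean position of the selected particles. Masses default to
#' uniform, appropriate for coarse-grained beads of equal mass; a per-name
#' mass table can be supplied. The selection is assumed whole (not split
#' across the periodic boundary); unwrap first if needed.
#'
#' @param frame an `mt_frame`.
#' @param sel an `mt_selection` (or integer vector of particle indices).
#' @param masses either `NULL` (uniform), a numeric vector of per-particle
#'   masses aligned with the selection, or a named vector keyed by particle
#'   name.
#' @return numeric length-3 centre of mass (nm).
#' @export
center_of_mass <- function(frame, sel, masses = NULL) {
  rows <- sel_rows(frame, sel)
  if (length(rows) == 0) stop("empty selection")
  xyz <- as.matrix(frame$atoms[rows, c("x", "y", "z")])
  if (is.null(masses)) {
    w <- rep(1, length(rows))
  } else if (!is.null(names(masses))) {
    w <- unname(masses[frame$atoms$name[rows]])
    if (anyNA(w)) stop("mass table lacks entries for some particle names")
  } else {
    if (length(masses) != length(rows))
      stop("masses length must match selection size")
    w <- masses
  }
  as.numeric(colSums(xyz * w) / sum(w))
}
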