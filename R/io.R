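#' Read a structure file
#'
#' Reads a single-frame coordinate file in GRO (fixed-column, nm) or PDB
#' (Angstrom, converted to nm on read) dialect. Only orthorhombic boxes are
#' supported; triclinic box records are rejected.
#'
#' @param path file path.
#' @param dialect `"gro"` or `"pdb"`; default guessed from the extension.
#' @return An [mt_frame()].
#' @export
read_structure <- function(path, dialect = c("auto", "gro", "pdb")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext == "pdb") "pdb" else "gro"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect, gro = read_gro(path), pdb = read_pdb(path))
}

num_field <- function(line, from, to, lineno, what) {
  s <- trimws(substr(line, from, to))
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v))
    stop(sprintf("parse error at line %d: bad %s field '%s'", lineno, what, s))
  v
}

read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("GRO file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("parse error at line 2: bad atom count")
  if (length(lines) < 2 + n + 1)
    stop("GRO file truncated: expected ", n, " atom records plus box line")
  at <- lines[3:(2 + n)]
  resid <- integer(n); resname <- character(n); name <- character(n)
  x <- numeric(n); y <- numeric(n); z <- numeric(n)
  for (i in seq_len(n)) {
    ln <- at[i]; lineno <- i + 2
    if (nchar(ln) < 44)
      stop(sprintf("parse error at line %d: record shorter than 44 columns", lineno))
    resid[i] <- as.integer(num_field(ln, 1, 5, lineno, "residue id"))
    resname[i] <- trimws(substr(ln, 6, 10))
    name[i] <- trimws(substr(ln, 11, 15))
    x[i] <- num_field(ln, 21, 28, lineno, "x coordinate")
    y[i] <- num_field(ln, 29, 36, lineno, "y coordinate")
    z[i] <- num_field(ln, 37, 44, lineno, "z coordinate")
  }
  boxline <- trimws(lines[2 + n + 1])
  if (boxline == "") stop("missing box record on line ", 2 + n + 1)
  bv <- suppressWarnings(as.numeric(strsplit(boxline, "\\s+")[[1]]))
  if (anyNA(bv)) stop("parse error in box record: '", boxline, "'")
  if (length(bv) >= 9 && any(abs(bv[4:9]) > 1e-9))
    stop("triclinic box not supported (off-diagonal box elements present)")
  if (length(bv) < 3) stop("box record needs three edge lengths")
  mt_frame(data.frame(index = seq_len(n), name = name, resname = resname,
                      resid = resid, chain = "0", x = x, y = y, z = z,
                      stringsAsFactors = FALSE),
           box = bv[1:3], time = 0)
}

read_pdb <- function(path) {
  lines <- readLines(path)
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry) == 0)
    stop("missing CRYST1 box record in ", path, " (no silent default box)")
  cl <- cry[1]
  a <- num_field(cl, 7, 15, 1, "box a") / 10
  b <- num_field(cl, 16, 24, 1, "box b") / 10
  c3 <- num_field(cl, 25, 33, 1, "box c") / 10
  ang <- c(num_field(cl, 34, 40, 1, "alpha"), num_field(cl, 41, 47, 1, "beta"),
           num_field(cl, 48, 54, 1, "gamma"))
  if (any(abs(ang - 90) > 1e-6))
    stop("triclinic box not supported (CRYST1 angles differ from 90)")
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
  n <- length(rec)
  resid <- integer(n); resname <- character(n); name <- character(n)
  chain <- character(n); x <- numeric(n); y <- numeric(n); z <- numeric(n)
  for (k in seq_len(n)) {
    ln <- lines[rec[k]]; lineno <- rec[k]
    if (nchar(ln) < 54)
      stop(sprintf("parse error at line %d: ATOM record shorter than 54 columns", lineno))
    name[k] <- trimws(substr(ln, 13, 16))
    resname[k] <- trimws(substr(ln, 18, 21))
    chain[k] <- trimws(substr(ln, 22, 22))
    resid[k] <- as.integer(num_field(ln, 23, 26, lineno, "residue id"))
    x[k] <- num_field(ln, 31, 38, lineno, "x coordinate") / 10
    y[k] <- num_field(ln, 39, 46, lineno, "y coordinate") / 10
    z[k] <- num_field(ln, 47, 54, lineno, "z coordinate") / 10
  }
  chain[chain == ""] <- "0"
  mt_frame(data.frame(index = seq_len(n), name = name, resname = resname,
                      resid = resid, chain = chain, x = x, y = y, z = z,
                      stringsAsFactors = FALSE),
           box = c(a, b, c3), time = 0)
}

#' Write a structure file
#'
#' @param frame an [mt_frame()].
#' @param path output path.
#' @param dialect `"gro"` or `"pdb"`; default guessed from the extension.
#' @export
write_structure <- function(frame, path, dialect = c("auto", "gro", "pdb")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext == "pdb") "pdb" else "gro"
  }
  a <- frame$atoms
  if (dialect == "gro") {
    lines <- c("written by memtraj", sprintf("%5d", nrow(a)),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$resid %% 100000, substr(a$resname, 1, 5),
                       substr(a$name, 1, 5), a$index %% 100000, a$x, a$y, a$z),
               sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3]))
  } else {
    lines <- c(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       frame$box[1] * 10, frame$box[2] * 10, frame$box[3] * 10,
                       90, 90, 90),
               sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       a$index %% 100000, substr(a$name, 1, 4),
                       substr(a$resname, 1, 4), substr(a$chain, 1, 1),
                       a$resid %% 10000, a$x * 10, a$y * 10, a$z * 10),
               "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text trajectory
#'
#' The mandatory trajectory dialect is a whitespace table: a `FRAME` record
#' carrying time (ps) and the three box edges (nm) followed by one row
#' `index x y z` per particle, in the template's particle order. Lines
#' starting with `#` are comments. See the README for the grammar.
#'
#' @param path file path.
#' @param template an [mt_frame()] supplying particle labels and count.
#' @return list of [mt_frame()]s (possibly empty, with a warning).
#' @export
read_trajectory <- function(path, template) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    warning("empty trajectory file: ", path)
    return(list())
  }
  starts <- grep("^FRAME\\b", lines)
  if (length(starts) == 0) stop("no FRAME records in ", path)
  n <- n_particles(template)
  ends <- c(starts[-1] - 1, length(lines))
  frames <- vector("list", length(starts))
  for (f in seq_along(starts)) {
    hdr <- strsplit(trimws(lines[starts[f]]), "\\s+")[[1]]
    if (length(hdr) != 5)
      stop("frame ", f, ": FRAME record needs time and three box edges")
    meta <- suppressWarnings(as.numeric(hdr[-1]))
    if (anyNA(meta)) stop("frame ", f, ": bad FRAME record '", lines[starts[f]], "'")
    body <- lines[(starts[f] + 1):ends[f]]
    if (length(body) != n)
      stop(sprintf("frame %d: expected %d particles, found %d", f, n, length(body)))
    m <- matrix(suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+")))),
                ncol = 4, byrow = TRUE)
    if (anyNA(m)) stop("frame ", f, ": non-numeric particle row")
    atoms <- template$atoms
    if (!all(m[, 1] == atoms$index))
      stop("frame ", f, ": particle index order differs from template")
    atoms$x <- m[, 2]; atoms$y <- m[, 3]; atoms$z <- m[, 4]
    frames[[f]] <- mt_frame(atoms, box = meta[2:4], time = meta[1])
  }
  frames
}

#' Write a plain-text trajectory
#'
#' @param frames list of [mt_frame()]s.
#' @param path output path.
#' @export
write_trajectory <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# memtraj trajectory: FRAME <time_ps> <box_x> <box_y> <box_z>; rows: index x y z (nm)", con)
  for (fr in frames) {
    writeLines(sprintf("FRAME %.6g %.6f %.6f %.6f", fr$time,
                       fr$box[1], fr$box[2], fr$box[3]), con)
    a <- fr$atoms
    writeLines(sprintf("%d %.6f %.6f %.6f", a$index, a$x, a$y, a$z), con)
  }
  invisible(path)
}

#' Read named selections from an index file
#'
#' Index-file dialect: `[ name ]` section headers followed by whitespace- or
#' newline-separated 1-based particle indices, as in the common MD index
#' convention.
#'
#' @param path file path.
#' @return named list of [mt_selection()]s.
#' @export
read_index <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(;|#|$)", lines)]
  heads <- grep("^\\s*\\[", lines)
  if (length(heads) == 0) stop("no group headers in index file ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1)
  for (g in seq_along(heads)) {
    nm <- gsub("^\\s*\\[\\s*|\\s*\\]\\s*$", "", lines[heads[g]])
    body <- lines[seq2(heads[g] + 1, bounds[g + 1] - 1)]
    idx <- suppressWarnings(as.integer(unlist(strsplit(trimws(body), "\\s+"))))
    if (anyNA(idx)) stop("non-integer entry in index group '", nm, "'")
    out[[nm]] <- mt_selection(idx, name = nm)
  }
  out
}

seq2 <- function(from, to) if (from > to) integer(0) else seq(from, to)

#' Write selections to an index file
#' @param sels named list of [mt_selection()]s.
#' @param path output path.
#' @export
write_index <- function(sels, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in sels) {
    writeLines(sprintf("[ %s ]", s$name), con)
    writeLines(paste(s$indices, collapse = " "), con)
  }
  invisible(path)
}

#' Construct a lipid topology map
#'
#' Maps lipid residue names to a lipid type and names the headgroup and
#' phosphate beads of each type. Each lipid molecule is counted once in any
#' census regardless of how many phosphate beads it carries (cardiolipin
#' has two).
#'
#' @param table data frame with columns `residue_name`, `lipid_type`,
#'   `headgroup_beads`, `phosphate_beads`; the bead columns are
#'   comma-separated bead-name lists.
#' @return object of class `mt_topology`.
#' @export
mt_topology <- function(table) {
  required <- c("residue_name", "lipid_type", "headgroup_beads", "phosphate_beads")
  if (!all(required %in% names(table)))
    stop("topology table needs columns: ", paste(required, collapse = ", "))
  if (anyDuplicated(table$residue_name))
    stop("each lipid residue name must map to exactly one lipid type")
  structure(as.data.frame(table, stringsAsFactors = FALSE), class = c("mt_topology", "data.frame"))
}

#' Read a lipid topology map from TSV
#' @param path TSV with the [mt_topology()] columns; `#` lines are comments.
#' @return an `mt_topology`.
#' @export
read_topology <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  mt_topology(tb)
}

#' Write a lipid topology map to TSV
#' @param topo an `mt_topology`.
#' @param path output path.
#' @export
write_topology <- function(topo, path) {
  utils::write.table(as.data.frame(topo), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

split_beads <- function(s) trimws(strsplit(s, ",", fixed = TRUE)[[1]])

# Rows of frame$atoms that are phosphate (or headgroup) beads of mapped lipids,
# with the molecule id (resid) and lipid type attached.
lipid_bead_rows <- function(frame, topo, which = c("phosphate", "headgroup")) {
  which <- match.arg(which)
  col <- if (which == "phosphate") "phosphate_beads" else "headgroup_beads"
  a <- frame$atoms
  hit <- integer(0); type <- character(0)
  for (r in seq_len(nrow(topo))) {
    beads <- split_beads(topo[[col]][r])
    rows <- which(a$resname == topo$residue_name[r] & a$name %in% beads)
    hit <- c(hit, rows)
    type <- c(type, rep(topo$lipid_type[r], length(rows)))
  }
  data.frame(row = hit, resid = a$resid[hit], lipid_type = type,
             stringsAsFactors = FALSE)
}

# One row per lipid molecule present in the frame.
lipid_molecules <- function(frame, topo) {
  a <- frame$atoms
  keep <- a$resname %in% topo$residue_name
  mol <- unique(data.frame(resid = a$resid[keep], resname = a$resname[keep],
                           stringsAsFactors = FALSE))
  mol$lipid_type <- topo$lipid_type[match(mol$resname, topo$residue_name)]
  mol
}
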