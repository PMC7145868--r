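# Small deterministic fixtures built in code.

# A three-particle GRO file with a 10x10x10 nm box.
write_tiny_gro <- function(path) {
  rec <- function(resid, resname, name, num, x, y, z)
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", resid, resname, name, num, x, y, z)
  writeLines(c(
    "tiny fixture",
    "    3",
    rec(1, "LIG", "C1", 1, 1.0, 2.0, 3.0),
    rec(1, "LIG", "C2", 2, 4.0, 6.0, 3.0),
    rec(2, "SOL", "W", 3, 9.9, 0.0, 0.0),
    "  10.00000  10.00000  10.00000"), path)
  path
}

write_tiny_pdb <- function(path) {
  writeLines(c(
    "CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  C1  LIG A   1      10.000  20.000  30.000  1.00  0.00",
    "ATOM      2  C2  LIG A   1      40.000  60.000  30.000  1.00  0.00",
    "END"), path)
  path
}

# Flat bilayer frame without randomness: n lipids per leaflet on a lattice,
# leaflet phosphates at z0 +/- half_thickness, one POPE-like bead set each.
flat_bilayer_frame <- function(n_side = 6, half_thickness = 2, box = 10,
                               z0 = 5) {
  site <- expand.grid(x = (seq_len(n_side) - 0.5) * box / n_side,
                      y = (seq_len(n_side) - 0.5) * box / n_side)
  n <- nrow(site)
  one_leaflet <- function(sign, resid0) {
    data.frame(name = rep(c("NH3", "PO4", "C1A", "C1B"), n),
               resname = "POPE",
               resid = rep(resid0 + seq_len(n), each = 4), chain = "L",
               x = rep(site$x, each = 4), y = rep(site$y, each = 4),
               z = rep(z0 + sign * half_thickness, each = 4 * 1) +
                 sign * rep(c(0.3, 0, -0.5, -1.0), n),
               stringsAsFactors = FALSE)
  }
  at <- rbind(one_leaflet(1, 0), one_leaflet(-1, n))
  at$index <- seq_len(nrow(at))
  mt_frame(at[, c("index", "name", "resname", "resid", "chain", "x", "y", "z")],
           box = c(box, box, box))
}

simple_topology <- function() {
  mt_topology(data.frame(residue_name = "POPE", lipid_type = "POPE",
                         headgroup_beads = "NH3,PO4", phosphate_beads = "PO4",
                         stringsAsFactors = FALSE))
}

# O(N^2) brute-force contact oracle: loops over every protein particle and
# every lipid headgroup bead with scalar minimum-image distances.
brute_force_contacts <- function(frame, protein_sel, topo, cutoff = 0.7) {
  prow <- which(frame$atoms$index %in% protein_sel$indices)
  out <- NULL
  for (r in seq_len(nrow(topo))) {
    hbeads <- trimws(strsplit(topo$headgroup_beads[r], ",")[[1]])
    lrow <- which(frame$atoms$resname == topo$residue_name[r] &
                    frame$atoms$name %in% hbeads)
    for (i in prow) {
      for (j in lrow) {
        d <- minimum_image_distance(
          as.numeric(frame$atoms[i, c("x", "y", "z")]),
          as.numeric(frame$atoms[j, c("x", "y", "z")]), frame$box)
        if (d <= cutoff)
          out <- rbind(out, data.frame(
            residue_id = frame$atoms$resid[i],
            lipid_id = frame$atoms$resid[j],
            lipid_type = topo$lipid_type[r], stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    return(data.frame(residue_id = integer(0), lipid_id = integer(0),
                      lipid_type = character(0), stringsAsFactors = FALSE))
  unique(out)
}

sort_pairs <- function(df) df[order(df$residue_id, df$lipid_id, df$lipid_type), ]

# Finite-difference Monge-patch mean curvature of a fitted surface.
fd_mean_curvature <- function(fit, x, y, h = 1e-4) {
  z <- function(xx, yy) predict(fit, xx, yy)
  zx <- (z(x + h, y) - z(x - h, y)) / (2 * h)
  zy <- (z(x, y + h) - z(x, y - h)) / (2 * h)
  zxx <- (z(x + h, y) - 2 * z(x, y) + z(x - h, y)) / h^2
  zyy <- (z(x, y + h) - 2 * z(x, y) + z(x, y - h)) / h^2
  zxy <- (z(x + h, y + h) - z(x + h, y - h) - z(x - h, y + h) + z(x - h, y - h)) /
    (4 * h^2)
  ((1 + zy^2) * zxx - 2 * zx * zy * zxy + (1 + zx^2) * zyy) /
    (2 * (1 + zx^2 + zy^2)^1.5)
}

analytic_curvature_from_fit <- function(fit, x, y) {
  d <- memtraj:::surface_derivs(fit, x, y)
  memtraj:::monge_mean_curvature(d)
}
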