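make_contact_fixture <- function() {
  # dummy protein (2 residues x 2 beads) plus hand-placed lipids
  prot <- data.frame(index = 1:4, name = "BB", resname = "PROT",
                     resid = c(1, 1, 2, 2), chain = "P",
                     x = c(5.0, 5.2, 5.0, 5.2), y = 5, z = c(5, 5, 5.3, 5.3))
  lip <- data.frame(index = 5:10,
                    name = rep(c("HGB", "TL1"), 3),
                    resname = rep(c("POPE", "POPE", "CL"), each = 2),
                    resid = rep(3:5, each = 2), chain = "L",
                    x = c(5.69 + 5, 6.9, 5.71 + 5, 7.4, 5.0, 5.0),
                    y = c(5, 5, 5, 5, 5.69 + 5, 7.0),
                    z = 5)
  lip$x[1] <- 5 + 0.69   # residue 3 headgroup 0.69 nm from protein bead 1
  lip$x[3] <- 5.2 + 0.71 # residue 4 headgroup just outside the cutoff of every bead
  lip$y[5] <- 5 + 0.65  # CL headgroup inside cutoff
  topo <- mt_topology(data.frame(residue_name = c("POPE", "CL"),
                                 lipid_type = c("POPE", "CL"),
                                 headgroup_beads = c("HGB", "HGB"),
                                 phosphate_beads = c("HGB", "HGB")))
  list(frame = mt_frame(rbind(prot, lip), box = c(10, 10, 10)),
       topo = topo, protein = mt_selection(1:4, "protein"))
}

test_that("contact rule is a 0.7 nm headgroup cutoff with per-pair dedup", {
  fx <- make_contact_fixture()
  ct <- lipid_contacts(fx$frame, fx$protein, fx$topo)
  # 0.69 nm -> contact, 0.71 nm -> none
  expect_true(any(ct$lipid_id == 3))
  expect_false(any(ct$lipid_id == 4))
  # each (residue, lipid) pair at most once even with multiple close beads
  expect_equal(anyDuplicated(ct[, c("residue_id", "lipid_id")]), 0L)
  expect_error(lipid_contacts(fx$frame, fx$protein, fx$topo, cutoff = -1),
               "positive")
})

test_that("contacts equal the O(N^2) brute-force oracle on random fixtures", {
  set.seed(41)
  for (rep in 1:3) {
    n_lip <- 50
    prot <- data.frame(index = 1:6, name = "BB", resname = "PROT",
                       resid = rep(1:3, each = 2), chain = "P",
                       x = runif(6, 4.5, 5.5), y = runif(6, 4.5, 5.5),
                       z = runif(6, 4.5, 5.5))
    lip <- data.frame(index = 6 + seq_len(2 * n_lip),
                      name = rep(c("HGB", "TL1"), n_lip),
                      resname = rep(sample(c("POPE", "CL"), n_lip, TRUE), each = 2),
                      resid = rep(3 + seq_len(n_lip), each = 2), chain = "L",
                      x = runif(2 * n_lip, 0, 10), y = runif(2 * n_lip, 0, 10),
                      z = runif(2 * n_lip, 0, 10))
    fr <- mt_frame(rbind(prot, lip), box = c(10, 10, 10))
    topo <- mt_topology(data.frame(residue_name = c("POPE", "CL"),
                                   lipid_type = c("POPE", "CL"),
                                   headgroup_beads = c("HGB", "HGB"),
                                   phosphate_beads = c("HGB", "HGB")))
    got <- sort_pairs(lipid_contacts(fr, mt_selection(1:6), topo))
    want <- sort_pairs(brute_force_contacts(fr, mt_selection(1:6), topo))
    expect_equal(got$residue_id, want$residue_id)
    expect_equal(got$lipid_id, want$lipid_id)
    expect_equal(got$lipid_type, want$lipid_type)
  }
})

test_that("shell census counts molecules once and per-frame ratios sum to one", {
  sh <- make_enriched_shell_frames(c(POPE = 0.7, POPG = 0.25, CL = 0.05),
                                   c(POPE = 0.6, POPG = 0.3, CL = 0.1),
                                   n_shell = 10, n_bulk = 90, n_frames = 6,
                                   seed = 42)
  cen <- shell_census(sh$frames, sh$protein_sel, sh$topology)
  expect_equal(unname(rowSums(cen$shell_counts)), rep(10, 6))
  expect_equal(cen$bulk_counts[order(names(cen$bulk_counts))],
               sh$bulk_counts[order(names(sh$bulk_counts))])
  ratios <- cen$shell_counts / rowSums(cen$shell_counts)
  expect_equal(unname(rowSums(ratios)), rep(1, 6))
})

test_that("D-E index arithmetic matches hand-computed shell ratios", {
  # constructed census: bulk 70:25:5, shell constantly 60:30:10
  cen <- structure(list(
    shell_counts = matrix(rep(c(12, 6, 2), each = 5), nrow = 5,
                          dimnames = list(NULL, c("POPE", "POPG", "CL"))),
    bulk_counts = c(POPE = 140, POPG = 50, CL = 10),
    cutoff = 0.7, n_frames = 5), class = "mt_shell_census")
  de <- de_index(cen)
  expect_equal(de$de_index[de$lipid_type == "CL"], 0.10 / 0.05)
  expect_equal(de$de_index[de$lipid_type == "POPE"], 0.60 / 0.70)
  expect_equal(de$de_index[de$lipid_type == "POPG"], 0.30 / 0.25)
  # neutral shell: all indices exactly 1
  cen$shell_counts <- matrix(rep(c(14, 5, 1), each = 5), nrow = 5,
                             dimnames = list(NULL, c("POPE", "POPG", "CL")))
  expect_equal(de_index(cen)$de_index, c(1, 1, 1),
               ignore_attr = TRUE, tolerance = 1e-12)
  # pooled estimator satisfies the weighted identity sum(bulk_ratio * DE) = 1
  set.seed(43)
  cen$shell_counts <- matrix(rpois(15, c(12, 6, 2)), nrow = 5, byrow = TRUE,
                             dimnames = list(NULL, c("POPE", "POPG", "CL")))
  dep <- de_index(cen, estimator = "pooled")
  br <- attr(dep, "bulk_ratio")
  expect_equal(sum(br * dep$de_index), 1, tolerance = 1e-12)
})

test_that("D-E errors cleanly on absent types and empty shells", {
  cen <- structure(list(
    shell_counts = matrix(0, 3, 2, dimnames = list(NULL, c("POPE", "CL"))),
    bulk_counts = c(POPE = 10, CL = 1), cutoff = 0.7, n_frames = 3),
    class = "mt_shell_census")
  expect_error(de_index(cen), "empty")
  cen$bulk_counts <- c(POPE = 10, CL = 0)
  expect_error(de_index(cen), "absent")
})

test_that("D-E is invariant under frame reordering and recovers enrichment", {
  sh <- make_enriched_shell_frames(c(POPE = 0.7, POPG = 0.25, CL = 0.05),
                                   c(POPE = 0.6, POPG = 0.3, CL = 0.1),
                                   n_shell = 20, n_bulk = 380, n_frames = 40,
                                   seed = 44)
  cen <- shell_census(sh$frames, sh$protein_sel, sh$topology)
  de1 <- de_index(cen)
  cen2 <- shell_census(rev(sh$frames), sh$protein_sel, sh$topology)
  de2 <- de_index(cen2)
  expect_equal(sort(de1$de_index), sort(de2$de_index), tolerance = 1e-12)
  decl <- de1$de_index[de1$lipid_type == "CL"]
  expect_lt(abs(decl - 2), 3 * de1$se[de1$lipid_type == "CL"] + 0.2)
})

test_that("residue occupancy matches an exhaustive recount on a 3-frame fixture", {
  fx <- make_contact_fixture()
  f2 <- fx$frame; f2$atoms$x[f2$atoms$resid == 3] <- 9  # move lipid 3 away
  frames <- list(fx$frame, f2, fx$frame)
  prof <- residue_contact_profile(frames, fx$protein, fx$topo)
  # brute-force recount
  occ <- matrix(0, length(prof$residues), length(prof$types),
                dimnames = list(prof$residues, prof$types))
  for (fr in frames) {
    ct <- brute_force_contacts(fr, fx$protein, fx$topo)
    per <- unique(ct[, c("residue_id", "lipid_type")])
    for (k in seq_len(nrow(per)))
      occ[as.character(per$residue_id[k]), per$lipid_type[k]] <-
        occ[as.character(per$residue_id[k]), per$lipid_type[k]] + 1
  }
  expect_equal(prof$occupancy, occ / 3)
  # permanently bound lipid gives occupancy 1; absent gives 0
  expect_true(all(prof$occupancy >= 0 & prof$occupancy <= 1))
})

test_that("binding sites group residues co-contacting the same lipid", {
  fx <- make_contact_fixture()
  # lipid 3 sits within cutoff of both residues' beads in every frame
  fr <- fx$frame
  fr$atoms$x[fr$atoms$index == 5] <- 5.35
  fr$atoms$z[fr$atoms$index == 5] <- 5.15
  prof <- residue_contact_profile(list(fr, fr, fr), fx$protein, fx$topo)
  sites <- binding_sites(prof, "POPE", min_cofreq = 0.5)
  expect_true(any(vapply(sites, function(s) setequal(s, c(1, 2)), logical(1))))
})

test_that("headgroup density map integrates to the bead count and flags empty types", {
  fx <- make_contact_fixture()
  g <- mt_grid(5, 0.5)
  dm <- headgroup_density_map(list(fx$frame), fx$topo, "POPE", g)
  cell_area <- 0.25
  expect_equal(sum(dm$values) * cell_area, 2)  # two POPE headgroup beads
  expect_warning(headgroup_density_map(list(fx$frame), fx$topo, "DOPC", g),
                 "all zero")
  # uniform placements give a flat map within Poisson noise (chi-squared)
  set.seed(45)
  n <- 4000
  at <- data.frame(index = seq_len(n), name = "HGB", resname = "POPE",
                   resid = seq_len(n), chain = "L",
                   x = runif(n, 0, 10), y = runif(n, 0, 10), z = 5)
  fr <- mt_frame(at, box = c(10, 10, 10))
  topo <- simple_topology()
  topo$headgroup_beads <- "HGB"
  dm2 <- headgroup_density_map(list(fr), topo, "POPE", mt_grid(5, 1))
  counts <- dm2$values * 1  # cell area 1 nm^2, one frame
  chi2 <- sum((counts - mean(counts))^2 / mean(counts))
  df <- length(counts) - 1
  expect_lt(chi2, df + 4 * sqrt(2 * df))
})
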