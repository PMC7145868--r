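test_that("leaflet assignment splits a flat bilayer and applies the dead zone", {
  f <- flat_bilayer_frame(n_side = 6, half_thickness = 2)
  topo <- simple_topology()
  lf <- assign_leaflets(f, topo)
  expect_equal(sum(lf$leaflet == "upper"), 36)
  expect_equal(sum(lf$leaflet == "lower"), 36)
  expect_equal(sum(lf$leaflet == "excluded"), 0)
  expect_equal(attr(lf, "midplane_z"), 5, tolerance = 1e-9)

  # one lipid dragged onto the midplane is excluded
  f2 <- f
  r1 <- f2$atoms$resid == 1
  f2$atoms$z[r1] <- f2$atoms$z[r1] - 2
  lf2 <- assign_leaflets(f2, topo)
  expect_equal(lf2$leaflet[lf2$resid == 1], "excluded")

  expect_error(assign_leaflets(f, mt_topology(data.frame(
    residue_name = "DOPC", lipid_type = "DOPC", headgroup_beads = "PO4",
    phosphate_beads = "PO4"))), "no phosphate beads")
})

test_that("cardiolipin with phosphates straddling a height is assigned by their average", {
  at <- rbind(
    data.frame(index = 1:3, name = c("PO41", "PO42", "GL0"), resname = "CL",
               resid = 1, chain = "L", x = 1, y = 1, z = c(1.9, 2.1, 2.3)),
    data.frame(index = 4:5, name = "PO4", resname = "POPE", resid = 2:3,
               chain = "L", x = 2, y = 2, z = c(2, -2)))
  f <- mt_frame(at, box = c(10, 10, 10))
  topo <- mt_topology(data.frame(
    residue_name = c("CL", "POPE"), lipid_type = c("CL", "POPE"),
    headgroup_beads = c("GL0,PO41,PO42", "PO4"),
    phosphate_beads = c("PO41,PO42", "PO4")))
  lf <- assign_leaflets(f, topo)
  expect_equal(lf$leaflet[lf$resid == 1], "upper")
  expect_equal(lf$z[lf$resid == 1], 2.0)
})

test_that("surface fit recovers plane and paraboloid coefficients", {
  set.seed(31)
  x <- runif(100, -4, 4); y <- runif(100, -4, 4)
  flat <- fit_leaflet_surface(data.frame(x = x, y = y, z = 2))
  expect_lt(flat$fit_rms, 1e-8)
  expect_equal(unname(flat$coefficients["x0y0"]), 2, tolerance = 1e-8)
  expect_equal(predict(flat, 0.3, -1.2), 2, tolerance = 1e-8)

  z <- 2 + 0.05 * x^2 + 0.05 * y^2 + rnorm(100, 0, 0.05)
  fit <- fit_leaflet_surface(data.frame(x = x, y = y, z = z))
  # coefficient standard errors from the classical linear-model formula
  X <- memtraj:::poly_design(x, y, fit$exponents)
  se <- sqrt(diag(solve(crossprod(X))) * sum((z - predict(fit, x, y))^2) /
               (100 - 15))
  expect_lt(abs(fit$coefficients["x2y0"] - 0.05), 3 * se[which(names(fit$coefficients) == "x2y0")])
  expect_lt(abs(fit$coefficients["x0y2"] - 0.05), 3 * se[which(names(fit$coefficients) == "x0y2")])

  expect_error(fit_leaflet_surface(data.frame(x = x[1:10], y = y[1:10],
                                              z = z[1:10])), "at least 15")
  expect_error(fit_leaflet_surface(data.frame(x = x, y = 0 * y, z = z)),
               "rank-deficient")
})

test_that("thickness map is the surface difference; mirror symmetry holds pointwise", {
  set.seed(32)
  x <- runif(80, -4, 4); y <- runif(80, -4, 4)
  g <- mt_grid(3, 0.5)
  up <- fit_leaflet_surface(data.frame(x = x, y = y, z = 2))
  lo <- fit_leaflet_surface(data.frame(x = x, y = y, z = -2))
  tm <- thickness_map(up, lo, g)
  expect_true(all(abs(tm$values - 4) < 1e-8))

  # mirror-symmetric leaflets: thickness = 2 * upper surface
  zu <- 2 + 0.03 * x^2 - 0.02 * y^2
  upc <- fit_leaflet_surface(data.frame(x = x, y = y, z = zu))
  loc <- fit_leaflet_surface(data.frame(x = x, y = y, z = -zu))
  tm2 <- thickness_map(upc, loc, g)
  gg <- expand.grid(x = g$x_centers, y = g$y_centers)
  expect_equal(as.vector(tm2$values), 2 * predict(upc, gg$x, gg$y),
               tolerance = 1e-8)

  # upper below lower: negative values reported with a warning
  expect_warning(tm3 <- thickness_map(lo, up, g), "negative")
  expect_true(all(tm3$values < 0))

  expect_error(thickness_map(up, lo, mt_grid(20, 1)), "outside")
})

test_that("mean curvature matches analytic values and transforms correctly", {
  set.seed(33)
  x <- runif(120, -3, 3); y <- runif(120, -3, 3)
  g <- mt_grid(1, 0.25)
  flat <- fit_leaflet_surface(data.frame(x = x, y = y, z = 1.7))
  expect_true(all(abs(mean_curvature_map(flat, g)$values) < 1e-10))

  # paraboloid z = 0.05 x^2 + 0.05 y^2: H = 0.1 at the origin
  par <- fit_leaflet_surface(data.frame(x = x, y = y,
                                        z = 0.05 * (x^2 + y^2)))
  H <- mean_curvature_map(par, g)
  cc <- which.min(abs(g$x_centers))
  expect_equal(H$values[cc, cc], 0.1, tolerance = 1e-3)

  # invariant under adding a constant; sign flips under z-reflection
  par2 <- par; par2$coefficients["x0y0"] <- par2$coefficients["x0y0"] + 5
  expect_equal(mean_curvature_map(par2, g)$values, H$values, tolerance = 1e-9)
  neg <- par; neg$coefficients <- -neg$coefficients
  expect_equal(mean_curvature_map(neg, g)$values, -H$values, tolerance = 1e-9)
})

test_that("analytic curvature equals finite differences on random degree-4 surfaces", {
  set.seed(34)
  for (rep in 1:5) {
    x <- runif(60, -2, 2); y <- runif(60, -2, 2)
    co <- rnorm(15, 0, 0.02)
    ex <- memtraj:::poly_exponents(4)
    z <- as.vector(memtraj:::poly_design(x, y, ex) %*% co)
    fit <- fit_leaflet_surface(data.frame(x = x, y = y, z = z))
    px <- runif(12, -1.5, 1.5); py <- runif(12, -1.5, 1.5)
    expect_lt(max(abs(analytic_curvature_from_fit(fit, px, py) -
                        fd_mean_curvature(fit, px, py))), 1e-4)
  }
})

test_that("sphere-cap cloud yields mean curvature near 1/R at the apex", {
  set.seed(35)
  R <- 10
  r <- sqrt(runif(1500)) * 4; th <- runif(1500, 0, 2 * pi)
  x <- r * cos(th); y <- r * sin(th)
  z <- R - sqrt(R^2 - r^2) + rnorm(1500, 0, 0.01)
  fit <- fit_leaflet_surface(data.frame(x = x, y = y, z = z))
  g <- mt_grid(0.5, 0.1)
  H <- mean_curvature_map(fit, g)
  apex <- H$values[which.min(abs(g$x_centers)), which.min(abs(g$y_centers))]
  expect_lt(abs(apex - 0.1) / 0.1, 0.05)
})

test_that("protein footprint masks cells near particles and matches brute force", {
  g <- mt_grid(1, 0.2)
  f <- flat_bilayer_frame(n_side = 2)
  expect_false(any(protein_footprint(f, NULL, g)))

  at <- data.frame(index = 1, name = "BB", resname = "PROT", resid = 1,
                   chain = "P", x = 5, y = 5, z = 5)
  fp <- mt_frame(at, box = c(10, 10, 10))
  mask <- protein_footprint(fp, mt_selection(1), g, pad = 0.3, center = c(5, 5))
  # brute-force cell enumeration oracle
  expected <- matrix(FALSE, length(g$x_centers), length(g$y_centers))
  for (i in seq_along(g$x_centers)) for (j in seq_along(g$y_centers))
    expected[i, j] <- sqrt(g$x_centers[i]^2 + g$y_centers[j]^2) <= 0.3
  expect_equal(mask, expected)
  expect_equal(sum(mask), sum(expected))

  # protein spanning the whole patch: everything masked, downstream fit errors
  atw <- do.call(rbind, lapply(1:121, function(i)
    data.frame(index = i, name = "BB", resname = "PROT", resid = i, chain = "P",
               x = 5 + ((i - 1) %% 11 - 5) * 0.2,
               y = 5 + ((i - 1) %/% 11 - 5) * 0.2, z = 5)))
  fw <- mt_frame(atw, box = c(10, 10, 10))
  mw <- protein_footprint(fw, mt_selection(1:121), g, pad = 0.3, center = c(5, 5))
  expect_true(all(mw))
})

test_that("dimpled synthetic bilayer maps recover the thickness field", {
  bs <- bilayer_spec(
    n_lipids_per_leaflet = 400, composition = c(POPE = 1),
    thickness_field = function(x, y) 4 - 0.4 * exp(-(x^2 + y^2) / (2 * 2^2)),
    phosphate_noise_sd = 0.1, seed = 7)
  bl <- make_bilayer_trajectory(bs, n_frames = 10)
  maps <- membrane_maps(bl$frames, bl$topology, grid = mt_grid(4, 0.2))
  expect_equal(min(maps$thickness$values, na.rm = TRUE), 3.6, tolerance = 0.02)
  # upper leaflet has a curvature annulus signature: nonzero curvature at centre
  cc <- which.min(abs(maps$curvature_upper$x_centers))
  expect_gt(maps$curvature_upper$values[cc, cc], 0.01)
  expect_equal(maps$thickness$n_frames_averaged, 10)
})

test_that("radial basis fit reproduces radially symmetric surfaces", {
  set.seed(36)
  x <- runif(200, -3, 3); y <- runif(200, -3, 3)
  z <- 1 + 0.04 * (x^2 + y^2) - 0.002 * (x^2 + y^2)^2
  fit <- fit_leaflet_surface(data.frame(x = x, y = y, z = z), basis = "radial4")
  expect_lt(fit$fit_rms, 1e-8)
  expect_equal(predict(fit, 1, 1), 1 + 0.04 * 2 - 0.002 * 4, tolerance = 1e-8)
})

test_that("grid maps write TSV with unit-bearing commented headers", {
  set.seed(37)
  x <- runif(60, -2, 2); y <- runif(60, -2, 2)
  fit <- fit_leaflet_surface(data.frame(x = x, y = y, z = 2))
  tm <- thickness_map(fit, fit, mt_grid(1, 0.5))
  p <- tempfile(fileext = ".tsv")
  write_grid_map(tm, p)
  lines <- readLines(p)
  expect_match(lines[1], "^# thickness \\(nm\\)")
  expect_match(lines[2], "x_edges_nm")
})
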