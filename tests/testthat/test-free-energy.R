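harmonic_windows <- function(k_harm = 100, centers = seq(-1.2, 1.2, by = 0.1),
                             n = 1500, seed = 51, K = 2500, temp = 303) {
  make_umbrella_samples(potential_spec(
    U = function(x) 0.5 * k_harm * x^2, domain = c(min(centers) - 0.4,
                                                   max(centers) + 0.4),
    centers = centers, force_constant = K, n_per_window = n,
    temperature = temp, seed = seed))
}

test_that("reaction coordinate is the COM-COM distance", {
  at <- data.frame(index = 1:4, name = "BB", resname = "PROT",
                   resid = c(1, 1, 2, 2), chain = "P",
                   x = c(-0.5, 0.5, 2.0, 3.0), y = 0.01, z = 0.01)
  f <- mt_frame(at, box = c(50, 50, 50))
  expect_equal(reaction_coordinate(f, mt_selection(1:2), mt_selection(3:4)), 2.5)
  expect_equal(reaction_coordinate(f, mt_selection(1:2), mt_selection(1:2)), 0)
  # random fixture against independent COM arithmetic
  set.seed(52)
  at2 <- data.frame(index = 1:20, name = "BB", resname = "X",
                    resid = rep(1:2, each = 10), chain = "P",
                    x = runif(20, 2, 8), y = runif(20, 2, 8), z = runif(20, 2, 8))
  f2 <- mt_frame(at2, box = c(50, 50, 50))
  coma <- colMeans(at2[1:10, c("x", "y", "z")])
  comb <- colMeans(at2[11:20, c("x", "y", "z")])
  expect_equal(reaction_coordinate(f2, mt_selection(1:10), mt_selection(11:20)),
               sqrt(sum((coma - comb)^2)), tolerance = 1e-12)
})

test_that("window validation reports overlaps and catches gaps", {
  ws <- harmonic_windows(k_harm = 0, centers = seq(0, 1, by = 0.1), n = 400)
  rep_ok <- validate_windows(ws)
  expect_true(all(rep_ok$overlaps > 0))
  expect_lt(max(abs(rep_ok$windows$deviation)), 0.02)
  # sample SD close to sqrt(kT/K) for a flat underlying potential
  expect_equal(mean(rep_ok$windows$sd), sqrt(0.0083144621 * 303 / 2500),
               tolerance = 0.05)
  # two far-apart tight windows share no occupied bins
  w1 <- mt_window(0, 2500, samples = rnorm(100, 0, 0.03))
  w2 <- mt_window(5, 2500, samples = rnorm(100, 5, 0.03))
  expect_error(validate_windows(mt_window_set(list(w1, w2))), "no occupied bins")
  expect_warning(validate_windows(mt_window_set(list(w1))), "single")
})

test_that("WHAM recovers a flat potential to within noise", {
  ws <- harmonic_windows(k_harm = 0, centers = seq(0, 1.5, by = 0.1),
                         n = 2000, seed = 53)
  pr <- bootstrap_pmf(ws, n_boot = 60, seed = 9)
  sel <- pr$bin_centers > 0.1 & pr$bin_centers < 1.4 & is.finite(pr$free_energy)
  expect_true(all(abs(pr$free_energy[sel]) <= pmax(3 * pr$errors[sel], 0.2)))
})

test_that("WHAM recovers a harmonic potential and the solver is estimator-invariant", {
  ws <- harmonic_windows(n = 2000, seed = 54)
  pr <- wham(ws)
  sel <- abs(pr$bin_centers) <= 1 & is.finite(pr$free_energy)
  truth <- 0.5 * 100 * pr$bin_centers^2
  truth <- truth - min(truth[sel])
  rms <- sqrt(mean((pr$free_energy[sel] - truth[sel])^2))
  expect_lt(rms, 0.5)
  # accelerated and plain fixed-point solves reach the same fixed point
  pr2 <- wham(ws, accelerate = FALSE)
  expect_equal(pr$window_offsets, pr2$window_offsets, tolerance = 1e-4)
  expect_equal(pr$free_energy, pr2$free_energy, tolerance = 1e-4)
})

test_that("single-window limit reproduces direct Boltzmann inversion", {
  ws <- harmonic_windows(k_harm = 20, centers = 0.3, n = 20000, seed = 55)
  expect_warning(pr <- wham(ws), "single umbrella window")
  w <- ws$windows[[1]]
  kT <- 0.0083144621 * 303
  h <- hist(w$samples, breaks = pr$bin_edges, plot = FALSE)
  direct <- -kT * log(h$counts / sum(h$counts)) -
    0.5 * w$force_constant * (pr$bin_centers - w$center)^2
  ok <- is.finite(direct) & is.finite(pr$free_energy) & h$counts > 50
  dev <- (pr$free_energy - direct)[ok]
  expect_lt(stats::sd(dev), 0.05)  # equal up to an additive constant
})

test_that("PMF is invariant under a rigid shift of the whole problem", {
  ws <- harmonic_windows(centers = seq(-0.5, 0.5, by = 0.1), n = 800, seed = 56)
  shift <- 2.0
  ws2 <- mt_window_set(lapply(ws$windows, function(w)
    mt_window(w$center + shift, w$force_constant, w$samples + shift)),
    ws$temperature)
  pr <- wham(ws); pr2 <- wham(ws2)
  expect_equal(pr2$bin_centers, pr$bin_centers + shift, tolerance = 1e-9)
  expect_equal(pr2$free_energy, pr$free_energy, tolerance = 1e-6)
})

test_that("iterative WHAM matches a direct fine-grid fixed point on a small set", {
  ws <- harmonic_windows(centers = seq(-0.2, 0.2, by = 0.1), n = 200, seed = 57)
  pr <- wham(ws, tol = 1e-9)
  # independent direct solve: plain successive substitution on histograms
  kT <- 0.0083144621 * 303
  edges <- pr$bin_edges
  centers <- pr$bin_centers
  H <- t(vapply(ws$windows, function(w)
    tabulate(findInterval(w$samples, edges, rightmost.closed = TRUE),
             nbins = length(centers)), numeric(length(centers))))
  ci <- vapply(ws$windows, `[[`, numeric(1), "center")
  B <- exp(-0.5 * 2500 * outer(ci, centers, "-")^2 / kT)
  n_i <- rowSums(H); N_j <- colSums(H)
  f <- numeric(length(ci))
  for (it in 1:200000) {
    denom <- colSums(B * (n_i * exp(f / kT)))
    p <- ifelse(N_j > 0, N_j / denom, 0); p <- p / sum(p)
    fn <- -kT * log(as.vector(B %*% p)); fn <- fn - fn[1]
    if (max(abs(fn - f)) < 1e-10) { f <- fn; break }
    f <- fn
  }
  expect_equal(pr$window_offsets, f, tolerance = 1e-6)
})

test_that("bootstrap errors are deterministic per seed and near zero for tight data", {
  ws <- harmonic_windows(centers = seq(-0.3, 0.3, by = 0.1), n = 400, seed = 58)
  p1 <- bootstrap_pmf(ws, n_boot = 40, seed = 7)
  p2 <- bootstrap_pmf(ws, n_boot = 40, seed = 7)
  expect_identical(p1$errors, p2$errors)
  p3 <- bootstrap_pmf(ws, n_boot = 40, seed = 8)
  expect_false(identical(p1$errors, p3$errors))
  # independent samples: estimated block length is ~1
  expect_true(all(attr(p1, "block_lengths") < 2))
  # zero within-window variance gives exactly zero errors
  wtight <- lapply(c(0, 0.05, 0.1), function(c)
    mt_window(c, 2500, samples = rep(0.01, 100)))
  pt <- bootstrap_pmf(mt_window_set(wtight), n_boot = 20, seed = 3)
  expect_equal(max(pt$errors, na.rm = TRUE), 0)
})

test_that("autocorrelated series produce block lengths above one", {
  set.seed(59)
  n <- 4000
  ar <- as.numeric(arima.sim(list(ar = 0.8), n)) * 0.01
  expect_gt(memtraj:::integrated_act(ar), 3)
  expect_equal(memtraj:::integrated_act(rnorm(n)), 1, tolerance = 0.5)
})

test_that("window files and manifests round-trip", {
  ws <- harmonic_windows(centers = seq(0, 0.2, by = 0.1), n = 50, seed = 60)
  d <- tempfile(); man <- write_windows(ws, d)
  ws2 <- read_windows(file.path(d, "manifest.tsv"), temperature = 303)
  expect_equal(length(ws2$windows), 3)
  expect_equal(ws2$windows[[2]]$center, ws$windows[[2]]$center)
  expect_equal(ws2$windows[[2]]$force_constant, 2500)
  expect_equal(ws2$windows[[2]]$samples, ws$windows[[2]]$samples,
               tolerance = 1e-6)
  p <- tempfile(fileext = ".tsv")
  write_pmf(wham(ws2), p)
  expect_match(readLines(p)[1], "kJ/mol")
})

test_that("radial Jacobian correction changes the profile by 2kT log x", {
  ws <- harmonic_windows(centers = seq(1.0, 1.4, by = 0.1), n = 500, seed = 61)
  pr <- wham(ws)
  prj <- wham(ws, radial_correction = TRUE)
  kT <- 0.0083144621 * 303
  d <- prj$free_energy - pr$free_energy - 2 * kT * log(prj$bin_centers)
  d <- d[is.finite(d)]
  expect_lt(diff(range(d)), 1e-9)  # constant offset only
})
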