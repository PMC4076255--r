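test_that("area per lipid is exact arithmetic with block standard error", {
  tr <- trajectory(array(0, c(1, 3, 10)), c(50, 50, 40))
  ar <- compute_area_per_lipid(tr, 64, analysis_window(tr, 0, 10,
                                                       blocks = 5))
  expect_equal(unique(ar$area_A2), 50 * 50 / 64)
  expect_equal(attr(ar, "mean"), 39.0625)
  expect_equal(attr(ar, "se"), 0)
  expect_true(attr(ar, "mean") >= min(ar$area_A2) &&
                attr(ar, "mean") <= max(ar$area_A2))
  # a fluctuating box gives a positive block SE
  box <- cbind(50 + sin(1:10), 50, 40)
  tr2 <- trajectory(array(0, c(1, 3, 10)), box)
  ar2 <- compute_area_per_lipid(tr2, 64, analysis_window(tr2, 0, 10,
                                                         blocks = 5))
  expect_gt(attr(ar2, "se"), 0)
  expect_error(compute_area_per_lipid(tr, 0), "lipids_per_leaflet > 0")
})

uniform_box_system <- function(n_atoms, box, n_frames = 4L, seed = 31L) {
  set.seed(seed)
  coords <- array(runif(n_atoms * 3 * n_frames), c(n_atoms, 3L, n_frames))
  for (k in 1:3) coords[, k, ] <- coords[, k, ] * box[k]
  names <- paste0("C", seq_len(n_atoms))
  traj <- trajectory(coords, box,
                     atoms = tibble::tibble(name = names, lipid = 1L))
  map <- role_map(tibble::tibble(lipid = 1L, atom = names,
                                 role = "chain_carbon"))
  list(traj = traj, map = map)
}

test_that("uniform atoms give a flat profile within counting noise", {
  sys <- uniform_box_system(4000, c(20, 20, 40), n_frames = 5L)
  w <- full_window(sys$traj)
  ldp <- compute_local_density_profile(sys$traj, sys$map, w, bin_width = 2)
  tot <- ldp[ldp$component == "total" & ldp$block == 0L, ]
  counts_per_bin <- 4000 * 2 / 40          # expected atoms per bin per frame
  sigma <- sqrt(counts_per_bin * 5) / 5    # Poisson, 5 frames
  dev_atoms <- abs(tot$density - mean(tot$density)) *
    (20 * 20 * 2) / 12.011
  expect_lt(max(dev_atoms), 4 * sigma)
})

test_that("density profile conserves total mass", {
  sys <- uniform_box_system(500, c(15, 15, 30), n_frames = 1L)
  w <- analysis_window(sys$traj, 0, 1, blocks = 1)
  ldp <- compute_local_density_profile(sys$traj, sys$map, w,
                                       bin_width = 0.5)
  tot <- ldp[ldp$component == "total" & ldp$block == 0L, ]
  bin_vol <- 15 * 15 * attr(ldp, "bin_width")
  expect_equal(sum(tot$density) * bin_vol, 500 * 12.011,
               tolerance = 1e-9)
})

test_that("a single atom occupies one bin at mass over bin volume", {
  tr <- trajectory(matrix(c(5, 5, 10.2), 1, 3), c(10, 10, 40),
                   atoms = tibble::tibble(name = "C1", lipid = 1L))
  map <- role_map(tibble::tibble(lipid = 1L, atom = "C1",
                                 role = "chain_carbon"))
  ldp <- compute_local_density_profile(tr, map,
                                       analysis_window(tr, 0, 1, 1),
                                       bin_width = 0.5)
  tot <- ldp[ldp$component == "total" & ldp$block == 0L, ]
  expect_equal(sum(tot$density > 0), 1L)
  expect_equal(max(tot$density), 12.011 / (10 * 10 * 0.5))
  expect_equal(tot$z[which.max(tot$density)], 10.25)
})

test_that("bin width sanity checks fire", {
  sys <- uniform_box_system(10, c(10, 10, 20), n_frames = 1L)
  w <- analysis_window(sys$traj, 0, 1, 1)
  expect_error(compute_local_density_profile(sys$traj, sys$map, w, -1),
               "positive")
  expect_error(compute_local_density_profile(sys$traj, sys$map, w, 6),
               "quarter")
})

delta_profile <- function(zpeaks, lz, bin = 0.5) {
  z <- seq(bin / 2, lz - bin / 2, by = bin)
  dens <- numeric(length(z))
  for (zp in zpeaks) dens[which.min(abs(z - zp))] <- 1
  out <- tibble::tibble(z = z, component = "sugar", block = 0L,
                        density = dens)
  attr(out, "lz") <- lz
  out
}

test_that("d-spacing of two delta peaks is their separation", {
  d <- extract_d_spacing(delta_profile(c(0.25, 32.25), 64))
  expect_equal(as.numeric(d), 32, tolerance = 0.5)
})

test_that("d-spacing recovery from the synthetic density generator", {
  for (d_true in c(32.2, 41.9)) {
    dt <- make_density_trajectory(d_true, 2, n_frames = 6L, noise = 0.5,
                                  seed = 17L)
    w <- full_window(dt$trajectory)
    ldp <- compute_local_density_profile(dt$trajectory, dt$map, w, 0.5)
    d <- extract_d_spacing(ldp)
    expect_equal(as.numeric(d), d_true, tolerance = 0.5)
  }
})

test_that("d-spacing is invariant to rigid z translation (modulo box)", {
  dt <- make_density_trajectory(35, 2, n_frames = 4L, seed = 19L)
  w <- full_window(dt$trajectory)
  d0 <- as.numeric(extract_d_spacing(
    compute_local_density_profile(dt$trajectory, dt$map, w, 0.5)))
  shifted <- dt$trajectory
  shifted$coords[, 3, ] <- (shifted$coords[, 3, ] + 13.7) %% 70
  d1 <- as.numeric(extract_d_spacing(
    compute_local_density_profile(shifted, dt$map, w, 0.5)))
  expect_equal(d0, d1, tolerance = 0.5)
})

test_that("flat or single-peak profiles are rejected", {
  flat <- delta_profile(numeric(0), 64)
  flat$density <- rep(1, nrow(flat))
  expect_error(extract_d_spacing(flat), "flat")
  expect_error(extract_d_spacing(delta_profile(10, 64)), "fewer than two")
})

test_that("RDF equals the brute-force pair-count oracle bin for bin", {
  set.seed(41)
  n <- 120
  box <- c(18, 18, 18)
  pts <- array(runif(n * 3 * 5), c(n, 3L, 5L))
  for (k in 1:3) pts[, k, ] <- pts[, k, ] * box[k]
  got <- compute_rdf(pts, box = box, bin_width = 0.25, r_max = 8)
  want <- oracle_rdf(pts, box = box, bin_width = 0.25, r_max = 8)
  expect_equal(got$r, want$r)
  expect_equal(got$g, want$g, tolerance = 1e-12)
  # with intra-group exclusion
  grp <- rep(seq_len(n / 4), each = 4)
  got2 <- compute_rdf(pts, box = box, bin_width = 0.25, r_max = 8,
                      ref_group = grp, target_group = grp)
  want2 <- oracle_rdf(pts, box = box, bin_width = 0.25, r_max = 8,
                      ref_group = grp, target_group = grp)
  expect_equal(got2$g, want2$g, tolerance = 1e-12)
})

test_that("a single pair lands in one bin at the oracle value", {
  pp <- rbind(c(10, 10, 10), c(14, 10, 10))
  r <- compute_rdf(pp, box = c(40, 40, 40), bin_width = 0.1, r_max = 10)
  nz <- which(r$g > 0)
  expect_length(nz, 1L)
  expect_equal(r$r[nz], 4.05)
  expect_equal(r$g[nz], 40^3 / (4 * pi * 4.05^2 * 0.1))
})

test_that("ideal-gas RDF plateaus at one", {
  set.seed(43)
  pts <- matrix(runif(3 * 3000, 0, 25), ncol = 3)
  r <- compute_rdf(pts, box = c(25, 25, 25), bin_width = 0.25, r_max = 10)
  plateau <- r$g[r$r >= 3 & r$r <= 5]
  # normalized pair counts fluctuate as 1/sqrt(pairs per shell)
  n_shell <- 3000 * 4 * pi * mean(plateau) * (3:5 %o% c(1))^2
  expect_lt(abs(mean(plateau) - 1), 0.02)
})

test_that("pair-count conservation: g integrates back to the pair count", {
  set.seed(47)
  pts <- matrix(runif(3 * 300, 0, 12), ncol = 3)
  box <- c(12, 12, 12)
  r <- compute_rdf(pts, box = box, bin_width = 0.2, r_max = 5)
  rho <- (300 - 1) / prod(box)
  dn <- r$g * 4 * pi * r$r^2 * 0.2 * rho
  expect_equal(sum(dn) * 300, attr(r, "mean_pairs"), tolerance = 1e-9)
})

test_that("RDF guards reject invalid setups", {
  pts <- matrix(runif(30, 0, 10), ncol = 3)
  expect_error(compute_rdf(pts, box = c(10, 10, 10), r_max = 6),
               "half the smallest")
  expect_error(compute_rdf(pts[0, , drop = FALSE], box = c(10, 10, 10)),
               "empty selection")
})

test_that("jittered hexagonal slab peaks at the lattice constant", {
  # several independently jittered configurations as frames
  frames <- lapply(1:8, function(s) {
    make_hex_lattice_slab(5.1, 20, jitter = 0.3, seed = 53L + s)$points
  })
  hx <- make_hex_lattice_slab(5.1, 20, jitter = 0.3, seed = 53L)
  pts <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3L, 8L))
  r <- compute_rdf(pts, box = hx$box, bin_width = 0.1, r_max = 12)
  expect_lt(abs(rdf_first_peak(r, r_min = 2) - 5.1), 0.1 + 1e-9)
  # the in-plane normalization flag changes scale, not the peak position
  r2d <- compute_rdf(pts, box = hx$box, bin_width = 0.1, r_max = 12,
                     norm = "2d")
  expect_equal(rdf_first_peak(r2d, r_min = 2), rdf_first_peak(r, r_min = 2))
})

test_that("chain-carbon RDF on an untilted lamella sees the lattice", {
  gen <- small_lamellar(
    n_frames = 4L, xy_jitter = 0.2,
    tilt_modes = tibble::tibble(mean = 0, sd = 0, weight = 1))
  w <- full_window(gen$trajectory)
  r <- rdf_chain_carbon(gen$trajectory, gen$map, "C76", w,
                        bin_width = 0.1, blocks = 2L)
  expect_lt(abs(rdf_first_peak(r, r_min = 3) - 6.28), 0.4)
  expect_true(all(r$g >= 0))
})
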