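test_that("generators are bit-reproducible from their seed", {
  g1 <- small_lamellar(n_frames = 3L, seed = 5L)
  g2 <- small_lamellar(n_frames = 3L, seed = 5L)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  expect_identical(g1$truth$tilt, g2$truth$tilt)
  g3 <- small_lamellar(n_frames = 3L, seed = 6L)
  expect_false(identical(g1$trajectory$coords, g3$trajectory$coords))
})

test_that("all-trans, untilted spec gives exactly trans dihedrals and 0 tilt", {
  gen <- make_lamellar_trajectory(lamellar_spec(
    lipids_per_leaflet = 9L, n_frames = 2L, gauche_p = 0,
    tilt_modes = tibble::tibble(mean = 0, sd = 0, weight = 1), seed = 3L))
  w <- full_window(gen$trajectory)
  ang <- glycolam:::chain_dihedral_angles(gen$trajectory, gen$map, w)
  expect_true(all(abs(abs(ang$angle) - 180) < 1e-8))
  cv <- compute_chain_vectors(gen$trajectory, gen$map, window = w)
  ori <- gen$truth$leaflets$orientation[cv$lipid]
  theta_leaflet <- ifelse(ori == 1L, cv$theta_deg, 180 - cv$theta_deg)
  expect_lt(max(theta_leaflet), 1e-6)
})

test_that("default spec builds 4 leaflets of 64 lipids with matching atoms", {
  gen <- make_lamellar_trajectory(lamellar_spec(n_frames = 1L, seed = 2L))
  expect_equal(nrow(gen$truth$leaflets), 256L)
  expect_equal(unname(table(gen$truth$leaflets$leaflet)),
               rep(64L, 4), ignore_attr = TRUE)
  expect_equal(n_atoms(gen$trajectory), nrow(gen$map$roles))
  # 4 anchors + 12 carbons + 24 hydrogens per lipid
  expect_equal(n_atoms(gen$trajectory) / 256L, 40)
})

test_that("sampled tilts are reproduced exactly by the chain vectors", {
  gen <- small_lamellar(n_frames = 4L, seed = 9L,
                        tilt_modes = tibble::tibble(mean = c(18, 40),
                                                    sd = c(3, 5),
                                                    weight = c(0.7, 0.3)))
  cv <- compute_chain_vectors(gen$trajectory, gen$map,
                              window = full_window(gen$trajectory))
  got <- dplyr::arrange(tibble::as_tibble(cv), .data$frame, .data$lipid)
  want <- dplyr::arrange(gen$truth$tilt, .data$frame, .data$lipid)
  expect_equal(got$theta_deg, want$theta_z, tolerance = 1e-9)
})

test_that("chain overflow beyond the half-box is refused", {
  expect_error(make_lamellar_trajectory(
    lamellar_spec(lipids_per_leaflet = 4L, d_spacing = 20,
                  chain_length = 18L, n_frames = 1L)),
    "half the box")
})

test_that("frozen rotational diffusion keeps vectors constant", {
  vs <- simulate_rotational_diffusion(0, 1, 100, n_vectors = 5, seed = 4L)
  for (v in vs$vectors) {
    expect_equal(v, matrix(v[1, ], 100, 3, byrow = TRUE), tolerance = 1e-14)
  }
})

test_that("rotational diffusion preserves unit norm to 1e-9", {
  vs <- simulate_rotational_diffusion(0.01, 1, 2000, n_vectors = 10,
                                      seed = 8L)
  for (v in vs$vectors) {
    expect_lt(max(abs(sqrt(rowSums(v^2)) - 1)), 1e-9)
  }
})

test_that("too-coarse rotational steps are refused", {
  expect_error(simulate_rotational_diffusion(0.2, 1, 10), "small-angle")
})

test_that("sampled C2 fits exp(-6 D t) (Hotelling goodness-of-fit)", {
  # per-vector C2 values are independent replicates; lags share vectors,
  # so the quadratic-form test must use the empirical lag covariance
  d_r <- 0.002
  vs <- simulate_rotational_diffusion(d_r, 1, 4000, n_vectors = 60,
                                      seed = 12L)
  acf <- compute_acf_p2(vs, max_lag = 120)
  lags <- seq(10, 120, by = 10)
  X <- t(attr(acf, "per_series")[lags + 1, ])
  mu0 <- exp(-6 * d_r * lags)
  n <- nrow(X); p <- ncol(X)
  dbar <- colMeans(X) - mu0
  T2 <- n * drop(t(dbar) %*% solve(stats::cov(X), dbar))
  Fstat <- (n - p) / (p * (n - 1)) * T2
  expect_gt(stats::pf(Fstat, p, n - p, lower.tail = FALSE), 0.01)
})

test_that("jitter-free hexagonal lattice has nearest neighbours at a", {
  hx <- make_hex_lattice_slab(5.1, 6, jitter = 0)
  d2 <- glycolam:::min_image_dist2(hx$points, hx$points, hx$box)
  diag(d2) <- Inf
  nn <- sqrt(apply(d2, 1, min))
  expect_equal(nn, rep(5.1, nrow(hx$points)), tolerance = 1e-9)
})

test_that("density trajectory places head maxima d apart by construction", {
  dt <- make_density_trajectory(32, 1.5, n_frames = 1L, noise = 0,
                                seed = 21L)
  z <- dt$trajectory$coords[grepl("^O", dt$trajectory$atoms$name), 3, 1]
  means <- sort(as.numeric(tapply(z, z > 32, mean)))
  expect_equal(means, c(16, 48), tolerance = 0.01)
  dt2 <- make_density_trajectory(32, 1.5, n_frames = 1L, noise = 0,
                                 seed = 21L)
  expect_identical(dt$trajectory$coords, dt2$trajectory$coords)
})
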