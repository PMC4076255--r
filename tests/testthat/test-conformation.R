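test_that("gauche profile is exactly zero for all-trans chains", {
  gen <- make_lamellar_trajectory(lamellar_spec(
    lipids_per_leaflet = 9L, n_frames = 2L, gauche_p = 0, seed = 13L))
  gp <- compute_gauche_profile(gen$trajectory, gen$map,
                               window = full_window(gen$trajectory))
  expect_true(all(gp$p_gauche == 0))
})

test_that("a 12-carbon chain yields the nine expected dihedral labels", {
  gen <- small_lamellar(n_frames = 1L)
  gp <- compute_gauche_profile(gen$trajectory, gen$map,
                               window = full_window(gen$trajectory))
  labs <- unique(gp$label[gp$label != "chain"])
  expect_equal(sort(labs),
               sort(paste0("C7", 1:9, "-C", 74:82)))
  expect_length(labs, 9L)
})

test_that("per-cell gauche fractions recover Bernoulli ground truth", {
  p_vec <- c(0.14, 0.16, 0.20, 0.40)
  gen <- make_lamellar_trajectory(lamellar_spec(
    lipids_per_leaflet = 16L, n_frames = 120L, gauche_p = p_vec,
    seed = 23L))
  gp <- compute_gauche_profile(gen$trajectory, gen$map,
                               window = full_window(gen$trajectory))
  cells <- gp[gp$label != "chain", ]
  dih_index <- as.integer(substr(cells$label, 3, 3)) - 0  # C71.. -> 1..9
  p_true <- rep_len(p_vec, 9)[dih_index]
  z <- abs(cells$p_gauche - p_true) /
    sqrt(p_true * (1 - p_true) / cells$n)
  expect_lt(max(z), 3)
  # the estimator agrees exactly with the recorded rotamer states
  truth_p <- mean(gen$truth$dihedrals$state != "t")
  expect_equal(gp$p_gauche[gp$label == "chain" & gp$leaflet == 0L],
               truth_p)
})

test_that("gauche bookkeeping is internally consistent", {
  gen <- small_lamellar(n_frames = 3L, gauche_p = 0.3)
  gp <- compute_gauche_profile(gen$trajectory, gen$map,
                               window = full_window(gen$trajectory))
  expect_equal(gp$p_gauche, gp$p_gauche_plus + gp$p_gauche_minus)
  expect_true(all(gp$p_gauche >= 0 & gp$p_gauche <= 1))
  # chain averages lie within the constituent cells, per leaflet
  for (lf in 1:4) {
    cells <- gp$p_gauche[gp$label != "chain" & gp$leaflet == lf]
    avg <- gp$p_gauche[gp$label == "chain" & gp$leaflet == lf]
    expect_gte(avg, min(cells))
    expect_lte(avg, max(cells))
  }
})

straight_chain_traj <- function(theta_deg = 0) {
  # 12 carbons along a direction theta from +z, one lipid
  u <- c(sin(theta_deg * pi / 180), 0, cos(theta_deg * pi / 180))
  pos <- t(sapply(0:11, function(i) c(25, 25, 5) + i * 1.3 * u))
  names <- paste0("C", 71:82)
  traj <- trajectory(pos, c(50, 50, 50),
                     atoms = tibble::tibble(name = names, lipid = 1L))
  map <- role_map(tibble::tibble(lipid = 1L, atom = names,
                                 role = "chain_carbon", chain = "sn1"))
  list(traj = traj, map = map)
}

test_that("chain vectors follow rigid rotations exactly", {
  s0 <- straight_chain_traj(0)
  cv0 <- compute_chain_vectors(s0$traj, s0$map,
                               window = analysis_window(s0$traj, 0, 1, 1))
  expect_equal(c(cv0$vx, cv0$vy, cv0$vz), c(0, 0, 1), tolerance = 1e-12)
  s24 <- straight_chain_traj(24)
  cv24 <- compute_chain_vectors(s24$traj, s24$map,
                                window = analysis_window(s24$traj, 0, 1, 1))
  expect_equal(cv24$theta_deg, 24, tolerance = 1e-9)
})

test_that("coincident midpoints are an error", {
  pos <- matrix(rep(c(1, 1, 1), 12), 12, 3, byrow = TRUE)
  names <- paste0("C", 71:82)
  traj <- trajectory(pos, c(10, 10, 10),
                     atoms = tibble::tibble(name = names, lipid = 1L))
  map <- role_map(tibble::tibble(lipid = 1L, atom = names,
                                 role = "chain_carbon", chain = "sn1"))
  expect_error(compute_chain_vectors(traj, map,
                                     window = analysis_window(traj, 0, 1, 1)),
               "coincident")
})

fake_vectors <- function(theta_deg, lipid = seq_along(theta_deg)) {
  th <- theta_deg * pi / 180
  out <- tibble::tibble(frame = 0L, lipid = lipid,
                        vx = sin(th), vy = 0, vz = cos(th),
                        theta_deg = theta_deg)
  class(out) <- c("glyco_chainvec", class(out))
  out
}

test_that("tilt histogram conserves counts and finds a delta peak", {
  v <- fake_vectors(rep(18, 500))
  td <- compute_tilt_distribution(v, bin_width = 2)
  expect_equal(sum(td$count), 500)
  pk <- tilt_peaks(td)
  expect_equal(pk$theta_deg[1], 19)   # bin center of [18, 20)
  expect_lte(abs(pk$theta_deg[1] - 18), 2)
})

test_that("a vector and its negation have supplementary tilts", {
  set.seed(61)
  v <- matrix(rnorm(300), 100, 3)
  v <- v / sqrt(rowSums(v^2))
  th <- acos(pmin(pmax(v[, 3], -1), 1)) * 180 / pi
  th_neg <- acos(pmin(pmax(-v[, 3], -1), 1)) * 180 / pi
  expect_equal(th + th_neg, rep(180, 100), tolerance = 1e-9)
})

test_that("isotropic vectors give a sin-theta histogram within noise", {
  set.seed(67)
  n <- 40000
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  vv <- fake_vectors(acos(pmin(pmax(v[, 3], -1), 1)) * 180 / pi,
                     lipid = rep(1L, n))
  td <- compute_tilt_distribution(vv, bin_width = 5)
  lo <- (td$bin_center_deg - 2.5) * pi / 180
  hi <- (td$bin_center_deg + 2.5) * pi / 180
  p <- (cos(lo) - cos(hi)) / 2
  z <- (td$count - n * p) / sqrt(n * p * (1 - p))
  expect_lt(max(abs(z)), 4)
})

test_that("bimodal tilt mixtures yield both detected peaks", {
  gen <- make_lamellar_trajectory(lamellar_spec(
    lipids_per_leaflet = 36L, n_frames = 30L,
    tilt_modes = tibble::tibble(mean = c(24, 156), sd = c(3, 3),
                                weight = c(0.5, 0.5)),
    seed = 29L))
  cv <- compute_chain_vectors(gen$trajectory, gen$map,
                              window = full_window(gen$trajectory))
  lf <- assign_leaflets(gen$trajectory, gen$map)
  td <- compute_tilt_distribution(cv, lf, bin_width = 2)
  pk <- tilt_peaks(td)
  for (leaf in 1:4) {
    pks <- sort(pk$theta_deg[pk$leaflet == leaf][1:2])
    expect_lte(abs(pks[1] - 24), 2)
    expect_lte(abs(pks[2] - 156), 2)
  }
})

test_that("protrusion classification covers the trivial regimes", {
  v0 <- fake_vectors(rep(0, 50))
  expect_equal(classify_protruding(v0)$fraction, 0)
  v90 <- fake_vectors(rep(90, 50))
  expect_equal(classify_protruding(v90)$fraction, 1)   # boundary inclusive
  expect_error(classify_protruding(v0, theta_lo = -5), "theta_lo")
})

test_that("protruding fraction recovers the generator flip rate", {
  gen <- make_lamellar_trajectory(lamellar_spec(
    lipids_per_leaflet = 16L, n_frames = 100L, flip_fraction = 0.1,
    seed = 37L))
  cv <- compute_chain_vectors(gen$trajectory, gen$map,
                              window = full_window(gen$trajectory))
  lf <- assign_leaflets(gen$trajectory, gen$map)
  pr <- classify_protruding(cv, lf)
  for (i in seq_len(nrow(pr))) {
    z <- abs(pr$fraction[i] - 0.10) / sqrt(0.1 * 0.9 / pr$n[i])
    expect_lt(z, 3)
  }
  # and the classification matches the recorded flips exactly
  truth_frac <- mean(gen$truth$tilt$flipped)
  overall <- sum(pr$fraction * pr$n) / sum(pr$n)
  expect_equal(overall, truth_frac)
})
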