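test_that("vector series enforce unit norm", {
  good <- matrix(c(1, 0, 0), 5, 3, byrow = TRUE)
  expect_s3_class(vector_series(good), "glyco_vector_series")
  expect_error(vector_series(good * 2), "unit")
})

test_that("C-H mode vectors are normalized bond directions", {
  names <- c("C71", "H71A", "H71B")
  coords <- array(0, c(3, 3, 2))
  coords[1, , ] <- c(5, 5, 5)
  coords[2, , ] <- c(5, 5, 5 + 1.09)
  coords[3, , ] <- c(5 + 1.09, 5, 5)
  traj <- trajectory(coords, c(20, 20, 20),
                     atoms = tibble::tibble(name = names, lipid = 1L))
  map <- role_map(tibble::tibble(
    lipid = 1L, atom = names,
    role = c("chain_carbon", "chain_hydrogen", "chain_hydrogen"),
    parent = c(NA, "C71", "C71"), chain = c("sn1", "sn1", "sn1")))
  vs <- build_vector_series(traj, map, "CH", carbon = "C71",
                            window = analysis_window(traj, 0, 2, 1))
  expect_length(vs$vectors, 2L)   # one series per hydrogen
  expect_equal(vs$vectors[[1]][1, ], c(0, 0, 1))
  expect_equal(vs$vectors[[2]][1, ], c(1, 0, 0))
})

test_that("ring vectors rotate with a rigid headgroup (equivariance)", {
  names <- c("C1", "C4", "C1p", "C4p")
  base <- rbind(c(0, 0, 0), c(2, 1, 2), c(-1, 1, 0.5), c(-3, 2, 2.5))
  R <- glycolam:::rotation_axis_angle(c(1 / sqrt(2), 1 / sqrt(2), 0), 0.7)
  coords <- array(0, c(4, 3, 2))
  coords[, , 1] <- base + 10
  coords[, , 2] <- t(R %*% t(base)) + 10
  traj <- trajectory(coords, c(40, 40, 40),
                     atoms = tibble::tibble(name = names, lipid = 1L))
  map <- role_map(tibble::tibble(lipid = 1L, atom = names,
                                 role = "ring_anchor"))
  w <- analysis_window(traj, 0, 2, 1)
  for (mode in c("ring1", "ring2", "ring12")) {
    vs <- build_vector_series(traj, map, mode, window = w)
    expect_equal(vs$vectors[[1]][2, ],
                 drop(R %*% vs$vectors[[1]][1, ]), tolerance = 1e-12)
  }
})

test_that("C2 is identically one for a frozen vector", {
  v <- matrix(c(0.6, 0.8, 0), 200, 3, byrow = TRUE)
  acf <- compute_acf_p2(v, max_lag = 50)
  expect_equal(acf$c2, rep(1, 51), tolerance = 1e-12)
})

test_that("C2 of i.i.d. random directions vanishes beyond lag zero", {
  set.seed(71)
  mats <- lapply(1:40, function(i) {
    v <- matrix(rnorm(300 * 3), 300, 3)
    v / sqrt(rowSums(v^2))
  })
  acf <- compute_acf_p2(vector_series(mats), max_lag = 20)
  expect_equal(acf$c2[1], 1, tolerance = 1e-12)
  z <- abs(acf$c2[-1]) / acf$c2_se[-1]
  expect_lt(stats::median(z), 3)
  expect_lt(max(abs(acf$c2[-1])), 0.05)
})

test_that("FFT C2 equals the brute-force all-origins double loop", {
  set.seed(73)
  for (n in c(50, 500)) {
    v <- matrix(rnorm(n * 3), n, 3)
    v <- v / sqrt(rowSums(v^2))
    got <- compute_acf_p2(v, max_lag = n - 1)
    want <- oracle_acf_p2(v, n - 1)
    expect_equal(got$c2, want, tolerance = 1e-8)
  }
})

test_that("max lag must be below the series length", {
  v <- matrix(c(1, 0, 0), 10, 3, byrow = TRUE)
  expect_error(compute_acf_p2(v, max_lag = 10), "max lag")
})

test_that("an exact exponential is recovered to three decimals", {
  t <- seq(0, 40000, by = 5)   # ps, like 5 ps archiving over 40 ns
  curve <- tibble::tibble(lag = seq_along(t) - 1L, lag_ps = t,
                          c2 = exp(-t / 10000), c2_se = NA_real_)
  class(curve) <- c("glyco_acf", class(curve))
  attr(curve, "label") <- "exact"
  ft <- fit_correlation_time(curve)
  expect_equal(ft$tau_ns, 10, tolerance = 1e-3)
  expect_equal(ft$tau_analytic_ns, 10, tolerance = 1e-3)
  expect_equal(ft$flag, "ok")
})

test_that("a non-decaying curve is flagged, not silently fitted", {
  t <- seq(0, 500, by = 5)
  curve <- tibble::tibble(lag = seq_along(t) - 1L, lag_ps = t,
                          c2 = rep(1, length(t)), c2_se = NA_real_)
  class(curve) <- c("glyco_acf", class(curve))
  ft <- fit_correlation_time(curve)
  expect_equal(ft$flag, "non_decaying")
})

test_that("correlation-time profile tracks per-carbon diffusion", {
  dr <- seq(0.002, 0.02, length.out = 12)
  sp <- make_spinning_trajectory(d_r_chain = dr, n_lipids = 4L,
                                 n_frames = 1500L, seed = 79L)
  w <- analysis_window(sp$trajectory, 0, 1500, blocks = 1)
  prof <- correlation_time_profile(sp$trajectory, sp$map, w, max_lag = 500)
  chain <- prof[grepl("-H$", prof$label), ]
  expect_equal(nrow(chain), 12L)
  # within 25% of 1/(6 D_r) per carbon, monotone head-to-tail decrease
  expect_lt(max(abs(chain$tau_ns * 1000 - sp$truth$tau_expected_ps) /
                  sp$truth$tau_expected_ps), 0.25)
  expect_lt(stats::cor(seq_len(12), chain$tau_ns, method = "spearman"), -0.9)
  # ring modes present
  expect_true(all(c("ring1", "ring2", "ring12") %in% prof$label))
})

test_that("a single-frame window cannot support correlation analysis", {
  gen <- small_lamellar(n_frames = 1L)
  w <- analysis_window(gen$trajectory, 0, 1, 1)
  expect_error(correlation_time_profile(gen$trajectory, gen$map, w),
               "two frames")
})
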