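# Independent oracles used across tests. These deliberately use the
# slowest, most literal formulation of each quantity.

p2_legendre <- function(x) (3 * x^2 - 1) / 2

# Minimum-image displacement by exhaustive search over all 27 periodic
# images of b.
oracle_min_image <- function(a, b, box) {
  best <- NULL
  best_d <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- (b + c(ix, iy, iz) * box) - a
    if (sum(d^2) < best_d) {
      best_d <- sum(d^2)
      best <- d
    }
  }
  best
}

# Signed torsion by explicit construction of an orthonormal frame around
# the central bond and projection of the outer bonds onto it.
oracle_torsion <- function(p1, p2, p3, p4) {
  u <- p3 - p2
  u <- u / sqrt(sum(u^2))
  a <- (p1 - p2) - sum((p1 - p2) * u) * u
  b <- (p4 - p3) - sum((p4 - p3) * u) * u
  e1 <- a / sqrt(sum(a^2))
  # right-handed in-plane basis (e1, e2) with e2 = e1 x u gives the
  # conventional sign: cis = 0, trans = 180
  e2 <- c(e1[2] * u[3] - e1[3] * u[2],
          e1[3] * u[1] - e1[1] * u[3],
          e1[1] * u[2] - e1[2] * u[1])
  atan2(sum(b * e2), sum(b * e1)) * 180 / pi
}

# Brute-force RDF: double loop over reference/target atoms and frames,
# literal application of the shell normalization.
oracle_rdf <- function(ref, target = NULL, box, bin_width, r_max,
                       ref_group = NULL, target_group = NULL) {
  same <- is.null(target)
  if (same) {
    target <- ref
    target_group <- ref_group
  }
  if (length(dim(ref)) == 2L) ref <- array(ref, dim = c(dim(ref), 1L))
  if (length(dim(target)) == 2L) {
    target <- array(target, dim = c(dim(target), 1L))
  }
  nf <- dim(ref)[3]
  nr <- dim(ref)[1]; nt <- dim(target)[1]
  n_bins <- ceiling(r_max / bin_width)
  counts <- numeric(n_bins)
  rho_acc <- 0
  for (f in seq_len(nf)) {
    bx <- if (is.matrix(box)) box[f, ] else box
    n_elig_tot <- 0
    for (i in seq_len(nr)) for (j in seq_len(nt)) {
      if (same && is.null(ref_group) && i == j) next
      if (!is.null(ref_group) && !is.null(target_group) &&
          ref_group[i] == target_group[j]) next
      n_elig_tot <- n_elig_tot + 1
      d <- target[j, , f] - ref[i, , f]
      d <- d - bx * round(d / bx)
      r <- sqrt(sum(d^2))
      if (r < r_max) {
        k <- min(floor(r / bin_width) + 1, n_bins)
        counts[k] <- counts[k] + 1
      }
    }
    rho_acc <- rho_acc + (n_elig_tot / nr) / prod(bx)
  }
  centers <- (seq_len(n_bins) - 0.5) * bin_width
  dn <- counts / (nr * nf)
  g <- dn / (4 * pi * centers^2 * bin_width * (rho_acc / nf))
  list(r = centers, g = g)
}

# Brute-force all-origins P2 autocorrelation of one unit-vector series.
oracle_acf_p2 <- function(v, max_lag) {
  n <- nrow(v)
  sapply(0:max_lag, function(l) {
    mean(sapply(seq_len(n - l), function(t0) {
      p2_legendre(sum(v[t0, ] * v[t0 + l, ]))
    }))
  })
}

# Small lamellar system shared by several tests.
small_lamellar <- function(n_frames = 5L, seed = 42L, ...) {
  make_lamellar_trajectory(
    lamellar_spec(lipids_per_leaflet = 16L, n_frames = n_frames,
                  seed = seed, ...))
}

full_window <- function(traj, blocks = 1L) {
  analysis_window(traj, 0L, glycolam::n_frames(traj), blocks = blocks)
}
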