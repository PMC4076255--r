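#' Specification for a synthetic lamellar trajectory
#'
#' Describes an anhydrous double-bilayer stack of glycolipids on an in-plane
#' lattice: 4 leaflets of 64 lipids emulate the 256-lipid study system.
#' Chains are built with ideal geometry (1.53 A C-C bonds, 111 degree
#' angles) and per-dihedral trans/gauche+- states drawn independently per
#' frame; whole chains are rigidly rotated to tilt angles sampled from a
#' mixture of Gaussian modes measured from the leaflet chain axis
#' (so a mode at 156 degrees is a "flipped", protruding chain).
#'
#' @param lipids_per_leaflet Lipids per leaflet; must be a perfect square
#'   (placed on a square lattice). Default 64 (an 8 x 8 monolayer).
#' @param n_leaflets Even number of leaflets (default 4: a double bilayer).
#' @param chain_length sn-1 chain carbons (default 12, C71..C82).
#' @param sn2_length sn-2 chain carbons (default 0; 10 gives C83..C92).
#' @param tilt_modes Tibble/data.frame with columns `mean`, `sd` (degrees)
#'   and `weight` (sums to 1): the chain-tilt mixture, relative to the
#'   leaflet chain axis. Default a single mode at 18 degrees, sd 3.
#' @param gauche_p Per-dihedral gauche probability, recycled to the number
#'   of chain dihedrals (`chain_length - 3`). Default 0.16 throughout.
#' @param flip_fraction Probability that a lipid-frame's tilt is mirrored to
#'   `180 - tilt` (a protruding chain). Default 0.
#' @param d_spacing Lamellar repeat distance d in Angstrom (default 32.2).
#' @param lattice_a In-plane square-lattice constant in Angstrom (default
#'   6.28, area per lipid 39.4 A^2).
#' @param head_offset Distance of each leaflet's headgroup plane from the
#'   bilayer interface plane (A, default 1.5).
#' @param head_width Per-lipid Gaussian jitter of the headgroup center
#'   along z (A, default 0.3).
#' @param xy_jitter In-plane Gaussian jitter per lipid-frame (A).
#' @param dihedral_jitter Gaussian jitter (degrees) around the ideal
#'   180/+60/-60 dihedral values (default 0: exact rotamers).
#' @param n_frames,dt_ps Frame count and interval (ps).
#' @param seed Integer seed; the generator is reproducible from it.
#' @return A `lamellar_spec` list.
#' @export
lamellar_spec <- function(lipids_per_leaflet = 64L, n_leaflets = 4L,
                          chain_length = 12L, sn2_length = 0L,
                          tilt_modes = tibble::tibble(mean = 18, sd = 3,
                                                      weight = 1),
                          gauche_p = 0.16, flip_fraction = 0,
                          d_spacing = 32.2, lattice_a = 6.28,
                          head_offset = 1.5, head_width = 0.3,
                          xy_jitter = 0.3, dihedral_jitter = 0,
                          n_frames = 50L, dt_ps = 5, seed = 1L) {
  nx <- sqrt(lipids_per_leaflet)
  if (nx != round(nx)) {
    stop("lipids_per_leaflet must be a perfect square", call. = FALSE)
  }
  if (n_leaflets %% 2L != 0L) stop("n_leaflets must be even", call. = FALSE)
  tilt_modes <- tibble::as_tibble(tilt_modes)
  if (abs(sum(tilt_modes$weight) - 1) > 1e-9) {
    stop("tilt mode weights must sum to 1", call. = FALSE)
  }
  n_dih <- chain_length - 3L
  gauche_p <- rep_len(gauche_p, n_dih)
  if (any(gauche_p < 0 | gauche_p > 1)) {
    stop("gauche probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (d_spacing <= 0 || lattice_a <= 0) {
    stop("spacing and lattice constant must be positive", call. = FALSE)
  }
  structure(as.list(environment()), class = "lamellar_spec")
}

#' Generate a synthetic lamellar trajectory with ground truth
#'
#' Builds the trajectory described by a [lamellar_spec()]: lipids on a
#' square lattice per leaflet, chains grown carbon-by-carbon from sampled
#' rotamer states, rigidly rotated to sampled tilt angles, headgroup ring
#' anchors in a slab at each lamellar interface. The returned ground truth
#' records every sampled tilt, rotamer state and leaflet label, so expected
#' values of all downstream estimators are known without re-simulation.
#'
#' @param spec A `lamellar_spec`.
#' @return List with elements `trajectory` (a `glyco_trajectory`), `map`
#'   (a `glyco_rolemap`), and `truth` (list of tibbles `leaflets`, `tilt`,
#'   `dihedrals`, plus the `spec`).
#' @export
make_lamellar_trajectory <- function(spec) {
  stopifnot(inherits(spec, "lamellar_spec"))
  with_seed(spec$seed, build_lamellar(spec))
}

build_lamellar <- function(spec) {
  nx <- as.integer(sqrt(spec$lipids_per_leaflet))
  n_lip <- spec$lipids_per_leaflet * spec$n_leaflets
  n_bilayers <- spec$n_leaflets %/% 2L
  lx <- nx * spec$lattice_a
  lz <- n_bilayers * spec$d_spacing
  box <- c(lx, lx, lz)
  chain_len_A <- (spec$chain_length - 1) * 1.53 * sin(deg2rad(111) / 2)
  if (chain_len_A > lz / 2) {
    stop("chain longer than half the box height; increase d_spacing",
         call. = FALSE)
  }
  map <- standard_role_map(n_lip, spec$chain_length, spec$sn2_length)
  tmpl <- lipid_template(spec$chain_length, spec$sn2_length)
  atoms_per_lipid <- nrow(tmpl)
  atoms <- tibble::tibble(
    name = rep(tmpl$atom, n_lip),
    lipid = rep(seq_len(n_lip), each = atoms_per_lipid))

  # static per-lipid layout: leaflet, lattice site, head plane, orientation
  leaflet <- rep(seq_len(spec$n_leaflets), each = spec$lipids_per_leaflet)
  orientation <- ifelse(leaflet %% 2L == 1L, 1L, -1L)
  bilayer <- (leaflet - 1L) %/% 2L
  head_plane <- ifelse(orientation == 1L,
                       bilayer * spec$d_spacing + spec$head_offset,
                       (bilayer + 1L) * spec$d_spacing - spec$head_offset)
  site <- (seq_len(n_lip) - 1L) %% spec$lipids_per_leaflet
  site_x <- (site %% nx + 0.5) * spec$lattice_a
  site_y <- (site %/% nx + 0.5) * spec$lattice_a

  truth_leaflets <- tibble::tibble(lipid = seq_len(n_lip), leaflet = leaflet,
                                   orientation = orientation)
  chains <- list(list(chain = "sn1", lo = 71L, n = spec$chain_length))
  if (spec$sn2_length > 0L) {
    chains <- c(chains, list(list(chain = "sn2", lo = 83L,
                                  n = spec$sn2_length)))
  }
  n_dih1 <- spec$chain_length - 3L
  coords <- array(0, dim = c(atoms_per_lipid * n_lip, 3L, spec$n_frames))
  tilt_rec <- vector("list", spec$n_frames)
  dih_rec <- vector("list", spec$n_frames)
  # column index of each template atom, per name
  tmpl_idx <- stats::setNames(seq_len(atoms_per_lipid), tmpl$atom)
  # zero-centroid so the per-lipid head center sits on the head plane
  anchor_tmpl <- rbind(C1  = c(0.975, -0.8, -1.575),
                       C4  = c(2.075, 0.4, 0.625),
                       C1p = c(-0.925, -0.2, -0.575),
                       C4p = c(-2.125, 0.6, 1.525))

  for (f in seq_len(spec$n_frames)) {
    frame <- matrix(0, atoms_per_lipid * n_lip, 3L)
    cx <- site_x + stats::rnorm(n_lip, 0, spec$xy_jitter)
    cy <- site_y + stats::rnorm(n_lip, 0, spec$xy_jitter)
    cz <- head_plane + stats::rnorm(n_lip, 0, spec$head_width)
    # headgroup ring anchors: fixed template about the head center
    for (a in rownames(anchor_tmpl)) {
      rows <- (seq_len(n_lip) - 1L) * atoms_per_lipid + tmpl_idx[[a]]
      frame[rows, ] <- cbind(cx + anchor_tmpl[a, 1],
                             cy + anchor_tmpl[a, 2],
                             cz + orientation * anchor_tmpl[a, 3] * -1)
    }
    # sample one tilt per lipid-frame (shared by sn-1 and sn-2)
    tilt <- sample_tilt_mixture(n_lip, spec$tilt_modes)
    flipped <- stats::runif(n_lip) < spec$flip_fraction
    tilt[flipped] <- 180 - tilt[flipped]
    azim <- stats::runif(n_lip, 0, 2 * pi)
    theta_z <- ifelse(orientation == 1L, tilt, 180 - tilt)
    tilt_rec[[f]] <- tibble::tibble(frame = f, lipid = seq_len(n_lip),
                                    tilt_leaflet = tilt, theta_z = theta_z,
                                    flipped = flipped)
    dih_frames <- list()
    for (ch in chains) {
      n_dih <- ch$n - 3L
      p <- rep_len(spec$gauche_p, n_dih)
      state <- matrix(sample_rotamers(n_lip * n_dih, rep(p, each = n_lip)),
                      n_lip, n_dih)
      ang <- rotamer_angle(state) +
        stats::rnorm(n_lip * n_dih, 0, spec$dihedral_jitter)
      pos <- build_chains(n_lip, ch$n, ang)   # list of n_lip x 3, per carbon
      pos <- orient_chains(pos, tilt, azim, orientation, cx, cy, cz,
                           spec$head_offset)
      hyd <- place_hydrogens(pos)
      cn <- paste0("C", seq.int(ch$lo, ch$lo + ch$n - 1L))
      for (i in seq_len(ch$n)) {
        rows <- (seq_len(n_lip) - 1L) * atoms_per_lipid + tmpl_idx[[cn[i]]]
        frame[rows, ] <- pos[[i]]
        nn <- sub("^C", "", cn[i])
        ra <- (seq_len(n_lip) - 1L) * atoms_per_lipid +
          tmpl_idx[[paste0("H", nn, "A")]]
        rb <- (seq_len(n_lip) - 1L) * atoms_per_lipid +
          tmpl_idx[[paste0("H", nn, "B")]]
        frame[ra, ] <- hyd$a[[i]]
        frame[rb, ] <- hyd$b[[i]]
      }
      dih_frames[[ch$chain]] <- tibble::tibble(
        frame = f,
        lipid = rep(seq_len(n_lip), n_dih),
        chain = ch$chain,
        dihedral = rep(seq_len(n_dih), each = n_lip),
        label = rep(paste0("C", seq.int(ch$lo, ch$lo + n_dih - 1L), "-",
                           "C", seq.int(ch$lo + 3L, ch$lo + n_dih + 2L)),
                    each = n_lip),
        state = as.vector(state))
    }
    dih_rec[[f]] <- dplyr::bind_rows(dih_frames)
    coords[, , f] <- frame
  }
  traj <- trajectory(coords, box, time = (seq_len(spec$n_frames) - 1) *
                       spec$dt_ps, atoms = atoms)
  truth <- list(leaflets = truth_leaflets,
                tilt = dplyr::bind_rows(tilt_rec),
                dihedrals = dplyr::bind_rows(dih_rec),
                spec = spec)
  list(trajectory = traj, map = map, truth = truth)
}

# trans with prob 1-p, gauche+ / gauche- with p/2 each
sample_rotamers <- function(n, p) {
  u <- stats::runif(n)
  out <- rep("t", n)
  out[u < p / 2] <- "g+"
  out[u >= p / 2 & u < p] <- "g-"
  out
}

rotamer_angle <- function(state) {
  a <- matrix(180, nrow(state), ncol(state))
  a[state == "g+"] <- 60
  a[state == "g-"] <- -60
  a
}

sample_tilt_mixture <- function(n, modes) {
  comp <- sample.int(nrow(modes), n, replace = TRUE, prob = modes$weight)
  pmin(pmax(stats::rnorm(n, modes$mean[comp], modes$sd[comp]), 0), 180)
}

# Grow all lipids' chains at once with ideal geometry; dihedrals in degrees,
# matrix [n_lipids x (n_carbons - 3)]. Returns list of n_lipids x 3
# matrices, one per carbon, in a local frame with the chain roughly along +z.
build_chains <- function(n_lip, n_carbons, dihedrals) {
  b <- 1.53
  theta <- deg2rad(111)
  pos <- vector("list", n_carbons)
  pos[[1]] <- matrix(0, n_lip, 3L)
  pos[[2]] <- matrix(rep(c(0, 0, b), each = n_lip), n_lip, 3L)
  g <- pi - theta
  pos[[3]] <- pos[[2]] + matrix(rep(b * c(sin(g), 0, cos(g)), each = n_lip),
                                n_lip, 3L)
  if (n_carbons >= 4L) {
    for (i in 4:n_carbons) {
      phi <- deg2rad(dihedrals[, i - 3L])
      A <- pos[[i - 3L]]; B <- pos[[i - 2L]]; C <- pos[[i - 1L]]
      b2 <- C - B
      u2 <- b2 / row_norm(b2)
      n1 <- row_cross(B - A, b2)
      n1 <- n1 / row_norm(n1)
      m1 <- row_cross(n1, u2)
      D <- C + b * (-u2 * cos(theta) +
                      m1 * (sin(theta) * cos(phi)) -
                      n1 * (sin(theta) * sin(phi)))
      pos[[i]] <- D
    }
  }
  pos
}

# Rigidly rotate each chain so its tilt vector (mid C1C2 -> mid C(n-1)Cn)
# points at `tilt` degrees from the leaflet chain axis (orientation * +z),
# then anchor the first midpoint just inside the head plane.
orient_chains <- function(pos, tilt, azim, orientation, cx, cy, cz,
                          stand_off) {
  n_carbons <- length(pos)
  n_lip <- nrow(pos[[1]])
  m1 <- (pos[[1]] + pos[[2]]) / 2
  m2 <- (pos[[n_carbons - 1L]] + pos[[n_carbons]]) / 2
  v <- m2 - m1
  th <- deg2rad(tilt)
  # target direction of the chain vector, measured from the leaflet axis
  tz <- ifelse(orientation == 1L, cos(th), -cos(th))
  tx <- sin(th) * cos(azim)
  ty <- sin(th) * sin(azim)
  target <- cbind(tx, ty, tz)
  anchor <- cbind(cx, cy, cz + orientation * stand_off)
  out <- lapply(pos, function(p) p)
  chain_mat <- matrix(0, n_carbons, 3L)
  for (l in seq_len(n_lip)) {
    R <- rotation_between(v[l, ], target[l, ])
    for (i in seq_len(n_carbons)) chain_mat[i, ] <- pos[[i]][l, ] - m1[l, ]
    rot <- chain_mat %*% t(R)
    for (i in seq_len(n_carbons)) out[[i]][l, ] <- rot[i, ] + anchor[l, ]
  }
  out
}

# Two hydrogens per carbon, perpendicular to the local C-C-C plane; terminal
# carbons borrow the plane of their two nearest neighbours.
place_hydrogens <- function(pos) {
  n <- length(pos)
  half <- deg2rad(109.5 / 2)
  ch <- 1.09
  a <- vector("list", n); b <- vector("list", n)
  for (i in seq_len(n)) {
    p_prev <- pos[[max(1L, i - 1L)]]
    p_next <- pos[[min(n, i + 1L)]]
    if (i == 1L) p_prev <- pos[[3L]]
    if (i == n) p_next <- pos[[n - 2L]]
    u1 <- row_unit(p_prev - pos[[i]])
    u2 <- row_unit(p_next - pos[[i]])
    nrm <- row_unit(row_cross(u1, u2))
    w <- -(u1 + u2)
    w <- w / row_norm(w)
    a[[i]] <- pos[[i]] + ch * (w * cos(half) + nrm * sin(half))
    b[[i]] <- pos[[i]] + ch * (w * cos(half) - nrm * sin(half))
  }
  list(a = a, b = b)
}

#' Simulate isotropic rotational diffusion of unit vectors
#'
#' Rotational Brownian motion: at every step each vector is rotated about a
#' uniformly random axis by a Gaussian angle. Because the chain is Markov
#' and isotropic, the second-rank autocorrelation decays exactly
#' geometrically, one factor `E[P2(cos(step))]` per step; the step-angle
#' variance is calibrated (to leading order `6 * d_r * dt_ps`, i.e. three
#' independent body-axis rotations of variance `2 d_r dt` each) so that
#' this factor equals `exp(-6 * d_r * dt_ps)` exactly. The sampled series
#' therefore obeys the isotropic-diffusion closed form
#' `C2(t) = exp(-6 * d_r * t)` at every lag, which makes the generator the
#' closed-form oracle for ACF and correlation-time estimation.
#'
#' @param d_r Rotational diffusion coefficient (1/ps), >= 0.
#' @param dt_ps Frame interval (ps), > 0.
#' @param n_frames Number of frames.
#' @param n_vectors Number of independent vectors.
#' @param seed Integer seed.
#' @return A `glyco_vector_series`: list of `n_frames x 3` unit-vector
#'   matrices (one per vector), with attributes `dt_ps` and `label`.
#' @export
simulate_rotational_diffusion <- function(d_r, dt_ps, n_frames,
                                          n_vectors = 1L, seed = 1L) {
  stopifnot(d_r >= 0, dt_ps > 0, n_frames >= 1)
  if (d_r * dt_ps > 0.1) {
    stop("d_r * dt_ps > 0.1: the small-angle rotation step is invalid",
         call. = FALSE)
  }
  with_seed(seed, {
    out <- array(0, dim = c(n_frames, 3L, n_vectors))
    v <- random_unit_vectors(n_vectors)
    out[1, , ] <- t(v)
    sd_ang <- calibrate_step_angle(d_r, dt_ps)
    if (n_frames > 1L) {
      for (f in 2:n_frames) {
        if (d_r > 0) {
          k <- random_unit_vectors(n_vectors)
          alpha <- stats::rnorm(n_vectors, 0, sd_ang)
          v <- rotate_rows(v, k, alpha)
          v <- v / row_norm(v)
        }
        out[f, , ] <- t(v)
      }
    }
    vector_series(lapply(seq_len(n_vectors), function(j) out[, , j]),
                  dt_ps = dt_ps, label = "rotdiff")
  })
}

# Step-angle sd such that E[P2(u . u')] over a uniform axis and a Gaussian
# angle N(0, s^2) equals exp(-6 d_r dt). With u.u' = 1 - (1 - cos a) sin^2(psi)
# and psi the axis-vector angle, E[P2] = 0.2 + 0.4 exp(-s^2/2) +
# 0.4 exp(-2 s^2); solve for s. Leading order s^2 = 6 d_r dt.
calibrate_step_angle <- function(d_r, dt_ps) {
  target <- exp(-6 * d_r * dt_ps)
  if (target >= 1) return(0)
  f <- function(s2) 0.2 + 0.4 * exp(-s2 / 2) + 0.4 * exp(-2 * s2) - target
  s2 <- stats::uniroot(f, c(0, 50), tol = 1e-14)$root
  sqrt(s2)
}

# Rodrigues rotation of each row of v about the same-row axis k by alpha.
rotate_rows <- function(v, k, alpha) {
  ca <- cos(alpha); sa <- sin(alpha)
  kv <- rowSums(k * v)
  v * ca + row_cross(k, v) * sa + k * (kv * (1 - ca))
}

random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3L * n), n, 3L)
  m / row_norm(m)
}

#' Hexagonal lattice slab
#'
#' A 2-D hexagonal lattice at fixed z inside a commensurate periodic box
#' (the lattice continues seamlessly across boundaries when `n_side` is
#' even). With small thermal jitter, the first RDF maximum sits at the
#' lattice constant, providing a geometric oracle for the pair-correlation
#' analysis.
#'
#' @param a Lattice constant (A), > 0.
#' @param n_side Points per side (total `n_side^2`).
#' @param jitter Gaussian in-plane jitter sd (A), >= 0.
#' @param seed Integer seed.
#' @return List with `points` (`n_side^2 x 3` matrix) and `box` (lengths).
#' @export
make_hex_lattice_slab <- function(a, n_side, jitter = 0, seed = 1L) {
  stopifnot(a > 0, jitter >= 0, n_side >= 1)
  dy <- a * sqrt(3) / 2
  ij <- expand.grid(i = 0:(n_side - 1L), j = 0:(n_side - 1L))
  x <- (ij$i + 0.5 * (ij$j %% 2L)) * a
  y <- ij$j * dy
  box <- c(n_side * a, n_side * dy, max(n_side * a, n_side * dy))
  pts <- with_seed(seed, cbind(x + stats::rnorm(length(x), 0, jitter),
                               y + stats::rnorm(length(y), 0, jitter),
                               box[3] / 2))
  list(points = pts, box = box)
}

#' Synthetic layered density trajectory
#'
#' Headgroup ("sugar") atoms Gaussian-distributed about planes separated by
#' the repeat distance `d`; chain atoms fill the slabs in between. Provides
#' exact ground truth for local density profiles and d-spacing extraction.
#'
#' @param d Repeat spacing (A); must exceed `2 * head_width`.
#' @param head_width Gaussian sd of the headgroup planes (A).
#' @param n_frames Frames (independent resamples).
#' @param noise Extra per-frame positional jitter sd (A).
#' @param seed Integer seed.
#' @param repeats Number of lamellar repeats stacked along z (box height is
#'   `repeats * d`).
#' @param n_head,n_chain Atoms per repeat in the head planes / chain slabs.
#' @return List with `trajectory` and `map` (heads as `headgroup_atom`,
#'   chain fillers as `chain_carbon`).
#' @export
make_density_trajectory <- function(d, head_width, n_frames = 10L,
                                    noise = 0, seed = 1L, repeats = 2L,
                                    n_head = 400L, n_chain = 600L) {
  stopifnot(d > 2 * head_width, n_frames >= 1, repeats >= 1)
  lz <- repeats * d
  lx <- 30
  n_h <- n_head * repeats
  n_c <- n_chain * repeats
  names_all <- c(paste0("O", seq_len(n_h)), paste0("C", seq_len(n_c)))
  coords <- with_seed(seed, {
    arr <- array(0, dim = c(n_h + n_c, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      plane <- rep(seq_len(repeats) - 0.5, each = n_head) * d
      zh <- (plane + stats::rnorm(n_h, 0, head_width) +
               stats::rnorm(n_h, 0, noise)) %% lz
      slab <- rep(seq_len(repeats) - 0.5, each = n_chain) * d
      zc <- (slab + d / 2 +
               stats::runif(n_c, -(d / 2 - head_width),
                            d / 2 - head_width) +
               stats::rnorm(n_c, 0, noise)) %% lz
      arr[, 1, f] <- stats::runif(n_h + n_c, 0, lx)
      arr[, 2, f] <- stats::runif(n_h + n_c, 0, lx)
      arr[, 3, f] <- c(zh, zc)
    }
    arr
  })
  traj <- trajectory(coords, c(lx, lx, lz),
                     atoms = tibble::tibble(name = names_all, lipid = 1L))
  roles <- tibble::tibble(
    lipid = 1L, atom = names_all,
    role = rep(c("headgroup_atom", "chain_carbon"), c(n_h, n_c)))
  list(trajectory = traj, map = role_map(roles))
}

#' Trajectory whose C-H and ring vectors undergo rotational diffusion
#'
#' A validation scaffold for per-carbon correlation-time profiles: chain
#' carbons sit at fixed positions while each carbon's C-H unit vector (and
#' each headgroup ring vector) performs isotropic rotational diffusion with
#' a prescribed, possibly carbon-dependent, diffusion coefficient. The
#' expected correlation time per carbon is `1 / (6 d_r)`.
#'
#' @param d_r_chain Vector of rotational diffusion coefficients (1/ps), one
#'   per chain carbon (recycled to `chain_length`).
#' @param d_r_ring Diffusion coefficient of the ring vectors.
#' @param n_lipids,n_frames,dt_ps,seed Simulation dimensions.
#' @param chain_length Chain carbons (default 12).
#' @return List with `trajectory`, `map`, `truth` (tibble of `carbon`,
#'   `d_r`, `tau_expected_ps`).
#' @export
make_spinning_trajectory <- function(d_r_chain, d_r_ring = NULL,
                                     n_lipids = 8L, n_frames = 2000L,
                                     dt_ps = 1, seed = 1L,
                                     chain_length = 12L) {
  d_r_chain <- rep_len(d_r_chain, chain_length)
  if (is.null(d_r_ring)) d_r_ring <- d_r_chain[1]
  map <- standard_role_map(n_lipids, chain_length)
  tmpl <- lipid_template(chain_length)
  apl <- nrow(tmpl)
  atoms <- tibble::tibble(name = rep(tmpl$atom, n_lipids),
                          lipid = rep(seq_len(n_lipids), each = apl))
  tmpl_idx <- stats::setNames(seq_len(apl), tmpl$atom)
  box <- c(100, 100, 100)
  coords <- array(0, dim = c(apl * n_lipids, 3L, n_frames))
  # static skeleton: carbons on a line per lipid, anchors near the top
  for (l in seq_len(n_lipids)) {
    base <- (l - 1L) * apl
    ox <- 10 * l
    for (i in seq_len(chain_length)) {
      coords[base + tmpl_idx[[paste0("C", 70L + i)]], , ] <-
        c(ox, 10, 50 - 1.3 * i)
    }
    coords[base + tmpl_idx[["C1"]], , ] <- c(ox, 10, 55)
    coords[base + tmpl_idx[["C1p"]], , ] <- c(ox, 12, 58)
  }
  sub_seed <- function(k) (seed * 1000L + k) %% .Machine$integer.max
  k <- 0L
  for (l in seq_len(n_lipids)) {
    base <- (l - 1L) * apl
    for (i in seq_len(chain_length)) {
      k <- k + 1L
      vs <- simulate_rotational_diffusion(d_r_chain[i], dt_ps, n_frames,
                                          n_vectors = 1L,
                                          seed = sub_seed(k))
      u <- vs$vectors[[1]]
      ci <- coords[base + tmpl_idx[[paste0("C", 70L + i)]], , 1]
      nn <- 70L + i
      # target slice is 3 x n_frames; ci recycles down columns
      coords[base + tmpl_idx[[paste0("H", nn, "A")]], , ] <- ci + 1.09 * t(u)
      coords[base + tmpl_idx[[paste0("H", nn, "B")]], , ] <- ci - 1.09 * t(u)
    }
    # ring vectors: C4 diffuses about C1, C4p about C1p
    k <- k + 1L
    u1 <- simulate_rotational_diffusion(d_r_ring, dt_ps, n_frames, 1L,
                                        seed = sub_seed(k))$vectors[[1]]
    k <- k + 1L
    u2 <- simulate_rotational_diffusion(d_r_ring, dt_ps, n_frames, 1L,
                                        seed = sub_seed(k))$vectors[[1]]
    c1 <- coords[base + tmpl_idx[["C1"]], , 1]
    c1p <- coords[base + tmpl_idx[["C1p"]], , 1]
    coords[base + tmpl_idx[["C4"]], , ] <- c1 + 2.9 * t(u1)
    coords[base + tmpl_idx[["C4p"]], , ] <- c1p + 2.9 * t(u2)
  }
  truth <- tibble::tibble(carbon = paste0("C", 70L + seq_len(chain_length)),
                          d_r = d_r_chain,
                          tau_expected_ps = 1 / (6 * d_r_chain))
  traj <- trajectory(coords, box, time = (seq_len(n_frames) - 1) * dt_ps,
                     atoms = atoms)
  list(trajectory = traj, map = map, truth = truth)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
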