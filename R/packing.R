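#' Area per lipid time series
#'
#' The interfacial area per lipid is the x-y face of the box divided by the
#' number of lipids in one leaflet, per frame; the window mean is reported
#' with a block-average standard error.
#'
#' @param traj A `glyco_trajectory`.
#' @param lipids_per_leaflet Lipids in one leaflet (> 0).
#' @param window An [analysis_window()]; default is the trajectory's
#'   standard window (first 20% of frames discarded, 5 blocks).
#' @return A tibble of class `glyco_area` with columns `frame` (0-based),
#'   `time_ps`, `area_A2`, and attributes `mean`, `se`, `blocks`.
#' @examples
#' tr <- trajectory(matrix(0, 1, 3), box = c(50, 50, 40))
#' compute_area_per_lipid(tr, 64, analysis_window(tr, 0, 1, blocks = 1))
#' @export
compute_area_per_lipid <- function(traj, lipids_per_leaflet,
                                   window = analysis_window(traj)) {
  stopifnot(lipids_per_leaflet > 0)
  f <- window$frames
  a <- traj$box[f, 1] * traj$box[f, 2] / lipids_per_leaflet
  blk <- window_block_id(window)
  bm <- tapply(a, blk, mean)
  se <- if (window$blocks > 1L) stats::sd(bm) / sqrt(window$blocks) else 0
  out <- tibble::tibble(frame = f - 1L, time_ps = traj$time[f], area_A2 = a)
  class(out) <- c("glyco_area", class(out))
  attr(out, "mean") <- mean(a)
  attr(out, "se") <- unname(se)
  attr(out, "blocks") <- window$blocks
  out
}

#' Block-averaged local density profile along z
#'
#' Mass density (amu per cubic Angstrom) histogrammed along the layer
#' normal, split into sugar (headgroup + ring anchors), chain (carbons +
#' hydrogens) and total components. The window is divided into contiguous
#' blocks (default 5, the convention of averaging five block averages), and
#' both per-block and block-averaged profiles are returned. z is wrapped
#' into `[0, Lz)` of each frame's box; the bin grid uses the window-mean Lz.
#'
#' @param traj A `glyco_trajectory`.
#' @param map A `glyco_rolemap`.
#' @param window An [analysis_window()].
#' @param bin_width Bin width along z (A), must be positive and at most a
#'   quarter of the box height.
#' @return A tibble of class `glyco_ldp`: columns `z`, `component`,
#'   `block` (`0` = block average), `density`; attributes `bin_width`,
#'   `lz`, `blocks`.
#' @export
compute_local_density_profile <- function(traj, map,
                                          window = analysis_window(traj),
                                          bin_width = 0.5) {
  lz <- mean(traj$box[window$frames, 3])
  if (bin_width <= 0) stop("bin width must be positive", call. = FALSE)
  if (bin_width > lz / 4) {
    stop("bin width exceeds a quarter of the box height", call. = FALSE)
  }
  resolved <- resolve_atoms(traj, map)
  comp_of <- c(ring_anchor = "sugar", headgroup_atom = "sugar",
               chain_carbon = "chain", chain_hydrogen = "chain",
               other = "other")
  resolved$component <- comp_of[resolved$role]
  resolved$mass <- atom_mass(resolved$atom)
  n_bins <- max(1L, round(lz / bin_width))
  edges <- seq(0, lz, length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  blk <- window_block_id(window)
  comps <- intersect(c("sugar", "chain"), unique(resolved$component))
  acc <- array(0, dim = c(n_bins, length(comps) + 1L, window$blocks),
               dimnames = list(NULL, c(comps, "total"), NULL))
  nfrm <- tabulate(blk, nbins = window$blocks)
  for (j in seq_along(window$frames)) {
    f <- window$frames[j]
    box <- traj$box[f, ]
    vol_bin <- box[1] * box[2] * (lz / n_bins)
    z <- (traj$coords[resolved$atom_index, 3, f] %% box[3]) * (lz / box[3])
    bin <- pmin(pmax(floor(z / lz * n_bins) + 1L, 1L), n_bins)
    for (cm in comps) {
      sel <- resolved$component == cm
      h <- unname(tapply(resolved$mass[sel], bin[sel], sum))
      acc[sort(unique(bin[sel])), cm, blk[j]] <-
        acc[sort(unique(bin[sel])), cm, blk[j]] + h / vol_bin
    }
    ht <- unname(tapply(resolved$mass, bin, sum))
    acc[sort(unique(bin)), "total", blk[j]] <-
      acc[sort(unique(bin)), "total", blk[j]] + ht / vol_bin
  }
  for (b in seq_len(window$blocks)) acc[, , b] <- acc[, , b] / nfrm[b]
  avg <- apply(acc, c(1, 2), mean)
  rows <- list()
  for (cm in colnames(avg)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      z = centers, component = cm, block = 0L, density = avg[, cm])
    for (b in seq_len(window$blocks)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        z = centers, component = cm, block = b, density = acc[, cm, b])
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("glyco_ldp", class(out))
  attr(out, "bin_width") <- lz / n_bins
  attr(out, "lz") <- lz
  attr(out, "blocks") <- window$blocks
  out
}

#' Extract the lamellar d-spacing from a density profile
#'
#' The repeat distance is taken as the mean separation of consecutive
#' headgroup-density maxima, treating the profile as periodic in z. Peaks
#' are local maxima of the 3-bin moving-averaged profile that reach at
#' least `min_height` of the global maximum, refined by parabolic
#' interpolation; separations are measured circularly.
#'
#' @param profile A `glyco_ldp` (the block-average rows are used), or any
#'   tibble with `z`, `component`, `block`, `density`.
#' @param component Which density component carries the headgroup peaks.
#' @param min_height Relative peak height threshold (fraction of max).
#' @param min_separation Maxima closer than this (A) are treated as
#'   substructure of one headgroup region and merged, keeping the higher;
#'   the default (5 A) is far below any lamellar repeat of interest but
#'   above the width of intra-region features.
#' @return d-spacing in Angstrom (scalar), with attribute `peaks_z`.
#' @export
extract_d_spacing <- function(profile, component = "sugar",
                              min_height = 0.5, min_separation = 5) {
  p <- profile[profile$component == component & profile$block == 0L, ]
  if (!nrow(p)) stop("profile lacks component ", component, call. = FALSE)
  lz <- attr(profile, "lz") %||% (max(p$z) + min(p$z))
  y <- p$density
  if (max(y) <= 0 || stats::sd(y) < 1e-12) {
    stop("flat density profile: no headgroup maxima to measure",
         call. = FALSE)
  }
  peaks <- periodic_peaks(p$z, y, lz, min_height, min_separation)
  if (length(peaks) < 2L) {
    stop("fewer than two headgroup maxima; cannot measure a repeat distance",
         call. = FALSE)
  }
  ps <- sort(peaks)
  sep <- diff(c(ps, ps[1] + lz))
  d <- mean(sep)
  attr(d, "peaks_z") <- ps
  d
}

# Local maxima of a periodic profile after 3-bin circular smoothing, with
# parabolic sub-bin refinement. Flat-topped maxima (plateaus created by the
# smoothing) are collapsed to the bin with the highest raw density, and
# maxima closer than `min_sep` (noise splitting one physical peak) are
# merged, keeping the higher.
periodic_peaks <- function(z, y, lz, min_height, min_sep = 2.5) {
  n <- length(y)
  ys <- (y + y[c(n, 1:(n - 1))] + y[c(2:n, 1)]) / 3
  prev <- ys[c(n, 1:(n - 1))]
  nxt <- ys[c(2:n, 1)]
  cand <- which(ys >= prev & ys >= nxt & ys >= min_height * max(ys))
  idx <- collapse_plateaus(cand, y, n, circular = TRUE)
  if (!length(idx)) return(numeric())
  # greedy merge: keep the strongest of any pair closer than min_sep
  idx <- idx[order(ys[idx], decreasing = TRUE)]
  dz <- lz / n
  kept <- integer()
  for (i in idx) {
    circ <- abs(z[i] - z[kept])
    circ <- pmin(circ, lz - circ)
    if (!length(kept) || all(circ >= min_sep)) kept <- c(kept, i)
  }
  vapply(sort(kept), function(i) {
    ym <- ys[if (i == 1L) n else i - 1L]
    yp <- ys[if (i == n) 1L else i + 1L]
    denom <- ym - 2 * ys[i] + yp
    off <- if (abs(denom) < 1e-15) 0 else 0.5 * (ym - yp) / denom
    off <- max(-0.5, min(0.5, off))
    (z[i] + off * dz) %% lz
  }, numeric(1))
}

# Group runs of adjacent candidate bins and keep, per run, the bin with the
# highest raw value (ties resolve to the run centre).
collapse_plateaus <- function(cand, raw, n, circular = FALSE) {
  if (!length(cand)) return(integer())
  runs <- split(cand, cumsum(c(1L, diff(cand) != 1L)))
  if (circular && length(runs) > 1L) {
    first <- runs[[1]]; last <- runs[[length(runs)]]
    if (first[1] == 1L && last[length(last)] == n) {
      runs[[1]] <- c(last, first)
      runs[[length(runs)]] <- NULL
    }
  }
  out <- vapply(runs, function(r) {
    best <- r[raw[r] == max(raw[r])]
    best[ceiling(length(best) / 2)]
  }, integer(1))
  sort(unique(out))
}

#' Radial distribution function under periodic boundaries
#'
#' Pair correlation `g(r) = <dN(r, r + dr)> / (4 pi r^2 dr rho)`, where
#' `dN` is the number of target atoms in the spherical shell at distance r
#' from a reference atom (minimum-image convention) and `rho` is the target
#' number density. Averages run over reference atoms and frames; contiguous
#' frame blocks give per-block curves for error estimates. Because chain
#' packing in a lamella is quasi-two-dimensional, an alternative in-plane
#' normalization (`2 pi r dr` times the areal density) is available via
#' `norm = "2d"`; the spherical form is the default.
#'
#' @param ref,target Reference / target positions: an `n x 3` matrix (one
#'   frame) or an `n x 3 x frames` array. `target` defaults to `ref`.
#' @param box Box lengths, a length-3 vector or per-frame matrix.
#' @param bin_width Shell thickness dr (A).
#' @param r_max Maximum distance; must not exceed half the smallest box
#'   length.
#' @param blocks Number of frame blocks for error bars.
#' @param ref_group,target_group Optional group ids (e.g. lipid index);
#'   pairs sharing a group are excluded (intra-lipid exclusion). When the
#'   selections are identical and no groups are given, self pairs are
#'   excluded.
#' @param norm `"3d"` (spherical shells) or `"2d"` (in-plane annuli).
#' @return Tibble of class `glyco_rdf`: `r`, `g`, `g_block_sd`, plus
#'   per-block columns in attribute `blocks_g`; attributes `bin_width`,
#'   `norm`, `mean_pairs` (mean pair count within `r_max` per frame).
#' @export
compute_rdf <- function(ref, target = NULL, box, bin_width = 0.1,
                        r_max = NULL, blocks = 1L, ref_group = NULL,
                        target_group = NULL, norm = c("3d", "2d")) {
  norm <- match.arg(norm)
  same_sel <- is.null(target)
  if (same_sel) {
    target <- ref
    target_group <- ref_group
  }
  if (length(dim(ref)) == 2L) ref <- array(ref, dim = c(dim(ref), 1L))
  if (length(dim(target)) == 2L) {
    target <- array(target, dim = c(dim(target), 1L))
  }
  nf <- dim(ref)[3]
  if (is.null(dim(box))) box <- matrix(box, nf, 3L, byrow = TRUE)
  if (dim(ref)[1] == 0L || dim(target)[1] == 0L) {
    stop("empty selection for RDF", call. = FALSE)
  }
  if (is.null(r_max)) r_max <- min(box) / 2
  if (r_max > min(box) / 2 + 1e-9) {
    stop("r_max exceeds half the smallest box length", call. = FALSE)
  }
  if (bin_width <= 0) stop("bin width must be positive", call. = FALSE)
  n_bins <- ceiling(r_max / bin_width)
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nr <- dim(ref)[1]; nt <- dim(target)[1]
  blocks <- max(1L, min(as.integer(blocks), nf))
  blk <- pmin(((seq_len(nf) - 1L) %/% (nf %/% blocks)) + 1L, blocks)
  counts <- matrix(0, n_bins, blocks)       # sum of dN over frames, per block
  denom_frames <- numeric(blocks)
  rho_sum <- numeric(blocks)
  pair_total <- 0
  for (f in seq_len(nf)) {
    bx <- box[f, ]
    d2 <- min_image_dist2(matrix(ref[, , f], ncol = 3L),
                          matrix(target[, , f], ncol = 3L), bx)
    excl <- if (!is.null(ref_group) && !is.null(target_group)) {
      outer(ref_group, target_group, "==")
    } else if (same_sel) {
      diag(TRUE, nr, nt)
    } else {
      matrix(FALSE, nr, nt)
    }
    d <- sqrt(d2[!excl])
    d <- d[d < r_max]
    pair_total <- pair_total + length(d)
    h <- tabulate(pmin(floor(d / bin_width) + 1L, n_bins), nbins = n_bins)
    counts[, blk[f]] <- counts[, blk[f]] + h / nr
    n_elig <- (nr * nt - sum(excl)) / nr
    vol <- if (norm == "3d") prod(bx) else bx[1] * bx[2]
    rho_sum[blk[f]] <- rho_sum[blk[f]] + n_elig / vol
    denom_frames[blk[f]] <- denom_frames[blk[f]] + 1
  }
  shell <- if (norm == "3d") 4 * pi * centers^2 * bin_width else
    2 * pi * centers * bin_width
  g_blocks <- sapply(seq_len(blocks), function(b) {
    dn <- counts[, b] / denom_frames[b]
    rho <- rho_sum[b] / denom_frames[b]
    dn / (shell * rho)
  })
  g_blocks <- matrix(g_blocks, n_bins, blocks)
  w <- denom_frames / sum(denom_frames)
  g <- drop(g_blocks %*% w)
  g_sd <- if (blocks > 1L) apply(g_blocks, 1L, stats::sd) else
    rep(NA_real_, n_bins)
  out <- tibble::tibble(r = centers, g = g, g_block_sd = g_sd)
  class(out) <- c("glyco_rdf", class(out))
  attr(out, "bin_width") <- bin_width
  attr(out, "norm") <- norm
  attr(out, "blocks_g") <- g_blocks
  attr(out, "mean_pairs") <- pair_total / nf
  out
}

# Squared minimum-image distances between all rows of a and b (orthorhombic).
min_image_dist2 <- function(a, b, box) {
  tot <- 0
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    tot <- tot + dk * dk
  }
  tot
}

#' RDF of a chain carbon across lipids
#'
#' Convenience wrapper: selects one named chain carbon (e.g. "C72", "C76",
#' "C81") on every lipid and computes its RDF against the same carbon on
#' neighbouring lipids (intra-lipid pairs excluded).
#'
#' @param traj A `glyco_trajectory`.
#' @param map A `glyco_rolemap`.
#' @param carbon Atom name of the chain carbon.
#' @param window An [analysis_window()].
#' @inheritParams compute_rdf
#' @return A `glyco_rdf` tibble (see [compute_rdf()]).
#' @export
rdf_chain_carbon <- function(traj, map, carbon = "C72",
                             window = analysis_window(traj),
                             bin_width = 0.1, r_max = NULL, blocks = 1L,
                             norm = "3d") {
  resolved <- resolve_atoms(traj, map)
  idx <- atom_index_by_lipid(resolved, carbon)
  lip <- sort(unique(resolved$lipid))
  pts <- traj$coords[idx, , window$frames, drop = FALSE]
  compute_rdf(pts, box = traj$box[window$frames, , drop = FALSE],
              bin_width = bin_width, r_max = r_max, blocks = blocks,
              ref_group = lip, target_group = lip, norm = norm)
}

#' First-maximum position of an RDF
#'
#' @param rdf A `glyco_rdf`.
#' @param r_min Ignore bins below this distance (excludes bonded contacts).
#' @return Bin-center position (A) of the global maximum of g(r) at
#'   `r >= r_min`.
#' @export
rdf_first_peak <- function(rdf, r_min = 0) {
  keep <- rdf$r >= r_min
  rdf$r[keep][which.max(rdf$g[keep])]
}
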