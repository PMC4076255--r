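#' Classify a torsion angle as trans or gauche
#'
#' Three-fold symmetric split, the standard alkane convention: trans when
#' `|theta| >= 120` degrees (the boundary 120 counts as trans), gauche+
#' for `0 < theta < 120`, gauche- otherwise.
#'
#' @param theta Angle(s) in degrees in `(-180, 180]`.
#' @return Character vector in `c("trans", "gauche_plus", "gauche_minus")`.
#' @examples
#' classify_conformer(c(180, 60, -60, 120))
#' @export
classify_conformer <- function(theta) {
  out <- rep("gauche_minus", length(theta))
  out[abs(theta) >= 120] <- "trans"
  out[theta > 0 & theta < 120] <- "gauche_plus"
  out
}

# All chain dihedral angles of the trajectory in one long tibble:
# frame, lipid, chain, label, angle. Vectorized over lipids and frames.
chain_dihedral_angles <- function(traj, map, window = analysis_window(traj),
                                  chain = c("sn1", "sn2")) {
  chain <- match.arg(chain)
  resolved <- resolve_atoms(traj, map)
  cc <- resolved[resolved$role == "chain_carbon" & resolved$chain == chain, ]
  if (!nrow(cc)) stop("no ", chain, " chain carbons in role map",
                      call. = FALSE)
  cc$num <- as.integer(sub("^C", "", cc$atom))
  cc <- cc[order(cc$lipid, cc$num), ]
  nums <- sort(unique(cc$num))
  n_c <- length(nums)
  if (n_c < 4L) stop("chain too short for dihedrals", call. = FALSE)
  lipids <- sort(unique(cc$lipid))
  n_l <- length(lipids)
  idx <- matrix(cc$atom_index, n_c, n_l)   # carbons x lipids (ordered)
  fr <- window$frames
  out <- vector("list", n_c - 3L)
  for (k in seq_len(n_c - 3L)) {
    p <- lapply(0:3, function(o) {
      m <- traj$coords[idx[k + o, ], , fr, drop = FALSE]
      matrix(aperm(m, c(1, 3, 2)), ncol = 3L)   # (lipid x frame) rows
    })
    ang <- compute_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    out[[k]] <- tibble::tibble(
      frame = rep(fr - 1L, each = n_l),
      lipid = rep(lipids, length(fr)),
      chain = chain,
      label = paste0("C", nums[k], "-C", nums[k + 3L]),
      angle = ang)
  }
  dplyr::bind_rows(out)
}

#' Per-dihedral, per-leaflet gauche populations
#'
#' For every chain dihedral (labelled by its outer carbons, e.g. "C71-C74"
#' for the torsion C71-C72-C73-C74) the fraction of lipid-frames classified
#' gauche (gauche+ and gauche- pooled), resolved by leaflet, with a
#' binomial standard error. Chain-average rows (`label = "chain"`) per
#' leaflet and the overall chain average (`leaflet = 0`) are appended.
#'
#' @param traj A `glyco_trajectory`.
#' @param map A `glyco_rolemap`.
#' @param leaflets A `glyco_leaflets` from [assign_leaflets()] (computed on
#'   the first window frame if omitted).
#' @param window An [analysis_window()].
#' @param chain `"sn1"` or `"sn2"`.
#' @return Tibble of class `glyco_gauche`: `label`, `leaflet`, `p_gauche`,
#'   `p_gauche_plus`, `p_gauche_minus`, `se`, `n`.
#' @export
compute_gauche_profile <- function(traj, map, leaflets = NULL,
                                   window = analysis_window(traj),
                                   chain = "sn1") {
  if (is.null(leaflets)) {
    leaflets <- assign_leaflets(traj, map, frame = window$frames[1])
  }
  ang <- chain_dihedral_angles(traj, map, window, chain)
  ang$state <- classify_conformer(ang$angle)
  ang$leaflet <- leaflets$assignment$leaflet[
    match(ang$lipid, leaflets$assignment$lipid)]
  cell <- ang |>
    dplyr::summarise(
      p_gauche = mean(.data$state != "trans"),
      p_gauche_plus = mean(.data$state == "gauche_plus"),
      p_gauche_minus = mean(.data$state == "gauche_minus"),
      n = dplyr::n(),
      .by = c("label", "leaflet"))
  chain_avg <- ang |>
    dplyr::summarise(
      p_gauche = mean(.data$state != "trans"),
      p_gauche_plus = mean(.data$state == "gauche_plus"),
      p_gauche_minus = mean(.data$state == "gauche_minus"),
      n = dplyr::n(),
      .by = "leaflet") |>
    dplyr::mutate(label = "chain")
  overall <- ang |>
    dplyr::summarise(
      p_gauche = mean(.data$state != "trans"),
      p_gauche_plus = mean(.data$state == "gauche_plus"),
      p_gauche_minus = mean(.data$state == "gauche_minus"),
      n = dplyr::n()) |>
    dplyr::mutate(label = "chain", leaflet = 0L)
  out <- dplyr::bind_rows(cell, chain_avg, overall) |>
    dplyr::mutate(se = sqrt(.data$p_gauche * (1 - .data$p_gauche) /
                              .data$n)) |>
    dplyr::select("label", "leaflet", "p_gauche", "p_gauche_plus",
                  "p_gauche_minus", "se", "n") |>
    dplyr::arrange(.data$leaflet, .data$label)
  class(out) <- c("glyco_gauche", class(out))
  attr(out, "chain") <- chain
  out
}

#' Chain tilt vectors
#'
#' The chain vector runs from the midpoint of the first two chain carbons
#' to the midpoint of the last two: C71-C72 to C81-C82 for a 12-carbon
#' sn-1 chain, C83-C84 to C91-C92 for a 10-carbon sn-2 chain. Vectors are
#' normalized; the tilt angle is measured against the fixed +z layer
#' normal.
#'
#' @param traj A `glyco_trajectory`.
#' @param map A `glyco_rolemap`.
#' @param chain `"sn1"` or `"sn2"`.
#' @param window An [analysis_window()].
#' @return Tibble of class `glyco_chainvec`: `frame` (0-based), `lipid`,
#'   `vx`, `vy`, `vz` (unit vector), `theta_deg` (angle to +z).
#' @export
compute_chain_vectors <- function(traj, map, chain = "sn1",
                                  window = analysis_window(traj)) {
  resolved <- resolve_atoms(traj, map)
  cc <- resolved[resolved$role == "chain_carbon" & resolved$chain == chain, ]
  if (!nrow(cc)) stop("no ", chain, " chain carbons in role map",
                      call. = FALSE)
  cc$num <- as.integer(sub("^C", "", cc$atom))
  nums <- sort(unique(cc$num))
  pick <- function(nn) {
    r <- cc[cc$num == nn, ]
    r$atom_index[order(r$lipid)]
  }
  lipids <- sort(unique(cc$lipid))
  i1 <- pick(nums[1]); i2 <- pick(nums[2])
  i3 <- pick(nums[length(nums) - 1L]); i4 <- pick(nums[length(nums)])
  fr <- window$frames
  flat <- function(ii) {
    m <- traj$coords[ii, , fr, drop = FALSE]
    matrix(aperm(m, c(1, 3, 2)), ncol = 3L)
  }
  m1 <- (flat(i1) + flat(i2)) / 2
  m2 <- (flat(i3) + flat(i4)) / 2
  v <- m2 - m1
  nrm <- row_norm(v)
  if (any(nrm < 1e-8)) {
    stop("coincident chain midpoints; chain vector undefined", call. = FALSE)
  }
  v <- v / nrm
  out <- tibble::tibble(
    frame = rep(fr - 1L, each = length(lipids)),
    lipid = rep(lipids, length(fr)),
    vx = v[, 1], vy = v[, 2], vz = v[, 3],
    theta_deg = rad2deg(acos(pmin(pmax(v[, 3], -1), 1))))
  class(out) <- c("glyco_chainvec", class(out))
  attr(out, "chain") <- chain
  out
}

#' Chain-tilt histogram with peak detection
#'
#' Histograms the chain-vector angle to +z over `[0, 180]` degrees per
#' leaflet, smooths with a 3-bin moving average and reports local maxima in
#' descending height. Zero degrees means perfect alignment with the layer
#' normal; 180 means a fully flipped chain.
#'
#' @param vectors A `glyco_chainvec` from [compute_chain_vectors()].
#' @param leaflets Optional `glyco_leaflets`; without it all vectors form
#'   one pooled "leaflet" labelled 1.
#' @param bin_width Histogram bin width in degrees (default 2).
#' @param min_height Relative height threshold for reported peaks.
#' @return Tibble of class `glyco_tilt`: `leaflet`, `bin_center_deg`,
#'   `count`; attribute `peaks` is a tibble (`leaflet`, `theta_deg`,
#'   `height`) sorted by descending height within leaflet.
#' @export
compute_tilt_distribution <- function(vectors, leaflets = NULL,
                                      bin_width = 2, min_height = 0.2) {
  stopifnot(nrow(vectors) >= 1L)
  leaf <- if (is.null(leaflets)) rep(1L, nrow(vectors)) else
    leaflets$assignment$leaflet[match(vectors$lipid,
                                      leaflets$assignment$lipid)]
  n_bins <- ceiling(180 / bin_width)
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- pmin(floor(vectors$theta_deg / bin_width) + 1L, n_bins)
  out <- list(); peaks <- list()
  for (lf in sort(unique(leaf))) {
    h <- tabulate(bin[leaf == lf], nbins = n_bins)
    out[[length(out) + 1L]] <- tibble::tibble(
      leaflet = lf, bin_center_deg = centers, count = h)
    hs <- stats::filter(c(h[1], h, h[n_bins]), rep(1 / 3, 3))[2:(n_bins + 1)]
    cand <- which(hs >= c(-Inf, hs[-n_bins]) & hs >= c(hs[-1], -Inf) &
                    hs >= min_height * max(hs))
    pk <- collapse_plateaus(cand, h, n_bins)
    if (length(pk)) {
      peaks[[length(peaks) + 1L]] <- tibble::tibble(
        leaflet = lf, theta_deg = centers[pk],
        height = hs[pk])[order(hs[pk], decreasing = TRUE), ]
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("glyco_tilt", class(res))
  attr(res, "bin_width") <- bin_width
  attr(res, "peaks") <- dplyr::bind_rows(peaks)
  res
}

#' Detected tilt peaks
#' @param tilt A `glyco_tilt`.
#' @return The peak tibble (`leaflet`, `theta_deg`, `height`).
#' @export
tilt_peaks <- function(tilt) attr(tilt, "peaks")

#' Protruding-lipid fraction per leaflet
#'
#' A lipid-frame counts as protruding when its chain-vector angle to the
#' leaflet normal falls inside `[theta_lo, theta_hi]`: the chain points
#' sideways or back into the headgroup region. For leaflets whose chains
#' nominally run along +z the window applies to the angle to +z directly;
#' for oppositely oriented leaflets it is mirrored (`180 - theta`).
#'
#' @param vectors A `glyco_chainvec`.
#' @param leaflets A `glyco_leaflets` (provides per-leaflet orientation);
#'   omitted means one +z-oriented pool.
#' @param theta_lo,theta_hi Angular window in degrees,
#'   `0 < theta_lo < theta_hi <= 180` (default 70-180).
#' @return Tibble of class `glyco_protrusion`: `leaflet`, `fraction`, `se`
#'   (binomial), `n`.
#' @export
classify_protruding <- function(vectors, leaflets = NULL, theta_lo = 70,
                                theta_hi = 180) {
  if (!(theta_lo > 0 && theta_lo < theta_hi && theta_hi <= 180)) {
    stop("need 0 < theta_lo < theta_hi <= 180", call. = FALSE)
  }
  if (is.null(leaflets)) {
    leaf <- rep(1L, nrow(vectors))
    ori <- c(1L)
  } else {
    leaf <- leaflets$assignment$leaflet[match(vectors$lipid,
                                              leaflets$assignment$lipid)]
    ori <- leaflets$orientation
  }
  th <- ifelse(ori[leaf] == 1L, vectors$theta_deg, 180 - vectors$theta_deg)
  prot <- th >= theta_lo & th <= theta_hi
  out <- tibble::tibble(leaflet = leaf, prot = prot) |>
    dplyr::summarise(fraction = mean(.data$prot), n = dplyr::n(),
                     .by = "leaflet") |>
    dplyr::mutate(se = sqrt(.data$fraction * (1 - .data$fraction) /
                              .data$n)) |>
    dplyr::arrange(.data$leaflet)
  class(out) <- c("glyco_protrusion", class(out))
  out
}
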