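#' Assign lipids to leaflets
#'
#' A double bilayer stacks four leaflets along z. Lipids are assigned by a
#' deterministic, parameter-free 1-D clustering of the per-lipid headgroup
#' center z: positions are wrapped into `[0, Lz)`, sorted on the circle, and
#' cut at the `n_leaflets` largest circular gaps. Labels are 1..n in order
#' of increasing (unwrapped) mean z. When the clusters are not separable —
#' the cutting gaps are not clearly larger than the within-cluster gaps —
#' an error asks for a `leaflet_hint` in the role map instead.
#'
#' @param traj A `glyco_trajectory`.
#' @param map A `glyco_rolemap`; headgroup centers are the mean of each
#'   lipid's `ring_anchor` + `headgroup_atom` positions.
#' @param frame 1-based frame index used for the assignment.
#' @param n_leaflets Number of leaflets expected (default 4).
#' @param min_gap_ratio Separability threshold: the smallest cutting gap
#'   must exceed this multiple of the largest non-cutting gap.
#' @return Object of class `glyco_leaflets`: tibble `assignment` with
#'   columns `lipid`, `leaflet`, `head_z`, plus `counts` per leaflet and
#'   `orientation` (+1 if the leaflet's chains point along +z, -1
#'   otherwise, inferred from chain-carbon centers relative to the heads).
#' @export
assign_leaflets <- function(traj, map, frame = 1L, n_leaflets = 4L,
                            min_gap_ratio = 2) {
  resolved <- resolve_atoms(traj, map)
  head_rows <- resolved[resolved$role %in% c("ring_anchor", "headgroup_atom"), ]
  if (!nrow(head_rows)) {
    stop("role map declares no headgroup atoms; cannot assign leaflets",
         call. = FALSE)
  }
  lz <- traj$box[frame, 3]
  z <- traj$coords[head_rows$atom_index, 3, frame] %% lz
  # circular per-lipid mean: average unit phasors to dodge the wrap seam
  ang <- 2 * pi * z / lz
  hz <- tibble::tibble(lipid = head_rows$lipid, s = sin(ang), c = cos(ang)) |>
    dplyr::summarise(dplyr::across(c("s", "c"), mean), .by = "lipid") |>
    dplyr::mutate(head_z = (atan2(.data$s, .data$c) %% (2 * pi)) * lz / (2 * pi))
  if (!is.null(map$leaflet_hint)) {
    lab <- map$leaflet_hint[hz$lipid]
  } else {
    lab <- cluster_circular_1d(hz$head_z, lz, n_leaflets, min_gap_ratio)
  }
  assignment <- tibble::tibble(lipid = hz$lipid, leaflet = lab,
                               head_z = hz$head_z)
  assignment <- assignment[order(assignment$lipid), ]
  counts <- tabulate(assignment$leaflet, nbins = n_leaflets)
  orientation <- leaflet_orientation(traj, resolved, assignment, frame)
  structure(list(assignment = assignment, counts = counts,
                 orientation = orientation, n_leaflets = n_leaflets),
            class = "glyco_leaflets")
}

#' @export
print.glyco_leaflets <- function(x, ...) {
  cat(sprintf("<glyco_leaflets> %d leaflets, counts: %s\n",
              x$n_leaflets, paste(x$counts, collapse = ", ")))
  invisible(x)
}

# Cut sorted circular z values at the k largest gaps; label ascending in z.
# Separability: every cutting gap must exceed min_gap_ratio times the
# largest within-cluster standard deviation, otherwise the bands are not
# distinct and the caller is asked for an explicit hint.
cluster_circular_1d <- function(z, lz, k, min_gap_ratio) {
  n <- length(z)
  if (n < k) stop("fewer lipids than leaflets", call. = FALSE)
  o <- order(z)
  zs <- z[o]
  gaps <- c(diff(zs), zs[1] + lz - zs[n])  # gap i follows sorted point i
  gr <- order(gaps, decreasing = TRUE)
  cut_gaps <- gaps[gr[seq_len(k)]]
  cuts_tmp <- sort(gr[seq_len(k)])
  grp_tmp <- findInterval(seq_len(n), cuts_tmp + 1L) + 1L
  grp_tmp[grp_tmp > k] <- 1L
  max_sd <- max(vapply(seq_len(k), function(g) {
    zz <- zs[grp_tmp == g]
    if (length(zz) < 2L) return(0)
    if (max(zz) - min(zz) > lz / 2) zz <- ifelse(zz < lz / 2, zz + lz, zz)
    stats::sd(zz)
  }, numeric(1)))
  if (min(cut_gaps) <= 0 ||
      min(cut_gaps) <= min_gap_ratio * max_sd) {
    stop(paste0(
      "leaflets are not separable by headgroup z (gap statistic below ",
      "threshold); provide a leaflet_hint in the role map"), call. = FALSE)
  }
  cuts <- cuts_tmp
  # sorted point i belongs to the cluster ending at the first cut >= i;
  # points past the last cut wrap around to the first cluster
  grp_sorted <- findInterval(seq_len(n), cuts + 1L) + 1L
  grp_sorted[grp_sorted > k] <- 1L
  # unwrapped mean z per group for ascending relabel
  mean_z <- vapply(seq_len(k), function(gg) {
    zz <- zs[grp_sorted == gg]
    if (max(zz) - min(zz) > lz / 2) {           # group straddles the seam
      zz <- ifelse(zz < lz / 2, zz + lz, zz)
    }
    mean(zz) %% lz
  }, numeric(1))
  relabel <- match(seq_len(k), order(mean_z))
  out <- integer(n)
  out[o] <- relabel[grp_sorted]
  out
}

# +1 when the chain-carbon center of a leaflet sits above its headgroup
# center (chains point along +z), -1 otherwise.
leaflet_orientation <- function(traj, resolved, assignment, frame) {
  cc <- resolved[resolved$role == "chain_carbon", ]
  if (!nrow(cc)) return(rep(1L, max(assignment$leaflet)))
  lz <- traj$box[frame, 3]
  zc <- traj$coords[cc$atom_index, 3, frame]
  leaf_of <- assignment$leaflet[match(cc$lipid, assignment$lipid)]
  head_z <- assignment$head_z[match(cc$lipid, assignment$lipid)]
  dz <- zc - head_z
  dz <- dz - lz * floor(dz / lz + 0.5)        # minimum image along z
  s <- tapply(dz, leaf_of, function(v) sign(mean(v)))
  out <- as.integer(s[as.character(seq_len(max(assignment$leaflet)))])
  out[is.na(out) | out == 0L] <- 1L
  out
}
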