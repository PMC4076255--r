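#' Build a topology role map
#'
#' The role map declares, per lipid, which atom names play which role, so
#' every analysis is driven by names rather than file order. Roles:
#' \describe{
#'   \item{chain_carbon}{alkyl carbons; sn-1 carbons are named C71..C82
#'     (contiguous from C71), the optional branched sn-2 chain C83..C92.}
#'   \item{chain_hydrogen}{hydrogens bonded to a declared chain carbon
#'     (`parent` gives the carbon name).}
#'   \item{ring_anchor}{the sugar-ring anchor atoms C1, C4, C1p, C4p used to
#'     build headgroup ring vectors; each appears at most once per lipid.}
#'   \item{headgroup_atom}{any other headgroup atom (counts as sugar mass in
#'     density profiles and contributes to the headgroup center).}
#' }
#'
#' @param roles Tibble with columns `lipid` (integer), `atom` (name), `role`
#'   (one of the roles above), and optional `parent` (for chain hydrogens)
#'   and `chain` (`"sn1"`/`"sn2"` for chain atoms).
#' @param leaflet_hint Optional integer vector, one leaflet label per lipid,
#'   used to override automatic leaflet detection.
#' @return Object of class `glyco_rolemap`.
#' @export
role_map <- function(roles, leaflet_hint = NULL) {
  roles <- tibble::as_tibble(roles)
  needed <- c("lipid", "atom", "role")
  if (!all(needed %in% names(roles))) {
    stop("role table needs columns lipid, atom, role", call. = FALSE)
  }
  if (!"parent" %in% names(roles)) roles$parent <- NA_character_
  if (!"chain" %in% names(roles)) roles$chain <- NA_character_
  valid <- c("chain_carbon", "chain_hydrogen", "ring_anchor",
             "headgroup_atom", "other")
  if (!all(roles$role %in% valid)) {
    stop("unknown role(s): ",
         paste(setdiff(unique(roles$role), valid), collapse = ", "),
         call. = FALSE)
  }
  map <- structure(list(roles = roles,
                        lipid_count = length(unique(roles$lipid)),
                        leaflet_hint = leaflet_hint),
                   class = "glyco_rolemap")
  validate_role_map(map)
  map
}

#' @export
print.glyco_rolemap <- function(x, ...) {
  cat(sprintf("<glyco_rolemap> %d lipids, %d atoms/lipid\n",
              x$lipid_count, nrow(x$roles) / max(1L, x$lipid_count)))
  invisible(x)
}

# Invariant checks: contiguous chain carbons, hydrogens reference declared
# carbons, ring anchors unique per lipid.
validate_role_map <- function(map) {
  roles <- map$roles
  by_lipid <- split(roles, roles$lipid)
  for (lr in by_lipid) {
    lid <- lr$lipid[1]
    cc <- lr[lr$role == "chain_carbon", ]
    for (ch in unique(stats::na.omit(cc$chain))) {
      idx <- sort(as.integer(sub("^C", "", cc$atom[cc$chain == ch])))
      lo <- if (ch == "sn1") 71L else 83L
      if (length(idx) &&
          !identical(idx, seq.int(lo, lo + length(idx) - 1L))) {
        stop(sprintf(
          "lipid %d: %s chain carbons must be contiguous from C%d", lid, ch,
          lo), call. = FALSE)
      }
    }
    hh <- lr[lr$role == "chain_hydrogen", ]
    if (nrow(hh) && !all(hh$parent %in% cc$atom)) {
      stop(sprintf("lipid %d: chain hydrogen references undeclared carbon",
                   lid), call. = FALSE)
    }
    an <- lr$atom[lr$role == "ring_anchor"]
    if (anyDuplicated(an) ||
        !all(an %in% c("C1", "C4", "C1p", "C4p"))) {
      stop(sprintf(
        "lipid %d: ring anchors must be a subset of C1, C4, C1p, C4p, each at most once",
        lid), call. = FALSE)
    }
  }
  invisible(map)
}

#' Build the standard role map for identical glycolipids
#'
#' Convenience constructor for a system of `n_lipids` identical lipids with
#' a 4-anchor sugar headgroup, an sn-1 chain C71..C82 (length
#' `chain_length`) with two hydrogens per carbon, and an optional sn-2 chain
#' C83.. (length `sn2_length`, 0 to omit).
#'
#' @param n_lipids Number of lipids.
#' @param chain_length sn-1 chain carbon count (default 12).
#' @param sn2_length sn-2 chain carbon count (default 0 = monoalkylated).
#' @param leaflet_hint Optional per-lipid leaflet labels.
#' @return A `glyco_rolemap`.
#' @export
standard_role_map <- function(n_lipids, chain_length = 12L, sn2_length = 0L,
                              leaflet_hint = NULL) {
  tmpl <- lipid_template(chain_length, sn2_length)
  roles <- tidyr::expand_grid(lipid = seq_len(n_lipids), tmpl)
  role_map(roles, leaflet_hint = leaflet_hint)
}

# Per-lipid atom template, in the order the generator writes atoms.
lipid_template <- function(chain_length = 12L, sn2_length = 0L) {
  anchors <- tibble::tibble(atom = c("C1", "C4", "C1p", "C4p"),
                            role = "ring_anchor",
                            parent = NA_character_, chain = NA_character_)
  chain_block <- function(lo, n, chain) {
    cn <- paste0("C", seq.int(lo, lo + n - 1L))
    carb <- tibble::tibble(atom = cn, role = "chain_carbon",
                           parent = NA_character_, chain = chain)
    hyd <- tibble::tibble(
      atom = c(rbind(paste0("H", seq.int(lo, lo + n - 1L), "A"),
                     paste0("H", seq.int(lo, lo + n - 1L), "B"))),
      role = "chain_hydrogen",
      parent = rep(cn, each = 2L), chain = chain)
    dplyr::bind_rows(carb, hyd)
  }
  out <- dplyr::bind_rows(anchors, chain_block(71L, chain_length, "sn1"))
  if (sn2_length > 0L) {
    out <- dplyr::bind_rows(out, chain_block(83L, sn2_length, "sn2"))
  }
  out
}

#' Read / write a role map config file
#'
#' The on-disk form is a small human-editable YAML document:
#' ```yaml
#' lipid_count: 256
#' template:
#'   ring_anchors: [C1, C4, C1p, C4p]
#'   sn1_carbons: [C71, ..., C82]      # contiguous
#'   sn2_carbons: []                   # optional
#'   hydrogens: auto                   # HnnA/HnnB per carbon, or a mapping
#' leaflet_hint: []                    # optional, one label per lipid
#' ```
#' Every lipid is an instance of the template; `hydrogens: auto` expands to
#' two hydrogens `H<nn>A`/`H<nn>B` per chain carbon `C<nn>`.
#'
#' @param path File path.
#' @return `read_role_map()` returns a `glyco_rolemap`; `write_role_map()`
#'   returns `path` invisibly.
#' @export
read_role_map <- function(path) {
  if (!file.exists(path)) stop("role map file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), c("lipid_count", "template", "leaflet_hint"))
  if (length(bad)) stop("unknown role-map keys: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  tm <- y$template
  sn1 <- as.character(tm$sn1_carbons %||% character())
  sn2 <- as.character(tm$sn2_carbons %||% character())
  anchors <- as.character(tm$ring_anchors %||% character())
  parts <- list(tibble::tibble(atom = anchors, role = "ring_anchor",
                               parent = NA_character_,
                               chain = NA_character_))
  add_chain <- function(cn, chain) {
    carb <- tibble::tibble(atom = cn, role = "chain_carbon",
                           parent = NA_character_, chain = chain)
    if (identical(tm$hydrogens, "auto")) {
      nn <- sub("^C", "", cn)
      hyd <- tibble::tibble(atom = c(rbind(paste0("H", nn, "A"),
                                           paste0("H", nn, "B"))),
                            role = "chain_hydrogen",
                            parent = rep(cn, each = 2L), chain = chain)
      dplyr::bind_rows(carb, hyd)
    } else carb
  }
  if (length(sn1)) parts <- c(parts, list(add_chain(sn1, "sn1")))
  if (length(sn2)) parts <- c(parts, list(add_chain(sn2, "sn2")))
  tmpl <- dplyr::bind_rows(parts)
  n <- as.integer(y$lipid_count)
  roles <- tidyr::expand_grid(lipid = seq_len(n), tmpl)
  hint <- if (length(y$leaflet_hint)) as.integer(y$leaflet_hint) else NULL
  role_map(roles, leaflet_hint = hint)
}

#' @rdname read_role_map
#' @param map A `glyco_rolemap` whose lipids all share one template.
#' @export
write_role_map <- function(map, path) {
  r1 <- map$roles[map$roles$lipid == map$roles$lipid[1], ]
  y <- list(
    lipid_count = map$lipid_count,
    template = list(
      ring_anchors = r1$atom[r1$role == "ring_anchor"],
      sn1_carbons = r1$atom[r1$role == "chain_carbon" & r1$chain == "sn1"],
      sn2_carbons = r1$atom[r1$role == "chain_carbon" & r1$chain == "sn2"],
      hydrogens = "auto"))
  if (!is.null(map$leaflet_hint)) y$leaflet_hint <- map$leaflet_hint
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve atom indices in a trajectory for each (lipid, atom) row of the
# role map. PDB input carries lipid ids; XYZ input is matched by order,
# assuming atoms appear lipid-block by lipid-block in template order.
resolve_atoms <- function(traj, map) {
  roles <- map$roles
  if (all(is.na(traj$atoms$lipid))) {
    per <- nrow(roles) / map$lipid_count
    lipid_of_atom <- ((seq_len(n_atoms(traj)) - 1L) %/% per) + 1L
  } else {
    lipid_of_atom <- traj$atoms$lipid
  }
  key_t <- paste(lipid_of_atom, traj$atoms$name)
  key_r <- paste(roles$lipid, roles$atom)
  idx <- match(key_r, key_t)
  if (anyNA(idx)) {
    miss <- roles[is.na(idx), ][1, ]
    stop(sprintf("atom %s of lipid %d declared in role map not found in trajectory",
                 miss$atom, miss$lipid), call. = FALSE)
  }
  dplyr::mutate(roles, atom_index = idx)
}

# Indices (one per lipid, ordered by lipid) of a named atom.
atom_index_by_lipid <- function(resolved, atom_name) {
  r <- resolved[resolved$atom == atom_name, ]
  r <- r[order(r$lipid), ]
  if (!nrow(r)) stop("atom ", atom_name, " not in role map", call. = FALSE)
  r$atom_index
}

# Atomic mass from the leading element letter of the atom name (C/H/O/N/P/S).
atom_mass <- function(names) {
  el <- toupper(substr(names, 1, 1))
  m <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.974,
         S = 32.06)
  out <- unname(m[el])
  out[is.na(out)] <- 12.011
  out
}
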