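#' Construct a trajectory object
#'
#' A trajectory is an ordered set of frames of Cartesian coordinates
#' (Angstrom) in an orthorhombic periodic box, with one time stamp (ps) per
#' frame. Atom identity (name and parent lipid) is carried alongside so that
#' analyses can be driven by atom roles rather than file order.
#'
#' @param coords Numeric array `[n_atoms, 3, n_frames]` of coordinates in
#'   Angstrom. A single-frame `n x 3` matrix is promoted.
#' @param box Numeric matrix `[n_frames, 3]` of box lengths `(Lx, Ly, Lz)`
#'   in Angstrom (a length-3 vector is recycled across frames).
#' @param time Numeric vector of frame time stamps in ps, strictly
#'   increasing. Defaults to `0, 1, 2, ...`.
#' @param atoms Tibble with one row per atom: columns `name` (atom name,
#'   e.g. "C72") and `lipid` (1-based lipid index, `NA` if unknown).
#' @return An object of class `glyco_trajectory`.
#' @export
trajectory <- function(coords, box, time = NULL, atoms = NULL) {
  if (length(dim(coords)) == 2L) {
    coords <- array(coords, dim = c(dim(coords), 1L))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_atoms <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  if (is.null(dim(box))) {
    box <- matrix(box, nrow = n_frames, ncol = 3L, byrow = TRUE)
  }
  if (nrow(box) != n_frames) {
    stop("box must have one row per frame", call. = FALSE)
  }
  apply(box, 1L, check_box)
  if (is.null(time)) time <- seq_len(n_frames) - 1
  if (length(time) != n_frames || (n_frames > 1L && any(diff(time) <= 0))) {
    stop("frame times must be strictly increasing, one per frame",
         call. = FALSE)
  }
  if (is.null(atoms)) {
    atoms <- tibble::tibble(name = paste0("X", seq_len(n_atoms)),
                            lipid = NA_integer_)
  }
  if (nrow(atoms) != n_atoms) {
    stop("atoms table must have one row per atom", call. = FALSE)
  }
  structure(list(coords = coords, box = box, time = as.numeric(time),
                 atoms = tibble::as_tibble(atoms)),
            class = "glyco_trajectory")
}

#' @export
print.glyco_trajectory <- function(x, ...) {
  cat(sprintf(
    "<glyco_trajectory> %d atoms, %d frames, box %.2f x %.2f x %.2f A (frame 1)\n",
    n_atoms(x), n_frames(x), x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj A `glyco_trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Analysis window over a trajectory
#'
#' Frame indexing is 0-based and half-open: `[first, last)`. The default
#' window discards the first 20% of frames, the same convention as keeping
#' the final 160 ns of a 200 ns production run, and block-averages the rest
#' in `blocks` contiguous blocks (trailing frames that do not fill a block
#' evenly are assigned to the final block).
#'
#' @param traj A `glyco_trajectory` (used to bound the window).
#' @param first,last 0-based half-open frame range; `NULL` means the
#'   defaults `floor(0.2 * n)` and `n`.
#' @param blocks Number of blocks for block averaging (>= 1).
#' @return A list of class `glyco_window` with `first`, `last`, `blocks`,
#'   and `frames` (1-based frame indices in the window).
#' @export
analysis_window <- function(traj, first = NULL, last = NULL, blocks = 5L) {
  n <- n_frames(traj)
  if (is.null(first)) first <- floor(0.2 * n)
  if (is.null(last)) last <- n
  first <- as.integer(first); last <- as.integer(last)
  blocks <- as.integer(blocks)
  if (first < 0L || first >= last || last > n) {
    stop(sprintf("invalid window [%d, %d) for %d frames", first, last, n),
         call. = FALSE)
  }
  if (blocks < 1L || blocks > last - first) {
    stop("block count must be >= 1 and at most the window length",
         call. = FALSE)
  }
  frames <- seq.int(first + 1L, last)
  structure(list(first = first, last = last, blocks = blocks,
                 frames = frames),
            class = "glyco_window")
}

# Block id (1..blocks) per frame of a window.
window_block_id <- function(window) {
  n <- length(window$frames)
  per <- n %/% window$blocks
  id <- pmin(((seq_len(n) - 1L) %/% per) + 1L, window$blocks)
  id
}

#' Read a trajectory file
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`pdb_multimodel`}{Multi-model PDB. Each MODEL block is preceded by
#'     a CRYST1 record carrying the orthorhombic box for that frame (a single
#'     leading CRYST1 is also accepted and recycled). Lipid index is taken
#'     from the residue sequence number.}
#'   \item{`xyz`}{Extended XYZ: atom-count line, then a comment line
#'     `Lx Ly Lz time_ps`, then `name x y z` rows. Plain XYZ lacks box
#'     metadata, so the comment-line convention is mandatory.}
#' }
#'
#' @param path File path.
#' @param format One of `"pdb_multimodel"`, `"xyz"`; `"auto"` guesses from
#'   the extension.
#' @return A `glyco_trajectory`.
#' @export
load_trajectory <- function(path, format = c("auto", "pdb_multimodel", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("trajectory file not found: ", path,
                               call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE))
      "pdb_multimodel" else "xyz"
  }
  switch(format,
         pdb_multimodel = read_pdb_trajectory(path),
         xyz = read_xyz_trajectory(path))
}

read_pdb_trajectory <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  cryst_idx <- which(rec == "CRYST1")
  model_idx <- which(rec == "MODEL ")
  if (length(model_idx) == 0L) model_idx <- 0L  # single implicit model
  if (length(cryst_idx) == 0L) {
    stop("PDB trajectory has no CRYST1 box record", call. = FALSE)
  }
  atom_mask <- rec == "ATOM  " | rec == "HETATM"
  # frame id per line: number of MODEL records seen so far
  frame_of_line <- findInterval(seq_along(lines), model_idx)
  if (identical(model_idx, 0L)) frame_of_line <- rep(1L, length(lines))
  nf <- max(frame_of_line[atom_mask])
  atom_lines <- lines[atom_mask]
  frame_id <- frame_of_line[atom_mask]
  counts <- tabulate(frame_id, nbins = nf)
  if (length(unique(counts[counts > 0])) != 1L || any(counts == 0L)) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf(
      "inconsistent atom count across PDB MODEL blocks (frame %d has %d, frame 1 has %d)",
      bad, counts[bad], counts[1]), call. = FALSE)
  }
  na <- counts[1]
  x <- as.numeric(substr(atom_lines, 31, 38))
  y <- as.numeric(substr(atom_lines, 39, 46))
  z <- as.numeric(substr(atom_lines, 47, 54))
  coords <- array(0, dim = c(na, 3L, nf))
  coords[, 1, ] <- x; coords[, 2, ] <- y; coords[, 3, ] <- z
  first <- frame_id == 1L
  name <- trimws(substr(atom_lines[first], 13, 16))
  lipid <- suppressWarnings(as.integer(substr(atom_lines[first], 23, 26)))
  # one CRYST1 per model (written before or inside the MODEL block), or a
  # single leading record recycled
  last_atom_of_frame <- vapply(seq_len(nf), function(f) {
    max(which(atom_mask)[frame_id == f])
  }, integer(1))
  cf <- frame_of_line[cryst_idx]
  inside <- cf >= 1L & cryst_idx < last_atom_of_frame[pmax(cf, 1L)]
  cf[!inside] <- cf[!inside] + 1L
  cf <- pmin(cf, nf)
  box <- matrix(NA_real_, nf, 3)
  for (i in seq_along(cryst_idx)) {
    l <- lines[cryst_idx[i]]
    box[cf[i], ] <- c(as.numeric(substr(l, 7, 15)),
                      as.numeric(substr(l, 16, 24)),
                      as.numeric(substr(l, 25, 33)))
    ang <- c(as.numeric(substr(l, 34, 40)),
             as.numeric(substr(l, 41, 47)),
             as.numeric(substr(l, 48, 54)))
    if (any(abs(ang - 90) > 1e-3)) {
      stop("triclinic boxes are not supported (CRYST1 angles must be 90)",
           call. = FALSE)
    }
  }
  if (length(cryst_idx) == 1L && nf > 1L) {
    box <- matrix(box[cf[1], ], nf, 3, byrow = TRUE)
  }
  if (anyNA(box)) {
    stop(sprintf("missing CRYST1 box for frame %d",
                 which(is.na(box[, 1]))[1]), call. = FALSE)
  }
  trajectory(coords, box,
             time = seq_len(nf) - 1,
             atoms = tibble::tibble(name = name, lipid = lipid))
}

read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list(); boxes <- list(); times <- c(); atoms <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na)) stop("malformed XYZ atom-count line at line ", i,
                        call. = FALSE)
    meta <- suppressWarnings(
      as.numeric(strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]))
    if (length(meta) < 3L || anyNA(meta[1:3])) {
      stop(sprintf("missing box on XYZ comment line for frame %d",
                   length(frames) + 1L), call. = FALSE)
    }
    body <- lines[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(body), "\\s+")
    nm <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(atoms)) {
      atoms <- nm
    } else if (length(nm) != length(atoms) || !all(nm == atoms)) {
      stop(sprintf("inconsistent atoms in XYZ frame %d", length(frames) + 1L),
           call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- meta[1:3]
    times <- c(times, if (length(meta) >= 4L) meta[4] else length(times))
    i <- i + 2L + na
  }
  coords <- array(unlist(frames), dim = c(length(atoms), 3L, length(frames)))
  trajectory(coords, do.call(rbind, boxes), time = times,
             atoms = tibble::tibble(name = atoms, lipid = NA_integer_))
}

#' Write a trajectory file
#'
#' Writes the dialects that [load_trajectory()] reads. PDB output places a
#' CRYST1 record before every MODEL so each frame carries its own box.
#'
#' @param traj A `glyco_trajectory`.
#' @param path Output path.
#' @param format `"pdb_multimodel"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             format = c("pdb_multimodel", "xyz")) {
  format <- match.arg(format)
  nf <- n_frames(traj); na <- n_atoms(traj)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb_multimodel") {
    lipid <- traj$atoms$lipid
    lipid[is.na(lipid)] <- 1L
    nm <- format(substr(traj$atoms$name, 1, 4), width = 4)
    for (f in seq_len(nf)) {
      writeLines(sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
        traj$box[f, 1], traj$box[f, 2], traj$box[f, 3], 90, 90, 90), con)
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(sprintf(
        "ATOM  %5d %s LIP %1s%4d    %8.3f%8.3f%8.3f",
        seq_len(na) %% 100000L, nm, "A", lipid %% 10000L,
        traj$coords[, 1, f], traj$coords[, 2, f], traj$coords[, 3, f]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (f in seq_len(nf)) {
      writeLines(as.character(na), con)
      writeLines(sprintf("%.6f %.6f %.6f %.6f",
                         traj$box[f, 1], traj$box[f, 2], traj$box[f, 3],
                         traj$time[f]), con)
      writeLines(sprintf("%s %.6f %.6f %.6f", traj$atoms$name,
                         traj$coords[, 1, f], traj$coords[, 2, f],
                         traj$coords[, 3, f]), con)
    }
  }
  invisible(path)
}
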