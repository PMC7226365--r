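# ---------------------------------------------------------------------------
# Domain containers: topology, trajectory, selection
# ---------------------------------------------------------------------------

#' Construct a topology from an atom table
#'
#' A topology is the static description of a molecular system: one row per
#' atom with PDB-style naming plus a van der Waals radius.  The residue
#' table is derived from the atoms in first-appearance order.
#'
#' @param atoms data.frame with columns `atom_name`, `element`,
#'   `residue_name` (3-letter code), `residue_number` (integer, taken
#'   verbatim from the source file, never renumbered), `chain_id`,
#'   `vdw_radius` (Angstrom, > 0).
#' @return Object of class `"topology"`: list with `atoms` (the table,
#'   with an `atom_index` column 1..N) and `residues` (distinct
#'   chain/number/name keys in first-appearance order).
#' @export
topology <- function(atoms) {
  required <- c("atom_name", "element", "residue_name", "residue_number",
                "chain_id", "vdw_radius")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$atom_index <- seq_len(nrow(atoms))
  if (any(!is.finite(atoms$vdw_radius)) || any(atoms$vdw_radius <= 0)) {
    stop("all vdw_radius values must be positive and finite")
  }
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (chain, residue_number, atom_name) in topology: ", dup)
  }
  rkey <- paste(atoms$chain_id, atoms$residue_number, sep = "|")
  first <- !duplicated(rkey)
  residues <- data.frame(
    chain_id = atoms$chain_id[first],
    residue_number = atoms$residue_number[first],
    residue_name = atoms$residue_name[first],
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, residues = residues), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), nrow(x$residues),
              length(unique(x$atoms$chain_id))))
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Construct a trajectory
#'
#' Bundles a topology with an ordered stack of coordinate frames.  The
#' default frame spacing, 0.04 ns, is the 2500-frames-per-100-ns convention
#' of the MD runs this package post-processes.
#'
#' @param top A [topology()].
#' @param coords Numeric array `n_atoms x 3 x n_frames` (Angstrom), or a
#'   single `n_atoms x 3` matrix for a one-frame trajectory.
#' @param time_per_frame Time between stored frames, ns.
#' @return Object of class `"trajectory"`.
#' @export
trajectory <- function(top, coords, time_per_frame = 0.04) {
  stopifnot(inherits(top, "topology"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[3] < 1L) stop("trajectory must contain at least one frame")
  if (dim(coords)[1] != n_atoms(top)) {
    stop(sprintf("coordinate rows (%d) do not match topology atoms (%d)",
                 dim(coords)[1], n_atoms(top)))
  }
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  if (!is.numeric(time_per_frame) || time_per_frame <= 0) {
    stop("time_per_frame must be positive")
  }
  structure(list(topology = top, coords = coords,
                 time_per_frame = time_per_frame),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d atoms x %d frames (%.3g ns/frame, %.4g ns total)\n",
              dim(x$coords)[1], dim(x$coords)[3], x$time_per_frame,
              x$time_per_frame * dim(x$coords)[3]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A trajectory.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as an n x 3 coordinate matrix
#' @param traj A trajectory.
#' @param i Frame index (1-based).
#' @return Numeric matrix `n_atoms x 3`.
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range: ", i)
  m <- traj$coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

# ---------------------------------------------------------------------------
# Selections
# ---------------------------------------------------------------------------

#' Define an atom selection
#'
#' Selections combine an optional chain filter, inclusive residue-number
#' ranges, an optional atom-name set, and a heavy-atom flag.  Resolution
#' against a topology is deterministic and returns indices in topology
#' order.
#'
#' @param chain Character vector of chain ids, or NULL for all chains.
#' @param resno_ranges Two-column matrix (or vector of length 2) of
#'   inclusive residue-number ranges, or NULL for all residues.
#' @param atom_names Character vector of atom names, or NULL for all.
#' @param heavy_only If TRUE, hydrogen atoms are excluded.
#' @return Object of class `"selection"`.
#' @export
selection <- function(chain = NULL, resno_ranges = NULL, atom_names = NULL,
                      heavy_only = FALSE) {
  if (!is.null(resno_ranges)) {
    resno_ranges <- matrix(as.numeric(resno_ranges), ncol = 2, byrow = FALSE)
    if (is.null(dim(resno_ranges)) || ncol(resno_ranges) != 2) {
      stop("resno_ranges must have two columns (lo, hi)")
    }
    if (any(resno_ranges[, 1] > resno_ranges[, 2])) {
      stop("each residue range must satisfy lo <= hi")
    }
  }
  structure(list(chain = chain, resno_ranges = resno_ranges,
                 atom_names = atom_names, heavy_only = isTRUE(heavy_only)),
            class = "selection")
}

#' Parse a selection expression
#'
#' Small text syntax: clauses joined by `and`, each one of
#' `chain A B`, `resid 60-88 95`, `name N CA C O`, `noh`.
#'
#' @param text Selection expression, e.g.
#'   `"chain A and resid 60-88 and name N CA C O"`.  `"all"` (or an empty
#'   string) selects everything.
#' @return A [selection()].
#' @export
parse_selection <- function(text) {
  text <- trimws(text)
  if (text == "" || tolower(text) == "all") return(selection())
  clauses <- strsplit(text, "\\s+and\\s+")[[1]]
  chain <- NULL; ranges <- NULL; nm <- NULL; heavy <- FALSE
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    kw <- tolower(toks[1])
    if (kw == "chain") {
      chain <- toks[-1]
    } else if (kw %in% c("resid", "resno")) {
      for (t in toks[-1]) {
        if (grepl("-", t) && !grepl("^-", t)) {
          lohi <- as.numeric(strsplit(t, "-")[[1]])
          ranges <- rbind(ranges, lohi)
        } else {
          ranges <- rbind(ranges, c(as.numeric(t), as.numeric(t)))
        }
      }
    } else if (kw == "name") {
      nm <- toupper(toks[-1])
    } else if (kw == "noh") {
      heavy <- TRUE
    } else {
      stop("unknown selection clause: ", cl)
    }
  }
  selection(chain = chain, resno_ranges = ranges, atom_names = nm,
            heavy_only = heavy)
}

is_hydrogen <- function(element, atom_name) {
  el <- toupper(trimws(element))
  ifelse(el != "", el == "H",
         grepl("^[0-9]*H", toupper(atom_name)))
}

#' Resolve a selection against a topology
#'
#' @param sel A [selection()] (or a selection expression string).
#' @param top A [topology()].
#' @return Strictly increasing integer vector of atom indices (possibly
#'   empty; downstream operations decide whether that is an error).
#' @export
resolve_selection <- function(sel, top) {
  if (is.character(sel)) sel <- parse_selection(sel)
  stopifnot(inherits(sel, "selection"), inherits(top, "topology"))
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain_id %in% sel$chain
  if (!is.null(sel$resno_ranges)) {
    in_range <- rep(FALSE, nrow(a))
    for (k in seq_len(nrow(sel$resno_ranges))) {
      in_range <- in_range |
        (a$residue_number >= sel$resno_ranges[k, 1] &
         a$residue_number <= sel$resno_ranges[k, 2])
    }
    keep <- keep & in_range
  }
  if (!is.null(sel$atom_names)) {
    keep <- keep & toupper(a$atom_name) %in% sel$atom_names
  }
  if (sel$heavy_only) keep <- keep & !is_hydrogen(a$element, a$atom_name)
  which(keep)
}

# ---------------------------------------------------------------------------
# Readers / writers (PDB via bio3d, DCD read via bio3d, DCD write local)
# ---------------------------------------------------------------------------

#' Read a topology from a PDB file
#'
#' ATOM and HETATM records become one atom each; van der Waals radii are
#' assigned by element from `radius_table` with a fallback on the first
#' alphabetic character of the atom name.  Residue numbering is taken
#' verbatim from the file.
#'
#' @param path PDB file path.
#' @param radius_table Named radius vector, see [vdw_radius_table()].
#' @return A [topology()].
#' @export
read_topology <- function(path, radius_table = vdw_radius_table()) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("no ATOM/HETATM records in ", path)
  elem <- if ("elesy" %in% names(at)) at$elesy else rep("", nrow(at))
  elem[is.na(elem)] <- ""
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(
    atom_name = trimws(at$elety),
    element = trimws(elem),
    residue_name = trimws(at$resid),
    residue_number = at$resno,
    chain_id = chain,
    stringsAsFactors = FALSE
  )
  atoms$vdw_radius <- lookup_vdw_radius(atoms$element, atoms$atom_name,
                                        radius_table)
  topology(atoms)
}

#' Read a trajectory (multi-model PDB or DCD)
#'
#' @param top Topology matching the file's atom count.
#' @param path Multi-model PDB (`MODEL`/`ENDMDL`) or binary DCD file.
#' @param time_per_frame ns per stored frame (default 0.04: the
#'   2500-frames / 100-ns convention).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(top, path, time_per_frame = 0.04) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
  }
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0) stop("trajectory file contains no frames: ", path)
  nat <- ncol(xyz) / 3
  if (nat != n_atoms(top)) {
    stop(sprintf("frame 1 atom count (%d) does not match topology (%d)",
                 nat, n_atoms(top)))
  }
  coords <- array(NA_real_, dim = c(nat, 3, nrow(xyz)))
  for (f in seq_len(nrow(xyz))) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  trajectory(top, coords, time_per_frame = time_per_frame)
}

traj_to_xyz <- function(traj) {
  nf <- n_frames(traj)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3 * dim(traj$coords)[1])
  for (f in seq_len(nf)) xyz[f, ] <- as.vector(t(traj$coords[, , f]))
  xyz
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A trajectory.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$topology$atoms
  bio3d::write.pdb(
    file = path,
    xyz = traj_to_xyz(traj),
    resno = a$residue_number,
    resid = a$residue_name,
    eleno = a$atom_index,
    elety = a$atom_name,
    chain = a$chain_id,
    elesy = a$element
  )
  invisible(path)
}

#' Write a trajectory as a CHARMM-style DCD file
#'
#' Minimal single-precision CORD format (no unit cell, no fixed atoms),
#' readable by common trajectory tools.
#'
#' @param traj A trajectory.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  nf <- n_frames(traj)
  nat <- dim(traj$coords)[1]
  icntrl <- integer(20)
  icntrl[1] <- nf        # frames in file
  icntrl[2] <- 1L        # first step
  icntrl[3] <- 1L        # save interval
  icntrl[4] <- nf        # total steps
  icntrl[20] <- 24L      # CHARMM version stamp
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4, endian = "little")
  }, 84)
  title <- sprintf("%-80s", "portaldyn trajectory")
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(nat), con, size = 4, endian = "little"), 4)
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    for (ax in 1:3) {
      rec(function() writeBin(as.numeric(fr[, ax]), con, size = 4,
                              endian = "little"), 4 * nat)
    }
  }
  invisible(path)
}
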