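# ---------------------------------------------------------------------------
# Fractional occupancy-volume maps.
#
# Per frame, every lattice point is set to 1 if it lies inside (closed
# inequality) the van der Waals sphere of at least one selected atom, else
# 0; averaging the binary fields over the trajectory gives the fractional
# occupancy of each point.  Thresholding the map yields iso-volumes
# (e.g. 0.5 "outer" and 0.9 "inner" shells of the portal flanks).
# ---------------------------------------------------------------------------

#' Define a regular occupancy grid
#'
#' Lattice point (i, j, k) (0-based) sits at `origin + spacing * (i, j, k)`.
#'
#' @param origin Numeric 3-vector, A.
#' @param spacing Isotropic step, A (> 0).  The 0.5 A default mirrors the
#'   usual electrostatics grid convention (a 64 A cube at 0.5 A gives
#'   129 points per axis).
#' @param dims Integer 3-vector of point counts per axis.
#' @return Object of class `"grid_spec"`.
#' @export
grid_spec <- function(origin, spacing = 0.5, dims) {
  origin <- as.numeric(origin)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3, length(dims) == 3)
  if (spacing <= 0) stop("spacing must be positive")
  if (any(dims < 1)) stop("all grid dimensions must be >= 1")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d points (%s total), spacing %.3g A\n",
              x$dims[1], x$dims[2], x$dims[3],
              format(n_grid_points(x), big.mark = ","), x$spacing))
  invisible(x)
}

#' Total number of lattice points in a grid
#' @param grid A [grid_spec()].
#' @return Numeric scalar (may exceed integer range for fine grids).
#' @export
n_grid_points <- function(grid) prod(as.numeric(grid$dims))

# Lattice coordinates along one axis (0-based index k -> origin + k*h).
axis_coords <- function(grid, ax) {
  grid$origin[ax] + grid$spacing * (seq_len(grid$dims[ax]) - 1)
}

# Linear index with z fastest (matches OpenDX "data follows" ordering).
# i, j, k are 1-based axis indices.
lin_index <- function(grid, i, j, k) {
  nz <- grid$dims[3]; ny <- grid$dims[2]
  ((i - 1) * ny + (j - 1)) * nz + k
}

#' Build a grid covering a trajectory selection
#'
#' Axis-aligned bounding box of the selected atoms over all frames,
#' expanded by (max vdw radius + padding) on each side, discretised at
#' `spacing`.
#'
#' @param traj A trajectory.
#' @param sel Selection (object or expression string); must be non-empty.
#' @param spacing Grid step, A.
#' @param padding Extra margin beyond the largest radius, A.
#' @return A [grid_spec()].
#' @export
grid_from_trajectory <- function(traj, sel, spacing = 0.5, padding = 2) {
  idx <- resolve_selection(sel, traj$topology)
  if (!length(idx)) stop("cannot grid an empty selection")
  sub <- traj$coords[idx, , , drop = FALSE]
  lo <- apply(sub, 2, min)
  hi <- apply(sub, 2, max)
  margin <- max(traj$topology$atoms$vdw_radius[idx]) + padding
  lo <- lo - margin
  hi <- hi + margin
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  grid_spec(origin = lo, spacing = spacing, dims = dims)
}

#' Binary occupancy field of one frame
#'
#' Point p is occupied (1) iff there exists a selected atom a with
#' `|p - x_a| <= r_a` -- the sphere boundary counts as inside.
#'
#' @param frame n x 3 coordinate matrix.
#' @param atom_indices Atom indices to rasterise.
#' @param grid A [grid_spec()].
#' @param radii Per-atom radii (A), parallel to `atom_indices`.
#' @return Integer vector of 0/1 over grid points, z-fastest order.  The
#'   attribute `"n_clipped"` counts atoms whose sphere extended (partly or
#'   fully) outside the grid.
#' @export
frame_occupancy <- function(frame, atom_indices, grid, radii) {
  stopifnot(length(atom_indices) == length(radii))
  occ <- integer(n_grid_points(grid))
  h <- grid$spacing
  n_clipped <- 0L
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  for (a in seq_along(atom_indices)) {
    x <- frame[atom_indices[a], ]
    r <- radii[a]
    # candidate index window per axis (1-based, clamped to the grid)
    lo <- ceiling((x - r - grid$origin) / h) + 1
    hi <- floor((x + r - grid$origin) / h) + 1
    if (any(lo < 1) || any(hi > grid$dims)) n_clipped <- n_clipped + 1L
    lo <- pmax(lo, 1); hi <- pmin(hi, grid$dims)
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    dx2 <- (xs[ii] - x[1])^2
    dy2 <- (ys[jj] - x[2])^2
    dz2 <- (zs[kk] - x[3])^2
    # outer(i, j) then each z slab; small windows keep this cheap
    dxy2 <- outer(dx2, dy2, "+")
    r2 <- r * r + 1e-12          # closed inequality, guarded for roundoff
    for (kz in seq_along(kk)) {
      hit <- which(dxy2 + dz2[kz] <= r2, arr.ind = TRUE)
      if (nrow(hit)) {
        occ[lin_index(grid, ii[hit[, 1]], jj[hit[, 2]], kk[kz])] <- 1L
      }
    }
  }
  attr(occ, "n_clipped") <- n_clipped
  occ
}

#' Fractional occupancy map over a trajectory
#'
#' Streams over frames, accumulating the per-frame binary fields; the map
#' value at each point is the fraction of frames in which the point was
#' occupied by the selection.
#'
#' @param traj A trajectory (>= 1 frame).
#' @param sel Selection object or expression string.
#' @param grid Optional [grid_spec()]; default auto-grids over all frames
#'   via [grid_from_trajectory()].
#' @param spacing,padding Passed to the auto-gridder when `grid` is NULL.
#' @return Object of class `"occupancy_map"`: list with `grid`, `values`
#'   (fractions in [0, 1], z-fastest), `n_frames`, `selection_text`.
#' @export
fractional_occupancy <- function(traj, sel, grid = NULL, spacing = 0.5,
                                 padding = 2) {
  sel_text <- if (is.character(sel)) sel else "<selection object>"
  idx <- resolve_selection(sel, traj$topology)
  if (!length(idx)) stop("empty selection")
  if (is.null(grid)) {
    grid <- grid_from_trajectory(traj, sel, spacing = spacing,
                                 padding = padding)
  }
  radii <- traj$topology$atoms$vdw_radius[idx]
  nf <- n_frames(traj)
  acc <- numeric(n_grid_points(grid))
  clipped <- 0L
  for (t in seq_len(nf)) {
    f <- frame_occupancy(get_frame(traj, t), idx, grid, radii)
    clipped <- clipped + attr(f, "n_clipped")
    attributes(f) <- NULL
    acc <- acc + f
  }
  if (clipped > 0) {
    warning(sprintf(
      "%d atom-frame sphere(s) extended outside the grid; contributions clipped",
      clipped))
  }
  structure(list(grid = grid, values = acc / nf, n_frames = nf,
                 selection_text = sel_text),
            class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf(
    "<occupancy_map> %d x %d x %d grid, %d frame(s), occupied fraction range [%.3g, %.3g]\n",
    x$grid$dims[1], x$grid$dims[2], x$grid$dims[3], x$n_frames,
    min(x$values), max(x$values)))
  invisible(x)
}

#' Iso-occupancy point set and volume
#'
#' @param map An occupancy map.
#' @param threshold Occupancy fraction in (0, 1]; a point belongs to the
#'   volume when its value is >= threshold.
#' @return List with `points` (m x 3 matrix of lattice coordinates, A),
#'   `n_points`, and `volume` = n_points * spacing^3 (A^3; a
#'   point-counting estimator).
#' @export
occupied_volume <- function(map, threshold) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  keep <- which(map$values >= threshold - 1e-12)
  g <- map$grid
  nz <- g$dims[3]; ny <- g$dims[2]
  k <- (keep - 1) %% nz
  j <- ((keep - 1) %/% nz) %% ny
  i <- (keep - 1) %/% (nz * ny)
  pts <- cbind(g$origin[1] + g$spacing * i,
               g$origin[2] + g$spacing * j,
               g$origin[3] + g$spacing * k)
  colnames(pts) <- c("x", "y", "z")
  list(points = pts, n_points = length(keep),
       volume = length(keep) * g$spacing^3)
}

# ---------------------------------------------------------------------------
# OpenDX scalar grid I/O
# ---------------------------------------------------------------------------

#' Write an occupancy map in OpenDX scalar format
#'
#' `object 1 class gridpositions` dialect, data in z-fastest order, three
#' values per line -- loadable by the common molecular viewers.
#'
#' @param map An occupancy map (or any list with `grid` and `values`).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_dx <- function(map, path) {
  g <- map$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid written by portaldyn",
    sprintf("object 1 class gridpositions counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("origin %.6f %.6f %.6f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", g$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", g$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            as.integer(n_grid_points(g)))
  ), con)
  v <- map$values
  n <- length(v)
  pad <- (3 - n %% 3) %% 3
  vv <- c(v, rep(NA_real_, pad))
  m <- matrix(vv, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) {
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " ")
  })
  writeLines(lines, con)
  writeLines(c(
    'attribute "dep" string "positions"',
    'object "regular positions regular connections" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3'
  ), con)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' @param path DX file written by [write_dx()] or a compatible tool
#'   (regular gridpositions/gridconnections, scalar data).
#' @return An `occupancy_map` (with `n_frames = NA` unless recorded,
#'   since DX does not store it).
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  gp <- grep("class gridpositions", lines, value = TRUE)
  if (!length(gp)) stop("malformed DX file: no gridpositions object")
  dims <- as.integer(strsplit(sub(".*counts\\s+", "", gp[1]), "\\s+")[[1]])
  org_line <- grep("^\\s*origin", lines, value = TRUE)
  if (!length(org_line)) stop("malformed DX file: no origin")
  origin <- as.numeric(strsplit(trimws(sub("origin", "", org_line[1])),
                                "\\s+")[[1]])
  deltas <- grep("^\\s*delta", lines, value = TRUE)
  if (length(deltas) < 3) stop("malformed DX file: need 3 delta lines")
  dmat <- t(vapply(deltas[1:3], function(l) {
    as.numeric(strsplit(trimws(sub("delta", "", l)), "\\s+")[[1]])
  }, numeric(3)))
  spacing <- dmat[1, 1]
  if (abs(dmat[2, 2] - spacing) > 1e-9 || abs(dmat[3, 3] - spacing) > 1e-9) {
    stop("only isotropic axis-aligned DX grids are supported")
  }
  data_at <- grep("data follows", lines)
  if (!length(data_at)) stop("malformed DX file: no data section")
  n_items <- prod(as.numeric(dims))
  vals <- numeric(0)
  i <- data_at[1] + 1
  while (length(vals) < n_items && i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(attribute|object|component)", ln)) break
    vals <- c(vals, as.numeric(strsplit(ln, "\\s+")[[1]]))
    i <- i + 1
  }
  if (length(vals) != n_items) {
    stop(sprintf("malformed DX file: expected %d data values, found %d",
                 n_items, length(vals)))
  }
  structure(list(grid = grid_spec(origin, spacing, dims), values = vals,
                 n_frames = NA_integer_, selection_text = ""),
            class = "occupancy_map")
}

#' Export an iso-occupancy point set as PDB pseudo-atoms
#'
#' Convenience for visual inspection in a molecular viewer: each lattice
#' point in the volume becomes a HETATM pseudo-atom.
#'
#' @param vol Result of [occupied_volume()].
#' @param path Output PDB path.
#' @return Invisibly, `path`.
#' @export
write_volume_pdb <- function(vol, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(vol$points)
  for (i in seq_len(n)) {
    writeLines(sprintf(
      "HETATM%5d  DU  GRD A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      i %% 100000, i %% 10000,
      vol$points[i, 1], vol$points[i, 2], vol$points[i, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}
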