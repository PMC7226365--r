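# ---------------------------------------------------------------------------
# Multi-structure comparison: Kabsch superposition, pairwise RMSD
# matrices, and a classical-MDS 2D embedding of the matrix.  The
# RMSD-plus-MDS pipeline is a deliberate, documented surrogate for
# elastic structural-similarity scores: on rigid or near-rigid structure
# families it reproduces the same qualitative clustering in the plane.
# ---------------------------------------------------------------------------

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation (det = +1, reflections corrected) and
#' translation minimising the RMSD between `mobile[fit_idx, ]` and
#' `reference[fit_idx, ]`.  Row-vector convention: the transformed mobile
#' coordinates are `mobile %*% rotation + translation` (translation
#' recycled per row).
#'
#' @param mobile,reference n x 3 coordinate matrices (equal n, matched
#'   atom order).
#' @param fit_idx Indices used for the fit (>= 3, non-collinear); default
#'   all rows.
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (A, over the fit set after the transform).
#' @export
kabsch_superpose <- function(mobile, reference, fit_idx = seq_len(nrow(mobile))) {
  stopifnot(nrow(mobile) == nrow(reference))
  if (length(fit_idx) < 3) stop("need at least 3 fit atoms")
  p <- mobile[fit_idx, , drop = FALSE]
  q <- reference[fit_idx, , drop = FALSE]
  pc <- colMeans(p); qc <- colMeans(q)
  p0 <- sweep(p, 2, pc); q0 <- sweep(q, 2, qc)
  if (svd(p0)$d[2] < 1e-9) stop("fit atoms are collinear or coincident")
  h <- t(p0) %*% q0
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- qc - as.vector(pc %*% rot)
  moved <- sweep(p %*% rot, 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((moved - q)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

#' Pair residues/atoms between two structures
#'
#' One-to-one pairing by (residue_number, atom_name) within the selection;
#' entries present in only one structure are dropped and counted.
#'
#' @param struct_a,struct_b Lists with `topology` and `frame` (as returned
#'   by [build_ideal_helix()], or assembled from a trajectory frame).
#' @param sel Selection applied to both structures.
#' @param atom_names Optional atom-name filter applied on top of `sel`
#'   (e.g. `c("N","CA","C","O")` for backbone, `"CA"` for CA-only).
#' @return List with `xyz_a`, `xyz_b` (m x 3 matched coordinates),
#'   `n_matched`, `n_dropped`.
#' @export
pair_residues <- function(struct_a, struct_b, sel = selection(),
                          atom_names = NULL) {
  key_tab <- function(s) {
    idx <- resolve_selection(sel, s$topology)
    a <- s$topology$atoms[idx, ]
    if (!is.null(atom_names)) {
      keep <- toupper(a$atom_name) %in% toupper(atom_names)
      idx <- idx[keep]; a <- a[keep, ]
    }
    data.frame(key = paste(a$residue_number, toupper(a$atom_name), sep = "|"),
               idx = idx, stringsAsFactors = FALSE)
  }
  ta <- key_tab(struct_a); tb <- key_tab(struct_b)
  common <- intersect(ta$key, tb$key)
  if (!length(common)) stop("no common residue/atom pairs between structures")
  ia <- ta$idx[match(common, ta$key)]
  ib <- tb$idx[match(common, tb$key)]
  list(xyz_a = struct_a$frame[ia, , drop = FALSE],
       xyz_b = struct_b$frame[ib, , drop = FALSE],
       n_matched = length(common),
       n_dropped = (nrow(ta) - length(common)) + (nrow(tb) - length(common)))
}

#' Pairwise RMSD matrix over a set of structures
#'
#' Entry (i, j) is the Kabsch-superposed RMSD of the paired atoms of
#' structures i and j; each pair is computed once, so the matrix is
#' symmetric with a zero diagonal by construction.
#'
#' @param structures Named list of structures (`topology` + `frame`).
#' @param sel Selection applied to every structure.
#' @param atom_names Atom-name filter, see [pair_residues()].
#' @return Object of class `"similarity_matrix"`: the labelled symmetric
#'   RMSD matrix (A).
#' @export
rmsd_matrix <- function(structures, sel = selection(), atom_names = NULL) {
  n <- length(structures)
  if (n < 2) stop("need at least 2 structures")
  labels <- names(structures)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pr <- pair_residues(structures[[i]], structures[[j]], sel, atom_names)
      m[i, j] <- m[j, i] <-
        kabsch_superpose(pr$xyz_a, pr$xyz_b)$rmsd
    }
  }
  structure(m, class = c("similarity_matrix", "matrix"))
}

#' Classical (Torgerson) MDS embedding of a distance matrix
#'
#' Double-centres -D^2/2, eigendecomposes, and keeps the top `dims`
#' non-negative eigenpairs.  The embedding is centred at the origin and
#' the sign of each axis is fixed so the first point has non-negative
#' coordinates, making the output deterministic.
#'
#' @param d Symmetric non-negative distance matrix (zero diagonal), e.g.
#'   from [rmsd_matrix()].
#' @param dims Embedding dimension (default 2).
#' @return Object of class `"embedding2d"`: matrix n x dims with the input
#'   labels as rownames and eigenvalues in attribute `"eig"`.
#' @export
mds_embed <- function(d, dims = 2) {
  d <- as.matrix(unclass(d))
  n <- nrow(d)
  if (n != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d * d) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(dims)], 0)
  # eigenvalues at numerical-noise scale are exact zeros (flat axes)
  lam[lam <= max(abs(e$values)) * 1e-12] <- 0
  x <- e$vectors[, seq_len(dims), drop = FALSE] %*% diag(sqrt(lam), dims)
  for (k in seq_len(dims)) {
    pivot <- which(abs(x[, k]) > 1e-12)[1]
    if (!is.na(pivot) && x[pivot, k] < 0) x[, k] <- -x[, k]
  }
  rownames(x) <- rownames(d)
  colnames(x) <- paste0("dim", seq_len(dims))
  attr(x, "eig") <- e$values
  class(x) <- c("embedding2d", class(x))
  x
}

#' Assemble a structure (topology + frame) from a trajectory frame
#'
#' @param traj A trajectory.
#' @param i Frame index (default: final frame, the usual input to
#'   end-point structure comparisons).
#' @return List with `topology` and `frame`.
#' @export
structure_from_frame <- function(traj, i = n_frames(traj)) {
  list(topology = traj$topology, frame = get_frame(traj, i))
}
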