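# ---------------------------------------------------------------------------
# Backbone hydrogen-bond based alpha-helix assignment and segmentation.
#
# The Kabsch-Sander electrostatic model scores a backbone N-H...O=C
# hydrogen bond as
#     E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  kcal/mol
# and accepts it when E < -0.5 kcal/mol.  An (i, i+4) bond is a 4-turn at
# i; two consecutive 4-turns (i-1 and i) make residues i..i+3 helical
# (the minimal alpha-helix rule).  Only the alpha pattern is implemented;
# 3-10 and pi variants are not distinguished.
# ---------------------------------------------------------------------------

KS_COUPLING <- 0.084 * 332  # kcal/mol * A, fixed Kabsch-Sander constant

#' Kabsch-Sander hydrogen-bond energy
#'
#' @param n_xyz,h_xyz Donor backbone N and amide H coordinates (A).
#' @param c_xyz,o_xyz Acceptor backbone C and O coordinates (A).
#' @param coupling Energy constant (kcal/mol A); override only to emulate
#'   other DSSP builds.
#' @return Energy in kcal/mol; `Inf` when any interatomic distance is
#'   below 0.5 A (clash guard).
#' @export
ks_energy <- function(n_xyz, h_xyz, c_xyz, o_xyz, coupling = KS_COUPLING) {
  r_on <- vnorm(o_xyz - n_xyz)
  r_ch <- vnorm(c_xyz - h_xyz)
  r_oh <- vnorm(o_xyz - h_xyz)
  r_cn <- vnorm(c_xyz - n_xyz)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(Inf)
  coupling * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

#' Place missing amide hydrogens
#'
#' Standard DSSP construction: H sits 1.0 A from N along the direction of
#' the preceding residue's C=O bond reversed (anti to the carbonyl).
#' Residues with an experimentally present amide H keep it; the first
#' residue of a chain, prolines, and residues after a chain break
#' (C(prev)-N distance > 2.5 A) get no H and are flagged.
#'
#' @param top A [topology()].
#' @param frame n x 3 coordinate matrix.
#' @return List: `h_xyz` (n_residues x 3 matrix, NA rows where no H),
#'   `flagged` (indices into the residue table with no placeable H).
#' @export
place_amide_hydrogens <- function(top, frame) {
  res <- top$residues
  nr <- nrow(res)
  h_xyz <- matrix(NA_real_, nr, 3)
  flagged <- integer(0)
  idx_of <- function(i, name) residue_atom_index(top, res$chain_id[i],
                                                 res$residue_number[i], name)
  for (i in seq_len(nr)) {
    hi <- idx_of(i, "H")
    if (!is.na(hi)) {
      h_xyz[i, ] <- frame[hi, ]
      next
    }
    if (toupper(res$residue_name[i]) == "PRO") {
      flagged <- c(flagged, i)
      next
    }
    ni <- idx_of(i, "N")
    prev_ok <- i > 1 && res$chain_id[i - 1] == res$chain_id[i]
    ci_prev <- if (prev_ok) idx_of(i - 1, "C") else NA_integer_
    oi_prev <- if (prev_ok) idx_of(i - 1, "O") else NA_integer_
    if (is.na(ni) || is.na(ci_prev) || is.na(oi_prev)) {
      flagged <- c(flagged, i)
      next
    }
    if (vnorm(frame[ni, ] - frame[ci_prev, ]) > 2.5) {  # chain break
      flagged <- c(flagged, i)
      next
    }
    dir <- unitv(frame[ci_prev, ] - frame[oi_prev, ])
    h_xyz[i, ] <- frame[ni, ] + dir
  }
  list(h_xyz = h_xyz, flagged = flagged)
}

#' Alpha-helix flags from backbone hydrogen bonding
#'
#' @param top A [topology()] with backbone N, C, O atoms.
#' @param frame n x 3 coordinate matrix (typically a trajectory's final
#'   frame).
#' @param energy_cutoff H-bond acceptance threshold, kcal/mol.
#' @return Logical vector over the topology's residue table: TRUE where
#'   the residue is part of a minimal alpha-helix.
#' @export
assign_helix <- function(top, frame, energy_cutoff = -0.5) {
  res <- top$residues
  nr <- nrow(res)
  if (nr < 5) stop("helix assignment needs at least 5 residues")
  hs <- place_amide_hydrogens(top, frame)
  idx_of <- function(i, name) residue_atom_index(top, res$chain_id[i],
                                                 res$residue_number[i], name)
  # turn4[i]: H-bond N-H(i+4) -> C=O(i), both residues on the same chain
  turn4 <- rep(FALSE, nr)
  for (i in seq_len(nr - 4)) {
    j <- i + 4
    if (res$chain_id[i] != res$chain_id[j]) next
    if (any(is.na(hs$h_xyz[j, ]))) next
    ci <- idx_of(i, "C"); oi <- idx_of(i, "O"); nj <- idx_of(j, "N")
    if (is.na(ci) || is.na(oi) || is.na(nj)) next
    e <- ks_energy(frame[nj, ], hs$h_xyz[j, ], frame[ci, ], frame[oi, ])
    turn4[i] <- e < energy_cutoff
  }
  helical <- rep(FALSE, nr)
  for (i in 2:max(2, nr - 3)) {
    if (turn4[i - 1] && turn4[i]) helical[i:(i + 3)] <- TRUE
  }
  helical
}

#' Segment helical flags inside a region into helices and hinges
#'
#' Maximal helical runs inside the inclusive residue-number region become
#' segments; interior non-helical residues strictly between consecutive
#' segments are the hinges.
#'
#' @param flags Logical vector over the topology residue table (from
#'   [assign_helix()]), or a data.frame with `residue_number` and
#'   `helical` columns.
#' @param top Topology (needed when `flags` is a bare vector).
#' @param region Length-2 numeric: inclusive residue-number range.
#' @param chain_id Chain to segment (default first chain).
#' @return Object of class `"helix_segmentation"`: list with `region`,
#'   `segments` (two-column matrix of inclusive ranges), `hinges`
#'   (residue numbers between consecutive segments), `text`.
#' @export
segment_helices <- function(flags, top = NULL, region, chain_id = NULL) {
  if (is.data.frame(flags)) {
    resno <- flags$residue_number
    helical <- flags$helical
  } else {
    stopifnot(!is.null(top))
    res <- top$residues
    if (is.null(chain_id)) chain_id <- res$chain_id[1]
    keep <- res$chain_id == chain_id
    resno <- res$residue_number[keep]
    helical <- flags[keep]
  }
  in_region <- resno >= region[1] & resno <= region[2]
  resno <- resno[in_region]
  helical <- helical[in_region]
  ord <- order(resno)
  resno <- resno[ord]; helical <- helical[ord]
  segments <- matrix(numeric(0), ncol = 2)
  if (any(helical)) {
    r <- rle(helical)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      segments <- rbind(segments, c(resno[starts[k]], resno[ends[k]]))
    }
  }
  hinges <- numeric(0)
  if (nrow(segments) >= 2) {
    for (k in seq_len(nrow(segments) - 1)) {
      hinges <- c(hinges, resno[resno > segments[k, 2] &
                                resno < segments[k + 1, 1]])
    }
  }
  structure(list(region = region, segments = segments, hinges = hinges,
                 text = format_segments(segments)),
            class = "helix_segmentation")
}

#' @export
print.helix_segmentation <- function(x, ...) {
  cat(sprintf("<helix_segmentation> region %g-%g: %s", x$region[1],
              x$region[2], if (nzchar(x$text)) x$text else "(no helix)"))
  if (length(x$hinges)) {
    cat(sprintf("  [hinge: %s]", paste(x$hinges, collapse = ",")))
  }
  cat("\n")
  invisible(x)
}

#' Render helix segments as text
#'
#' Format: `"139-150 + 153-177"` with a figure dash (U+2012) inside each
#' inclusive range and " + " between segments, the layout used in
#' structural tables.
#'
#' @param segments Two-column matrix of inclusive residue ranges.
#' @return Single string ("" when no segments).
#' @export
format_segments <- function(segments) {
  if (!nrow(segments)) return("")
  paste(apply(segments, 1, function(s)
    sprintf("%d\u2012%d", as.integer(s[1]), as.integer(s[2]))),
    collapse = " + ")
}

#' Parse a helix-segment text rendering
#'
#' Accepts hyphen, en/em/figure dashes, and "+"-joined ranges; the inverse
#' of [format_segments()].
#'
#' @param text e.g. `"139-150 + 153-177"`.
#' @return Two-column numeric matrix of inclusive ranges.
#' @export
parse_segments <- function(text) {
  if (!nzchar(trimws(text))) return(matrix(numeric(0), ncol = 2))
  parts <- strsplit(text, "\\+")[[1]]
  segs <- t(vapply(parts, function(p) {
    nums <- as.numeric(strsplit(trimws(p),
                                "[-\u2010\u2012\u2013\u2014\u2015]")[[1]])
    if (length(nums) != 2 || anyNA(nums)) stop("cannot parse segment: ", p)
    nums
  }, numeric(2)))
  dimnames(segs) <- NULL
  segs
}

#' Ingest an external per-residue helix assignment
#'
#' Lets segmentation run on assignments computed by a reference
#' secondary-structure tool: a whitespace/CSV table with `residue_number`
#' and a structure code column where "H" means helix.
#'
#' @param path Table path with header; columns `residue_number`, `ss`.
#' @return data.frame with `residue_number`, `helical` suitable for
#'   [segment_helices()].
#' @export
read_helix_assignment <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("residue_number", "ss") %in% names(tab))) {
    stop("helix assignment table needs residue_number and ss columns")
  }
  data.frame(residue_number = tab$residue_number,
             helical = toupper(tab$ss) == "H")
}
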