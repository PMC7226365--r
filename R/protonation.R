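# ---------------------------------------------------------------------------
# Consensus pKa merging and pH-dependent protonation / net-charge
# assignment.
#
# Predicted pKa values from several methods are accepted for a residue when
# the largest subset of methods that all pairwise agree within +/-0.1 pKa
# units has at least two members; the consensus value is the mean of that
# subset.  Protonation at a given pH then follows the closed-inequality
# rules: acids (Asp/Glu, and Tyr) are protonated (neutral) when
# pKa >= pH, histidines are protonated (+1) when pKa >= pH, and Lys/Arg
# are always +1 in the 0-14 range considered.  (Protonation is uniformly
# the closed pKa >= pH test; what differs per residue type is the charge
# carried by each state.)
# ---------------------------------------------------------------------------

IONIZABLE <- c("ASP", "GLU", "HIS", "TYR", "LYS", "ARG")

# Fallback model pKa values used (and flagged) for unresolved residues.
MODEL_PKA <- c(ASP = 3.65, GLU = 4.25, HIS = 6.3, TYR = 9.8, LYS = 10.4,
               ARG = 12.0)

#' Merge multi-method pKa predictions into consensus values
#'
#' @param predictions data.frame with columns `chain_id`, `residue_number`,
#'   `residue_name`, `method`, `pka` (long format, as read by
#'   [read_pka_tables()] or produced by [build_pka_tables()]).
#' @param tol Pairwise agreement tolerance in pKa units (default 0.1).
#' @param min_agree Minimum number of agreeing methods (default 2).
#' @return data.frame of class `"consensus_pka"` with one row per residue:
#'   `chain_id`, `residue_number`, `residue_name`, `status`
#'   ("resolved"/"unresolved"), `pka` (NA when unresolved),
#'   `supporting_methods` (comma-joined), `n_support`.
#' @export
consensus_pka <- function(predictions, tol = 0.1, min_agree = 2) {
  req <- c("chain_id", "residue_number", "residue_name", "method", "pka")
  stopifnot(all(req %in% names(predictions)))
  bad <- !(toupper(predictions$residue_name) %in% IONIZABLE)
  if (any(bad)) {
    stop("non-ionizable residue in pKa table: ",
         paste(unique(predictions$residue_name[bad]), collapse = ", "))
  }
  key <- paste(predictions$chain_id, predictions$residue_number, sep = "|")
  out <- lapply(split(seq_len(nrow(predictions)), key), function(rows) {
    p <- predictions[rows, ]
    res <- data.frame(chain_id = p$chain_id[1],
                      residue_number = p$residue_number[1],
                      residue_name = toupper(p$residue_name[1]),
                      stringsAsFactors = FALSE)
    if (nrow(p) < min_agree) {
      warning(sprintf(
        "residue %s/%s predicted by only %d method(s); unresolved",
        p$chain_id[1], p$residue_number[1], nrow(p)))
      return(cbind(res, status = "unresolved", pka = NA_real_,
                   supporting_methods = "", n_support = 0L))
    }
    best <- best_agreeing_subset(p$pka, tol)
    if (length(best) >= min_agree) {
      cbind(res, status = "resolved", pka = mean(p$pka[best]),
            supporting_methods = paste(p$method[best], collapse = ","),
            n_support = length(best))
    } else {
      cbind(res, status = "unresolved", pka = NA_real_,
            supporting_methods = "", n_support = 0L)
    }
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out <- out[order(out$chain_id, out$residue_number), ]
  rownames(out) <- NULL
  class(out) <- c("consensus_pka", "data.frame")
  out
}

# Largest subset of values that all pairwise agree within tol; among
# equal-size subsets the one with the smallest spread wins, then the one
# appearing first.  Method counts are tiny (3-5), so exhaustive subset
# enumeration is exact and cheap.
best_agreeing_subset <- function(values, tol) {
  n <- length(values)
  best <- integer(0)
  best_spread <- Inf
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(idx) < length(best)) next
    v <- values[idx]
    if (max(v) - min(v) <= tol + 1e-9) {
      spread <- max(v) - min(v)
      if (length(idx) > length(best) ||
          (length(idx) == length(best) && spread < best_spread - 1e-12)) {
        best <- idx
        best_spread <- spread
      }
    }
  }
  best
}

#' Read delimited pKa prediction tables
#'
#' Each file must contain columns `chain`,`resnum`,`resname`,`method`,`pka`
#' (header required; comma or whitespace delimited).  Multiple files are
#' concatenated, so one file per predictor works naturally.
#'
#' @param paths Character vector of file paths.
#' @return Long-format data.frame as required by [consensus_pka()].
#' @export
read_pka_tables <- function(paths) {
  tabs <- lapply(paths, function(p) {
    first <- readLines(p, n = 1)
    sep <- if (grepl(",", first)) "," else ""
    tab <- utils::read.table(p, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    ren <- c(chain = "chain_id", resnum = "residue_number",
             resname = "residue_name")
    for (k in names(ren)) {
      if (k %in% names(tab)) names(tab)[names(tab) == k] <- ren[[k]]
    }
    need <- c("chain_id", "residue_number", "residue_name", "method", "pka")
    if (!all(need %in% names(tab))) {
      stop("pKa table ", p, " lacks required columns")
    }
    tab[, need]
  })
  do.call(rbind, c(tabs, list(make.row.names = FALSE)))
}

#' Assign protonation states and formal charges at a pH
#'
#' Rules (closed inequalities): Asp/Glu protonated (charge 0) when
#' pKa >= pH, else -1; His protonated (+1) when pKa >= pH, else 0;
#' Tyr 0 when pKa >= pH, else -1; Lys/Arg always +1.  Unresolved residues
#' fall back to model pKa values and are flagged.
#'
#' @param consensus A [consensus_pka()] table.
#' @param pH Target pH in \[0, 14\].
#' @param fallback Named vector of model pKa values for unresolved
#'   residues.
#' @return Object of class `"protonation_assignment"`: data.frame with
#'   `protonated`, `formal_charge`, `used_fallback` per residue, plus
#'   attributes `pH` and `net_charge`.
#' @export
assign_protonation <- function(consensus, pH,
                               fallback = MODEL_PKA) {
  if (pH < 0 || pH > 14) stop("pH must be in [0, 14]")
  df <- as.data.frame(consensus)
  pka <- df$pka
  fb <- is.na(pka) | df$status == "unresolved"
  pka[fb] <- unname(fallback[df$residue_name[fb]])
  rn <- df$residue_name
  protonated <- logical(nrow(df))
  charge <- integer(nrow(df))
  acid <- rn %in% c("ASP", "GLU", "TYR")
  protonated[acid] <- pka[acid] >= pH
  charge[acid] <- ifelse(protonated[acid], 0L, -1L)
  his <- rn == "HIS"
  protonated[his] <- pka[his] >= pH
  charge[his] <- ifelse(protonated[his], 1L, 0L)
  basev <- rn %in% c("LYS", "ARG")
  protonated[basev] <- TRUE
  charge[basev] <- 1L
  out <- data.frame(df[, c("chain_id", "residue_number", "residue_name")],
                    pka = pka, protonated = protonated,
                    formal_charge = charge, used_fallback = fb,
                    stringsAsFactors = FALSE)
  attr(out, "pH") <- pH
  attr(out, "net_charge") <- sum(charge)
  class(out) <- c("protonation_assignment", "data.frame")
  out
}

#' @export
print.protonation_assignment <- function(x, ...) {
  cat(sprintf("<protonation_assignment> pH %.2f, %d residues, net charge %+d\n",
              attr(x, "pH"), nrow(x), net_charge(x)))
  if (any(x$used_fallback)) {
    cat(sprintf("  (%d residue(s) used fallback model pKa)\n",
                sum(x$used_fallback)))
  }
  invisible(x)
}

#' Net formal charge of a protonation assignment
#'
#' Sum of the side-chain formal charges; termini are excluded (side-chain
#' arithmetic only).
#'
#' @param assignment A [assign_protonation()] result (an empty one gives 0).
#' @return Integer net charge in elementary-charge units.
#' @export
net_charge <- function(assignment) {
  if (is.null(assignment) || nrow(assignment) == 0) return(0L)
  as.integer(sum(assignment$formal_charge))
}

# Representative side-chain atom that carries the formal charge in PQR
# export (documented mapping; protons are not modelled explicitly).
CHARGE_ATOM <- c(ASP = "OD2", GLU = "OE2", HIS = "NE2", TYR = "OH",
                 LYS = "NZ", ARG = "NH1")

#' Write PQR-style per-atom charges
#'
#' PDB-like whitespace-delimited PQR records: occupancy/B-factor columns
#' carry per-atom charge and radius.  Each residue's formal charge is
#' placed on its titratable group's representative atom (OD2/OE2/NE2/OH/
#' NZ/NH1); every other atom carries 0.  The file's summed charge
#' therefore equals the assignment's net charge exactly.
#'
#' @param top A [topology()] covering the assignment's residues.
#' @param assignment A [assign_protonation()] result.
#' @param path Output file.
#' @param frame Optional n x 3 coordinate matrix (default: zeros, for
#'   charge bookkeeping without structure).
#' @return Invisibly, `path`.
#' @export
write_pqr_charges <- function(top, assignment, path, frame = NULL) {
  a <- top$atoms
  if (is.null(frame)) frame <- matrix(0, nrow(a), 3)
  charges <- numeric(nrow(a))
  for (i in seq_len(nrow(assignment))) {
    rs <- assignment[i, ]
    in_res <- which(a$chain_id == rs$chain_id &
                    a$residue_number == rs$residue_number)
    if (!length(in_res)) {
      stop(sprintf("assignment residue %s/%s absent from topology",
                   rs$chain_id, rs$residue_number))
    }
    if (rs$formal_charge == 0L) next
    target <- CHARGE_ATOM[[rs$residue_name]]
    hit <- in_res[toupper(a$atom_name[in_res]) == target]
    if (!length(hit)) {
      hit <- in_res[toupper(a$atom_name[in_res]) == "CA"]
      if (!length(hit)) hit <- in_res[1]
      warning(sprintf(
        "residue %s/%s lacks %s; charge placed on %s",
        rs$chain_id, rs$residue_number, target, a$atom_name[hit[1]]))
    }
    charges[hit[1]] <- rs$formal_charge
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK   1 PQR written by portaldyn (formal side-chain charges)",
             con)
  for (i in seq_len(nrow(a))) {
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f %8.3f %8.3f %7.4f %6.3f",
      i, a$atom_name[i], a$residue_name[i], a$chain_id[i],
      a$residue_number[i], frame[i, 1], frame[i, 2], frame[i, 3],
      charges[i], a$vdw_radius[i]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read back the charge column of a PQR file
#'
#' @param path PQR file written by [write_pqr_charges()].
#' @return Numeric vector of per-atom charges.
#' @export
read_pqr_charges <- function(path) {
  lines <- grep("^ATOM|^HETATM", readLines(path), value = TRUE)
  vapply(strsplit(trimws(lines), "\\s+"), function(f) {
    as.numeric(f[length(f) - 1])
  }, numeric(1))
}
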