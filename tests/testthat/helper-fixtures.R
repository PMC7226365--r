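# Shared fixtures, all built in code at test time.

# A tiny two-chain PDB written as literal text (fixed-width ATOM records).
write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  HB1 ALA A   1       2.500   1.500   0.900  1.00  0.00           H",
    "ATOM      5  N   GLY A   2       2.100  -1.100   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       3.500  -1.300   0.200  1.00  0.00           C",
    "ATOM      7  CA  ALA B  10       9.000   0.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

# Brute-force occupancy oracle: plain double loop over points x atoms.
brute_occupancy <- function(frame, atom_indices, grid, radii) {
  occ <- integer(portaldyn::n_grid_points(grid))
  p <- 0L
  for (i in seq_len(grid$dims[1])) {
    for (j in seq_len(grid$dims[2])) {
      for (k in seq_len(grid$dims[3])) {
        p <- p + 1L
        pt <- grid$origin + grid$spacing * c(i - 1, j - 1, k - 1)
        for (a in seq_along(atom_indices)) {
          d2 <- sum((pt - frame[atom_indices[a], ])^2)
          if (d2 <= radii[a]^2 + 1e-12) {
            occ[p] <- 1L
            break
          }
        }
      }
    }
  }
  occ
}

# Note: portaldyn stores values z-fastest; the loop above runs k fastest
# too, so the orderings agree.

# Multi-method pKa table for a literal list of (resname, resno, values).
pka_rows <- function(resname, resno, values, chain = "A",
                     methods = paste0("m", seq_along(values))) {
  data.frame(chain_id = chain, residue_number = resno,
             residue_name = resname, method = methods, pka = values,
             stringsAsFactors = FALSE)
}

# Consensus table with one resolved row per residue (direct construction,
# bypassing the merge) for protonation-rule tests.
direct_consensus <- function(resname, resno, pka, chain = "A") {
  out <- data.frame(chain_id = chain, residue_number = resno,
                    residue_name = resname, status = "resolved", pka = pka,
                    supporting_methods = "a,b", n_support = 2L,
                    stringsAsFactors = FALSE)
  class(out) <- c("consensus_pka", "data.frame")
  out
}

# The printed side-chain composition of the CD1d antigen-binding domain:
# 7 Asp, 10 Glu, 9 Lys, 9 Arg, 4 His.  Residue numbers use the structure's
# numbering where the source names them (Asp80, Glu132, Glu175,
# His38/68/105/115); the rest are synthetic placeholders.
domain_composition <- function() {
  data.frame(
    residue_name = c(rep("ASP", 7), rep("GLU", 10), rep("LYS", 9),
                     rep("ARG", 9), rep("HIS", 4)),
    residue_number = c(
      c(80, 201:206),            # Asp80 + placeholders
      c(132, 175, 301:308),      # Glu132, Glu175 + placeholders
      401:409,                   # Lys
      501:509,                   # Arg
      c(38, 68, 105, 115)        # His
    ),
    stringsAsFactors = FALSE
  )
}

# Consensus pKa values reproducing the two pH scenarios: at pH 7 all
# acids deprotonated and His neutral (+1 net); at pH 4.5 exactly Asp80,
# Glu132, Glu175 and the four His protonate (+8 net).
domain_consensus <- function() {
  comp <- domain_composition()
  pka <- numeric(nrow(comp))
  pka[comp$residue_name == "ASP"] <- 3.6
  pka[comp$residue_name == "GLU"] <- 4.1
  pka[comp$residue_number == 80] <- 5.2    # Asp80
  pka[comp$residue_number == 132] <- 4.9   # Glu132
  pka[comp$residue_number == 175] <- 4.7   # Glu175
  pka[comp$residue_name == "HIS"] <- 6.1   # >= 4.5, <= 7 is false -> neutral at 7
  pka[comp$residue_name == "LYS"] <- 10.4
  pka[comp$residue_name == "ARG"] <- 12.0
  direct_consensus(comp$residue_name, comp$residue_number, pka)
}
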