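#' Van der Waals radius tables
#'
#' Bondi radii by element symbol, used to assign a `vdw_radius` to every
#' atom when a topology is read.  The table ships as a plain CSV under
#' `inst/extdata/` so any other radius set (CHARMM, AMBER, ...) can be
#' substituted by pointing `read_topology()` at a different file.
#'
#' @param path Optional path to a CSV with columns `element,radius`.
#'   Defaults to the bundled Bondi set.
#' @return Named numeric vector, radii in Angstrom, names are upper-case
#'   element symbols.
#' @export
vdw_radius_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "radii_bondi.csv", package = "portaldyn")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "radius") %in% names(tab)))
  r <- tab$radius
  names(r) <- toupper(tab$element)
  if (any(r <= 0)) stop("radius table contains non-positive radii")
  r
}

#' Look up van der Waals radii for atoms
#'
#' Elements are matched against the table; an atom whose element is absent
#' falls back to the first alphabetic character of its PDB atom name
#' (so e.g. "CG2" resolves to carbon).
#'
#' @param element Character vector of element symbols (may be empty strings).
#' @param atom_name Character vector of PDB atom names, used as fallback.
#' @param table Named radius vector from [vdw_radius_table()].
#' @return Numeric vector of radii (Angstrom).
#' @export
lookup_vdw_radius <- function(element, atom_name, table = vdw_radius_table()) {
  el <- toupper(trimws(element))
  r <- unname(table[el])
  miss <- is.na(r) | el == ""
  if (any(miss)) {
    fallback <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", atom_name[miss]))
    r[miss] <- unname(table[fallback])
  }
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop(sprintf(
      "no van der Waals radius for atom '%s' (element '%s'); extend the radius table",
      atom_name[bad], element[bad]
    ))
  }
  r
}
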