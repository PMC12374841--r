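# Structure model: atom tables, PDB I/O, interfaces and inter-partner contacts.
#
# A complex is held as a plain data.frame of non-hydrogen ATOM records plus a
# chain -> partner ("antibody"/"antigen") assignment. Distances are strict
# "< cutoff" Euclidean atom-atom distances throughout, with a 4 Angstrom
# default, the same rule used for interfaces, contacts and graph edges.

#' Construct a complex structure
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer), `ins`
#'   (insertion code, "" when absent), `resid` (3-letter residue name),
#'   `elety` (atom name), `element`, and coordinates `x`, `y`, `z` in
#'   Angstrom.
#' @param partner_of Named character vector mapping every chain id to
#'   `"antibody"` or `"antigen"`.
#' @return An object of class `complex_structure`.
#' @export
complex_structure <- function(atoms, partner_of) {
  need <- c("chain", "resno", "ins", "resid", "elety", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$element))) stop("empty element fields")
  chains <- unique(atoms$chain)
  if (!all(chains %in% names(partner_of)))
    stop("chains without a partner assignment: ",
         paste(setdiff(chains, names(partner_of)), collapse = ", "))
  partner_of <- partner_of[names(partner_of) %in% chains]
  if (!all(partner_of %in% c("antibody", "antigen")))
    stop("partner_of values must be 'antibody' or 'antigen'")
  if (length(unique(partner_of)) < 2)
    stop("both partners (antibody and antigen) must be non-empty")
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$ins), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, partner_of = partner_of),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  np <- table(x$partner_of[x$atoms$chain])
  cat("complex_structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$ins))),
      "residues\n")
  cat("  chains:", paste(sprintf("%s(%s)", names(x$partner_of), x$partner_of),
                         collapse = ", "), "\n")
  invisible(x)
}

coords_of <- function(cs, idx = NULL) {
  m <- as.matrix(cs$atoms[, c("x", "y", "z")])
  if (is.null(idx)) m else m[idx, , drop = FALSE]
}

partner_mask <- function(cs) {
  unname(cs$partner_of[cs$atoms$chain] == "antibody")
}

res_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")

#' Read a PDB file into a complex structure
#'
#' Parses ATOM records with [bio3d::read.pdb()]. Hydrogens and HETATM records
#' are excluded; for alternate-location duplicates only the first-listed
#' conformer is kept; insertion codes are preserved.
#'
#' @param path Path to a PDB file.
#' @param partner_assignment Named character vector chain -> partner.
#' @return A [complex_structure()].
#' @export
read_pdb <- function(path, partner_assignment) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  elem <- at$elesy
  elem[is.na(elem) | !nzchar(elem)] <- substr(trimws(at$elety[is.na(elem) | !nzchar(elem)]), 1, 1)
  at$element <- toupper(trimws(elem))
  at <- at[at$element != "H" & at$element != "D", , drop = FALSE]
  if (!nrow(at)) stop("no atoms after filtering HETATM/hydrogens: ", path)
  ins <- at$insert
  ins[is.na(ins)] <- ""
  at$ins <- ins
  # first-listed altloc conformer only
  key <- paste(at$chain, at$resno, at$ins, at$elety, sep = "|")
  at <- at[!duplicated(key), , drop = FALSE]
  unknown <- setdiff(unique(at$chain), names(partner_assignment))
  if (length(unknown))
    stop("chain(s) not in partner_assignment: ", paste(unknown, collapse = ", "))
  atoms <- data.frame(chain = at$chain, resno = as.integer(at$resno),
                      ins = at$ins, resid = at$resid, elety = trimws(at$elety),
                      element = at$element,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  complex_structure(atoms, partner_assignment)
}

#' Write a complex structure to a PDB file
#'
#' Emits ATOM records only (single model, no altlocs) via
#' [bio3d::write.pdb()].
#'
#' @param cs A [complex_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_complex <- function(cs, path) {
  a <- cs$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  n <- nrow(a)
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", n),
                   resno = a$resno, resid = a$resid, eleno = seq_len(n),
                   elety = a$elety, chain = a$chain,
                   insert = ifelse(nzchar(a$ins), a$ins, NA),
                   elesy = a$element, o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Interface residues of a complex
#'
#' A residue is at the interface iff any of its non-hydrogen atoms lies
#' strictly within `cutoff` Angstrom of any non-hydrogen atom of the opposite
#' binding partner.
#'
#' @param cs A [complex_structure()].
#' @param cutoff Distance cutoff in Angstrom (default 4).
#' @return data.frame with one row per interface residue: `chain`, `resno`,
#'   `ins`, `resid`, `partner`.
#' @export
interface_residues <- function(cs, cutoff = 4.0) {
  ab <- partner_mask(cs)
  d2 <- cross_dist2(coords_of(cs)[ab, , drop = FALSE],
                    coords_of(cs)[!ab, , drop = FALSE])
  hit <- d2 < cutoff^2
  ab_rows <- which(ab)[rowSums(hit) > 0]
  ag_rows <- which(!ab)[colSums(hit) > 0]
  rows <- c(ab_rows, ag_rows)
  a <- cs$atoms[rows, , drop = FALSE]
  keep <- !duplicated(res_key(a))
  out <- a[keep, c("chain", "resno", "ins", "resid"), drop = FALSE]
  out$partner <- unname(cs$partner_of[out$chain])
  out <- out[order(out$chain, out$resno, out$ins), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count inter-partner atomic contacts
#'
#' Number of unordered non-hydrogen atom pairs, one atom on each binding
#' partner, strictly closer than `cutoff` Angstrom.
#'
#' @inheritParams interface_residues
#' @return Integer contact count.
#' @export
inter_partner_contacts <- function(cs, cutoff = 4.0) {
  ab <- partner_mask(cs)
  d2 <- cross_dist2(coords_of(cs)[ab, , drop = FALSE],
                    coords_of(cs)[!ab, , drop = FALSE])
  sum(d2 < cutoff^2)
}

#' Atom typing table
#'
#' Default element-class vocabulary used for one-hot node features:
#' \{C, N, O, S, P, halogen, metal, other\} (V = 8). Any element not covered
#' falls into the reserved "other" class; atoms are never dropped. A custom
#' table can be loaded from a two-column text file (element, class).
#'
#' @param path Optional path to a whitespace-delimited two-column file
#'   mapping elements to class names.
#' @return List with `classes` (character vector of class names, the last
#'   being `"other"`), `map` (named integer vector element -> 1-based index)
#'   and `V` (vocabulary size).
#' @export
atom_typing_table <- function(path = NULL) {
  if (is.null(path)) {
    halogens <- c("F", "CL", "BR", "I")
    metals <- c("NA", "MG", "K", "CA", "MN", "FE", "CO", "NI", "CU", "ZN")
    map <- c(stats::setNames(rep(1L, 1), "C"),
             stats::setNames(rep(2L, 1), "N"),
             stats::setNames(rep(3L, 1), "O"),
             stats::setNames(rep(4L, 1), "S"),
             stats::setNames(rep(5L, 1), "P"),
             stats::setNames(rep(6L, length(halogens)), halogens),
             stats::setNames(rep(7L, length(metals)), metals))
    classes <- c("C", "N", "O", "S", "P", "halogen", "metal", "other")
  } else {
    tab <- utils::read.table(path, header = FALSE, col.names = c("element", "class"),
                             stringsAsFactors = FALSE)
    classes <- unique(tab$class)
    if (!"other" %in% classes) classes <- c(classes, "other")
    map <- stats::setNames(match(tab$class, classes), toupper(tab$element))
  }
  structure(list(classes = classes, map = map, V = length(classes)),
            class = "atom_typing_table")
}

#' Type an atom
#'
#' @param element Character vector of element symbols.
#' @param table An [atom_typing_table()].
#' @return Integer vector of 1-based type indices in `[1, V]`; unknown
#'   elements map to the reserved "other" index.
#' @export
atom_type <- function(element, table = atom_typing_table()) {
  idx <- table$map[toupper(trimws(element))]
  idx[is.na(idx)] <- table$V
  unname(as.integer(idx))
}

# N x V one-hot node feature matrix for a subset of atoms.
atom_onehot <- function(atoms, table = atom_typing_table()) {
  idx <- atom_type(atoms$element, table)
  m <- matrix(0, nrow(atoms), table$V)
  m[cbind(seq_len(nrow(atoms)), idx)] <- 1
  m
}
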