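#' Supported AutoDock atom types
#'
#' The atom-type vocabulary used throughout the package: every affinity map
#' set carries one map per type in this universe (informative maps for types
#' present in the reference, all-zero general maps for the rest), so a
#' library compound containing any supported type can always be scored.
#'
#' @return Character vector of AutoDock atom-type codes.
#' @export
ad_atom_types <- function() {
  c("H", "HD", "HS", "C", "A", "N", "NA", "NS", "OA", "OS",
    "S", "SA", "F", "Cl", "Br", "I", "P")
}

# Element symbol implied by an AutoDock atom type.
ad_type_element <- function(ad_type) {
  map <- c(H = "H", HD = "H", HS = "H", C = "C", A = "C", N = "N",
           `NA` = "N", NS = "N", OA = "O", OS = "O", S = "S", SA = "S",
           F = "F", Cl = "Cl", Br = "Br", I = "I", P = "P")
  out <- unname(map[ad_type])
  out[is.na(out)] <- ad_type[is.na(out)]
  out
}

#' Construct a molecule object
#'
#' The package-internal molecule record: an atom table, a bond table and
#' (after preparation) AutoDock atom types, Gasteiger partial charges and a
#' torsion tree. Most users obtain molecules from [read_sdf()],
#' [read_pdbqt()] or [make_probe()] rather than calling this directly.
#'
#' @param name Identifier string.
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge`, `ad_type`.
#' @param bonds Data frame with columns `i`, `j`, `order` (1-based atom
#'   indices), or `NULL` for an isolated atom set.
#' @param torsions Data frame with columns `i`, `j` and a list column
#'   `moving` (atom indices displaced when the i-j bond rotates), or `NULL`.
#' @param prepared Logical: charges/types assigned and nonpolar hydrogens
#'   merged.
#' @param rigid Logical: all torsional freedom removed.
#' @return An object of class `lig_molecule`.
#' @export
new_molecule <- function(name, atoms, bonds = NULL, torsions = NULL,
                         prepared = FALSE, rigid = FALSE) {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  if (!"ad_type" %in% names(atoms)) atoms$ad_type <- NA_character_
  if (nrow(atoms) == 0L) abort("molecule must contain at least one atom")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) abort("atom coordinates must be finite")
  if (is.null(bonds)) {
    bonds <- tibble(i = integer(), j = integer(), order = integer())
  }
  bonds <- as_tibble(bonds)
  if (nrow(bonds) > 0 &&
      (max(bonds$i, bonds$j) > nrow(atoms) || min(bonds$i, bonds$j) < 1)) {
    abort("bond indices reference non-existent atoms")
  }
  if (is.null(torsions)) {
    torsions <- tibble(i = integer(), j = integer(), moving = list())
  }
  structure(
    list(name = name, atoms = atoms, bonds = bonds, torsions = torsions,
         prepared = prepared, rigid = rigid),
    class = "lig_molecule"
  )
}

#' @export
print.lig_molecule <- function(x, ...) {
  cat(sprintf(
    "<lig_molecule> %s: %d atoms, %d bonds, %d rotatable, %s%s\n",
    x$name, nrow(x$atoms), nrow(x$bonds), nrow(x$torsions),
    if (x$prepared) "prepared" else "unprepared",
    if (x$rigid) ", rigid" else ""
  ))
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param mol A `lig_molecule`.
#' @return Numeric n x 3 matrix of coordinates in Angstrom.
#' @export
coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

set_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

#' Geometric centroid of a molecule
#'
#' Unweighted mean of the atom coordinates; used as the grid-box center for
#' a reference ligand.
#'
#' @param mol A `lig_molecule` (or composite reference).
#' @return Numeric length-3 vector (Angstrom).
#' @export
centroid <- function(mol) {
  unname(colMeans(coords(mol)))
}

#' Axis-aligned extent of a molecule
#'
#' Per-axis maximum minus minimum atom coordinate; the molecular box size
#' used in grid-box determination.
#'
#' @param mol A `lig_molecule`.
#' @return Numeric length-3 vector `(dx, dy, dz)` in Angstrom.
#' @export
extent <- function(mol) {
  xyz <- coords(mol)
  unname(apply(xyz, 2, max) - apply(xyz, 2, min))
}

#' Total partial charge of a molecule
#' @param mol A `lig_molecule`.
#' @return Scalar net charge in elementary charge units.
#' @export
total_charge <- function(mol) {
  sum(mol$atoms$charge)
}

#' Count rotatable bonds
#'
#' Standard reporting definition: single, non-ring bonds between two
#' non-terminal heavy atoms. This is independent of the torsion tree a
#' prepared molecule carries (which follows AutoDock conventions and may,
#' e.g., include bonds that move only a polar hydrogen).
#'
#' @param mol A `lig_molecule` with a bond table.
#' @return Integer count.
#' @export
count_rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(0L)
  heavy <- mol$atoms$element != "H"
  # heavy-atom degree (number of heavy neighbours) per atom
  hb <- b[heavy[b$i] & heavy[b$j], , drop = FALSE]
  deg <- tabulate(c(hb$i, hb$j), nbins = nrow(mol$atoms))
  ring <- ring_bond_flags(mol)
  cand <- b$order == 1 & heavy[b$i] & heavy[b$j] & !ring &
    deg[b$i] >= 2 & deg[b$j] >= 2
  sum(cand)
}

# Flag each bond that is part of a cycle: removing it leaves the endpoints
# connected.
ring_bond_flags <- function(mol) {
  b <- mol$bonds
  n <- nrow(mol$atoms)
  if (nrow(b) == 0L) return(logical(0))
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], k)
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], k)
  }
  vapply(seq_len(nrow(b)), function(k) {
    src <- b$i[k]; dst <- b$j[k]
    seen <- logical(n); seen[src] <- TRUE
    stack <- src
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (e in adj[[v]]) {
        if (e == k) next
        w <- if (b$i[e] == v) b$j[e] else b$i[e]
        if (w == dst) return(TRUE)
        if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
      }
    }
    FALSE
  }, logical(1))
}

# Atoms in the connected component of `start`, never crossing bond `skip`.
component_atoms <- function(bonds, n, start, skip) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    if (k == skip) next
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
  }
  seen <- logical(n); seen[start] <- TRUE
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  which(seen)
}
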