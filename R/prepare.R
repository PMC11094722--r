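obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    abort("obabel not found on PATH; Open Babel is required for ligand preparation")
  }
  p
}

run_obabel <- function(args) {
  out <- suppressWarnings(system2(obabel_path(), args,
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  list(output = out, status = status)
}

prep_elements <- c("H", "C", "N", "O", "S", "F", "Cl", "Br", "I", "P")

#' Prepare a ligand for screening
#'
#' Assigns Gasteiger partial charges and AutoDock atom types, merges
#' nonpolar hydrogens into their parent heavy atoms (transferring their
#' charge, so net molecular charge is conserved), and constructs the
#' AutoDock torsion tree. The chemistry is delegated to Open Babel
#' (`obabel ... -opdbqt --partialcharge gasteiger`); aromatic carbons are
#' typed `A` by Open Babel's ring-aromaticity perception. Inputs are
#' assumed already protonated: a warning is emitted if the molecule carries
#' no hydrogens at all, but no protonation is attempted.
#'
#' @param mol An unprepared `lig_molecule` with explicit hydrogens
#'   (typically from [read_sdf()]).
#' @param rigid If `TRUE`, all torsional freedom is removed (the convention
#'   for a reference ligand in its bioactive conformation).
#' @return A prepared `lig_molecule`: nonpolar hydrogens merged, `charge`
#'   and `ad_type` filled, torsion tree attached (empty when `rigid`).
#' @export
prepare_ligand <- function(mol, rigid = FALSE) {
  bad <- which(!mol$atoms$element %in% prep_elements)
  if (length(bad)) {
    abort(sprintf("unsupported element '%s' at atom %d of %s",
                  mol$atoms$element[bad[1]], bad[1], mol$name))
  }
  if (!any(mol$atoms$element == "H")) {
    warn(sprintf(
      "molecule %s has no hydrogens; it is assumed to be intentionally unprotonated",
      mol$name))
  }
  tmp_in <- tempfile(fileext = ".sdf")
  tmp_out <- tempfile(fileext = ".pdbqt")
  on.exit(unlink(c(tmp_in, tmp_out)))
  write_sdf(mol, tmp_in)
  args <- c(tmp_in, "-opdbqt", "-O", tmp_out, "--partialcharge", "gasteiger")
  if (rigid) args <- c(args, "-xr")
  res <- run_obabel(args)
  if (res$status != 0 || !file.exists(tmp_out) ||
      file.info(tmp_out)$size == 0) {
    abort(sprintf("ligand preparation failed for %s: %s", mol$name,
                  paste(res$output, collapse = " | ")))
  }
  pm <- read_pdbqt(tmp_out)

  # Map prepared atoms back to the input atoms by coordinates + element so
  # the original atom order and bond table can be kept (restricted to the
  # retained, i.e. non-merged, atoms).
  in_xyz <- coords(mol)
  pm_xyz <- coords(pm)
  mapping <- integer(nrow(pm_xyz))   # pm index -> input index
  used <- logical(nrow(in_xyz))
  for (a in seq_len(nrow(pm_xyz))) {
    d2 <- rowSums(sweep(in_xyz, 2, pm_xyz[a, ])^2)
    cand <- which(d2 < 1e-4 & mol$atoms$element == pm$atoms$element[a] & !used)
    if (!length(cand)) {
      abort(sprintf("cannot match prepared atom %d back to input for %s",
                    a, mol$name))
    }
    mapping[a] <- cand[which.min(d2[cand])]
    used[mapping[a]] <- TRUE
  }
  keep <- sort(mapping)                 # retained input atoms, original order
  new_idx <- integer(nrow(in_xyz)); new_idx[keep] <- seq_along(keep)
  atoms <- mol$atoms[keep, ]
  ord <- match(keep, mapping)           # pm row for each retained atom
  atoms$charge <- pm$atoms$charge[ord]
  atoms$ad_type <- pm$atoms$ad_type[ord]
  atoms$is_polar_h <- pm$atoms$is_polar_h[ord]
  bonds <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, ]
  bonds$i <- new_idx[bonds$i]; bonds$j <- new_idx[bonds$j]

  torsions <- NULL
  if (!rigid && nrow(pm$torsions) > 0) {
    ti <- new_idx[mapping[pm$torsions$i]]
    tj <- new_idx[mapping[pm$torsions$j]]
    moving <- vector("list", length(ti))
    for (t in seq_along(ti)) {
      bidx <- which((bonds$i == ti[t] & bonds$j == tj[t]) |
                    (bonds$i == tj[t] & bonds$j == ti[t]))
      if (!length(bidx)) {
        # torsion bond absent from the input bond table: fall back to the
        # membership Open Babel wrote in the BRANCH block
        moving[[t]] <- sort(new_idx[mapping[pm$torsions$moving[[t]]]])
      } else {
        moving[[t]] <- setdiff(
          component_atoms(bonds, nrow(atoms), tj[t], bidx[1]), ti[t])
      }
    }
    torsions <- tibble(i = ti, j = tj, moving = moving)
  }
  new_molecule(mol$name, atoms, bonds, torsions,
               prepared = TRUE, rigid = rigid)
}

#' Prepare every molecule in a library
#'
#' Applies [prepare_ligand()] to each molecule; preparation failures are
#' logged and the molecule dropped rather than aborting the screen.
#'
#' @param mols List of `lig_molecule` objects.
#' @param rigid Passed to [prepare_ligand()].
#' @return List of prepared molecules (possibly shorter than the input).
#' @export
prepare_library <- function(mols, rigid = FALSE) {
  out <- list()
  for (m in mols) {
    p <- tryCatch(suppressWarnings(prepare_ligand(m, rigid = rigid)),
                  error = function(e) {
                    inform(sprintf("prepare_library: dropped %s (%s)",
                                   m$name, conditionMessage(e)))
                    NULL
                  })
    if (!is.null(p)) out[[length(out) + 1L]] <- p
  }
  out
}
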