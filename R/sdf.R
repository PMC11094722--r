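#' Read molecules from an SDF file
#'
#' Parses a (multi-record) MDL SDF file with ChemmineR and converts each
#' valid record into a [new_molecule()] object, in file order. Records that
#' fail sanitization are skipped with a message naming their index, so one
#' bad library record cannot abort a screen.
#'
#' @param path Path to an SDF file (V2000/V3000) with 3D coordinates.
#' @return List of `lig_molecule` objects.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) abort(sprintf("SDF file not found: %s", path))
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) {
    abort(sprintf("unreadable SDF file %s: %s", path, conditionMessage(e)))
  })
  # split into records so one malformed record cannot kill the parse
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1) + 1L)
  records <- Map(function(s, e) lines[s:e], starts, ends)
  parsed <- lapply(records, function(rec) {
    tryCatch({
      sdfset <- suppressWarnings(methods::as(
        ChemmineR::read.SDFstr(rec), "SDFset"))
      if (!length(sdfset) || !ChemmineR::validSDF(sdfset)[1]) NULL
      else sdfset[[1]]
    }, error = function(e) NULL)
  })
  ok <- !vapply(parsed, is.null, logical(1))
  if (length(which(!ok))) {
    inform(sprintf("read_sdf: skipped %d invalid record(s) at index: %s",
                   sum(!ok), paste(which(!ok), collapse = ", ")))
  }
  if (!any(ok)) abort(sprintf("no valid SDF records in %s", path))
  out <- vector("list", sum(ok))
  pos <- 0L
  for (idx in which(ok)) {
    sdf <- parsed[[idx]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_[0-9]+$", "", rownames(ab))
    atoms <- tibble(
      element = elements,
      x = unname(ab[, 1]), y = unname(ab[, 2]), z = unname(ab[, 3])
    )
    bonds <- if (is.matrix(bb) && nrow(bb) > 0) {
      tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
             order = as.integer(bb[, 3]))
    } else NULL
    nm <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if (is.null(nm) || is.na(nm) || !nzchar(nm)) nm <- sprintf("mol_%d", idx)
    pos <- pos + 1L
    out[[pos]] <- new_molecule(nm, atoms, bonds)
  }
  out
}

#' Write molecules to an SDF file
#'
#' Emits fixed-width V2000 records (coordinates to four decimals). Used by
#' the fixture generator and CLI; round-trips through [read_sdf()].
#'
#' @param mols A `lig_molecule` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "lig_molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    na <- nrow(mol$atoms); nb <- nrow(mol$bonds)
    lines <- c(
      mol$name, "  ligmaps", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              mol$atoms$x, mol$atoms$y, mol$atoms$z, mol$atoms$element)
    )
    if (nb > 0) {
      lines <- c(lines, sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j,
                                mol$bonds$order))
    }
    lines <- c(lines, "M  END", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}
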