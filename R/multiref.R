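# Multi-reference mode: several mutually pre-aligned reference ligands are
# concatenated into one multi-feature composite. Where references place
# atoms of one type near the same position, the pseudopotential
# accumulates, so recurring features (a pharmacophore) get amplified,
# more-negative map values.

#' Compose pre-aligned references into a composite
#'
#' Atoms are concatenated without any re-alignment — alignment is an input
#' requirement, not a feature. The composite's centroid (mean over all
#' constituent atoms) defines the grid-box center. Near-coincident
#' duplicate atoms are deliberately kept: by the count monotonicity of the
#' pseudopotential they deepen the map exactly where references agree.
#'
#' @param refs List of at least two prepared, mutually aligned
#'   `lig_molecule` objects.
#' @return A `composite_reference`: molecule-like (atom table is the
#'   concatenation; rigid) with the constituent list in `$references`.
#' @export
compose_references <- function(refs) {
  if (length(refs) < 2) {
    abort("compose_references needs >= 2 references; use the single-reference workflow otherwise")
  }
  for (r in refs) {
    if (!inherits(r, "lig_molecule") || !isTRUE(r$prepared)) {
      abort("all references must be prepared lig_molecule objects")
    }
  }
  cents <- do.call(rbind, lapply(refs, centroid))
  span <- max(dist(cents))
  ext <- apply(do.call(rbind, lapply(refs, extent)), 2, max)
  if (span > max(ext) / 2) {
    warn(sprintf(
      "reference centroids are up to %.1f A apart; inputs may not be mutually aligned",
      span))
  }
  atoms <- dplyr::bind_rows(lapply(refs, function(r) r$atoms))
  out <- new_molecule(
    paste(vapply(refs, function(r) r$name, character(1)), collapse = "+"),
    atoms, bonds = NULL, torsions = NULL, prepared = TRUE, rigid = TRUE)
  out$references <- refs
  class(out) <- c("composite_reference", class(out))
  out
}

#' Per-reference self-scores against composite maps
#'
#' Each constituent of a composite is scored in its own coordinates against
#' the composite's maps; the similarity denominator in multi-reference mode
#' is the sum of these values.
#'
#' @param composite A [compose_references()] result.
#' @param ms The `map_set` built from the composite.
#' @return Numeric vector of per-reference `s_ref` values (all negative).
#' @export
composite_reference_scores <- function(composite, ms) {
  if (!inherits(composite, "composite_reference")) {
    abort("composite must be a composite_reference")
  }
  vapply(composite$references, reference_score, numeric(1), ms = ms)
}
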