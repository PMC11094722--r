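# Pose scoring against a map set: each atom contributes the trilinearly
# interpolated value of its atom type's affinity map plus its partial
# charge times the interpolated electrostatic map. Atoms outside the grid
# box add a fixed positive penalty instead (no extrapolation), so a search
# can recover from boundary violations.

#' Trilinear interpolation on a grid map
#'
#' Interpolates the map over the eight grid nodes enclosing each query
#' point. Points outside the grid box yield `NA` (the caller decides how to
#' penalize; [score_pose()] adds a fixed out-of-box penalty).
#'
#' @param map A `grid_map`.
#' @param points Numeric n x 3 matrix (or length-3 vector) of coordinates,
#'   Angstrom.
#' @return Numeric vector of interpolated values (`NA` where out of box).
#' @export
interpolate_map <- function(map, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  spec <- map$spec
  org <- grid_origin(spec)
  h <- spec$spacing
  fx <- (points[, 1] - org[1]) / h
  fy <- (points[, 2] - org[2]) / h
  fz <- (points[, 3] - org[3]) / h
  ok <- fx >= 0 & fy >= 0 & fz >= 0 &
    fx <= spec$npts[1] & fy <= spec$npts[2] & fz <= spec$npts[3]
  out <- rep(NA_real_, nrow(points))
  if (!any(ok)) return(out)
  if (is_zero_map(map)) { out[ok] <- 0; return(out) }
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  i0 <- pmin(floor(fx), spec$npts[1] - 1L); tx <- fx - i0
  j0 <- pmin(floor(fy), spec$npts[2] - 1L); ty <- fy - j0
  k0 <- pmin(floor(fz), spec$npts[3] - 1L); tz <- fz - k0
  v <- map$values
  idx <- function(di, dj, dk) v[cbind(i0 + di + 1L, j0 + dj + 1L, k0 + dk + 1L)]
  out[ok] <-
    idx(0L, 0L, 0L) * (1 - tx) * (1 - ty) * (1 - tz) +
    idx(1L, 0L, 0L) * tx       * (1 - ty) * (1 - tz) +
    idx(0L, 1L, 0L) * (1 - tx) * ty       * (1 - tz) +
    idx(1L, 1L, 0L) * tx       * ty       * (1 - tz) +
    idx(0L, 0L, 1L) * (1 - tx) * (1 - ty) * tz +
    idx(1L, 0L, 1L) * tx       * (1 - ty) * tz +
    idx(0L, 1L, 1L) * (1 - tx) * ty       * tz +
    idx(1L, 1L, 1L) * tx       * ty       * tz
  out
}

#' Score a pose against a map set
#'
#' `total = sum_i [ affinity_map(type_i)(r_i) + q_i * e_map(r_i) ]`, with
#' every atom falling outside the grid box contributing
#' `out_of_box_penalty` instead of its map terms. The score carries only
#' these intermolecular grid terms; no intramolecular energy, torsional
#' entropy or desolvation enters (normalization by the reference
#' self-score cancels constant offsets anyway).
#'
#' @param ms A `map_set`.
#' @param mol A prepared `lig_molecule` supplying atom types and charges.
#' @param pose_coords Optional n x 3 matrix of pose coordinates; default
#'   the molecule's own coordinates.
#' @param out_of_box_penalty Positive additive penalty per out-of-box atom
#'   (default 1000, dominating any attainable map gain at desk scale).
#' @return A `pose_score`: list with `total`, `per_atom` (tibble with
#'   affinity, electrostatic and penalty columns) and `out_of_box` flag.
#' @export
score_pose <- function(ms, mol, pose_coords = NULL,
                       out_of_box_penalty = 1000) {
  if (any(is.na(mol$atoms$ad_type))) {
    abort("molecule atoms lack AutoDock types; run prepare_ligand() first")
  }
  xyz <- pose_coords %||% coords(mol)
  if (nrow(xyz) != nrow(mol$atoms)) {
    abort("pose coordinate count does not match atom count")
  }
  types <- mol$atoms$ad_type
  aff <- numeric(nrow(xyz))
  for (ty in unique(types)) {
    m <- ms$affinity[[ty]]
    if (is.null(m)) abort(sprintf("no map for atom type %s in map set", ty))
    sel <- types == ty
    aff[sel] <- interpolate_map(m, xyz[sel, , drop = FALSE])
  }
  ele <- mol$atoms$charge * interpolate_map(ms$electrostatic, xyz)
  outside <- is.na(aff) | is.na(ele)
  per_atom <- tibble(
    affinity = ifelse(outside, 0, aff),
    electrostatic = ifelse(outside, 0, ele),
    penalty = ifelse(outside, out_of_box_penalty, 0)
  )
  structure(
    list(total = sum(per_atom$affinity + per_atom$electrostatic +
                       per_atom$penalty),
         per_atom = per_atom, out_of_box = any(outside)),
    class = "pose_score"
  )
}
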