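# Ligand-derived grid maps: per-atom-type pseudopotential ("affinity") maps
# and a distance-dependent electrostatic map, on a regular grid whose box is
# sized to cover the reference and every library compound.

#' Round box dimensions up to even integers
#'
#' Each axis dimension is rounded up to the nearest even integer (an even
#' box is required by the downstream grid machinery, and rounding up keeps
#' the whole library inside the sampling space); e.g. extents
#' `(60.5, 49.5, 60.0)` become `(62, 50, 60)`.
#'
#' @param extents Numeric vector of per-axis extents in Angstrom.
#' @return Integer vector of even dimensions, each at least 2.
#' @export
even_dimensions <- function(extents) {
  if (any(!is.finite(extents)) || any(extents < 0)) {
    abort("extents must be finite and non-negative")
  }
  pmax(2L, as.integer(2 * ceiling(extents / 2)))
}

#' Construct a grid specification
#'
#' @param center Grid box center, length-3, Angstrom.
#' @param dims_angstrom Box dimensions, three even integers, Angstrom.
#' @param spacing Grid spacing in Angstrom (default 0.375).
#' @return A `grid_spec`: grid point `(i, j, k)` (0-based, `i` in
#'   `[0, npts]`) sits at `center + spacing * ((i, j, k) - npts/2)`, where
#'   `npts` (intervals per axis, even) is the smallest even integer with
#'   `npts * spacing >= dims_angstrom`.
#' @export
grid_spec <- function(center, dims_angstrom, spacing = 0.375) {
  stopifnot(length(center) == 3, length(dims_angstrom) == 3)
  if (spacing <= 0) abort("spacing must be positive")
  if (any(dims_angstrom %% 2 != 0) || any(dims_angstrom < 2)) {
    abort("dims_angstrom must be even integers >= 2")
  }
  npts <- as.integer(2 * ceiling(dims_angstrom / spacing / 2))
  structure(
    list(center = as.numeric(center),
         dims_angstrom = as.numeric(dims_angstrom),
         spacing = spacing, npts = npts),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> center (%.2f, %.2f, %.2f) A, box (%g, %g, %g) A, spacing %g A, npts (%d, %d, %d)\n",
    x$center[1], x$center[2], x$center[3],
    x$dims_angstrom[1], x$dims_angstrom[2], x$dims_angstrom[3],
    x$spacing, x$npts[1], x$npts[2], x$npts[3]))
  invisible(x)
}

# lower corner (coordinate of grid point (0,0,0))
grid_origin <- function(spec) {
  spec$center - spec$spacing * spec$npts / 2
}

# coordinates of the grid points along one axis
grid_axis <- function(spec, axis) {
  grid_origin(spec)[axis] + spec$spacing * (0:spec$npts[axis])
}

#' Determine the grid box from a reference and screening library
#'
#' The box center is the reference centroid. Each axis dimension is the
#' maximum extent of any molecule considered (reference and all library
#' compounds), rounded up to the nearest even integer so the largest
#' library compound fits the sampling space in any orientation offset.
#'
#' @param reference A prepared `lig_molecule` or `composite_reference`.
#' @param library Optional list of `lig_molecule`; when empty the reference
#'   alone sets the box.
#' @param spacing Grid spacing in Angstrom.
#' @return A [grid_spec()].
#' @export
determine_grid_box <- function(reference, library = list(), spacing = 0.375) {
  if (is.null(reference)) abort("a reference molecule is required")
  exts <- rbind(extent(reference),
                do.call(rbind, c(lapply(library, extent), list(NULL))))
  dims <- even_dimensions(apply(exts, 2, max))
  grid_spec(centroid(reference), dims, spacing)
}

#' Collect the pseudosphere neighborhood of a point
#'
#' All atoms whose Euclidean distance from `point` is at most `radius`
#' (closed ball), sorted ascending by distance with ties broken by atom
#' index.
#'
#' @param point Length-3 coordinate, Angstrom.
#' @param atoms Atom table (data frame with `x`, `y`, `z`) or a matrix of
#'   coordinates.
#' @param radius Pseudosphere radius in Angstrom (default 1.54, a carbon
#'   covalent diameter).
#' @return Tibble with columns `atom` (index into `atoms`) and `d`
#'   (distance, Angstrom), sorted ascending by `d`.
#' @export
collect_pseudosphere <- function(point, atoms, radius = 1.54) {
  if (radius <= 0) abort("radius must be positive")
  xyz <- if (is.matrix(atoms)) atoms else as.matrix(atoms[, c("x", "y", "z")])
  d <- sqrt((xyz[, 1] - point[1])^2 + (xyz[, 2] - point[2])^2 +
              (xyz[, 3] - point[3])^2)
  inside <- which(d <= radius)
  ord <- inside[order(d[inside], inside)]
  tibble(atom = ord, d = d[ord])
}

#' Pseudopotential of a neighborhood
#'
#' The affinity-map value at a grid point, computed from the distance-sorted
#' atoms of a single type inside its pseudosphere: starting from
#' `E_0 = 0`, each member updates `E_n = E_{n-1} - 1/d_n`, and the final
#' `E` is returned. An empty neighborhood gives exactly 0; otherwise the
#' value is strictly negative, and it grows more negative as atoms get
#' closer or more numerous. Distances below `d_min` are clamped to `d_min`
#' so a grid point coinciding with an atom cannot blow up.
#'
#' @param d Distances of the (single-type) member atoms, Angstrom, sorted
#'   ascending (a [collect_pseudosphere()] `d` column).
#' @param d_min Clamp distance in Angstrom (default 0.01).
#' @return Scalar pseudopotential (dimensionless, `<= 0`).
#' @export
affinity_value <- function(d, d_min = 0.01) {
  if (length(d) == 0L) return(0)
  e <- 0
  for (dn in pmax(d, d_min)) e <- e - 1 / dn
  e
}

#' Electrostatic potential of a neighborhood
#'
#' When any atom lies inside the pseudosphere of a grid point, the
#' electrostatic value is `sum_n Q_n / (eps * d_n)` over the member atoms,
#' with `Q_n` the partial charge, `d_n` the clamped distance and `eps` the
#' distance-independent dielectric factor (default -0.1465). With the
#' negative default, positive neighborhoods give negative map values
#' (regions preferring positive charge score favorably for positively
#' charged atoms through the `q * value` pose term).
#'
#' @param d Distances of member atoms (any type), Angstrom.
#' @param q Partial charges of the same atoms, elementary charge units.
#' @param dielectric Dielectric factor (nonzero; default -0.1465).
#' @param d_min Clamp distance in Angstrom.
#' @return Scalar potential; 0 for an empty neighborhood.
#' @export
electrostatic_value <- function(d, q, dielectric = -0.1465, d_min = 0.01) {
  if (dielectric == 0) abort("dielectric must be nonzero")
  if (length(d) == 0L) return(0)
  sum(q / (dielectric * pmax(d, d_min)))
}

new_grid_map <- function(ad_type, spec, values) {
  structure(list(ad_type = ad_type, spec = spec, values = values),
            class = "grid_map")
}

# all-zero general map, stored without materializing its array
new_zero_map <- function(ad_type, spec) {
  structure(list(ad_type = ad_type, spec = spec, values = NULL),
            class = c("zero_map", "grid_map"))
}

is_zero_map <- function(map) inherits(map, "zero_map")

map_values <- function(map) {
  if (is_zero_map(map)) array(0, dim = map$spec$npts + 1L) else map$values
}

#' @export
print.grid_map <- function(x, ...) {
  v <- if (is_zero_map(x)) "all-zero general map"
  else sprintf("range [%.3f, %.3f]", min(x$values), max(x$values))
  cat(sprintf("<grid_map> type %s, %s points, %s\n", x$ad_type,
              paste(x$spec$npts + 1L, collapse = "x"), v))
  invisible(x)
}

# Accumulate -1/d (affinity) or q/(eps d) (electrostatic) contributions of
# one atom into every grid node within `radius`, vectorized over the local
# index window around the atom.
accumulate_atom <- function(values, spec, at_xyz, radius, d_min, weight) {
  org <- grid_origin(spec)
  h <- spec$spacing
  lo <- pmax(0L, as.integer(ceiling((at_xyz - radius - org) / h)))
  hi <- pmin(spec$npts, as.integer(floor((at_xyz + radius - org) / h)))
  if (any(lo > hi)) return(values)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dx2 <- (org[1] + h * ix - at_xyz[1])^2
  dy2 <- (org[2] + h * iy - at_xyz[2])^2
  dz2 <- (org[3] + h * iz - at_xyz[3])^2
  d <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
  contrib <- weight / pmax(d, d_min)
  contrib[d > radius] <- 0
  values[ix + 1L, iy + 1L, iz + 1L] <-
    values[ix + 1L, iy + 1L, iz + 1L] + contrib
  values
}

#' Build a single-type affinity map
#'
#' Evaluates [affinity_value()] at every grid point against the reference
#' atoms of one atom type. Types absent from the reference give an all-zero
#' general map.
#'
#' @param ad_type AutoDock atom-type code.
#' @param reference A prepared `lig_molecule` or `composite_reference`
#'   whose atoms of `ad_type` source the map.
#' @param spec A [grid_spec()].
#' @param radius Pseudosphere radius, Angstrom.
#' @param d_min Distance clamp, Angstrom.
#' @return A `grid_map` with values `<= 0` everywhere.
#' @export
build_affinity_map <- function(ad_type, reference, spec,
                               radius = 1.54, d_min = 0.01) {
  sel <- which(reference$atoms$ad_type == ad_type)
  if (!length(sel)) return(new_zero_map(ad_type, spec))
  values <- array(0, dim = spec$npts + 1L)
  xyz <- coords(reference)
  for (a in sel) {
    values <- accumulate_atom(values, spec, xyz[a, ], radius, d_min, -1)
  }
  new_grid_map(ad_type, spec, values)
}

#' Build the electrostatic map
#'
#' Evaluates [electrostatic_value()] at every grid point against all
#' reference atoms within the pseudosphere radius.
#'
#' @inheritParams build_affinity_map
#' @param dielectric Dielectric factor (default -0.1465).
#' @return A `grid_map` with `ad_type = "e"`.
#' @export
build_electrostatic_map <- function(reference, spec, dielectric = -0.1465,
                                    radius = 1.54, d_min = 0.01) {
  if (dielectric == 0) abort("dielectric must be nonzero")
  values <- array(0, dim = spec$npts + 1L)
  xyz <- coords(reference)
  q <- reference$atoms$charge
  for (a in seq_len(nrow(xyz))) {
    values <- accumulate_atom(values, spec, xyz[a, ], radius, d_min,
                              q[a] / dielectric)
  }
  new_grid_map("e", spec, values)
}

#' Build the full map set for a reference
#'
#' Informative affinity maps for every atom type present in the reference,
#' all-zero general maps for the remaining supported types (so any library
#' compound can be scored), and the electrostatic map, all sharing one grid.
#'
#' @param reference A prepared `lig_molecule` or `composite_reference`.
#' @param library Optional list of library molecules taken into account
#'   when sizing the grid box.
#' @param spacing Grid spacing, Angstrom.
#' @param radius Pseudosphere radius, Angstrom.
#' @param dielectric Dielectric factor for the electrostatic map.
#' @param d_min Distance clamp, Angstrom.
#' @param types Atom-type universe (default [ad_atom_types()]).
#' @param spec Optionally a pre-determined [grid_spec()]; when `NULL` the
#'   box is determined from `reference` and `library`.
#' @return A `map_set`: list with `spec`, `affinity` (named list of
#'   `grid_map`), `electrostatic`, `dielectric`, `radius`, `d_min`,
#'   `reference_name`.
#' @export
build_mapset <- function(reference, library = list(), spacing = 0.375,
                         radius = 1.54, dielectric = -0.1465, d_min = 0.01,
                         types = ad_atom_types(), spec = NULL) {
  if (!isTRUE(reference$prepared)) {
    abort("reference must be prepared (prepare_ligand) before building maps")
  }
  if (is.null(spec)) {
    spec <- determine_grid_box(reference, library, spacing)
  }
  present <- unique(reference$atoms$ad_type)
  types <- union(types, present)
  affinity <- lapply(setNames(types, types), function(ty) {
    build_affinity_map(ty, reference, spec, radius, d_min)
  })
  electrostatic <- build_electrostatic_map(reference, spec, dielectric,
                                           radius, d_min)
  structure(
    list(spec = spec, affinity = affinity, electrostatic = electrostatic,
         dielectric = dielectric, radius = radius, d_min = d_min,
         reference_name = reference$name),
    class = "map_set"
  )
}

#' @export
print.map_set <- function(x, ...) {
  inf <- names(x$affinity)[!vapply(x$affinity, is_zero_map, logical(1))]
  cat(sprintf(
    "<map_set> reference %s; informative maps: %s; %d general zero maps; electrostatic map\n",
    x$reference_name, paste(inf, collapse = ", "),
    sum(vapply(x$affinity, is_zero_map, logical(1)))))
  print(x$spec)
  invisible(x)
}
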