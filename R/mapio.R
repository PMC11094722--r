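# AutoDock grid-map dialect: one `.map` file per atom type plus the
# electrostatic `e` map, indexed by a `.maps.fld` file. Map files carry a
# six-line header (GRID_PARAMETER_FILE, GRID_DATA_FILE, MACROMOLECULE,
# SPACING, NELEMENTS, CENTER) followed by one value per line, x-fastest.
# With no receptor in this workflow, MACROMOLECULE records the reference
# ligand's name.

map_file <- function(prefix, ad_type) sprintf("%s.%s.map", prefix, ad_type)

write_one_map <- function(map, prefix) {
  spec <- map$spec
  path <- map_file(prefix, map$ad_type)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("GRID_PARAMETER_FILE %s.gpf", basename(prefix)),
    sprintf("GRID_DATA_FILE %s.maps.fld", basename(prefix)),
    sprintf("MACROMOLECULE %s", attr(map, "macromolecule") %||% "reference"),
    sprintf("SPACING %.3f", spec$spacing),
    sprintf("NELEMENTS %d %d %d", spec$npts[1], spec$npts[2], spec$npts[3]),
    sprintf("CENTER %.3f %.3f %.3f",
            spec$center[1], spec$center[2], spec$center[3])
  ), con)
  # x-fastest, then y, then z: R arrays are column-major so this is the
  # natural unravel order
  writeLines(sprintf("%.3f", as.vector(map_values(map))), con)
  path
}

#' Write a map set to AutoDock-dialect files
#'
#' One `.map` file per supported atom type (zero general maps are
#' materialized as zero values) plus `<prefix>.e.map`, and a
#' `<prefix>.maps.fld` index.
#'
#' @param ms A `map_set` from [build_mapset()].
#' @param prefix Output path prefix (files `<prefix>.<type>.map` etc.).
#' @return Character vector of written file paths, invisibly.
#' @export
write_maps <- function(ms, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  types <- names(ms$affinity)
  paths <- character()
  for (ty in types) {
    m <- ms$affinity[[ty]]
    attr(m, "macromolecule") <- ms$reference_name
    paths <- c(paths, write_one_map(m, prefix))
  }
  e <- ms$electrostatic
  attr(e, "macromolecule") <- ms$reference_name
  paths <- c(paths, write_one_map(e, prefix))
  fld <- sprintf("%s.maps.fld", prefix)
  spec <- ms$spec
  writeLines(c(
    "# AVS field file",
    "# Ligand-derived atomic affinity and electrostatic grid maps",
    sprintf("# SPACING %.3f", spec$spacing),
    sprintf("# NELEMENTS %d %d %d", spec$npts[1], spec$npts[2], spec$npts[3]),
    sprintf("# CENTER %.3f %.3f %.3f",
            spec$center[1], spec$center[2], spec$center[3]),
    sprintf("# MACROMOLECULE %s", ms$reference_name),
    sprintf("# DIELECTRIC %.4f", ms$dielectric),
    "ndim=3",
    sprintf("dim1=%d", spec$npts[1] + 1L),
    sprintf("dim2=%d", spec$npts[2] + 1L),
    sprintf("dim3=%d", spec$npts[3] + 1L),
    sprintf("nspace=3"),
    sprintf("veclen=%d", length(types) + 1L),
    "data=double",
    "field=uniform",
    c(sprintf("variable %d file=%s filetype=ascii skip=6",
              seq_along(types), basename(map_file(prefix, types))),
      sprintf("variable %d file=%s filetype=ascii skip=6",
              length(types) + 1L, basename(map_file(prefix, "e"))))
  ), fld)
  invisible(c(paths, fld))
}

read_one_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1:6]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, key)]
    if (!length(ln)) abort(sprintf("missing %s header in %s", key, path))
    trimws(sub(key, "", ln[1]))
  }
  spacing <- as.numeric(get("SPACING"))
  npts <- as.integer(strsplit(get("NELEMENTS"), "\\s+")[[1]])
  center <- as.numeric(strsplit(get("CENTER"), "\\s+")[[1]])
  vals <- as.numeric(lines[-(1:6)])
  if (length(vals) != prod(npts + 1L) || anyNA(vals)) {
    abort(sprintf("map %s: expected %d values, found %d valid",
                  path, prod(npts + 1L), sum(!is.na(vals))))
  }
  # dims are informative; npts is authoritative for the array shape
  spec <- grid_spec(center, pmax(2, 2 * floor(npts * spacing / 2)), spacing)
  spec$npts <- npts
  list(spec = spec, values = array(vals, dim = npts + 1L),
       macromolecule = get("MACROMOLECULE"))
}

#' Read a map set from AutoDock-dialect files
#'
#' Reads every `<prefix>.<type>.map` found for the supported atom types
#' plus the electrostatic map, and reassembles a `map_set`. Maps that are
#' zero everywhere are stored as general zero maps.
#'
#' @param prefix Path prefix used in [write_maps()].
#' @param dielectric Dielectric factor to record (default read from the
#'   `.maps.fld` header when present, else -0.1465).
#' @return A `map_set`.
#' @export
read_maps <- function(prefix, dielectric = NULL) {
  epath <- map_file(prefix, "e")
  if (!file.exists(epath)) abort(sprintf("no electrostatic map at %s", epath))
  fld <- sprintf("%s.maps.fld", prefix)
  if (is.null(dielectric)) {
    dielectric <- -0.1465
    if (file.exists(fld)) {
      ln <- grep("^# DIELECTRIC", readLines(fld, warn = FALSE), value = TRUE)
      if (length(ln)) dielectric <- as.numeric(sub("# DIELECTRIC", "", ln[1]))
    }
  }
  e <- read_one_map(epath)
  spec <- e$spec
  affinity <- list()
  for (ty in ad_atom_types()) {
    p <- map_file(prefix, ty)
    if (!file.exists(p)) next
    m <- read_one_map(p)
    if (!identical(m$spec$npts, spec$npts)) {
      abort(sprintf("map %s grid differs from electrostatic grid", p))
    }
    affinity[[ty]] <- if (all(m$values == 0)) new_zero_map(ty, spec)
    else new_grid_map(ty, spec, m$values)
  }
  if (!length(affinity)) abort(sprintf("no affinity maps found for %s", prefix))
  structure(
    list(spec = spec, affinity = affinity,
         electrostatic = new_grid_map("e", spec, e$values),
         dielectric = dielectric, radius = 1.54, d_min = 0.01,
         reference_name = e$macromolecule),
    class = "map_set"
  )
}
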