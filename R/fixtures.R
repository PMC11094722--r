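# Synthetic, download-free inputs: exact hand-specified probe molecules
# for analytic map tests, a small drug-like example ligand, and a
# benchmark generator (actives = torsion-jittered copies of a reference;
# decoys = random branched molecules) with known expected ordering.

#' Build an exact probe molecule
#'
#' A molecule with hand-specified atoms, types and charges; no perception
#' or preparation is applied. Used for analytic map and scoring tests.
#'
#' @param atoms Data frame with columns `ad_type`, `x`, `y`, `z` and
#'   optionally `charge`.
#' @param name Identifier.
#' @return A prepared, rigid `lig_molecule`.
#' @export
make_probe <- function(atoms, name = "probe") {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("ad_type", "x", "y", "z") %in% names(atoms)))
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  bad <- setdiff(unique(atoms$ad_type), ad_atom_types())
  if (length(bad)) {
    abort(sprintf("unknown atom type(s): %s", paste(bad, collapse = ", ")))
  }
  atoms$element <- ad_type_element(atoms$ad_type)
  atoms$is_polar_h <- atoms$ad_type %in% c("HD", "HS")
  new_molecule(name, atoms, prepared = TRUE, rigid = TRUE)
}

#' Example reference ligand (synthetic)
#'
#' A synthetic 4-hydroxybenzamide built with idealized geometry (planar
#' aromatic ring, standard bond lengths): an aromatic ring, an amide and a
#' hydroxyl give a mix of atom types (A, C, OA, N/NA, HD) plus polar
#' hydrogens, in a compact ~10-heavy-atom frame. Returned unprepared (with
#' explicit hydrogens) so the standard preparation path applies.
#'
#' @return An unprepared `lig_molecule`.
#' @export
make_example_ligand <- function() {
  ang <- (0:5) * pi / 3
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  ringH <- cbind(2.47 * cos(ang), 2.47 * sin(ang), 0)
  atoms <- tibble(
    element = c(rep("C", 6),              # 1-6 ring
                "C", "O", "N",            # 7 amide C, 8 carbonyl O, 9 amide N
                "O",                      # 10 hydroxyl O
                "H", "H", "H", "H",       # 11-14 ring H (C2, C3, C5, C6)
                "H", "H",                 # 15-16 amide H
                "H"),                     # 17 hydroxyl H
    x = c(ring[, 1], 2.87, 3.485, 3.540, -2.750,
          ringH[c(2, 3, 5, 6), 1], 3.035, 4.545, -3.069),
    y = c(ring[, 2], 0.000, 1.065, -1.161, 0.000,
          ringH[c(2, 3, 5, 6), 2], -2.027, -1.159, 0.903),
    z = rep(0, 17)
  )
  bonds <- tibble(
    i = c(1, 2, 3, 4, 5, 6, 1, 7, 7, 4, 2, 3, 5, 6, 9, 9, 10),
    j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17),
    order = c(2L, 1L, 2L, 1L, 2L, 1L, 1L, 2L, 1L, 1L,
              1L, 1L, 1L, 1L, 1L, 1L, 1L)
  )
  new_molecule("example_ligand", atoms, bonds)
}

atom_valence <- c(C = 4L, N = 3L, O = 2L)

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Random branched heavy-atom tree with a plausible 3D embedding and
# explicit hydrogens filling the valences. Geometry is rough (random
# directions with clash rejection), which is all a decoy needs.
random_decoy <- function(n_heavy, name) {
  elements <- sample(c("C", "N", "O"), n_heavy, replace = TRUE,
                     prob = c(0.7, 0.15, 0.15))
  xyz <- matrix(0, n_heavy, 3)
  parent <- integer(n_heavy)
  degree <- integer(n_heavy)
  for (a in seq_len(n_heavy)[-1]) {
    open <- which(degree[seq_len(a - 1L)] <
                    atom_valence[elements[seq_len(a - 1L)]])
    if (!length(open)) open <- seq_len(a - 1L)
    p <- if (length(open) == 1L) open else sample(open, 1L)
    for (try in 1:60) {
      pos <- xyz[p, ] + 1.5 * random_unit_vector()
      d <- sqrt(rowSums(sweep(xyz[seq_len(a - 1L), , drop = FALSE], 2, pos)^2))
      d[p] <- Inf
      if (all(d > 1.8) || try == 60) break
    }
    xyz[a, ] <- pos
    parent[a] <- p
    degree[a] <- degree[a] + 1L; degree[p] <- degree[p] + 1L
  }
  # explicit hydrogens to fill valences
  hx <- list(); hparent <- integer()
  for (a in seq_len(n_heavy)) {
    nh <- atom_valence[elements[a]] - degree[a]
    if (nh <= 0) next
    for (h in seq_len(nh)) {
      for (try in 1:40) {
        pos <- xyz[a, ] + 1.05 * random_unit_vector()
        d <- sqrt(rowSums(sweep(xyz, 2, pos)^2))
        d[a] <- Inf
        if (all(d > 1.4) || try == 40) break
      }
      hx[[length(hx) + 1L]] <- pos
      hparent <- c(hparent, a)
    }
  }
  hxyz <- do.call(rbind, c(hx, list(NULL)))
  all_xyz <- rbind(xyz, hxyz)
  all_xyz <- sweep(all_xyz, 2, colMeans(all_xyz))
  atoms <- tibble(
    element = c(elements, rep("H", length(hparent))),
    x = all_xyz[, 1], y = all_xyz[, 2], z = all_xyz[, 3]
  )
  bonds <- tibble(
    i = c(parent[-1], hparent),
    j = c(seq_len(n_heavy)[-1], n_heavy + seq_along(hparent)),
    order = 1L
  )
  new_molecule(name, atoms, bonds)
}

#' Generate a synthetic screening benchmark
#'
#' Actives are conformers of the reference: its torsion tree is jittered
#' and mild coordinate noise added, so topology, types and charges are
#' identical to the reference but the conformation differs. Decoys are
#' random branched C/N/O molecules (explicit hydrogens, random 3D
#' embedding) in a heavy-atom size range matched loosely to the reference,
#' prepared through the standard path. Deterministic for a given `seed`.
#'
#' @param ref A prepared, flexible `lig_molecule` (see
#'   [make_example_ligand()] + [prepare_ligand()]).
#' @param n_actives,n_decoys Counts.
#' @param torsion_jitter SD (radians) of the torsion perturbation applied
#'   to actives.
#' @param coord_noise SD (Angstrom) of per-coordinate Gaussian noise
#'   applied to actives.
#' @param decoy_size_range Heavy-atom count range for decoys.
#' @param seed RNG seed.
#' @return List with `actives`, `decoys` (lists of prepared molecules) and
#'   `labels` (tibble `compound`, `is_active`).
#' @export
make_benchmark <- function(ref, n_actives = 5, n_decoys = 50,
                           torsion_jitter = 0.3, coord_noise = 0.05,
                           decoy_size_range = c(6, 14), seed = 7L) {
  if (!isTRUE(ref$prepared)) abort("reference must be prepared")
  stopifnot(n_actives >= 0, n_decoys >= 0, torsion_jitter >= 0,
            coord_noise >= 0)
  set.seed(seed)
  k <- nrow(ref$torsions)
  actives <- lapply(seq_len(n_actives), function(i) {
    g <- pose_genome(torsions = rnorm(k, 0, torsion_jitter))
    xyz <- apply_genome(ref, g) +
      matrix(rnorm(3 * nrow(ref$atoms), 0, coord_noise), ncol = 3)
    a <- set_coords(ref, xyz)
    a$name <- sprintf("active_%02d", i)
    a
  })
  decoys <- list()
  i <- 0L
  while (length(decoys) < n_decoys && i < 10L * max(1L, n_decoys)) {
    i <- i + 1L
    n_heavy <- sample(decoy_size_range[1]:decoy_size_range[2], 1L)
    d <- random_decoy(n_heavy, sprintf("decoy_%02d", length(decoys) + 1L))
    p <- tryCatch(suppressWarnings(prepare_ligand(d)),
                  error = function(e) NULL)
    if (!is.null(p)) decoys[[length(decoys) + 1L]] <- p
  }
  labels <- tibble(
    compound = c(vapply(actives, function(m) m$name, character(1)),
                 vapply(decoys, function(m) m$name, character(1))),
    is_active = rep(c(TRUE, FALSE), c(length(actives), length(decoys)))
  )
  list(actives = actives, decoys = decoys, labels = labels)
}
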