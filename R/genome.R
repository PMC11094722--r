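# Pose genome: translation (Angstrom displacement), rigid orientation
# (unit quaternion) and one absolute torsion increment per rotatable bond.

#' Construct a pose genome
#'
#' @param translation Length-3 displacement of the molecular centroid,
#'   Angstrom.
#' @param orientation Unit quaternion `(w, x, y, z)` for the rigid rotation
#'   about the (post-torsion) centroid.
#' @param torsions Torsion increments in radians, one per rotatable bond of
#'   the target molecule, wrapped to `(-pi, pi]`.
#' @return A `pose_genome`.
#' @export
pose_genome <- function(translation = c(0, 0, 0),
                        orientation = c(1, 0, 0, 0),
                        torsions = numeric()) {
  structure(
    list(translation = as.numeric(translation),
         orientation = quat_normalize(as.numeric(orientation)),
         torsions = wrap_angle(as.numeric(torsions))),
    class = "pose_genome"
  )
}

#' Apply a genome to a molecule
#'
#' Kinematics: torsion increments are applied along the torsion tree (each
#' rotatable bond rotates its moving atom set about the current bond axis),
#' then the whole conformation is rigidly rotated about its centroid by the
#' orientation quaternion, then displaced by the translation gene. The
#' identity genome returns the input conformation unchanged.
#'
#' @param mol A prepared `lig_molecule`.
#' @param genome A [pose_genome()] whose torsion count matches the
#'   molecule's rotatable bonds.
#' @return n x 3 matrix of pose coordinates, Angstrom.
#' @export
apply_genome <- function(mol, genome) {
  k <- nrow(mol$torsions)
  if (length(genome$torsions) != k) {
    abort(sprintf("genome has %d torsions but molecule %s has %d rotatable bonds",
                  length(genome$torsions), mol$name, k))
  }
  xyz <- coords(mol)
  if (k > 0) {
    for (t in seq_len(k)) {
      ang <- genome$torsions[t]
      if (ang == 0) next
      i <- mol$torsions$i[t]; j <- mol$torsions$j[t]
      mv <- mol$torsions$moving[[t]]
      # gene = dihedral increment: a right-handed rotation of the moving
      # side about i->j changes the i-j dihedral by -ang, hence the sign
      xyz[mv, ] <- rotate_about_axis(xyz[mv, , drop = FALSE],
                                     xyz[i, ], xyz[j, ], -ang)
    }
  }
  ctr <- colMeans(xyz)
  R <- quat_to_matrix(genome$orientation)
  sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + genome$translation, `+`)
}

random_genome <- function(k, spec, mol_centroid) {
  # centroid placed uniformly inside the grid box
  target <- spec$center +
    (runif(3) - 0.5) * spec$spacing * spec$npts
  pose_genome(
    translation = target - mol_centroid,
    orientation = random_quaternion(),
    torsions = runif(k, -pi, pi)
  )
}
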