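# Shared fixtures and independent oracles. Expensive objects (prepared
# reference, map set) are built once per suite and cached.

fixture_env <- new.env(parent = emptyenv())

fx_reference <- function() {
  if (is.null(fixture_env$ref)) {
    fixture_env$ref <- prepare_ligand(make_example_ligand())
  }
  fixture_env$ref
}

fx_rigid_reference <- function() {
  ref <- fx_reference()
  ref$torsions <- ref$torsions[0, ]
  ref$rigid <- TRUE
  ref
}

fx_mapset <- function() {
  if (is.null(fixture_env$ms)) {
    fixture_env$ms <- build_mapset(fx_reference())
  }
  fixture_env$ms
}

# a random rigid probe cloud of one atom type
random_cloud <- function(n, type = "C", scale = 3, charge = 0) {
  make_probe(tibble::tibble(
    ad_type = type,
    x = stats::runif(n, -scale, scale),
    y = stats::runif(n, -scale, scale),
    z = stats::runif(n, -scale, scale),
    charge = charge
  ))
}

# independent per-point map oracle: direct neighborhood scan + recurrence
naive_affinity_at <- function(point, ref, type, radius = 1.54, d_min = 0.01) {
  xyz <- coords(ref)
  sel <- ref$atoms$ad_type == type
  d <- sqrt(colSums((t(xyz[sel, , drop = FALSE]) - point)^2))
  d <- sort(d[d <= radius])
  if (!length(d)) return(0)
  -sum(1 / pmax(d, d_min))
}

naive_electrostatic_at <- function(point, ref, dielectric = -0.1465,
                                   radius = 1.54, d_min = 0.01) {
  xyz <- coords(ref)
  d <- sqrt(colSums((t(xyz) - point)^2))
  keep <- d <= radius
  if (!any(keep)) return(0)
  sum(ref$atoms$charge[keep] / (dielectric * pmax(d[keep], d_min)))
}

# O(n^2) pairwise AUROC oracle
pairwise_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# direct trilinear formula at one point, from the 8 enclosing nodes
naive_trilinear <- function(map, p) {
  spec <- map$spec
  org <- spec$center - spec$spacing * spec$npts / 2
  f <- (p - org) / spec$spacing
  i0 <- pmin(floor(f), spec$npts - 1)
  t <- f - i0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[1] else 1 - t[1]) * (if (dy) t[2] else 1 - t[2]) *
      (if (dz) t[3] else 1 - t[3])
    v <- v + w * map$values[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  v
}

measure_dihedral <- function(xyz, a, b, c, d) {
  ligmaps:::dihedral_angle(xyz[a, ], xyz[b, ], xyz[c, ], xyz[d, ])
}

# bonded random chain (valid for SDF round trips, which need a bond block)
random_chain <- function(n, scale = 3) {
  m <- random_cloud(max(n, 2), scale = scale)
  m$bonds <- tibble::tibble(i = seq_len(nrow(m$atoms) - 1L),
                            j = seq_len(nrow(m$atoms) - 1L) + 1L,
                            order = 1L)
  m
}

# random labeled ranking (optionally with forced score ties)
rand_ranking <- function(n, n_active, tie_prob = 0) {
  s <- stats::runif(n)
  if (tie_prob > 0) s <- round(s, 1)
  screen_ranking(tibble::tibble(
    compound = sprintf("c%03d", 1:n),
    s_sim = s,
    is_active = seq_len(n) %in% sample.int(n, n_active)))
}

# heavy-atom n-butane-like chain with a real torsion tree, for kinematics
fx_butane <- function() {
  atoms <- tibble::tibble(
    element = rep("C", 4),
    x = c(0, 1.54, 2.31, 3.85),
    y = c(0, 0, 1.33, 1.33),
    z = c(0, 0, 0, 0.5),
    charge = 0, ad_type = "C"
  )
  bonds <- tibble::tibble(i = 1:3, j = 2:4, order = 1L)
  torsions <- tibble::tibble(i = 2L, j = 3L, moving = list(c(3L, 4L)))
  new_molecule("butane_heavy", atoms, bonds, torsions,
               prepared = TRUE, rigid = FALSE)
}
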