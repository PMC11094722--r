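test_that("box dimensions round up to even integers", {
  expect_equal(even_dimensions(c(60.5, 49.5, 60.0)), c(62L, 50L, 60L))
  expect_equal(even_dimensions(4.0), 4L)
  expect_equal(even_dimensions(0), 2L)
  expect_error(even_dimensions(c(-1, 2, 3)), "non-negative")
})

test_that("determine_grid_box covers reference and library with even dims", {
  withr::local_seed(13)
  ref <- fx_rigid_reference()
  for (rep in 1:20) {
    library <- lapply(1:4, function(i) random_cloud(sample(2:30, 1),
                                                    scale = runif(1, 1, 8)))
    spec <- determine_grid_box(ref, library)
    exts <- rbind(extent(ref), t(vapply(library, extent, numeric(3))))
    expect_true(all(spec$dims_angstrom %% 2 == 0))
    expect_true(all(spec$dims_angstrom >= apply(exts, 2, max)))
    expect_equal(spec$center, centroid(ref))
    # npts even and covering the box
    expect_true(all(spec$npts %% 2 == 0))
    expect_true(all(spec$npts * spec$spacing >= spec$dims_angstrom))
  }
})

test_that("pseudosphere membership is exact, sorted and closed at the boundary", {
  withr::local_seed(5)
  cloud <- random_cloud(60, scale = 4)
  xyz <- coords(cloud)
  for (rep in 1:100) {
    p <- runif(3, -4, 4)
    nb <- collect_pseudosphere(p, cloud$atoms)
    d_all <- sqrt(colSums((t(xyz) - p)^2))
    expect_setequal(nb$atom, which(d_all <= 1.54))
    expect_false(is.unsorted(nb$d))
    expect_equal(nb$d, d_all[nb$atom])
  }
  # atom at exactly the radius is included (closed ball)
  one <- make_probe(tibble::tibble(ad_type = "C", x = 1.54, y = 0, z = 0))
  expect_equal(nrow(collect_pseudosphere(c(0, 0, 0), one$atoms)), 1L)
  # distance ties broken by atom index
  twin <- make_probe(tibble::tibble(ad_type = "C", x = c(1, -1), y = 0, z = 0))
  expect_equal(collect_pseudosphere(c(0, 0, 0), twin$atoms)$atom, c(1L, 2L))
})

test_that("pseudopotential is 0 on empty and monotone in distance and count", {
  expect_identical(affinity_value(numeric(0)), 0)
  expect_lt(affinity_value(1.0), 0)
  withr::local_seed(11)
  for (rep in 1:200) {
    n <- sample(1:6, 1)
    d <- sort(runif(n, 0.05, 1.54))
    v <- affinity_value(d)
    expect_lt(v, 0)
    # moving one atom closer can only deepen the value
    d2 <- d; i <- sample(n, 1); d2[i] <- d2[i] * runif(1, 0.1, 0.99)
    expect_lte(affinity_value(sort(d2)), v)
    # adding an atom can only deepen the value
    expect_lte(affinity_value(sort(c(d, runif(1, 0.05, 1.54)))), v)
  }
  # clamp: coincident atom does not blow up
  expect_equal(affinity_value(0), -1 / 0.01)
})

test_that("affinity maps: zero for absent types, compact support, never positive", {
  ms <- fx_mapset()
  ref <- fx_reference()
  # absent type -> all-zero general map
  expect_true(all(ligmaps:::map_values(ms$affinity[["Cl"]]) == 0))
  # informative maps are <= 0 everywhere
  for (ty in c("A", "C", "OA", "N", "HD")) {
    expect_lte(max(ligmaps:::map_values(ms$affinity[[ty]])), 0)
  }
  # compact support at the pseudosphere radius, per-point naive oracle
  withr::local_seed(3)
  spec <- ms$spec
  for (ty in c("A", "OA", "HD")) {
    vals <- ms$affinity[[ty]]$values
    for (rep in 1:40) {
      idx <- sapply(spec$npts, function(np) sample(0:np, 1))
      p <- spec$center + spec$spacing * (idx - spec$npts / 2)
      expect_equal(vals[idx[1] + 1, idx[2] + 1, idx[3] + 1],
                   naive_affinity_at(p, ref, ty), tolerance = 1e-9)
    }
  }
})

test_that("single-atom map has its minimum at the nearest grid nodes", {
  probe <- make_probe(tibble::tibble(ad_type = "OA", x = 0.1, y = 0, z = 0))
  spec <- grid_spec(c(0, 0, 0), c(6, 6, 6), 0.375)
  map <- build_affinity_map("OA", probe, spec)
  vals <- map$values
  best <- arrayInd(which.min(vals), dim(vals))
  node <- spec$center + spec$spacing * (as.vector(best) - 1 - spec$npts / 2)
  expect_lt(sqrt(sum((node - c(0.1, 0, 0))^2)), spec$spacing)
  # zero beyond the radius
  far <- abs(seq(-3, 3, by = 0.375) - 0.1) > 1.54 + 0.375
  expect_true(all(vals[far, , ] %in% 0))
})

test_that("electrostatic map follows the charge/dielectric convention", {
  # single atom, Q = +0.3, d = 1.0, eps = -0.1465: value = 0.3/(-0.1465 * 1)
  expect_equal(electrostatic_value(1.0, 0.3), 0.3 / (-0.1465 * 1.0))
  expect_identical(electrostatic_value(numeric(0), numeric(0)), 0)

  # positive neighborhood -> negative potential and vice versa
  pos <- make_probe(tibble::tibble(ad_type = "N", x = 0, y = 0, z = 0,
                                   charge = 0.5))
  neg <- make_probe(tibble::tibble(ad_type = "OA", x = 0, y = 0, z = 0,
                                   charge = -0.5))
  spec <- grid_spec(c(0, 0, 0), c(4, 4, 4), 0.5)
  mp <- build_electrostatic_map(pos, spec)
  mn <- build_electrostatic_map(neg, spec)
  nz <- mp$values != 0
  expect_true(any(nz))
  expect_true(all(mp$values[nz] < 0))
  expect_true(all(mn$values[nz] > 0))

  # naive per-point oracle on the example ligand's map
  ms <- fx_mapset()
  ref <- fx_reference()
  withr::local_seed(17)
  spec <- ms$spec
  for (rep in 1:60) {
    idx <- sapply(spec$npts, function(np) sample(0:np, 1))
    p <- spec$center + spec$spacing * (idx - spec$npts / 2)
    expect_equal(ms$electrostatic$values[idx[1] + 1, idx[2] + 1, idx[3] + 1],
                 naive_electrostatic_at(p, ref), tolerance = 1e-9)
  }
})

test_that("maps are translation equivariant", {
  ref <- fx_rigid_reference()
  shift <- c(11.3, -4.7, 2.9)
  ref2 <- ligmaps:::set_coords(ref, sweep(coords(ref), 2, -shift))
  spec1 <- determine_grid_box(ref)
  spec2 <- determine_grid_box(ref2)
  m1 <- build_affinity_map("A", ref, spec1)
  m2 <- build_affinity_map("A", ref2, spec2)
  expect_equal(m1$values, m2$values, tolerance = 1e-9)
  e1 <- build_electrostatic_map(ref, spec1)
  e2 <- build_electrostatic_map(ref2, spec2)
  expect_equal(e1$values, e2$values, tolerance = 1e-9)
})

test_that("map files round-trip at format precision and parse independently", {
  ms <- fx_mapset()
  prefix <- file.path(withr::local_tempdir(), "ref")
  paths <- write_maps(ms, prefix)
  expect_true(file.exists(paste0(prefix, ".maps.fld")))

  # (n+1)^3 value lines after the 6-line header
  lines <- readLines(paste0(prefix, ".e.map"))
  expect_length(lines, 6 + prod(ms$spec$npts + 1))
  expect_match(lines[5], "^NELEMENTS \\d+ \\d+ \\d+$")

  # independent parse: plain readLines + as.numeric, no package reader
  vals <- as.numeric(lines[-(1:6)])
  expect_equal(vals, as.vector(ms$electrostatic$values), tolerance = 5e-4)

  back <- read_maps(prefix)
  expect_equal(back$spec$npts, ms$spec$npts)
  expect_equal(back$spec$center, ms$spec$center, tolerance = 1e-3)
  expect_equal(back$electrostatic$values, ms$electrostatic$values,
               tolerance = 5e-4, ignore_attr = TRUE)
  for (ty in names(ms$affinity)) {
    expect_equal(ligmaps:::map_values(back$affinity[[ty]]),
                 ligmaps:::map_values(ms$affinity[[ty]]),
                 tolerance = 5e-4, ignore_attr = TRUE)
  }
  expect_equal(back$dielectric, ms$dielectric)
  expect_equal(back$reference_name, ms$reference_name)

  # truncated file is rejected
  writeLines(lines[1:20], paste0(prefix, ".e.map"))
  expect_error(read_maps(prefix), "expected")
})

test_that("a small grid writes the expected number of value lines", {
  probe <- make_probe(tibble::tibble(ad_type = "C", x = 0, y = 0, z = 0))
  spec <- grid_spec(c(0, 0, 0), c(2, 2, 2), 0.5)
  expect_equal(spec$npts, c(4L, 4L, 4L))
  map <- build_affinity_map("C", probe, spec)
  prefix <- file.path(withr::local_tempdir(), "tiny")
  ligmaps:::write_one_map(map, prefix)
  expect_length(readLines(paste0(prefix, ".C.map")), 6 + 125)
})
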