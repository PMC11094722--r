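test_that("read_sdf preserves record count and order, skipping bad records", {
  withr::local_seed(41)
  mols <- lapply(1:3, function(i) random_chain(5 + i))
  for (i in seq_along(mols)) mols[[i]]$name <- sprintf("m%d", i)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, path)
  back <- read_sdf(path)
  expect_length(back, 3)
  expect_equal(vapply(back, function(m) m$name, character(1)),
               c("m1", "m2", "m3"))

  # append a corrupt record: it must be skipped with a message, not fatal
  writeLines(c(readLines(path),
               "broken", "", "", "  2  1", "garbage", "$$$$"), path)
  expect_message(back2 <- read_sdf(path), "skipped")
  expect_length(back2, 3)

  expect_error(read_sdf(withr::local_tempfile(fileext = ".sdf")),
               "not found")
})

test_that("SDF write/read round-trips coordinates and bonds", {
  withr::local_seed(42)
  mols <- lapply(1:10, function(i) random_chain(sample(3:12, 1)))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, path)
  back <- read_sdf(path)
  for (i in seq_along(mols)) {
    expect_equal(nrow(back[[i]]$atoms), nrow(mols[[i]]$atoms))
    expect_equal(nrow(back[[i]]$bonds), nrow(mols[[i]]$bonds))
    expect_equal(coords(back[[i]]), coords(mols[[i]]), tolerance = 1e-3)
  }
})

test_that("preparation merges nonpolar hydrogens and conserves charge", {
  # methane: every hydrogen is nonpolar, so a single C atom remains
  methane <- new_molecule("methane", tibble::tibble(
    element = c("C", "H", "H", "H", "H"),
    x = c(0, 0.63, -0.63, 0.63, -0.63),
    y = c(0, 0.63, -0.63, -0.63, 0.63),
    z = c(0, 0.63, 0.63, -0.63, -0.63)),
    tibble::tibble(i = 1L, j = 2:5, order = 1L))
  pm <- prepare_ligand(methane)
  expect_equal(nrow(pm$atoms), 1L)
  expect_equal(pm$atoms$ad_type, "C")
  expect_lt(abs(total_charge(pm)), 1e-6)

  # the example ligand is neutral: merged charges must still sum to zero
  ref <- fx_reference()
  expect_lt(abs(total_charge(ref)), 1e-3)
  expect_false(any(ref$atoms$ad_type == "H" & !ref$atoms$is_polar_h))

  # hydroxyl typing: O is an acceptor (OA), its hydrogen polar (HD)
  oh_o <- which(ref$atoms$element == "O" &
                  ref$atoms$ad_type == "OA")
  expect_gte(length(oh_o), 1)
  expect_true(all(ref$atoms$ad_type[ref$atoms$element == "H"] == "HD"))
  # aromatic ring carbons typed A, amide carbon typed C
  expect_equal(sum(ref$atoms$ad_type == "A"), 6)
  expect_equal(sum(ref$atoms$ad_type == "C"), 1)

  # rigid preparation removes all torsional freedom
  rigid <- prepare_ligand(make_example_ligand(), rigid = TRUE)
  expect_equal(nrow(rigid$torsions), 0L)
  expect_true(rigid$rigid)

  # unsupported element is rejected by name
  bad <- new_molecule("bad", tibble::tibble(
    element = c("C", "Xx"), x = c(0, 1.5), y = 0, z = 0),
    tibble::tibble(i = 1L, j = 2L, order = 1L))
  expect_error(prepare_ligand(bad), "Xx")
})

test_that("PDBQT write/read round-trips atoms and torsion tree", {
  ref <- fx_reference()
  path <- withr::local_tempfile(fileext = ".pdbqt")
  write_pdbqt(ref, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "ATOM")), nrow(ref$atoms))
  expect_equal(sum(startsWith(lines, "BRANCH")), nrow(ref$torsions))
  expect_equal(sum(grepl("^TORSDOF 2$", lines)), 1L)

  back <- read_pdbqt(path)
  ord <- order(back$atoms$x, back$atoms$y, back$atoms$z)
  ord0 <- order(ref$atoms$x, ref$atoms$y, ref$atoms$z)
  expect_equal(coords(back)[ord, ], coords(ref)[ord0, ], tolerance = 1e-3)
  expect_equal(back$atoms$charge[ord], ref$atoms$charge[ord0],
               tolerance = 1e-3)
  expect_equal(back$atoms$ad_type[ord], ref$atoms$ad_type[ord0])
  expect_equal(nrow(back$torsions), nrow(ref$torsions))

  # rigid molecule: flat ROOT block, TORSDOF 0
  rigid <- fx_rigid_reference()
  write_pdbqt(rigid, path)
  lines <- readLines(path)
  expect_false(any(startsWith(lines, "BRANCH")))
  expect_true(any(grepl("^TORSDOF 0$", lines)))

  unp <- make_example_ligand()
  expect_error(write_pdbqt(unp, path), "prepare_ligand")
})

test_that("torsion moving sets rotate the expected side of the bond", {
  ref <- fx_reference()
  # amide torsion (ring C1 - amide C7) moves the amide group, not the ring
  t1 <- which(ref$torsions$i == 1 | ref$torsions$j == 1)
  expect_length(t1, 1)
  mv <- ref$torsions$moving[[t1]]
  expect_true(all(c(7, 8, 9) %in% mv))
  expect_false(any(1:6 %in% mv))
})

test_that("centroid and extent match brute force on random clouds", {
  withr::local_seed(7)
  for (rep in 1:200) {
    m <- random_cloud(sample(1:50, 1), scale = runif(1, 1, 20))
    xyz <- coords(m)
    expect_equal(centroid(m), colMeans(xyz), ignore_attr = TRUE)
    expect_equal(extent(m),
                 apply(xyz, 2, max) - apply(xyz, 2, min),
                 ignore_attr = TRUE)
  }
  one <- make_probe(tibble::tibble(ad_type = "C", x = 2, y = -1, z = 5))
  expect_equal(centroid(one), c(2, -1, 5))
  expect_equal(extent(one), c(0, 0, 0))
  two <- make_probe(tibble::tibble(ad_type = "C", x = c(0, 2), y = 0, z = 0))
  expect_equal(centroid(two), c(1, 0, 0))
  expect_equal(extent(two), c(2, 0, 0))
})

test_that("rotatable bond count follows the non-ring non-terminal rule", {
  expect_equal(count_rotatable_bonds(fx_butane()), 1L)
  benzene <- new_molecule("benzene", tibble::tibble(
    element = "C",
    x = 1.39 * cos((0:5) * pi / 3), y = 1.39 * sin((0:5) * pi / 3), z = 0),
    tibble::tibble(i = 1:6, j = c(2:6, 1L), order = c(2L, 1L)[c(1, 2, 1, 2, 1, 2)]))
  expect_equal(count_rotatable_bonds(benzene), 0L)
  # the example ligand: ring-amide bond only (hydroxyl O-H is terminal)
  expect_equal(count_rotatable_bonds(make_example_ligand()), 1L)
})
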