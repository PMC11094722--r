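test_that("the identity genome reproduces the input conformation", {
  ref <- fx_reference()
  g <- pose_genome(torsions = numeric(nrow(ref$torsions)))
  expect_equal(apply_genome(ref, g), coords(ref), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a pure translation genome shifts every atom equally", {
  ref <- fx_reference()
  g <- pose_genome(translation = c(1.5, -2, 0.25),
                   torsions = numeric(nrow(ref$torsions)))
  expect_equal(apply_genome(ref, g),
               sweep(coords(ref), 2, c(1.5, -2, 0.25), `+`),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("torsion genes rotate dihedrals by the requested angle", {
  but <- fx_butane()
  d0 <- measure_dihedral(coords(but), 1, 2, 3, 4)
  for (ang in c(pi, pi / 3, -2.1)) {
    xyz <- apply_genome(but, pose_genome(torsions = ang))
    d1 <- measure_dihedral(xyz, 1, 2, 3, 4)
    delta <- ((d1 - d0 - ang + pi) %% (2 * pi)) - pi
    expect_lt(abs(delta), 1e-9)
    # bond lengths are preserved by the kinematics
    expect_equal(sqrt(sum((xyz[2, ] - xyz[3, ])^2)),
                 sqrt(sum((coords(but)[2, ] - coords(but)[3, ])^2)),
                 tolerance = 1e-9)
  }
  expect_error(apply_genome(but, pose_genome()), "rotatable")
})

test_that("search runs are bit-identical under a fixed seed", {
  ms <- fx_mapset()
  probe <- make_probe(tibble::tibble(ad_type = "C", x = 0, y = 0, z = 0))
  cfg <- search_config(n_runs = 2, population_size = 20, n_generations = 5,
                       local_search_iters = 10)
  a <- screen_compound(probe, ms, cfg, seed = 99)
  b <- screen_compound(probe, ms, cfg, seed = 99)
  expect_identical(a$s_init, b$s_init)
  expect_identical(a$pose, b$pose)
  expect_identical(a$run_scores, b$run_scores)
  c <- screen_compound(probe, ms, cfg, seed = 100)
  expect_false(identical(a$s_init, c$s_init))
})

test_that("best-of-n is the running minimum over the seed stream", {
  ms <- fx_mapset()
  probe <- make_probe(tibble::tibble(ad_type = "OA", x = 0, y = 0, z = 0))
  cfg5 <- search_config(n_runs = 5, population_size = 15, n_generations = 4,
                        local_search_iters = 8)
  hit5 <- screen_compound(probe, ms, cfg5, seed = 7)
  expect_equal(hit5$s_init, min(hit5$run_scores))
  # prefix property: fewer runs over the same stream can never do better
  cfg2 <- cfg5; cfg2$n_runs <- 2
  hit2 <- screen_compound(probe, ms, cfg2, seed = 7)
  expect_equal(hit2$run_scores, hit5$run_scores[1:2])
  expect_gte(hit2$s_init, hit5$s_init)
})

test_that("a rigid probe search matches the exhaustive grid-node oracle", {
  ms <- fx_mapset()
  probe <- make_probe(tibble::tibble(ad_type = "C", x = 0, y = 0, z = 0))
  grid_min <- min(ligmaps:::map_values(ms$affinity[["C"]]))
  hit <- screen_compound(probe, ms,
                         search_config(n_runs = 5, population_size = 30,
                                       n_generations = 15,
                                       local_search_iters = 25),
                         seed = 3)
  expect_lt(hit$s_init, 0)
  expect_lte(hit$s_init, 0.95 * grid_min)
})

test_that("screen_library is order-stable, fault-tolerant and seed-derived", {
  ms <- fx_mapset()
  mols <- list(
    make_probe(tibble::tibble(ad_type = "C", x = 0, y = 0, z = 0), "p1"),
    make_probe(tibble::tibble(ad_type = "OA", x = 0.5, y = 0, z = 0), "p2"),
    make_probe(tibble::tibble(ad_type = "N", x = 0, y = 0.5, z = 0), "p3")
  )
  cfg <- search_config(n_runs = 1, population_size = 12, n_generations = 4,
                       local_search_iters = 6)
  res <- screen_library(mols, ms, cfg, seed = 5)
  expect_s3_class(res, "screen_result")
  expect_equal(res$compound, c("p1", "p2", "p3"))
  expect_true(all(res$status == "ok"))
  expect_true(all(res$s_init < 0))

  # per-compound results depend only on the compound's derived seed, not
  # on its neighbours in the library
  res2 <- screen_library(mols[c(1, 3)], ms, cfg, seed = 5)
  expect_equal(res2$s_init[1], res$s_init[1])

  # a broken molecule is reported, not fatal
  broken <- mols[[1]]
  broken$atoms$ad_type <- "ZZ"
  broken$name <- "broken"
  expect_message(res3 <- screen_library(c(mols[1], list(broken)), ms, cfg,
                                        seed = 5),
                 "failed")
  expect_equal(res3$status[1], "ok")
  expect_match(res3$status[2], "ZZ")
  expect_true(is.na(res3$s_init[2]))

  expect_equal(nrow(screen_library(list(), ms, cfg, seed = 1)), 0L)
})

test_that("search configuration validates its inputs", {
  expect_error(search_config(n_runs = 0), ">= 1")
  expect_error(search_config(mutation_rate = 1.5), "rates")
  cfg <- search_config()
  expect_gte(cfg$crossover_rate, 0)
})
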