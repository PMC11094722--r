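test_that("AUROC hits the analytic edge cases", {
  perfect <- screen_ranking(tibble::tibble(
    compound = letters[1:10], s_sim = 10:1,
    is_active = rep(c(TRUE, FALSE), each = 5)))
  expect_equal(auroc(perfect), 1.0)
  inverted <- screen_ranking(tibble::tibble(
    compound = letters[1:10], s_sim = 10:1,
    is_active = rep(c(FALSE, TRUE), each = 5)))
  expect_equal(auroc(inverted), 0)
  single_class <- screen_ranking(tibble::tibble(
    compound = letters[1:4], s_sim = 4:1, is_active = TRUE))
  expect_error(auroc(single_class), "active")
})

test_that("AUROC equals the pairwise-comparison oracle, with midrank ties", {
  withr::local_seed(43)
  for (rep in 1:30) {
    r <- rand_ranking(200, 20, tie_prob = rep %% 2)
    expect_equal(auroc(r), pairwise_auroc(r$s_sim, r$is_active),
                 tolerance = 1e-12)
  }
})

test_that("labels independent of score give AUROC near one half", {
  withr::local_seed(44)
  aucs <- replicate(200, auroc(rand_ranking(100, 20)))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("reversing a ranking complements the AUROC", {
  withr::local_seed(45)
  for (rep in 1:20) {
    r <- rand_ranking(100, 15)
    rev <- screen_ranking(tibble::tibble(
      compound = r$compound, s_sim = -r$s_sim, is_active = r$is_active))
    expect_equal(auroc(rev), 1 - auroc(r), tolerance = 1e-12)
  }
})

test_that("the ROC curve integrates to the AUROC", {
  withr::local_seed(46)
  for (rep in 1:100) {
    r <- rand_ranking(60, 10, tie_prob = rep %% 2)
    curve <- roc_curve(r)
    area <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
    expect_equal(area, auroc(r), tolerance = 1e-9)
    expect_equal(curve$fpr[1], 0); expect_equal(utils::tail(curve$tpr, 1), 1)
  }
  perfect <- screen_ranking(tibble::tibble(
    compound = letters[1:6], s_sim = 6:1,
    is_active = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)))
  curve <- roc_curve(perfect)
  expect_true(any(curve$fpr == 0 & curve$tpr == 1))
})

test_that("enrichment factor reproduces the worked case and edge cases", {
  # 200 compounds, 10 actives, both top-1% picks active -> EF = 20
  r <- screen_ranking(tibble::tibble(
    compound = sprintf("c%03d", 1:200),
    s_sim = seq(1, 0, length.out = 200),
    is_active = c(TRUE, TRUE, rep(FALSE, 190), rep(TRUE, 8))))
  ef <- enrichment_factor(r, 1)
  expect_equal(ef$n_top, 2L)
  expect_equal(ef$na_top, 2L)
  expect_equal(ef$ef, 20)
  # this is also the EF upper bound N_total / NA_total
  expect_equal(ef$ef, 200 / 10)

  # all actives at the bottom -> EF = 0
  bottom <- screen_ranking(tibble::tibble(
    compound = sprintf("c%03d", 1:200),
    s_sim = seq(1, 0, length.out = 200),
    is_active = c(rep(FALSE, 190), rep(TRUE, 10))))
  expect_equal(enrichment_factor(bottom, 1)$ef, 0)

  # uniform interleaving -> EF near 1
  uni <- screen_ranking(tibble::tibble(
    compound = sprintf("c%03d", 1:200),
    s_sim = seq(1, 0, length.out = 200),
    is_active = rep(c(TRUE, rep(FALSE, 19)), 10)))
  expect_equal(enrichment_factor(uni, 10)$ef, 1)

  # ceiling rule keeps the top set non-empty
  tiny <- screen_ranking(tibble::tibble(
    compound = letters[1:10], s_sim = 10:1,
    is_active = c(TRUE, rep(FALSE, 9))))
  expect_equal(enrichment_factor(tiny, 1)$n_top, 1L)
  expect_equal(enrichment_factor(tiny, 1)$ef, 10)

  expect_error(enrichment_factor(bottom, 0), "x_percent")
  noact <- screen_ranking(tibble::tibble(
    compound = letters[1:5], s_sim = 5:1, is_active = FALSE))
  expect_error(enrichment_factor(noact, 1), "active")
})

test_that("ties straddling the EF cutoff warn and resolve stably", {
  r <- screen_ranking(tibble::tibble(
    compound = letters[1:10],
    s_sim = c(1, rep(0.5, 4), seq(0.4, 0, length.out = 5)),
    is_active = c(TRUE, TRUE, rep(FALSE, 8))))
  expect_warning(ef <- enrichment_factor(r, 20), "tie")
  expect_equal(ef$n_top, 2L)
})

test_that("glance and autoplot work on rankings", {
  withr::local_seed(47)
  r <- rand_ranking(50, 10)
  gl <- glance(r, ef_percent = c(1, 10))
  expect_true(all(c("auroc", "ef_1", "ef_10") %in% names(gl)))
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})

test_that("rankings drop unscored entries with a warning", {
  expect_warning(r <- screen_ranking(tibble::tibble(
    compound = letters[1:5], s_sim = c(1, NA, 3, 2, NA),
    is_active = c(TRUE, TRUE, FALSE, FALSE, TRUE))), "missing")
  expect_equal(nrow(r), 3)
  expect_equal(r$compound, c("c", "d", "a"))
})
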