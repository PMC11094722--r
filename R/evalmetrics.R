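# Screen evaluation: rank-based AUROC (Mann-Whitney with midranks for
# ties) and enrichment factors at a top fraction of the ranked library.

#' Build a labeled screen ranking
#'
#' @param entries Data frame with columns `compound`, `s_sim` (or another
#'   score where higher is better) and logical `is_active`.
#' @return A `screen_ranking` tibble sorted descending by `s_sim` (stable
#'   for ties), with attributes `n_actives` and `n_total`.
#' @export
screen_ranking <- function(entries) {
  entries <- as_tibble(entries)
  stopifnot(all(c("compound", "s_sim", "is_active") %in% names(entries)))
  if (any(is.na(entries$s_sim))) {
    warn(sprintf("dropping %d entries with missing scores",
                 sum(is.na(entries$s_sim))))
    entries <- entries[!is.na(entries$s_sim), ]
  }
  out <- entries[order(-entries$s_sim), ]
  class(out) <- c("screen_ranking", class(out))
  attr(out, "n_actives") <- sum(out$is_active)
  attr(out, "n_total") <- nrow(out)
  out
}

#' Area under the ROC curve of a ranked screen
#'
#' Rank-based (Mann-Whitney) formulation with midranks for tied scores:
#' the probability that a random active outscores a random decoy. 1 is
#' perfect separation; 0.5 is random.
#'
#' @param r A [screen_ranking()].
#' @return Scalar in `[0, 1]`.
#' @export
auroc <- function(r) {
  y <- r$is_active
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("auroc needs at least one active and one decoy")
  rk <- rank(r$s_sim, ties.method = "average")
  (sum(rk[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve of a ranked screen
#'
#' Standard step curve over the descending score order, with ties advanced
#' together; the trapezoid area under it equals [auroc()].
#'
#' @param r A [screen_ranking()].
#' @return Tibble with columns `fpr`, `tpr`, starting at (0, 0) and ending
#'   at (1, 1).
#' @export
roc_curve <- function(r) {
  y <- r$is_active
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("roc_curve needs at least one active and one decoy")
  # advance over distinct score levels so ties move diagonally
  lev <- split(seq_along(y), factor(-r$s_sim, levels = unique(-r$s_sim)))
  tp <- unname(cumsum(vapply(lev, function(ix) sum(y[ix]), numeric(1))))
  fp <- unname(cumsum(vapply(lev, function(ix) sum(!y[ix]), numeric(1))))
  tibble(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

#' Enrichment factor at a top fraction
#'
#' `EF = (NA_top / N_top) / (NA_total / N_total)` where the top set is the
#' first `ceil(x_percent/100 * N_total)` compounds of the ranking (ceiling
#' guarantees a non-empty top set). Tied scores straddling the cutoff are
#' resolved by stable input order, with a warning.
#'
#' @param r A [screen_ranking()].
#' @param x_percent Top percentage in `(0, 100]` (default 1, the
#'   conventional early-enrichment cut).
#' @return A tibble row: `x_percent`, `n_top`, `na_top`, `n_total`,
#'   `na_total`, `ef`.
#' @export
enrichment_factor <- function(r, x_percent = 1) {
  if (x_percent <= 0 || x_percent > 100) abort("x_percent must be in (0, 100]")
  n_total <- nrow(r); na_total <- sum(r$is_active)
  if (na_total == 0) abort("enrichment_factor needs at least one active")
  n_top <- as.integer(ceiling(x_percent / 100 * n_total))
  if (n_top < n_total &&
      isTRUE(r$s_sim[n_top] == r$s_sim[n_top + 1L])) {
    warn("score tie straddles the top-fraction cutoff; resolved by stable input order")
  }
  na_top <- sum(r$is_active[seq_len(n_top)])
  tibble(x_percent = x_percent, n_top = n_top, na_top = na_top,
         n_total = n_total, na_total = na_total,
         ef = (na_top / n_top) / (na_total / n_total))
}

#' Summary metrics of a ranked screen
#'
#' @param x A `screen_ranking`.
#' @param ef_percent Top percentages at which to report enrichment.
#' @param ... Unused.
#' @return One-row tibble with counts, `auroc` and one `ef_<x>` column per
#'   requested percentage.
#' @method glance screen_ranking
#' @export
glance.screen_ranking <- function(x, ef_percent = 1, ...) {
  out <- tibble(n_total = nrow(x), n_actives = sum(x$is_active),
                auroc = auroc(x))
  for (p in ef_percent) {
    out[[sprintf("ef_%g", p)]] <- enrichment_factor(x, p)$ef
  }
  out
}

#' Plot the ROC curve of a ranked screen
#'
#' @param object A `screen_ranking`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot screen_ranking
#' @export
autoplot.screen_ranking <- function(object, ...) {
  curve <- roc_curve(object)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUROC = %.3f)", auroc(object))) +
    ggplot2::theme_minimal()
}

#' Plot a slice through a grid map
#'
#' Renders one z-slice of an affinity or electrostatic map as a raster;
#' useful for inspecting where a map prefers its atom type.
#'
#' @param object A `grid_map`.
#' @param z_index 1-based slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grid_map
#' @export
autoplot.grid_map <- function(object, z_index = NULL, ...) {
  spec <- object$spec
  z_index <- z_index %||% (spec$npts[3] %/% 2L + 1L)
  vals <- map_values(object)[, , z_index]
  df <- expand.grid(x = grid_axis(spec, 1), y = grid_axis(spec, 2))
  df$value <- as.vector(vals)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (Å)", y = "y (Å)", fill = "value",
      title = sprintf("%s map, z = %.2f Å", object$ad_type,
                      grid_axis(spec, 3)[z_index])) +
    ggplot2::theme_minimal()
}
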