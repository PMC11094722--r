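# Similarity normalization: s_sim = s_init / sum(s_ref). The reference
# self-score is the theoretical ceiling of s_init, so s_sim normally lies
# in [0, 1] with 1 attained by the reference itself.

#' Reference self-score
#'
#' Scores the reference ligand against its own maps. Mode `"fixed"`
#' (default) scores the input bioactive coordinates directly — the
#' deterministic ceiling, making the reference's own similarity exactly 1.
#' Mode `"selfdock"` instead self-docks the reference with the stochastic
#' search and returns the best score found, mirroring a screening run.
#'
#' @param ref Prepared `lig_molecule` the maps were built from (or one
#'   constituent of the composite, in multi-reference mode).
#' @param ms The `map_set` built from `ref` (or from the composite).
#' @param mode `"fixed"` or `"selfdock"`.
#' @param cfg [search_config()] used by `"selfdock"` mode.
#' @param seed Seed for `"selfdock"` mode.
#' @return Scalar `s_ref` (strictly negative; degenerate references with a
#'   non-negative self-score are an error).
#' @export
reference_score <- function(ref, ms, mode = c("fixed", "selfdock"),
                            cfg = search_config(), seed = 1L) {
  mode <- match.arg(mode)
  s <- if (mode == "fixed") {
    score_pose(ms, ref)$total
  } else {
    screen_compound(ref, ms, cfg, seed)$s_init
  }
  if (!is.finite(s) || s >= 0) {
    abort(sprintf(
      "degenerate reference %s: self-score %.4f is not negative", ref$name, s))
  }
  s
}

#' Normalize raw screen scores to similarities
#'
#' `s_sim = s_init / sum(s_ref_values)`. With a single reference this is
#' the quotient of the compound's best score by the reference self-score;
#' in multi-reference mode the denominator is the sum of the per-reference
#' self-scores against the composite maps. Higher `s_sim` means more
#' similar; the transform is a positive monotone function of `s_init`, so
#' rankings are preserved. Values outside `[0, 1]` (possible when
#' electrostatic terms push `s_init` positive, or with a shallow
#' self-docked `s_ref`) are reported and flagged, never clamped.
#'
#' @param result A `screen_result` tibble from [screen_library()], or a
#'   numeric vector of `s_init` values.
#' @param s_ref_values Numeric vector of reference self-scores (all
#'   strictly negative).
#' @return For a tibble input: the tibble with columns `s_ref_total`,
#'   `s_sim`, `outside_range` and `rank` (1 = most similar) added, sorted
#'   by rank. For numeric input: a tibble with `s_init`, `s_ref_total`,
#'   `s_sim`, `outside_range`.
#' @export
normalize_similarity <- function(result, s_ref_values) {
  if (!length(s_ref_values) || any(!is.finite(s_ref_values))) {
    abort("s_ref_values must be finite and non-empty")
  }
  if (any(s_ref_values >= 0)) abort("all s_ref values must be negative")
  s_ref_total <- sum(s_ref_values)
  if (s_ref_total == 0) abort("sum of s_ref values must be nonzero")
  if (is.numeric(result)) {
    result <- tibble(s_init = result)
  }
  out <- dplyr::mutate(
    result,
    s_ref_total = s_ref_total,
    s_sim = .data$s_init / s_ref_total,
    outside_range = !is.na(.data$s_sim) &
      (.data$s_sim < 0 | .data$s_sim > 1)
  )
  if (any(out$outside_range, na.rm = TRUE)) {
    warn(sprintf("%d similarity value(s) fall outside [0, 1] (reported unclamped)",
                 sum(out$outside_range, na.rm = TRUE)))
  }
  out$rank <- rank(-out$s_sim, ties.method = "first", na.last = "keep")
  dplyr::arrange(out, .data$rank)
}

#' @importFrom rlang .data
NULL

#' Tidy a screen result
#'
#' Drops the list columns (genomes, poses) of a `screen_result`, returning
#' the plain per-compound score table.
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) {
  keep <- setdiff(names(x), c("genome", "pose"))
  out <- as_tibble(x)[, keep]
  out
}

#' One-row summary of a screen result
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return A one-row tibble: compounds screened/failed, best and median
#'   `s_init` (and `s_sim` when present).
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  out <- tibble(
    n_compounds = nrow(x),
    n_failed = sum(x$status != "ok"),
    best_s_init = suppressWarnings(min(x$s_init, na.rm = TRUE)),
    median_s_init = stats::median(x$s_init, na.rm = TRUE)
  )
  if ("s_sim" %in% names(x)) {
    out$best_s_sim <- suppressWarnings(max(x$s_sim, na.rm = TRUE))
    out$median_s_sim <- stats::median(x$s_sim, na.rm = TRUE)
  }
  out
}
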