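# End-to-end workflow: prepare -> maps -> screen -> normalize ->
# (optional) evaluate, with reproducibility metadata embedded in every
# output.

read_reference_file <- function(path) {
  if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) {
    read_pdbqt(path)
  } else {
    prepare_ligand(read_sdf(path)[[1]], rigid = TRUE)
  }
}

#' Run the full screening pipeline
#'
#' Prepares the reference(s) and library, builds the ligand-derived map
#' set, screens every library compound with the LGA, normalizes scores to
#' similarities and (when labels are supplied) evaluates AUROC and
#' enrichment. With multiple reference paths the multi-reference mode is
#' used: maps come from the composite and the similarity denominator is
#' the sum of per-reference self-scores.
#'
#' @param reference_paths Character vector of reference files (PDBQT, or
#'   SDF prepared rigid on the fly). More than one triggers
#'   multi-reference mode (inputs must be mutually aligned).
#' @param library_path Multi-record SDF of screening compounds.
#' @param out_dir Output directory; `NULL` suppresses file output.
#' @param labels Optional data frame (or TSV path) with columns `compound`
#'   and `is_active` for evaluation.
#' @param spacing,radius,dielectric Map parameters (Angstrom, Angstrom,
#'   dielectric factor).
#' @param cfg A [search_config()].
#' @param s_ref_mode `"fixed"` or `"selfdock"` (see [reference_score()]).
#' @param seed Master seed for the screen.
#' @param ef_percent Enrichment-factor percentages for evaluation.
#' @return List with `result` (similarity tibble), `s_ref` (per-reference
#'   self-scores), `metrics` (or `NULL`), `mapset`, and `paths` of any
#'   files written.
#' @export
run_pipeline <- function(reference_paths, library_path, out_dir = NULL,
                         labels = NULL, spacing = 0.375, radius = 1.54,
                         dielectric = -0.1465, cfg = search_config(),
                         s_ref_mode = c("fixed", "selfdock"), seed = 1L,
                         ef_percent = 1) {
  s_ref_mode <- match.arg(s_ref_mode)
  t0 <- Sys.time()
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", what,
                    conditionMessage(e)))
    })
  }
  refs <- stage("prepare-reference",
                lapply(reference_paths, read_reference_file))
  reference <- if (length(refs) > 1) compose_references(refs) else refs[[1]]
  library_mols <- stage("prepare-library",
                        prepare_library(read_sdf(library_path)))
  ms <- stage("make-maps",
              build_mapset(reference, library_mols, spacing = spacing,
                           radius = radius, dielectric = dielectric))
  screened <- stage("screen", screen_library(library_mols, ms, cfg, seed))
  s_ref <- stage("normalize", {
    if (inherits(reference, "composite_reference")) {
      composite_reference_scores(reference, ms)
    } else {
      reference_score(reference, ms, mode = s_ref_mode, cfg = cfg,
                      seed = derive_seed(seed, 999L))
    }
  })
  result <- normalize_similarity(screened, s_ref)

  metrics <- NULL
  if (!is.null(labels)) {
    if (is.character(labels)) {
      labels <- utils::read.delim(labels, sep = "\t")
    }
    ranked <- screen_ranking(dplyr::inner_join(
      tidy(result), as_tibble(labels), by = "compound"))
    metrics <- glance(ranked, ef_percent = ef_percent)
  }

  run_meta <- list(
    version = as.character(utils::packageVersion("ligmaps")),
    seed = seed, s_ref_mode = s_ref_mode, spacing = spacing,
    radius = radius, dielectric = dielectric,
    n_runs = cfg$n_runs, reference = reference$name,
    config_hash = rlang::hash(list(spacing, radius, dielectric, cfg,
                                   s_ref_mode, seed))
  )
  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tsv <- file.path(out_dir, "results.tsv")
    hdr <- sprintf("# %s\t%s", names(run_meta),
                   vapply(run_meta, as.character, character(1)))
    writeLines(hdr, tsv)
    suppressWarnings(utils::write.table(
      tidy(result), tsv, sep = "\t", quote = FALSE, row.names = FALSE,
      append = TRUE))
    paths <- c(paths, tsv)
    if (!is.null(metrics)) {
      mjson <- file.path(out_dir, "metrics.json")
      jsonlite::write_json(c(run_meta, as.list(metrics)), mjson,
                           auto_unbox = TRUE, digits = NA)
      paths <- c(paths, mjson)
    }
  }
  inform(sprintf("pipeline finished in %.1f s",
                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  list(result = result, s_ref = s_ref, metrics = metrics, mapset = ms,
       meta = run_meta, paths = paths)
}
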