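# Lamarckian genetic algorithm over translation/orientation/torsion genes:
# generational GA with tournament selection, block crossover and Gaussian
# mutation, plus a Solis-Wets local search whose accepted moves are written
# back into the genome (the Lamarckian step).

#' Search configuration
#'
#' Defaults are desk-scale: small populations and few generations chosen so
#' that a full synthetic screen runs in minutes on one CPU. For
#' production-size screens raise `n_runs` (100 is the conventional
#' full-scale setting), `population_size` and `n_generations`.
#'
#' @param n_runs Independent LGA runs per compound; the best pose across
#'   runs is kept.
#' @param population_size Individuals per generation.
#' @param n_generations Generations per run.
#' @param mutation_rate Per-gene mutation probability.
#' @param crossover_rate Probability a child is produced by crossover
#'   rather than cloning.
#' @param local_search_iters Solis-Wets iterations per refined individual.
#' @param local_search_frac Fraction of the population refined each
#'   generation (at least one individual).
#' @param trans_step,rot_step,tors_step Base step sizes for mutation and
#'   local search: Angstrom, radians, radians.
#' @param elitism Number of best individuals copied unchanged.
#' @param out_of_box_penalty Additive score penalty per out-of-box atom.
#' @param rng_seed Optional default master seed used when a search function
#'   is called without an explicit seed.
#' @return A `search_config` list.
#' @export
search_config <- function(n_runs = 5, population_size = 50,
                          n_generations = 40, mutation_rate = 0.06,
                          crossover_rate = 0.8, local_search_iters = 40,
                          local_search_frac = 0.08, trans_step = 0.4,
                          rot_step = 0.3, tors_step = 0.4, elitism = 1,
                          out_of_box_penalty = 1000, rng_seed = NULL) {
  cfg <- list(n_runs = n_runs, population_size = population_size,
              n_generations = n_generations, mutation_rate = mutation_rate,
              crossover_rate = crossover_rate,
              local_search_iters = local_search_iters,
              local_search_frac = local_search_frac,
              trans_step = trans_step, rot_step = rot_step,
              tors_step = tors_step, elitism = elitism,
              out_of_box_penalty = out_of_box_penalty, rng_seed = rng_seed)
  num <- vapply(cfg[setdiff(names(cfg), "rng_seed")], as.numeric, numeric(1))
  if (any(num[c("n_runs", "population_size", "n_generations",
                "local_search_iters")] < 1)) {
    abort("n_runs, population_size, n_generations and local_search_iters must be >= 1")
  }
  if (any(num[c("mutation_rate", "crossover_rate")] < 0 |
            num[c("mutation_rate", "crossover_rate")] > 1)) {
    abort("rates must lie in [0, 1]")
  }
  structure(cfg, class = "search_config")
}

mutate_genome <- function(g, cfg) {
  for (d in 1:3) {
    if (runif(1) < cfg$mutation_rate) {
      g$translation[d] <- g$translation[d] + rnorm(1, 0, cfg$trans_step)
    }
  }
  if (runif(1) < cfg$mutation_rate) {
    ax <- rnorm(3)
    g$orientation <- quat_normalize(
      quat_multiply(axis_angle_quat(ax, rnorm(1, 0, cfg$rot_step)),
                    g$orientation))
  }
  k <- length(g$torsions)
  if (k > 0) {
    hit <- runif(k) < cfg$mutation_rate
    g$torsions[hit] <- wrap_angle(g$torsions[hit] +
                                    rnorm(sum(hit), 0, cfg$tors_step))
  }
  g
}

crossover_genomes <- function(a, b) {
  g <- a
  if (runif(1) < 0.5) g$translation <- b$translation
  if (runif(1) < 0.5) g$orientation <- b$orientation
  k <- length(a$torsions)
  if (k > 0) {
    take_b <- runif(k) < 0.5
    g$torsions[take_b] <- b$torsions[take_b]
  }
  g
}

perturb_genome <- function(g, dt, dq, dtau) {
  g$translation <- g$translation + dt
  g$orientation <- quat_normalize(quat_multiply(dq, g$orientation))
  if (length(dtau)) g$torsions <- wrap_angle(g$torsions + dtau)
  g
}

solis_wets <- function(g, score, eval_fn, cfg) {
  k <- length(g$torsions)
  rho <- 1
  succ <- 0L; fail <- 0L
  bias_t <- c(0, 0, 0); bias_tau <- numeric(k)
  for (it in seq_len(cfg$local_search_iters)) {
    dt <- rnorm(3, bias_t, rho * cfg$trans_step)
    ang <- rnorm(1, 0, rho * cfg$rot_step)
    ax <- rnorm(3)
    dq <- axis_angle_quat(ax, ang)
    dtau <- if (k > 0) rnorm(k, bias_tau, rho * cfg$tors_step) else numeric()
    cand <- perturb_genome(g, dt, dq, dtau)
    s <- eval_fn(cand)
    if (s < score) {
      g <- cand; score <- s
      bias_t <- 0.4 * bias_t + 0.2 * dt
      if (k > 0) bias_tau <- 0.4 * bias_tau + 0.2 * dtau
      succ <- succ + 1L; fail <- 0L
    } else {
      cand2 <- perturb_genome(g, -dt, axis_angle_quat(ax, -ang), -dtau)
      s2 <- eval_fn(cand2)
      if (s2 < score) {
        g <- cand2; score <- s2
        bias_t <- bias_t - 0.4 * dt
        if (k > 0) bias_tau <- bias_tau - 0.4 * dtau
        succ <- succ + 1L; fail <- 0L
      } else {
        bias_t <- 0.5 * bias_t
        if (k > 0) bias_tau <- 0.5 * bias_tau
        fail <- fail + 1L; succ <- 0L
      }
    }
    if (succ >= 4L) { rho <- min(rho * 2, 4); succ <- 0L }
    if (fail >= 4L) { rho <- rho * 0.5; fail <- 0L }
    if (rho < 0.005) break
  }
  list(genome = g, score = score)
}

# Compiled pose evaluator: plain-matrix kinematics plus a single shared
# trilinear-weight computation reused across every map (all maps share one
# grid). This is the search hot path; the public score_pose() is the
# reference implementation and the two are cross-checked in the tests.
compile_evaluator <- function(mol, ms, penalty) {
  xyz0 <- coords(mol)
  n <- nrow(xyz0)
  k <- nrow(mol$torsions)
  tor_i <- mol$torsions$i; tor_j <- mol$torsions$j
  tor_mv <- mol$torsions$moving
  charges <- mol$atoms$charge
  types <- mol$atoms$ad_type
  spec <- ms$spec
  org <- grid_origin(spec); h <- spec$spacing; npts <- spec$npts
  groups <- list()
  for (ty in unique(types)) {
    m <- ms$affinity[[ty]]
    if (is.null(m)) abort(sprintf("no map for atom type %s in map set", ty))
    if (is_zero_map(m)) next
    groups[[length(groups) + 1L]] <- list(idx = which(types == ty),
                                          values = m$values)
  }
  evalues <- ms$electrostatic$values
  group_values <- lapply(groups, function(gr) as.numeric(gr$values))
  group_idx <- lapply(groups, function(gr) gr$idx)
  evec <- as.numeric(evalues)
  pose_of <- function(g) {
    pose_from_genome_cpp(xyz0, tor_i, tor_j, tor_mv, g$torsions,
                         g$orientation, g$translation)
  }
  list(pose_of = pose_of,
       eval_genome = function(g) {
         grid_score_cpp(pose_of(g), group_values, group_idx, evec,
                        charges, org, h, npts, penalty)
       })
}

#' One Lamarckian genetic algorithm run
#'
#' Optimizes the pose/conformation of one molecule against a map set.
#' Reproducible: the same `(mol, ms, cfg, seed)` gives a bit-identical
#' trajectory.
#'
#' @param mol Prepared `lig_molecule`.
#' @param ms A `map_set` covering all of the molecule's atom types.
#' @param cfg A [search_config()].
#' @param seed Integer seed for this run.
#' @return List with `genome`, `pose` (coordinate matrix) and `score`.
#' @export
lga_run <- function(mol, ms, cfg = search_config(), seed = 1L) {
  set.seed(seed)
  k <- nrow(mol$torsions)
  ctr <- centroid(mol)
  ev <- compile_evaluator(mol, ms, cfg$out_of_box_penalty)
  eval_fn <- ev$eval_genome
  pop <- replicate(cfg$population_size,
                   random_genome(k, ms$spec, ctr), simplify = FALSE)
  scores <- vapply(pop, eval_fn, numeric(1))
  n_ls <- max(1L, ceiling(cfg$local_search_frac * cfg$population_size))
  for (gen in seq_len(cfg$n_generations)) {
    ord <- order(scores)
    newpop <- pop[ord[seq_len(min(cfg$elitism, length(pop)))]]
    newscores <- scores[ord[seq_len(length(newpop))]]
    while (length(newpop) < cfg$population_size) {
      pick <- function() {
        c2 <- sample.int(length(pop), 2L)
        c2[which.min(scores[c2])]
      }
      p1 <- pop[[pick()]]
      child <- if (runif(1) < cfg$crossover_rate) {
        crossover_genomes(p1, pop[[pick()]])
      } else p1
      child <- mutate_genome(child, cfg)
      newpop[[length(newpop) + 1L]] <- child
      newscores <- c(newscores, eval_fn(child))
    }
    pop <- newpop; scores <- newscores
    # Lamarckian step: refine the current best individuals and write the
    # improved genomes back into the population
    for (iref in order(scores)[seq_len(n_ls)]) {
      res <- solis_wets(pop[[iref]], scores[iref], eval_fn, cfg)
      pop[[iref]] <- res$genome
      scores[iref] <- res$score
    }
  }
  best <- which.min(scores)
  list(genome = pop[[best]], pose = ev$pose_of(pop[[best]]),
       score = scores[best])
}

#' Screen one compound
#'
#' Runs `cfg$n_runs` independent LGA runs (per-run seeds derived from the
#' master seed by a counter scheme) and keeps the pose with the lowest
#' score; that minimum is the compound's raw score `s_init`. More negative
#' `s_init` means better map fit, i.e. higher similarity to the reference.
#'
#' @inheritParams lga_run
#' @param seed Master seed for this compound.
#' @return A `screen_hit`: list with `compound`, `genome`, `pose`,
#'   `s_init`, `run_scores`, `n_runs`, `seed`.
#' @export
screen_compound <- function(mol, ms, cfg = search_config(), seed = 1L) {
  if (cfg$n_runs < 1) abort("n_runs must be >= 1")
  best <- NULL
  run_scores <- numeric(cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    res <- lga_run(mol, ms, cfg, derive_seed(seed, r))
    run_scores[r] <- res$score
    if (is.null(best) || res$score < best$score) best <- res
  }
  structure(
    list(compound = mol$name, genome = best$genome, pose = best$pose,
         s_init = best$score, run_scores = run_scores,
         n_runs = cfg$n_runs, seed = seed),
    class = "screen_hit"
  )
}

#' Screen a library of compounds
#'
#' One [screen_compound()] per molecule, order-stable, with per-compound
#' seeds derived from the master seed (so results do not depend on
#' evaluation order). Per-compound failures are logged and reported in the
#' `status` column, never fatal.
#'
#' @param library List of prepared `lig_molecule` objects.
#' @param ms A `map_set`.
#' @param cfg A [search_config()].
#' @param seed Master seed for the screen.
#' @return A `screen_result` tibble: columns `compound`, `s_init`,
#'   `n_runs`, `seed`, `status`, and list columns `genome`, `pose`.
#' @export
screen_library <- function(library, ms, cfg = search_config(),
                           seed = cfg$rng_seed %||% 1L) {
  rows <- purrr::imap(library, function(mol, i) {
    cseed <- derive_seed(seed, 100000L + i)
    hit <- tryCatch(screen_compound(mol, ms, cfg, cseed), error = function(e) e)
    if (inherits(hit, "error")) {
      inform(sprintf("screen_library: %s failed (%s)", mol$name,
                     conditionMessage(hit)))
      tibble(compound = mol$name, s_init = NA_real_, n_runs = cfg$n_runs,
             seed = cseed, status = conditionMessage(hit),
             genome = list(NULL), pose = list(NULL))
    } else {
      tibble(compound = hit$compound, s_init = hit$s_init,
             n_runs = hit$n_runs, seed = cseed, status = "ok",
             genome = list(hit$genome), pose = list(hit$pose))
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("screen_result", class(out))
  attr(out, "reference_name") <- ms$reference_name
  attr(out, "master_seed") <- seed
  out
}
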