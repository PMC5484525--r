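#' Genetic-algorithm configuration
#'
#' Defaults follow the published multi-state design protocol: a population
#' of 210 sequences of which the worst-scoring half is replaced each
#' generation by offspring generated by single point mutation or
#' recombination of surviving parents. Convergence is declared when the
#' best fitness improves by less than `convergence_tolerance` over
#' `convergence_window` consecutive generations.
#'
#' @param population_size Number of sequences per generation (>= 2,
#'   default 210).
#' @param replaced_fraction Fraction of the population replaced per
#'   generation (0 < f < 1, default 1/2); the replaced members are those
#'   with the worst fitness.
#' @param mutation_probability Probability that an offspring arises by a
#'   single point mutation of one surviving parent rather than by
#'   recombination of two distinct survivors (default 0.5).
#' @param generations_max Hard cap on generations (default 600).
#' @param convergence_window Generations without sufficient improvement
#'   that trigger early stopping (default 50; `Inf` disables it).
#' @param convergence_tolerance Minimum improvement of the best fitness
#'   over the window (default 1e-6).
#' @param rng_seed Optional integer seed set at the start of a run.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 210L, replaced_fraction = 0.5,
                      mutation_probability = 0.5, generations_max = 600L,
                      convergence_window = 50L,
                      convergence_tolerance = 1e-6, rng_seed = NULL) {
  stopifnot(population_size >= 2L,
            replaced_fraction > 0, replaced_fraction < 1,
            mutation_probability >= 0, mutation_probability <= 1,
            generations_max >= 1L, convergence_tolerance >= 0)
  structure(list(population_size = as.integer(population_size),
                 replaced_fraction = replaced_fraction,
                 mutation_probability = mutation_probability,
                 generations_max = as.integer(generations_max),
                 convergence_window = convergence_window,
                 convergence_tolerance = convergence_tolerance,
                 rng_seed = rng_seed),
            class = "ga_config")
}

.new_population <- function(generation, sequences, fitness) {
  ord <- order(fitness)  # stable; ties keep insertion order
  structure(list(generation = as.integer(generation),
                 sequences = sequences[ord],
                 fitness = unname(fitness[ord])),
            class = "ga_population")
}

#' @export
print.ga_population <- function(x, ...) {
  cat(sprintf("<ga_population> generation %d, %d members, best fitness %s\n",
              x$generation, length(x$sequences),
              format(x$fitness[1], digits = 6)))
  invisible(x)
}

.random_point_mutant <- function(seq, alphabet, id) {
  at <- sample.int(length(seq$residues), 1L)
  choices <- setdiff(alphabet, seq$residues[at])
  mutate_residue(seq, at, choices[sample.int(length(choices), 1L)], id = id)
}

#' Initialize a GA population from a seed sequence
#'
#' The first generation consists of the seed itself plus
#' `population_size - 1` variants, each carrying exactly one random point
#' mutation relative to the seed (position uniform, replacement residue
#' uniform over the non-seed letters of the shell alphabet).
#'
#' @param seed_sequence A `seq_record` aligned to the shell.
#' @param config A [ga_config()].
#' @param shell The `design_shell` providing positions and alphabet.
#' @return A `ga_population` (generation 1, fitness not yet evaluated).
#' @export
ga_init <- function(seed_sequence, config, shell) {
  stopifnot(inherits(seed_sequence, "seq_record"),
            inherits(config, "ga_config"), inherits(shell, "design_shell"))
  if (!identical(seed_sequence$positions, shell$design_positions))
    stop("seed sequence is not aligned to the shell", call. = FALSE)
  if (!all(seed_sequence$residues %in% shell$alphabet))
    stop("seed sequence uses residues outside the shell alphabet",
         call. = FALSE)
  n <- config$population_size
  seed <- seed_sequence
  seed$id <- "g1_seed"
  seqs <- vector("list", n)
  seqs[[1L]] <- seed
  for (k in seq_len(n - 1L))
    seqs[[k + 1L]] <- .random_point_mutant(seed_sequence, shell$alphabet,
                                           sprintf("g1_m%03d", k))
  structure(list(generation = 1L, sequences = seqs,
                 fitness = rep(NA_real_, n)),
            class = "ga_population")
}

#' Evaluate (or re-evaluate) a population's fitness
#'
#' @param pop A `ga_population`.
#' @param ensemble A `state_ensemble`.
#' @param evaluator An evaluator.
#' @param fitness A `fitness_spec`.
#' @param workers Parallel worker count for [evaluate_batch()].
#' @return The population, sorted ascending by fitness.
#' @export
ga_evaluate <- function(pop, ensemble, evaluator,
                        fitness = fitness_spec("mean"), workers = 1L) {
  ts <- evaluate_batch(ensemble, pop$sequences, evaluator, workers)
  .new_population(pop$generation, pop$sequences, apply_fitness(ts, fitness))
}

#' Advance a GA population by one generation
#'
#' The worst `ceiling(replaced_fraction * size)` members are replaced by
#' offspring of the surviving (best) members: with probability
#' `mutation_probability` a single-point mutant of one uniformly chosen
#' survivor, otherwise a single-point crossover of two distinct survivors.
#' Only the offspring are evaluated; survivors keep their cached fitness.
#'
#' @inheritParams ga_evaluate
#' @param config A [ga_config()].
#' @return The next `ga_population`, re-sorted ascending by fitness.
#' @export
ga_generation <- function(pop, ensemble, evaluator,
                          fitness = fitness_spec("mean"), config,
                          workers = 1L) {
  stopifnot(inherits(pop, "ga_population"), inherits(config, "ga_config"))
  if (anyNA(pop$fitness))
    stop("population must be evaluated before breeding (see ga_evaluate)",
         call. = FALSE)
  n <- length(pop$sequences)
  n_rep <- as.integer(ceiling(config$replaced_fraction * n))
  n_sur <- n - n_rep
  if (n_sur < 1L)
    stop("replaced_fraction leaves no survivors", call. = FALSE)
  ord <- order(pop$fitness)
  survivors <- pop$sequences[ord[seq_len(n_sur)]]
  surv_fit <- pop$fitness[ord[seq_len(n_sur)]]
  alphabet <- ensemble$shell$alphabet
  gen <- pop$generation + 1L

  Lp <- length(survivors[[1L]]$residues)
  offspring <- vector("list", n_rep)
  for (k in seq_len(n_rep)) {
    id <- sprintf("g%d_o%03d", gen, k)
    use_mutation <- stats::runif(1) < config$mutation_probability ||
      n_sur < 2L || Lp < 2L
    if (use_mutation) {
      parent <- survivors[[sample.int(n_sur, 1L)]]
      offspring[[k]] <- .random_point_mutant(parent, alphabet, id)
    } else {
      pidx <- sample.int(n_sur, 2L)
      p1 <- survivors[[pidx[1L]]]
      p2 <- survivors[[pidx[2L]]]
      cut <- sample.int(Lp - 1L, 1L)
      res <- c(p1$residues[seq_len(cut)], p2$residues[(cut + 1L):Lp])
      offspring[[k]] <- sequence_record(id, res, p1$positions)
    }
  }
  ts <- evaluate_batch(ensemble, offspring, evaluator, workers)
  off_fit <- apply_fitness(ts, fitness)
  p <- .new_population(gen, c(survivors, offspring), c(surv_fit, off_fit))
  p
}

#' Run a multi-state design with the genetic algorithm
#'
#' Seeds a population from `seed_sequence`, evolves it with
#' [ga_generation()] until `generations_max` or energetic convergence, and
#' records a per-generation convergence trace: the best fitness, the
#' best-so-far fitness, and the mean total score and (if a native sequence
#' is supplied) the nsr/nssr of the `top_k` best-scoring sequences.
#'
#' @param ensemble A `state_ensemble`.
#' @param seed_sequence Seed `seq_record` (see [make_seed()]).
#' @param evaluator An evaluator.
#' @param fitness A `fitness_spec` (default: mean over states).
#' @param config A [ga_config()].
#' @param native Optional native `seq_record` for recovery metrics.
#' @param top_k How many top-scoring sequences enter the trace statistics
#'   (default 5).
#' @param matrix Substitution matrix for nssr (default [blosum62()]).
#' @param workers Parallel workers for evaluation.
#' @param record_populations Keep every generation's population (memory
#'   heavy; used by [msd_curves()]).
#' @return A list of class `msd_run` with components `population` (final),
#'   `trace` (data.frame: generation, best_fitness, best_so_far, topk_ts,
#'   topk_nsr, topk_nssr), `best_sequence`, `best_fitness`, `generations`,
#'   `converged`, and optionally `history`.
#' @export
run_msd <- function(ensemble, seed_sequence, evaluator,
                    fitness = fitness_spec("mean"), config = ga_config(),
                    native = NULL, top_k = 5L, matrix = blosum62(),
                    workers = 1L, record_populations = FALSE) {
  stopifnot(inherits(config, "ga_config"))
  if (top_k > config$population_size)
    stop("top_k exceeds the population size", call. = FALSE)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)

  pop <- ga_init(seed_sequence, config, ensemble$shell)
  pop <- ga_evaluate(pop, ensemble, evaluator, fitness, workers)
  history <- if (record_populations) list(pop) else NULL

  trace_row <- function(pop, best_so_far) {
    top <- pop$sequences[seq_len(top_k)]
    data.frame(generation = pop$generation,
               best_fitness = pop$fitness[1L],
               best_so_far = best_so_far,
               topk_ts = mean(pop$fitness[seq_len(top_k)]),
               topk_nsr = if (is.null(native)) NA_real_ else
                 mean(vapply(top, nsr_seq, numeric(1), s2 = native)),
               topk_nssr = if (is.null(native)) NA_real_ else
                 nssr_set(top, native, matrix))
  }

  best_hist <- pop$fitness[1L]
  trace <- trace_row(pop, best_hist)
  converged <- FALSE
  while (pop$generation < config$generations_max) {
    pop <- ga_generation(pop, ensemble, evaluator, fitness, config, workers)
    best_hist <- c(best_hist, pop$fitness[1L])
    trace <- rbind(trace, trace_row(pop, min(best_hist)))
    if (record_populations) history[[length(history) + 1L]] <- pop
    w <- config$convergence_window
    if (is.finite(w) && length(best_hist) > w) {
      improvement <- best_hist[length(best_hist) - w] - best_hist[length(best_hist)]
      if (improvement < config$convergence_tolerance) {
        converged <- TRUE
        break
      }
    }
  }
  rownames(trace) <- NULL
  structure(list(population = pop, trace = trace,
                 best_sequence = pop$sequences[[1L]],
                 best_fitness = pop$fitness[1L],
                 generations = pop$generation,
                 converged = converged,
                 history = history),
            class = "msd_run")
}

#' @export
print.msd_run <- function(x, ...) {
  cat(sprintf("<msd_run> %d generation(s)%s, best fitness %s (%s)\n",
              x$generations, if (x$converged) " (converged)" else "",
              format(x$best_fitness, digits = 6),
              as.character(x$best_sequence)))
  invisible(x)
}
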