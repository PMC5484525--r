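#' Monte-Carlo simulated-annealing configuration
#'
#' Configuration of the single-state design baseline: an annealed
#' Metropolis walk over single-point mutations with a geometric cooling
#' schedule from `t_initial` to `t_final`. This is a generic simulated
#' annealing sequence optimizer, not a rotamer-level packer; it plays the
#' role the single-state Monte-Carlo protocol plays in the benchmark
#' comparisons.
#'
#' @param steps Number of proposal steps (>= 1, default 10000).
#' @param t_initial Initial temperature in score units (default 2).
#' @param t_final Final temperature (default 0.02). A zero temperature
#'   degenerates to accepting only non-worsening proposals.
#' @param rng_seed Optional integer seed.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(steps = 10000L, t_initial = 2, t_final = 0.02,
                      rng_seed = NULL) {
  stopifnot(steps >= 1L, t_initial >= 0, t_final >= 0,
            t_final <= t_initial)
  structure(list(steps = as.integer(steps), t_initial = t_initial,
                 t_final = t_final, rng_seed = rng_seed),
            class = "mc_config")
}

#' Run a single-state design with simulated annealing
#'
#' Metropolis acceptance on single-point mutation proposals: a proposal
#' with score difference `d` is accepted if `d <= 0` or with probability
#' `exp(-d / T)` under the current temperature `T` of a geometric cooling
#' schedule. Returns the best sequence visited over the whole walk (not the
#' last one).
#'
#' @param state A single `design_state`.
#' @param seed_sequence Starting `seq_record`.
#' @param evaluator An evaluator scoring `state`.
#' @param config An [mc_config()].
#' @param shell The `design_shell` providing the mutation alphabet.
#' @return A list of class `ssd_run` with `best_sequence`, `best_score`,
#'   `trace` (data.frame: step, score, best_so_far) and `accepted` (count).
#' @export
run_ssd_mc <- function(state, seed_sequence, evaluator, config, shell) {
  stopifnot(inherits(state, "design_state"), inherits(config, "mc_config"),
            inherits(shell, "design_shell"))
  if (!identical(seed_sequence$positions, shell$design_positions))
    stop("seed sequence is not aligned to the shell", call. = FALSE)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)

  temp_at <- function(k) {
    if (config$steps == 1L) return(config$t_initial)
    if (config$t_initial == 0) return(0)
    r <- max(config$t_final, .Machine$double.xmin) / config$t_initial
    config$t_initial * r^((k - 1) / (config$steps - 1))
  }

  current <- seed_sequence
  cur_score <- score_sequence(evaluator, state, current)
  if (!is.finite(cur_score))
    stop("evaluator returned a non-finite score for the seed", call. = FALSE)
  best <- current
  best_score <- cur_score
  accepted <- 0L
  score_trace <- numeric(config$steps)
  best_trace <- numeric(config$steps)

  for (k in seq_len(config$steps)) {
    prop <- .random_point_mutant(current, shell$alphabet,
                                 sprintf("mc_step%05d", k))
    prop_score <- score_sequence(evaluator, state, prop)
    d <- prop_score - cur_score
    accept <- d <= 0
    if (!accept) {
      tk <- temp_at(k)
      if (tk > 0) accept <- stats::runif(1) < exp(-d / tk)
    }
    if (accept) {
      current <- prop
      cur_score <- prop_score
      accepted <- accepted + 1L
      if (cur_score < best_score) {
        best <- current
        best_score <- cur_score
      }
    }
    score_trace[k] <- cur_score
    best_trace[k] <- best_score
  }
  best$id <- paste0(state$id, "_ssd_best")
  structure(list(best_sequence = best, best_score = best_score,
                 trace = data.frame(step = seq_len(config$steps),
                                    score = score_trace,
                                    best_so_far = best_trace),
                 accepted = accepted),
            class = "ssd_run")
}

#' @export
print.ssd_run <- function(x, ...) {
  cat(sprintf("<ssd_run> %d step(s), best score %s (%s)\n",
              nrow(x$trace), format(x$best_score, digits = 6),
              as.character(x$best_sequence)))
  invisible(x)
}

#' Select the best of several optimization runs
#'
#' @param run_results Non-empty list, each element a list with components
#'   `sequence` and `score`.
#' @return The element with the minimal score, with its index attached as
#'   `run_index`; ties are broken in favor of the earliest run.
#' @export
best_of_runs <- function(run_results) {
  if (length(run_results) == 0L)
    stop("empty run list", call. = FALSE)
  scores <- vapply(run_results, function(r) r$score, numeric(1))
  i <- which.min(scores)  # earliest index on ties
  out <- run_results[[i]]
  out$run_index <- i
  out
}
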