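#' Score one sequence in one state
#'
#' The evaluator contract: given a state and a sequence, return a single
#' finite total score in energy-like units where lower is better. Scoring
#' must be deterministic — repeated calls with identical inputs return
#' identical values — which is what makes multi-worker evaluation
#' serial-equivalent.
#'
#' @param evaluator An evaluator object (e.g. from
#'   [landscape_evaluator()] or [surrogate_evaluator()]).
#' @param state A `design_state`.
#' @param sequence A `seq_record` aligned to the design shell.
#' @param ... Passed to methods.
#' @return A finite numeric scalar.
#' @export
score_sequence <- function(evaluator, state, sequence, ...) {
  UseMethod("score_sequence")
}

#' @export
score_sequence.default <- function(evaluator, state, sequence, ...) {
  stop("no score_sequence method for class ",
       paste(class(evaluator), collapse = "/"), call. = FALSE)
}

#' Score many sequences in one state
#'
#' Vectorized companion of [score_sequence()]; the default method loops.
#' Evaluators with a cheap batched form (the landscape evaluator) override
#' it.
#'
#' @inheritParams score_sequence
#' @param sequences List of `seq_record` objects.
#' @return Numeric vector, one score per sequence.
#' @export
score_state_batch <- function(evaluator, state, sequences, ...) {
  UseMethod("score_state_batch")
}

#' @export
score_state_batch.default <- function(evaluator, state, sequences, ...) {
  vapply(sequences, function(s) score_sequence(evaluator, state, s, ...),
         numeric(1))
}

#' Evaluate a batch of sequences against every state of an ensemble
#'
#' Produces the n x m score table (states x sequences) that the fitness
#' function consumes. Tasks are ordered (state, sequence) lexicographically
#' and each (state, sequence) score is computed independently, so the result
#' is bit-identical for any worker count.
#'
#' @param ensemble A `state_ensemble`.
#' @param sequences List of `seq_record` objects aligned to the shell.
#' @param evaluator An evaluator implementing [score_sequence()].
#' @param workers Number of parallel worker processes (forked; `1` runs
#'   serially). Parallelism never changes results, only wall time.
#' @return A numeric matrix with state ids as row names and sequence ids as
#'   column names; every cell finite.
#' @export
evaluate_batch <- function(ensemble, sequences, evaluator, workers = 1L) {
  stopifnot(inherits(ensemble, "state_ensemble"), workers >= 1L)
  if (length(sequences) == 0L)
    stop("empty sequence batch", call. = FALSE)
  shell_pos <- ensemble$shell$design_positions
  for (s in sequences) {
    if (!identical(s$positions, shell_pos))
      stop(sprintf("sequence '%s' is not aligned to the ensemble shell", s$id),
           call. = FALSE)
  }
  ids <- state_ids(ensemble)
  one_state <- function(st) {
    sc <- score_state_batch(evaluator, st, sequences)
    if (any(!is.finite(sc)))
      stop(sprintf("evaluator returned a non-finite score for state '%s'",
                   st$id), call. = FALSE)
    sc
  }
  rows <- if (workers > 1L && length(ensemble$states) > 1L) {
    parallel::mclapply(ensemble$states, one_state,
                       mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(ensemble$states, one_state)
  }
  ts <- do.call(rbind, rows)
  dimnames(ts) <- list(ids, vapply(sequences, function(s) s$id, character(1)))
  ts
}

#' Specify how per-state scores combine into a fitness value
#'
#' Two modes are supported. `"mean"` is the multi-state consensus fitness:
#' the arithmetic mean of the per-state total scores. `"pos_neg"` is the
#' positive/negative design fitness
#' `fitness = dscore_plus - w * dscore_minus`, where each `dscore` is the
#' (state-mean) score difference between the candidate and a reference
#' sequence; minimizing it rewards stabilizing the positive states and
#' penalizes stabilizing the negative ones. All fitness values are
#' minimized.
#'
#' @param mode `"mean"` or `"pos_neg"`.
#' @param w Non-negative weight of the negative-design term (`pos_neg`
#'   only). No default is provided deliberately: its scale is
#'   application-specific.
#' @param positive_states,negative_states State id character vectors
#'   (`pos_neg` only); `positive_states` must be non-empty.
#' @param reference_scores Named numeric vector of reference-sequence scores
#'   covering every named state (`pos_neg` only); typically the per-state
#'   scores of the optimal single-state design.
#' @return An object of class `fitness_spec`.
#' @export
fitness_spec <- function(mode = c("mean", "pos_neg"), w = NULL,
                         positive_states = NULL, negative_states = NULL,
                         reference_scores = NULL) {
  mode <- match.arg(mode)
  if (mode == "mean")
    return(structure(list(mode = "mean"), class = "fitness_spec"))
  if (is.null(w) || !is.numeric(w) || length(w) != 1L || w < 0)
    stop("pos_neg fitness requires a single non-negative weight `w`",
         call. = FALSE)
  if (is.null(positive_states) || length(positive_states) == 0L)
    stop("pos_neg fitness requires non-empty `positive_states`", call. = FALSE)
  negative_states <- as.character(negative_states %||% character())
  need <- c(positive_states, negative_states)
  if (is.null(reference_scores) || !all(need %in% names(reference_scores)))
    stop("`reference_scores` must cover all positive and negative states",
         call. = FALSE)
  structure(list(mode = "pos_neg", w = w,
                 positive_states = as.character(positive_states),
                 negative_states = negative_states,
                 reference_scores = reference_scores),
            class = "fitness_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean-over-states fitness of one sequence
#'
#' @param column Numeric vector of per-state total scores (n >= 1, finite).
#' @return Arithmetic mean.
#' @export
fitness_mean <- function(column) {
  if (length(column) == 0L)
    stop("empty score column", call. = FALSE)
  if (any(!is.finite(column)))
    stop("scores must be finite", call. = FALSE)
  mean(column)
}

#' Positive/negative design fitness of one sequence
#'
#' `dscore_plus - w * dscore_minus`, with each side averaged over its states
#' before differencing when it contains more than one state. Lower is
#' better; for the reference sequence itself the value is 0 for any `w`.
#'
#' @param seq_scores Named numeric vector of per-state scores for the
#'   candidate sequence, covering all states named in `spec`.
#' @param spec A `fitness_spec` with `mode = "pos_neg"`.
#' @return Numeric scalar.
#' @export
fitness_pos_neg <- function(seq_scores, spec) {
  stopifnot(inherits(spec, "fitness_spec"))
  if (spec$mode != "pos_neg")
    stop("spec is not a pos_neg fitness specification", call. = FALSE)
  need <- c(spec$positive_states, spec$negative_states)
  if (!all(need %in% names(seq_scores)))
    stop("seq_scores must cover all positive and negative states",
         call. = FALSE)
  dpos <- fitness_mean(seq_scores[spec$positive_states] -
                         spec$reference_scores[spec$positive_states])
  dneg <- if (length(spec$negative_states))
    fitness_mean(seq_scores[spec$negative_states] -
                   spec$reference_scores[spec$negative_states])
  else 0
  unname(dpos - spec$w * dneg)
}

#' Apply a fitness specification to a score table
#'
#' @param score_table Numeric matrix from [evaluate_batch()] (states x
#'   sequences).
#' @param spec A `fitness_spec`.
#' @return Named numeric vector of fitness values, one per sequence column.
#' @export
apply_fitness <- function(score_table, spec = fitness_spec("mean")) {
  stopifnot(is.matrix(score_table), inherits(spec, "fitness_spec"))
  if (spec$mode == "mean")
    return(colMeans(score_table))
  apply(score_table, 2L, fitness_pos_neg, spec = spec)
}
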