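# Synthetic multi-state sequence-energy landscapes.
#
# Each state l assigns a sequence the additive energy
#   score_l(seq) = sum_i h_l(i, aa_i) + sum_{(i,j) in couplings} J(i,j,aa_i,aa_j)
# (lower is better). A "native" sequence is planted as the exact optimum of
# the MEAN score across states, while individual states are perturbed so
# their own optima drift away from it as `divergence` grows. This emulates
# an ensemble of unrelated near-native conformations: single-state design
# customizes to one state's quirks, multi-state design recovers the
# consensus.

# Default design alphabet prefix: always contains alanine (so all-alanine
# seeding works) and BLOSUM62-similar pairs (A/S, D/E, I/L/V) so that nssr
# is informative on reduced alphabets.
.alphabet_prefix <- c("A", "S", "D", "E", "L", "K", "F", "G", "T", "V",
                      "N", "I", "R", "W", "Y", "M", "H", "C", "Q", "P")

#' Generate a multi-state synthetic landscape with a planted native optimum
#'
#' Draws a base additive table in which the planted native residue is lower
#' than every alternative by `margin` at each position, then derives each
#' state by adding zero-mean Gaussian noise of scale `divergence` to every
#' table entry. The per-entry noise is recentered so that it sums to zero
#' across states: the mean score table therefore equals the base table
#' exactly and the planted native is the exact brute-force optimum of the
#' mean score by construction, for every divergence. With couplings enabled
#' the guarantee is re-established by enumeration and recentering of the
#' native entries.
#'
#' @param L Number of design positions (>= 1).
#' @param A Alphabet size (2..20); the alphabet is a fixed subset of the 20
#'   standard codes unless `alphabet` is given.
#' @param n_states Number of states in the ensemble (>= 1).
#' @param divergence Standard deviation of the per-state perturbation, in
#'   score units; 0 makes all states identical.
#' @param coupling_density Probability that a position pair carries a
#'   pairwise coupling table (default 0: purely additive, so closed-form
#'   per-position optima exist).
#' @param rng_seed Integer seed; the generator is fully deterministic given
#'   it.
#' @param alphabet Optional explicit residue subset (overrides `A`).
#' @param margin Per-position score advantage of the native residue in the
#'   base table (score units, default 1).
#' @param base_sd Standard deviation of the base table entries (default 1).
#' @param coupling_sd Standard deviation of coupling entries (default 0.3).
#' @param max_attempts Recentering attempts for the coupled case before
#'   giving up.
#' @param id Landscape identifier.
#' @return A list with components `landscape` (a `synthetic_landscape`) and
#'   `ensemble` (the corresponding `state_ensemble` of landscape states).
#' @export
#' @examples
#' gen <- generate_landscape_ensemble(L = 4, A = 3, n_states = 3,
#'                                    divergence = 1, rng_seed = 1)
#' gen$landscape$planted_native
generate_landscape_ensemble <- function(L, A = 5, n_states,
                                        divergence = 1,
                                        coupling_density = 0,
                                        rng_seed = 1L,
                                        alphabet = NULL,
                                        margin = 1,
                                        base_sd = 1,
                                        coupling_sd = 0.3,
                                        max_attempts = 20L,
                                        id = "synthetic") {
  if (is.null(alphabet)) {
    if (A < 2L || A > 20L) stop("A must be in 2..20", call. = FALSE)
    alphabet <- .alphabet_prefix[seq_len(A)]
  }
  alphabet <- sort(unique(alphabet))
  .check_residues(alphabet, "alphabet")
  A <- length(alphabet)
  stopifnot(L >= 1L, n_states >= 1L, divergence >= 0, margin > 0)

  rng <- .local_rng(rng_seed)
  positions <- paste0("A:", seq_len(L))
  native_res <- alphabet[rng(function() sample.int(A, L, replace = TRUE))]
  native <- sequence_record(paste0(id, "_native"), native_res, positions)

  h0 <- matrix(rng(function() stats::rnorm(L * A, sd = base_sd)), L, A,
               dimnames = list(positions, alphabet))
  nat_idx <- match(native_res, alphabet)
  for (i in seq_len(L)) {
    others <- h0[i, -nat_idx[i]]
    h0[i, nat_idx[i]] <- min(others) - margin
  }

  # per-entry noise, recentered to zero mean across states
  noise <- array(rng(function() stats::rnorm(L * A * n_states, sd = divergence)),
                 dim = c(L, A, n_states))
  if (n_states > 1L) {
    noise <- sweep(noise, c(1, 2), apply(noise, c(1, 2), mean))
  } else {
    noise[] <- 0
  }
  ids <- sprintf("%s_s%02d", id, seq_len(n_states))
  h <- lapply(seq_len(n_states), function(l) {
    m <- h0 + noise[, , l]
    dimnames(m) <- list(positions, alphabet)
    m
  })
  names(h) <- ids

  couplings <- list()
  if (coupling_density > 0 && L >= 2L) {
    for (i in seq_len(L - 1L)) for (j in seq(i + 1L, L)) {
      if (rng(function() stats::runif(1)) < coupling_density) {
        J <- matrix(rng(function() stats::rnorm(A * A, sd = coupling_sd)),
                    A, A, dimnames = list(alphabet, alphabet))
        couplings[[length(couplings) + 1L]] <- list(i = i, j = j, J = J)
      }
    }
  }

  land <- structure(list(id = id, L = L, alphabet = alphabet,
                         positions = positions, margin = margin,
                         divergence = divergence,
                         coupling_density = coupling_density,
                         rng_seed = rng_seed,
                         planted_native = native,
                         h = h, couplings = couplings),
                    class = "synthetic_landscape")

  if (length(couplings)) {
    land <- .recenter_coupled(land, max_attempts)
  }

  list(landscape = land, ensemble = landscape_ensemble(land))
}

# Run random draws in an isolated RNG stream so landscape generation never
# perturbs (or is perturbed by) the caller's RNG state.
.local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  function(draw) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- draw()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
}

# With couplings, the additive margin no longer guarantees mean-optimality;
# enumerate, and if a sequence beats the planted native, lower the native
# additive entries uniformly (identically in every state, preserving the
# centered noise) until the native is strictly optimal.
.recenter_coupled <- function(land, max_attempts) {
  if (length(land$alphabet)^land$L > 1e6)
    stop("coupled landscapes must be enumerable (A^L <= 1e6) to certify ",
         "the planted optimum", call. = FALSE)
  nat_idx <- match(land$planted_native$residues, land$alphabet)
  for (attempt in seq_len(max_attempts)) {
    opt <- brute_force_optimum(land)
    f_nat <- landscape_mean_score(land, land$planted_native)
    gap <- f_nat - opt$fitness
    if (gap <= 0 && opt$sequence == land$planted_native)
      return(land)
    delta <- (gap + land$margin / 2) / land$L
    for (l in seq_along(land$h))
      land$h[[l]][cbind(seq_len(land$L), nat_idx)] <-
        land$h[[l]][cbind(seq_len(land$L), nat_idx)] - delta
    land
  }
  opt <- brute_force_optimum(land)
  if (opt$sequence == land$planted_native) return(land)
  stop("could not certify the planted native after ", max_attempts,
       " recentering attempts; reduce divergence or coupling_density",
       call. = FALSE)
}

#' Score a sequence in one landscape state
#'
#' @param landscape A `synthetic_landscape`.
#' @param state_id State identifier (one of `names(landscape$h)`).
#' @param sequence A `seq_record` over the landscape positions and alphabet.
#' @return Numeric score (additive table plus coupling terms).
#' @export
landscape_score <- function(landscape, state_id, sequence) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  if (!state_id %in% names(landscape$h))
    stop("unknown landscape state: ", state_id, call. = FALSE)
  idx <- .landscape_res_idx(landscape, sequence)
  h <- landscape$h[[state_id]]
  s <- sum(h[cbind(seq_len(landscape$L), idx)])
  for (cp in landscape$couplings)
    s <- s + cp$J[idx[cp$i], idx[cp$j]]
  s
}

.landscape_res_idx <- function(landscape, sequence) {
  stopifnot(inherits(sequence, "seq_record"))
  if (length(sequence$residues) != landscape$L)
    stop("sequence length does not match the landscape", call. = FALSE)
  idx <- match(sequence$residues, landscape$alphabet)
  if (anyNA(idx))
    stop("invalid residue(s) for this landscape alphabet: ",
         paste(unique(sequence$residues[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  idx
}

#' Mean-over-states score of a sequence on a landscape
#'
#' @inheritParams landscape_score
#' @return Mean of [landscape_score()] over all states.
#' @export
landscape_mean_score <- function(landscape, sequence) {
  mean(vapply(names(landscape$h), landscape_score, numeric(1),
              landscape = landscape, sequence = sequence))
}

# Vectorized scoring of an index matrix (m sequences x L positions) in one
# state; used by the batch evaluator and the brute-force oracle.
.landscape_score_idx <- function(landscape, state_id, IDX) {
  h <- landscape$h[[state_id]]
  L <- landscape$L
  lin <- sweep((IDX - 1L) * L, 2L, seq_len(L), `+`)
  # index with a plain vector: a two-column index matrix would otherwise be
  # taken as (row, col) pairs
  s <- rowSums(matrix(h[as.vector(lin)], nrow(lin), ncol(lin)))
  for (cp in landscape$couplings)
    s <- s + cp$J[cbind(IDX[, cp$i], IDX[, cp$j])]
  s
}

#' Build the state ensemble of a synthetic landscape
#'
#' @param landscape A `synthetic_landscape`.
#' @return A `state_ensemble` whose shell spans the landscape positions,
#'   carries the planted native and restricts the alphabet to the
#'   landscape's.
#' @export
landscape_ensemble <- function(landscape) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  shell <- design_shell(landscape$positions,
                        native_sequence = landscape$planted_native,
                        alphabet = landscape$alphabet)
  states <- lapply(names(landscape$h), design_state, kind = "landscape")
  state_ensemble(landscape$id, states, shell)
}

#' Landscape evaluator
#'
#' Wraps a `synthetic_landscape` as an evaluator: landscape states are
#' scored by direct table lookup, with a vectorized batch path.
#'
#' @param landscape A `synthetic_landscape`.
#' @return An evaluator object of class `landscape_evaluator`.
#' @export
landscape_evaluator <- function(landscape) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  structure(list(landscape = landscape),
            class = c("landscape_evaluator", "msd_evaluator"))
}

#' @export
score_sequence.landscape_evaluator <- function(evaluator, state, sequence, ...) {
  landscape_score(evaluator$landscape, state$payload, sequence)
}

#' @export
score_state_batch.landscape_evaluator <- function(evaluator, state, sequences, ...) {
  land <- evaluator$landscape
  IDX <- t(vapply(sequences, .landscape_res_idx, integer(land$L),
                  landscape = land))
  if (land$L == 1L) IDX <- matrix(IDX, ncol = 1L)
  .landscape_score_idx(land, state$payload, IDX)
}

#' Brute-force optimum of a landscape under a fitness specification
#'
#' Exhaustively enumerates all `A^L` sequences and returns the fitness
#' minimizer; ties are broken lexicographically (alphabet order, leftmost
#' position most significant). This is the test oracle against which the
#' genetic algorithm is validated.
#'
#' @param landscape A `synthetic_landscape`.
#' @param fitness A `fitness_spec` (default mean over all states).
#' @param enumeration_bound Refuse to enumerate more than this many
#'   sequences (default 1e6).
#' @return A list with `sequence` (a `seq_record`), `fitness` (its value)
#'   and `n_enumerated`.
#' @export
brute_force_optimum <- function(landscape, fitness = fitness_spec("mean"),
                                enumeration_bound = 1e6) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  A <- length(landscape$alphabet)
  L <- landscape$L
  n_seq <- A^L
  if (n_seq > enumeration_bound)
    stop(sprintf("enumeration of %.0f sequences exceeds the bound %.0f",
                 n_seq, enumeration_bound), call. = FALSE)
  # lexicographic order: position 1 most significant
  grid <- do.call(expand.grid, rep(list(seq_len(A)), L))
  IDX <- as.matrix(grid)[, rev(seq_len(L)), drop = FALSE]
  colnames(IDX) <- NULL
  ts <- vapply(names(landscape$h),
               function(sid) .landscape_score_idx(landscape, sid, IDX),
               numeric(nrow(IDX)))
  ts <- t(ts)  # states x sequences
  fit <- apply_fitness(ts, fitness)
  best <- which.min(fit)
  seq <- sequence_record("brute_force_optimum",
                         landscape$alphabet[IDX[best, ]],
                         landscape$positions)
  list(sequence = seq, fitness = unname(fit[best]), n_enumerated = n_seq)
}
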