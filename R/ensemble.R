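#' Create a design state
#'
#' A state is one conformational (or chemical) entity scored independently
#' for each candidate sequence: either a structure file on disk or one state
#' of a synthetic sequence-energy landscape.
#'
#' @param id Unique text label within an ensemble.
#' @param kind `"structure"` or `"landscape"`.
#' @param payload Path to a PDB file (structure states) or a landscape state
#'   identifier (landscape states).
#' @return An object of class `design_state`.
#' @export
design_state <- function(id, kind = c("structure", "landscape"), payload = id) {
  kind <- match.arg(kind)
  structure(list(id = as.character(id), kind = kind,
                 payload = payload),
            class = "design_state")
}

#' Create a design/repack shell
#'
#' The design shell is the set of positions whose amino-acid identity the
#' optimizer may change; the repack shell holds positions that are
#' conformationally adjustable but sequence-fixed. The two sets are
#' disjoint. The shell optionally restricts the design alphabet (used by
#' synthetic landscapes over reduced alphabets).
#'
#' @param design_positions Character vector of unique `"chain:resno"` labels.
#' @param repack_positions Character vector, disjoint from
#'   `design_positions`.
#' @param native_sequence Optional `seq_record` over exactly the design
#'   positions.
#' @param alphabet Allowed design residues; defaults to the 20 standard
#'   codes.
#' @return An object of class `design_shell`.
#' @export
design_shell <- function(design_positions, repack_positions = character(),
                         native_sequence = NULL, alphabet = aa_alphabet()) {
  design_positions <- as.character(design_positions)
  repack_positions <- as.character(repack_positions)
  if (length(design_positions) == 0L)
    stop("a shell needs at least one design position", call. = FALSE)
  if (anyDuplicated(design_positions) || anyDuplicated(repack_positions))
    stop("shell positions must be unique", call. = FALSE)
  if (length(intersect(design_positions, repack_positions)))
    stop("design and repack positions must be disjoint", call. = FALSE)
  .check_residues(alphabet, "alphabet")
  if (length(alphabet) < 2L)
    stop("the design alphabet needs at least two residues", call. = FALSE)
  if (!is.null(native_sequence)) {
    stopifnot(inherits(native_sequence, "seq_record"))
    if (!identical(native_sequence$positions, design_positions))
      stop("native_sequence positions must equal design_positions",
           call. = FALSE)
  }
  structure(list(design_positions = design_positions,
                 repack_positions = repack_positions,
                 native_sequence = native_sequence,
                 alphabet = sort(unique(alphabet))),
            class = "design_shell")
}

#' Assemble an ensemble of states
#'
#' @param id Text label.
#' @param states List of `design_state` objects with unique ids (n >= 1).
#' @param shell The `design_shell` shared by all states.
#' @return An object of class `state_ensemble`.
#' @export
state_ensemble <- function(id, states, shell) {
  if (length(states) == 0L)
    stop("an ensemble needs at least one state", call. = FALSE)
  if (!all(vapply(states, inherits, logical(1), "design_state")))
    stop("`states` must be a list of design_state objects", call. = FALSE)
  ids <- vapply(states, function(s) s$id, character(1))
  if (anyDuplicated(ids))
    stop("state ids must be unique within an ensemble", call. = FALSE)
  stopifnot(inherits(shell, "design_shell"))
  structure(list(id = as.character(id), states = states, shell = shell),
            class = "state_ensemble")
}

#' @export
print.state_ensemble <- function(x, ...) {
  cat(sprintf("<state_ensemble %s> %d state(s), %d design position(s)\n",
              x$id, length(x$states), length(x$shell$design_positions)))
  invisible(x)
}

#' State identifiers of an ensemble
#'
#' @param ensemble A `state_ensemble`.
#' @return Character vector of state ids in ensemble order.
#' @export
state_ids <- function(ensemble) {
  vapply(ensemble$states, function(s) s$id, character(1))
}

#' Build a seed sequence for an optimization run
#'
#' Either the native design-shell sequence or an all-alanine sequence over
#' the design positions (the de-novo benchmark convention, which removes
#' native side-chain information before design).
#'
#' @param shell A `design_shell`.
#' @param mode `"native"` or `"all_alanine"`.
#' @return A `seq_record` over the shell's design positions.
#' @export
make_seed <- function(shell, mode = c("native", "all_alanine")) {
  mode <- match.arg(mode)
  stopifnot(inherits(shell, "design_shell"))
  if (mode == "native") {
    if (is.null(shell$native_sequence))
      stop("shell carries no native sequence", call. = FALSE)
    return(shell$native_sequence)
  }
  if (!"A" %in% shell$alphabet)
    stop("all-alanine seeding requires 'A' in the design alphabet",
         call. = FALSE)
  sequence_record("seed_all_ala",
                  rep("A", length(shell$design_positions)),
                  shell$design_positions)
}
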