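#' Create a design sequence record
#'
#' A `seq_record` holds a designed (or native) amino-acid sequence over the
#' design-shell positions: one residue per position, positions identified by
#' `"chain:resno"` reference labels. Sequences produced for the same shell
#' are position-aligned by construction, so no pairwise alignment is ever
#' performed by the metrics.
#'
#' @param id Text label.
#' @param residues Character vector of one-letter codes, or a single string
#'   (e.g. `"AWLK"`).
#' @param positions Character vector of unique residue identifiers of the
#'   same length. Defaults to `"A:1"`, `"A:2"`, ... when omitted.
#'
#' @return An object of class `seq_record`.
#' @export
#' @examples
#' sequence_record("design1", "AWLK")
sequence_record <- function(id, residues, positions = NULL) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- as.character(residues)
  if (length(residues) == 0L)
    stop("a sequence record must contain at least one residue", call. = FALSE)
  .check_residues(residues)
  if (is.null(positions))
    positions <- paste0("A:", seq_along(residues))
  positions <- as.character(positions)
  if (length(positions) != length(residues))
    stop("`positions` and `residues` must have equal length", call. = FALSE)
  if (anyDuplicated(positions))
    stop("positions must be unique", call. = FALSE)
  structure(list(id = as.character(id), residues = residues,
                 positions = positions),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s> %s (%d positions)\n",
              x$id, paste(x$residues, collapse = ""), length(x$residues)))
  invisible(x)
}

#' @export
as.character.seq_record <- function(x, ...) paste(x$residues, collapse = "")

#' @export
length.seq_record <- function(x) length(x$residues)

#' @export
`==.seq_record` <- function(e1, e2) {
  identical(e1$residues, e2$residues) && identical(e1$positions, e2$positions)
}

.check_aligned <- function(s1, s2) {
  if (!inherits(s1, "seq_record") || !inherits(s2, "seq_record"))
    stop("expected seq_record objects", call. = FALSE)
  if (length(s1$residues) != length(s2$residues) ||
      !identical(s1$positions, s2$positions))
    stop(sprintf("sequences '%s' and '%s' are not position-aligned",
                 s1$id, s2$id), call. = FALSE)
  invisible(TRUE)
}

#' Point-mutate a sequence record
#'
#' Returns a copy of `seq` whose residue at position index `at` is replaced
#' with `to`. Used by the GA and the simulated-annealing baseline.
#'
#' @param seq A `seq_record`.
#' @param at Position index (1-based).
#' @param to Replacement one-letter code.
#' @param id Optional new id for the mutant.
#' @return A `seq_record` at Hamming distance `as.integer(to != seq$residues[at])`
#'   from `seq`.
#' @export
mutate_residue <- function(seq, at, to, id = seq$id) {
  stopifnot(inherits(seq, "seq_record"))
  if (at < 1L || at > length(seq$residues))
    stop("mutation index out of range", call. = FALSE)
  .check_residues(to)
  res <- seq$residues
  res[at] <- to
  sequence_record(id, res, seq$positions)
}

#' Hamming distance between two aligned sequence records
#'
#' @param s1,s2 Position-aligned `seq_record` objects.
#' @return Integer count of differing positions.
#' @export
hamming <- function(s1, s2) {
  .check_aligned(s1, s2)
  sum(s1$residues != s2$residues)
}
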