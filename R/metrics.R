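#' Residue-pair similarity indicator
#'
#' Two residues count as similar iff their substitution-matrix score is
#' strictly positive (BLOSUM62 by default). This is the per-pair building
#' block of the native sequence similarity recovery (nssr).
#'
#' @param a,b One-letter residue codes.
#' @param matrix A `subst_matrix`; defaults to [blosum62()].
#' @return `1L` if similar, else `0L`.
#' @export
#' @examples
#' nssr_pair("E", "K")  # BLOSUM62(E,K) = 1 > 0 -> 1
#' nssr_pair("W", "G")  # BLOSUM62(W,G) = -2   -> 0
nssr_pair <- function(a, b, matrix = blosum62()) {
  .check_residues(c(a, b))
  as.integer(matrix$scores[a, b] > 0)
}

#' Native sequence similarity recovery between two aligned sequences
#'
#' Mean of the per-position similarity indicators: the fraction of positions
#' at which the two residues have a positive substitution score.
#'
#' @param s1,s2 Position-aligned `seq_record` objects.
#' @param matrix A `subst_matrix`; defaults to [blosum62()].
#' @return Fraction in \[0, 1\].
#' @export
nssr_seq <- function(s1, s2, matrix = blosum62()) {
  .check_aligned(s1, s2)
  mean(matrix$scores[cbind(s1$residues, s2$residues)] > 0)
}

#' Native sequence recovery between two aligned sequences
#'
#' Fraction of positions with identical residues. Since every diagonal
#' substitution score is positive, `nsr_seq(s1, s2) <= nssr_seq(s1, s2)`
#' always holds.
#'
#' @inheritParams nssr_seq
#' @return Fraction in \[0, 1\].
#' @export
nsr_seq <- function(s1, s2) {
  .check_aligned(s1, s2)
  mean(s1$residues == s2$residues)
}

#' Similarity recovery of a set of designs against a native sequence
#'
#' Arithmetic mean of `nssr_seq(design, native)` over the design set.
#'
#' @param designs Non-empty list of `seq_record` objects aligned to `native`.
#' @param native The native `seq_record`.
#' @param matrix A `subst_matrix`; defaults to [blosum62()].
#' @return Fraction in \[0, 1\].
#' @export
nssr_set <- function(designs, native, matrix = blosum62()) {
  if (length(designs) == 0L)
    stop("empty design set", call. = FALSE)
  mean(vapply(designs, nssr_seq, numeric(1), s2 = native, matrix = matrix))
}

#' Per-amino-acid similarity recovery profile
#'
#' For each amino acid type, the fraction of (design, position) pairs whose
#' native residue is that type and whose designed residue is similar to it
#' (positive substitution score). Amino acids absent from the native
#' sequence get `NA` (undefined denominator).
#'
#' Weighted by the native residue counts, the profile reproduces
#' `nssr_set(designs, native)` exactly.
#'
#' @inheritParams nssr_set
#' @return Named numeric vector over the 20 standard codes, with `n_native`
#'   (native position counts) attached as an attribute.
#' @export
residue_recovery_profile <- function(designs, native, matrix = blosum62()) {
  if (length(designs) == 0L)
    stop("empty design set", call. = FALSE)
  for (d in designs) .check_aligned(d, native)
  nat <- native$residues
  sim_counts <- stats::setNames(numeric(20), AA20)
  tot_counts <- stats::setNames(numeric(20), AA20)
  for (d in designs) {
    sim <- matrix$scores[cbind(nat, d$residues)] > 0
    t_sim <- tapply(sim, factor(nat, levels = AA20), sum)
    t_tot <- table(factor(nat, levels = AA20))
    sim_counts <- sim_counts + ifelse(is.na(t_sim), 0, t_sim)
    tot_counts <- tot_counts + as.numeric(t_tot)
  }
  prof <- ifelse(tot_counts > 0, sim_counts / tot_counts, NA_real_)
  names(prof) <- AA20
  attr(prof, "n_native") <- tot_counts
  prof
}

#' Tabulate recovery metrics for a design population
#'
#' @param designs List of `seq_record` objects aligned to `native`.
#' @param native The native `seq_record`.
#' @param matrix A `subst_matrix`; defaults to [blosum62()].
#' @return A data.frame with columns `design_id`, `nsr`, `nssr` (fractions).
#' @export
recovery_table <- function(designs, native, matrix = blosum62()) {
  if (length(designs) == 0L)
    stop("empty design set", call. = FALSE)
  data.frame(
    design_id = vapply(designs, function(d) d$id, character(1)),
    nsr = vapply(designs, nsr_seq, numeric(1), s2 = native),
    nssr = vapply(designs, nssr_seq, numeric(1), s2 = native, matrix = matrix),
    stringsAsFactors = FALSE
  )
}
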