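#' The 20 standard one-letter amino-acid codes
#'
#' Alphabetical order ("A", "C", ..., "Y"). All sequence containers in the
#' package are restricted to this alphabet; non-standard codes (B, J, O, U,
#' X, Z) are rejected at validation time.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() AA20

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Canonical NCBI BLOSUM62 half-bit scores, rows/cols in the classic
# ARNDCQEGHILKMFPSTWYV order. Kept as a compact text block so the table is
# auditable against the published matrix.
.blosum62_text <- "
A  4 -1 -2 -2  0 -1 -1  0 -2 -1 -1 -1 -1 -2 -1  1  0 -3 -2  0
R -1  5  0 -2 -3  1  0 -2  0 -3 -2  2 -1 -3 -2 -1 -1 -3 -2 -3
N -2  0  6  1 -3  0  0  0  1 -3 -3  0 -2 -3 -2  1  0 -4 -2 -3
D -2 -2  1  6 -3  0  2 -1 -1 -3 -4 -1 -3 -3 -1  0 -1 -4 -3 -3
C  0 -3 -3 -3  9 -3 -4 -3 -3 -1 -1 -3 -1 -2 -3 -1 -1 -2 -2 -1
Q -1  1  0  0 -3  5  2 -2  0 -3 -2  1  0 -3 -1  0 -1 -2 -1 -2
E -1  0  0  2 -4  2  5 -2  0 -3 -3  1 -2 -3 -1  0 -1 -3 -2 -2
G  0 -2  0 -1 -3 -2 -2  6 -2 -4 -4 -2 -3 -3 -2  0 -2 -2 -3 -3
H -2  0  1 -1 -3  0  0 -2  8 -3 -3 -1 -2 -1 -2 -1 -2 -2  2 -3
I -1 -3 -3 -3 -1 -3 -3 -4 -3  4  2 -3  1  0 -3 -2 -1 -3 -1  3
L -1 -2 -3 -4 -1 -2 -3 -4 -3  2  4 -2  2  0 -3 -2 -1 -2 -1  1
K -1  2  0 -1 -3  1  1 -2 -1 -3 -2  5 -1 -3 -1  0 -1 -3 -2 -2
M -1 -1 -2 -3 -1  0 -2 -3 -2  1  2 -1  5  0 -2 -1 -1 -1 -1  1
F -2 -3 -3 -3 -2 -3 -3 -3 -1  0  0 -3  0  6 -4 -2 -2  1  3 -1
P -1 -2 -2 -1 -3 -1 -1 -2 -2 -3 -3 -1 -2 -4  7 -1 -1 -4 -3 -2
S  1 -1  1  0 -1  0  0  0 -1 -2 -2  0 -1 -2 -1  4  1 -3 -2 -2
T  0 -1  0 -1 -1 -1 -1 -2 -2 -1 -1 -1 -1 -2 -1  1  5 -2 -2  0
W -3 -3 -4 -4 -2 -2 -3 -2 -2 -3 -2 -3 -1  1 -4 -3 -2 11  2 -3
Y -2 -2 -2 -3 -2 -1 -2 -3  2 -1 -1 -2 -1  3 -3 -2 -2  2  7 -1
V  0 -3 -3 -3 -1 -2 -2 -3 -3  3  1 -2  1 -1 -2 -2  0 -3 -1  4
"

.parse_blosum62 <- function() {
  lines <- strsplit(trimws(.blosum62_text), "\n")[[1]]
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  aa <- vapply(toks, `[`, character(1), 1L)
  m <- t(vapply(toks, function(x) as.integer(x[-1]), integer(20)))
  dimnames(m) <- list(aa, aa)
  # reorder to the package's alphabetical residue order
  m[AA20, AA20]
}

#' Construct a substitution matrix object
#'
#' @param name Text label for the matrix.
#' @param scores Symmetric 20x20 integer matrix with the 20 standard
#'   one-letter codes as row and column names. All diagonal entries must be
#'   positive so that residue identity always implies similarity.
#'
#' @return An object of class `subst_matrix`.
#' @export
substitution_matrix <- function(name, scores) {
  if (!is.matrix(scores) || !all(dim(scores) == c(20L, 20L)))
    stop("`scores` must be a 20x20 matrix", call. = FALSE)
  if (is.null(dimnames(scores)) ||
      !setequal(rownames(scores), AA20) || !setequal(colnames(scores), AA20))
    stop("`scores` must be named by the 20 standard residue codes",
         call. = FALSE)
  scores <- scores[AA20, AA20]
  if (!isTRUE(all.equal(scores, t(scores))))
    stop("substitution matrix must be symmetric", call. = FALSE)
  if (any(diag(scores) <= 0))
    stop("all diagonal entries must be > 0", call. = FALSE)
  structure(list(name = name, scores = scores), class = "subst_matrix")
}

#' The BLOSUM62 substitution matrix
#'
#' Canonical NCBI BLOSUM62 table used by the nssr similarity criterion: two
#' residues are "similar" iff their BLOSUM62 score is strictly positive.
#'
#' @return A `subst_matrix` object.
#' @export
#' @examples
#' b62 <- blosum62()
#' b62$scores["E", "K"]  # 1, so E and K count as similar
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- substitution_matrix("BLOSUM62", .parse_blosum62())
    cache
  }
})

#' @export
print.subst_matrix <- function(x, ...) {
  cat("Substitution matrix:", x$name, "(20 x 20)\n")
  print(x$scores)
  invisible(x)
}

.check_residues <- function(res, what = "residue") {
  bad <- setdiff(unique(res), AA20)
  if (length(bad))
    stop(sprintf("invalid %s code(s): %s (only the 20 standard one-letter codes are allowed)",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
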