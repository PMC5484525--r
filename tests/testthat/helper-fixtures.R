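# Shared fixtures: random sequences, tiny hand-written landscapes, toy PDB
# files, and independent oracles used across the test files.

random_seq <- function(len, id = "rnd", alphabet = aa_alphabet(),
                       positions = NULL) {
  sequence_record(id, sample(alphabet, len, replace = TRUE), positions)
}

# A fully hand-specified two-state landscape over alphabet {A, W} with two
# positions; used wherever scores must be checkable by hand.
#   state s1: h = [A: -1, W: 2; A: 0, W: 1]
#   state s2: h = [A:  3, W: 0; A: 1, W: -2]
hand_landscape <- function(couple = FALSE) {
  alphabet <- c("A", "W")
  positions <- c("A:1", "A:2")
  h1 <- matrix(c(-1, 0, 2, 1), 2, 2, dimnames = list(positions, alphabet))
  h2 <- matrix(c(3, 1, 0, -2), 2, 2, dimnames = list(positions, alphabet))
  couplings <- list()
  if (couple) {
    J <- matrix(c(0.5, -1, 2, 0), 2, 2,
                dimnames = list(alphabet, alphabet))
    J <- (J + t(J)) / 2  # hand table need not be symmetric; couplings may be
    couplings <- list(list(i = 1L, j = 2L, J = J))
  }
  structure(list(id = "hand", L = 2L, alphabet = alphabet,
                 positions = positions, margin = 1, divergence = 0,
                 coupling_density = if (couple) 1 else 0, rng_seed = 0L,
                 planted_native = sequence_record("nat", "AA", positions),
                 h = list(s1 = h1, s2 = h2), couplings = couplings),
            class = "synthetic_landscape")
}

# Minimal fixed-width PDB writer for toy structures. Each atom is a list
# or data.frame row with record, name, resn, chain, resno, x, y, z,
# optionally occ and alt.
write_toy_pdb <- function(atoms, path, models = 1L) {
  fmt <- function(i, a, model_shift = 0) {
    sprintf("%-6s%5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$record, i, a$name, a$alt %||alt% " ", a$resn, a$chain, a$resno,
            a$x + model_shift, a$y, a$z, a$occ %||alt% 1, 0,
            substr(trimws(a$name), 1, 1))
  }
  lines <- character()
  for (m in seq_len(models)) {
    if (models > 1L) lines <- c(lines, sprintf("MODEL %8d", m))
    lines <- c(lines, vapply(seq_along(atoms), function(i)
      fmt(i, atoms[[i]], model_shift = (m - 1) * 0.5), character(1)))
    if (models > 1L) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

`%||alt%` <- function(a, b) if (is.null(a)) b else a

toy_atom <- function(record, name, resn, chain, resno, x, y, z,
                     occ = NULL, alt = NULL) {
  list(record = record, name = name, resn = resn, chain = chain,
       resno = resno, x = x, y = y, z = z, occ = occ, alt = alt)
}

# Exact two-sided signed-rank null by full enumeration of sign vectors;
# independent of stats::wilcox.test. Assumes distinct non-zero |d|.
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vs >= v_obs), mean(vs <= v_obs)))
}

# The full synthetic benchmark comparison is expensive; run it once and
# share the result between the acceptance blocks that examine it.
.bench_cache <- new.env()

benchmark_fixture <- function() {
  if (is.null(.bench_cache$result)) {
    design <- synthetic_benchmark(n_proteins = 16L, n_conf = 20L,
                                  n_ens = 4L, L = 6L, A = 5L,
                                  divergence = 1, rng_seed = 20260930L)
    .bench_cache$design <- design
    .bench_cache$result <- run_synthetic_benchmark(design, rng_seed = 101L)
  }
  list(design = .bench_cache$design, result = .bench_cache$result)
}
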