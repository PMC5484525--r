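# Evaluator contract, batch evaluation, and fitness functions.

test_that("fitness_mean is the arithmetic mean of per-state scores", {
  expect_equal(fitness_mean(c(2, 4)), 3)
  expect_equal(fitness_mean(-7.5), -7.5)
  expect_equal(fitness_mean(c(-1, 0, 1)), 0)
  expect_error(fitness_mean(numeric(0)), "empty")
  expect_error(fitness_mean(c(1, NA)), "finite")
  col <- rnorm(7)
  expect_true(fitness_mean(col) >= min(col) && fitness_mean(col) <= max(col))
})

test_that("pos/neg fitness differences behave as specified", {
  spec <- fitness_spec("pos_neg", w = 1, positive_states = "p",
                       negative_states = "n",
                       reference_scores = c(p = 0, n = 0))
  expect_equal(fitness_pos_neg(c(p = -5, n = -2), spec), -3)
  # w = 0 reduces to the positive-side difference
  spec0 <- fitness_spec("pos_neg", w = 0, positive_states = "p",
                        negative_states = "n",
                        reference_scores = c(p = 1, n = 9))
  expect_equal(fitness_pos_neg(c(p = -5, n = 123), spec0), -6)
  # the reference sequence itself scores 0 for any w
  for (w in c(0, 0.5, 3)) {
    sp <- fitness_spec("pos_neg", w = w, positive_states = "p",
                       negative_states = "n",
                       reference_scores = c(p = 2.5, n = -1))
    expect_equal(fitness_pos_neg(c(p = 2.5, n = -1), sp), 0)
  }
  # multi-state sides are averaged before differencing
  spm <- fitness_spec("pos_neg", w = 2, positive_states = c("p1", "p2"),
                      negative_states = "n",
                      reference_scores = c(p1 = 0, p2 = 0, n = 0))
  expect_equal(fitness_pos_neg(c(p1 = -2, p2 = -4, n = -1), spm),
               -3 - 2 * (-1))
})

test_that("pos/neg fitness slope in the negative term equals w", {
  w <- 1.7
  sp <- fitness_spec("pos_neg", w = w, positive_states = "p",
                     negative_states = "n",
                     reference_scores = c(p = 0, n = 0))
  base <- fitness_pos_neg(c(p = -1, n = 0), sp)
  # improving (lowering) the negative-state score raises the fitness by w per unit
  expect_equal(fitness_pos_neg(c(p = -1, n = -1), sp) - base, w)
  # improving the positive-state score lowers the fitness one-for-one
  expect_equal(fitness_pos_neg(c(p = -2, n = 0), sp) - base, -1)
})

test_that("fitness_spec validates its configuration", {
  expect_error(fitness_spec("pos_neg", w = -1, positive_states = "p",
                            reference_scores = c(p = 0)), "non-negative")
  expect_error(fitness_spec("pos_neg", w = 1, positive_states = character(),
                            reference_scores = c(p = 0)), "positive_states")
  expect_error(fitness_spec("pos_neg", w = 1, positive_states = "p",
                            negative_states = "n",
                            reference_scores = c(p = 0)), "cover")
  sp <- fitness_spec("pos_neg", w = 1, positive_states = "p",
                     reference_scores = c(p = 0))
  expect_error(fitness_pos_neg(c(q = 1), sp), "cover")
})

test_that("evaluate_batch has the (states x sequences) shape and exact values", {
  land <- hand_landscape()
  ens <- landscape_ensemble(land)
  ev <- landscape_evaluator(land)
  seqs <- list(sequence_record("aa", "AA", land$positions),
               sequence_record("aw", "AW", land$positions),
               sequence_record("wa", "WA", land$positions),
               sequence_record("ww", "WW", land$positions))
  ts <- evaluate_batch(ens, seqs, ev)
  expect_equal(dim(ts), c(2L, 4L))
  expect_equal(rownames(ts), c("s1", "s2"))
  expect_equal(colnames(ts), c("aa", "aw", "wa", "ww"))
  # hand-summed additive energies
  expect_equal(unname(ts["s1", ]), c(-1, 0, 2, 3))
  expect_equal(unname(ts["s2", ]), c(4, 1, 1, -2))
  # per-cell lookup oracle: batch equals state-by-state, sequence-by-sequence scoring
  for (st in ens$states)
    for (s in seqs)
      expect_identical(ts[st$id, s$id], score_sequence(ev, st, s))
})

test_that("batch evaluation is serial-equivalent and concatenation-consistent", {
  gen <- generate_landscape_ensemble(L = 5, A = 4, n_states = 3,
                                     divergence = 0.8, rng_seed = 12)
  ens <- gen$ensemble
  ev <- landscape_evaluator(gen$landscape)
  set.seed(5)
  seqs <- lapply(1:7, function(i)
    random_seq(5, paste0("s", i), gen$landscape$alphabet,
               gen$landscape$positions))
  t1 <- evaluate_batch(ens, seqs, ev, workers = 1L)
  t4 <- evaluate_batch(ens, seqs, ev, workers = 4L)
  expect_identical(t1, t4)
  ta <- evaluate_batch(ens, seqs[1:3], ev)
  tb <- evaluate_batch(ens, seqs[4:7], ev)
  expect_identical(cbind(ta, tb), t1)
})

test_that("misaligned sequences are rejected by evaluate_batch", {
  land <- hand_landscape()
  ens <- landscape_ensemble(land)
  ev <- landscape_evaluator(land)
  wrong <- sequence_record("bad", "AA", c("B:1", "B:2"))
  expect_error(evaluate_batch(ens, list(wrong), ev), "not aligned")
})

test_that("apply_fitness maps a score table to per-sequence values", {
  ts <- matrix(c(2, 4, -1, 3), 2, 2,
               dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_equal(apply_fitness(ts, fitness_spec("mean")), c(a = 3, b = 1))
  sp <- fitness_spec("pos_neg", w = 0.5, positive_states = "s1",
                     negative_states = "s2",
                     reference_scores = c(s1 = 1, s2 = 1))
  expect_equal(apply_fitness(ts, sp),
               c(a = (2 - 1) - 0.5 * (4 - 1), b = (-1 - 1) - 0.5 * (3 - 1)))
})

test_that("the contact surrogate reproduces a hand-summed toy score", {
  path <- tempfile(fileext = ".pdb")
  write_toy_pdb(list(
    toy_atom("ATOM", "CA", "ALA", "A", 1, 0, 0, 0),
    toy_atom("ATOM", "CB", "ALA", "A", 1, 1, 0, 0),
    toy_atom("ATOM", "CA", "TRP", "A", 2, 4, 0, 0),
    toy_atom("ATOM", "CB", "TRP", "A", 2, 5, 0, 0),
    toy_atom("ATOM", "CA", "LYS", "A", 3, 20, 0, 0),
    toy_atom("ATOM", "CB", "LYS", "A", 3, 21, 0, 0),
    toy_atom("HETATM", "C1", "LIG", "B", 9, 0.5, 0, 0)), path)
  m <- read_structure(path)
  shell <- design_shell(c("A:1", "A:2", "A:3"))
  pp <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  pp["A", "W"] <- pp["W", "A"] <- -2
  pp["A", "K"] <- pp["K", "A"] <- 5   # pair beyond cutoff: must not count
  bp <- stats::setNames(numeric(20), aa_alphabet())
  bp["K"] <- 0.5
  cs <- contact_surrogate_model(pp, bp, contact_cutoff = 8,
                                neighbor_cutoff = 10)
  ev <- surrogate_evaluator(cs, shell)
  st <- design_state("c1", "structure", path)
  sq <- sequence_record("s", "AWK", shell$design_positions)
  # contacts: (A:1, A:2) CB distance 4 <= 8; A:3 is 20 A away (no pair term)
  # burial: K at A:3 has zero CA neighbors within 10 A -> 0.5 * 0
  expect_equal(score_sequence(ev, st, sq), -2)
  # neighbor-weighted burial: A at A:1 has one CA neighbor (A:2)
  bp2 <- bp; bp2["A"] <- 3
  ev2 <- surrogate_evaluator(contact_surrogate_model(pp, bp2), shell)
  # A:1 and A:2 see each other: 3*1 (A) + 0 (W at A:2) + 0 = 3 extra
  expect_equal(score_sequence(ev2, st, sq), -2 + 3)
  # all-zero potentials score 0 for any sequence
  ev0 <- surrogate_evaluator(contact_surrogate_model(), shell)
  expect_equal(score_sequence(ev0, st, sq), 0)
  # determinism across repeated calls (cached geometry)
  expect_identical(score_sequence(ev, st, sq), score_sequence(ev, st, sq))
})
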