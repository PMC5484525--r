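# Benchmark calculus: curves, summaries, ensemble grouping, signed rank.

test_that("ssd_curves applies the best-so-far selection run by run", {
  nat <- sequence_record("nat", "AW")
  natives <- list(p1 = nat)
  df <- data.frame(protein = "p1", conf = "c1", run = 1:3,
                   sequence = c("GG", "AW", "AG"),
                   ts = c(5, 3, 4), stringsAsFactors = FALSE)
  curve <- ssd_curves(df, natives)
  expect_equal(curve$ts, c(5, 3, 3))
  # the nssr curve uses exactly the selected sequences:
  # GG (0), then AW (1.0) twice
  expect_equal(curve$nssr, c(0, 1, 1))
  expect_equal(curve$nsr, c(0, 1, 1))

  # two conformations with constant scores -> flat mean curve
  df2 <- data.frame(protein = "p1", conf = rep(c("c1", "c2"), each = 2),
                    run = rep(1:2, 2),
                    sequence = "AW", ts = rep(c(2, 8), each = 2),
                    stringsAsFactors = FALSE)
  curve2 <- ssd_curves(df2, natives)
  expect_equal(curve2$ts, c(5, 5))
  # ragged run counts are rejected
  expect_error(ssd_curves(df2[-1, ], natives), "ragged")
})

test_that("msd_curves averages the top-k of each recorded generation", {
  land <- hand_landscape()
  ens <- landscape_ensemble(land)
  ev <- landscape_evaluator(land)
  nat <- land$planted_native
  cfg <- ga_config(population_size = 8, generations_max = 5,
                   convergence_window = Inf, rng_seed = 42)
  run <- run_msd(ens, nat, ev, config = cfg, native = nat, top_k = 2,
                 record_populations = TRUE)
  # k = 1: the per-generation best fitness
  c1 <- msd_curves(run$history, k = 1, native = nat)
  expect_equal(c1$ts, run$trace$best_fitness)
  # k = population size: the whole-population mean
  call <- msd_curves(run$history, k = 8, native = nat)
  expect_equal(call$ts,
               vapply(run$history, function(p) mean(p$fitness), numeric(1)))
  # k = top_k reproduces the trace statistics recorded online
  c2 <- msd_curves(run$history, k = 2, native = nat)
  expect_equal(c2$ts, run$trace$topk_ts)
  expect_equal(c2$nssr, run$trace$topk_nssr)
  # a constant population gives flat curves
  flat <- msd_curves(rep(run$history[1], 3), k = 2, native = nat)
  expect_equal(length(unique(flat$ts)), 1L)
  expect_error(msd_curves(run$history, k = 9), "exceeds")
})

test_that("per_protein_summary averages per unit and appends a grand mean", {
  ssd <- data.frame(protein = rep(c("p1", "p2"), each = 2),
                    nsr = c(0.2, 0.4, 0.6, 0.8),
                    nssr = c(0.3, 0.5, 0.7, 0.9),
                    ts = c(-1, -3, -5, -7))
  msd <- data.frame(protein = c("p1", "p2"),
                    nsr = c(0.5, 0.9), nssr = c(0.6, 1.0), ts = c(-2, -6))
  tab <- per_protein_summary(ssd, msd)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$nsr_ssd, c(0.3, 0.7, 0.5))
  expect_equal(tab$nssr_msd, c(0.6, 1.0, 0.8))
  # grand average equals the mean of the per-protein rows
  expect_equal(tab$ts_ssd[3], mean(tab$ts_ssd[1:2]))
  # metric inequality holds row-wise
  expect_true(all(tab$nsr_ssd <= tab$nssr_ssd))
  # identical designs everywhere collapse to those designs' metrics
  one <- data.frame(protein = "p1", nsr = 0.4, nssr = 0.6, ts = -2)
  tab1 <- per_protein_summary(rbind(one, one), one)
  expect_equal(tab1$nssr_ssd, c(0.6, 0.6))
  expect_error(per_protein_summary(ssd[1:2, ], msd), "different protein sets")
})

test_that("rank_ensembles orders ascending and assembles ES partitions", {
  df <- data.frame(protein = "p1",
                   ensemble = c("e1", "e2", "e3", "e4"),
                   nssr = c(0.30, 0.10, 0.20, 0.40))
  g <- rank_ensembles(df)
  tab <- g$table
  expect_equal(tab$rank[match(c("e2", "e3", "e1", "e4"), tab$ensemble)],
               1:4)
  # two proteins x four ensembles: each ES holds one ensemble per protein
  df2 <- rbind(df, data.frame(protein = "p2",
                              ensemble = paste0("f", 1:4),
                              nssr = c(0.5, 0.2, 0.9, 0.1)))
  g2 <- rank_ensembles(df2)
  for (u in 1:4) {
    sel <- g2$table[g2$table$es == paste0("ES", u), ]
    expect_equal(nrow(sel), 2L)
    expect_setequal(sel$protein, c("p1", "p2"))
  }
  # the ES sets partition all ensembles
  counts <- table(g2$table$es)
  expect_equal(as.vector(counts), rep(2L, 4))
  expect_setequal(names(counts), paste0("ES", 1:4))
  # ties broken by ensemble id
  tied <- data.frame(protein = "p1", ensemble = c("b", "a", "c"),
                     nssr = c(0.5, 0.5, 0.5))
  gt <- rank_ensembles(tied)
  expect_equal(gt$table$rank[match(c("a", "b", "c"), gt$table$ensemble)],
               1:3)
  expect_error(rank_ensembles(df2[-1, ]), "unequal")
})

test_that("ES boxplot statistics match the 1.5 IQR whisker rule", {
  v <- c(1, 2, 3, 4, 100)
  st <- es_group_stats(v, rep("ES1", 5))
  bx <- grDevices::boxplot.stats(v, coef = 1.5)$stats
  expect_equal(st$whisker_lo, bx[1])
  expect_equal(st$q1, unname(stats::quantile(v, 0.25)))
  expect_equal(st$median, bx[3])
  expect_equal(st$whisker_hi, bx[5])  # 100 is an outlier beyond the whisker
})

test_that("paired signed-rank handles exact, degenerate and swapped inputs", {
  # identical samples: degenerate, p = 1
  res <- paired_signed_rank(1:6, 1:6)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  # six strictly improved pairs with distinct margins: exact p = 2/2^6
  a <- c(1.1, 2.3, 3.6, 4.2, 5.9, 7.4)
  b <- c(1.0, 2.0, 3.0, 4.0, 5.0, 7.0)
  res2 <- paired_signed_rank(a, b)
  expect_equal(res2$p_value, 0.03125)
  expect_equal(res2$p_value, signed_rank_exact_p(a - b))  # enumeration oracle
  expect_equal(res2$statistic, 21)
  # swapping the samples keeps p, reflects the statistic
  res3 <- paired_signed_rank(b, a)
  expect_equal(res3$p_value, res2$p_value)
  expect_equal(res3$statistic, 0)
  expect_error(paired_signed_rank(1:3, 2:4), "at least 5")
})

test_that("signed-rank p agrees with full enumeration on random paired data", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (length(d) < 5 || anyDuplicated(abs(d))) next
    p_pkg <- paired_signed_rank(d, rep(0, length(d)))$p_value
    expect_equal(p_pkg, signed_rank_exact_p(d))
  }
})

test_that("make_seed produces native or all-alanine shell sequences", {
  nat <- sequence_record("nat", "WKDLE", paste0("A:", 1:5))
  shell <- design_shell(paste0("A:", 1:5), native_sequence = nat)
  expect_true(make_seed(shell, "native") == nat)
  ala <- make_seed(shell, "all_alanine")
  expect_equal(as.character(ala), "AAAAA")
  expect_equal(ala$positions, shell$design_positions)
  # the alanine baseline has a computable recovery against the native:
  # BLOSUM62(A, x) <= 0 for all of W, K, D, L, E
  expect_equal(nssr_seq(ala, nat), 0)
  nat2 <- sequence_record("nat2", "SAGCT", paste0("A:", 1:5))
  shell_s <- design_shell(paste0("A:", 1:5), native_sequence = nat2)
  # A is similar to S (1), itself (4), and T (0 -> not similar), G (0), C (0)
  expect_equal(nssr_seq(make_seed(shell_s, "all_alanine"), nat2), 0.4)
  shell2 <- design_shell("A:1", alphabet = c("D", "E"))
  expect_error(make_seed(shell2, "all_alanine"), "requires 'A'")
})

test_that("benchmark designs partition conformations exactly", {
  design <- synthetic_benchmark(n_proteins = 2, n_conf = 8, n_ens = 4,
                                L = 3, A = 3, rng_seed = 7)
  for (unit in design$units) {
    sizes <- vapply(unit$partitions, function(e) length(e$states), integer(1))
    expect_true(all(sizes == 2L))
    ids <- unlist(lapply(unit$partitions, state_ids))
    expect_equal(sort(ids), sort(state_ids(landscape_ensemble(unit$landscape))))
    expect_equal(anyDuplicated(ids), 0L)
  }
  expect_error(synthetic_benchmark(n_proteins = 1, n_conf = 10, n_ens = 4),
               "divide")
})
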