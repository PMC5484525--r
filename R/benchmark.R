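# SSD-versus-MSD benchmarking calculus: best-so-far single-state curves,
# generation-wise multi-state top-k curves, per-protein summaries, ensemble
# ranking into ES groups, and the paired signed-rank comparison.

#' Generate a synthetic multi-protein benchmark design
#'
#' Each benchmark unit ("protein") is a synthetic landscape with `n_conf`
#' states (conformations) and a planted native sequence; its conformations
#' are partitioned, in order, into `n_ens` disjoint ensembles of equal
#' size. The default shape mirrors the published benchmark layout: 16
#' proteins, 20 conformations each, divided into four ensembles of five.
#'
#' @param n_proteins Number of benchmark units (default 16).
#' @param n_conf Conformations per protein (default 20).
#' @param n_ens Ensembles per protein (default 4); must divide `n_conf`.
#' @param L,A,divergence,coupling_density Landscape parameters, see
#'   [generate_landscape_ensemble()].
#' @param rng_seed Integer seed; unit seeds are derived from it.
#' @param ... Further arguments to [generate_landscape_ensemble()].
#' @return An object of class `benchmark_design`: a list of units, each
#'   with `id`, `landscape`, `native`, `conformations` (list of
#'   `design_state`), `shell`, and `partitions` (list of `n_ens`
#'   `state_ensemble`s).
#' @export
synthetic_benchmark <- function(n_proteins = 16L, n_conf = 20L, n_ens = 4L,
                                L = 6L, A = 5L, divergence = 1,
                                coupling_density = 0, rng_seed = 1L, ...) {
  stopifnot(n_proteins >= 1L, n_conf >= 1L, n_ens >= 1L)
  if (n_conf %% n_ens != 0L)
    stop("n_ens must divide n_conf exactly (disjoint equal-size partition)",
         call. = FALSE)
  size <- n_conf %/% n_ens
  units <- vector("list", n_proteins)
  for (k in seq_len(n_proteins)) {
    uid <- sprintf("prot%02d", k)
    # per-unit seed derived from the master seed, kept within integer range
    unit_seed <- as.integer((as.numeric(rng_seed) %% 1000003) * 1000 + k)
    gen <- generate_landscape_ensemble(
      L = L, A = A, n_states = n_conf, divergence = divergence,
      coupling_density = coupling_density,
      rng_seed = unit_seed, id = uid, ...)
    full <- gen$ensemble
    partitions <- lapply(seq_len(n_ens), function(m) {
      sel <- seq((m - 1L) * size + 1L, m * size)
      state_ensemble(sprintf("%s_ens%d", uid, m), full$states[sel],
                     full$shell)
    })
    units[[k]] <- list(id = uid, landscape = gen$landscape,
                       native = gen$landscape$planted_native,
                       conformations = full$states,
                       shell = full$shell,
                       partitions = partitions)
  }
  structure(list(units = units,
                 n_proteins = n_proteins, n_conf = n_conf, n_ens = n_ens,
                 rng_seed = rng_seed),
            class = "benchmark_design")
}

#' @export
print.benchmark_design <- function(x, ...) {
  cat(sprintf("<benchmark_design> %d protein(s) x %d conformation(s), %d ensemble(s) each\n",
              x$n_proteins, x$n_conf, x$n_ens))
  invisible(x)
}

#' Best-so-far convergence curves of repeated single-state designs
#'
#' For every number of runs `i`, selects per conformation the best-scoring
#' sequence among runs `1..i` (ties to the earliest run), then averages the
#' total score and the nsr/nssr of those selections across all
#' conformations and proteins. The total-score series is therefore monotone
#' non-increasing in `i`, and the recovery series at `i` is computed from
#' exactly the sequences selected for the score series.
#'
#' @param ssd_results Data frame with columns `protein`, `conf`, `run`,
#'   `sequence` (design-shell residue string) and `ts`; every
#'   (protein, conf) pair must have the same number of runs.
#' @param natives Named list of native `seq_record`s, one per protein.
#' @param matrix Substitution matrix for nssr.
#' @return Data frame with columns `run`, `ts`, `nsr`, `nssr`.
#' @export
ssd_curves <- function(ssd_results, natives, matrix = blosum62()) {
  req <- c("protein", "conf", "run", "sequence", "ts")
  if (!all(req %in% names(ssd_results)))
    stop("ssd_results must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  key <- interaction(ssd_results$protein, ssd_results$conf, drop = TRUE)
  counts <- table(key)
  if (length(unique(counts)) != 1L)
    stop("ragged run counts across conformations", call. = FALSE)
  R <- unname(counts[1])

  groups <- split(ssd_results, key)
  per_group <- lapply(groups, function(g) {
    g <- g[order(g$run), , drop = FALSE]
    nat <- natives[[as.character(g$protein[1])]]
    if (is.null(nat))
      stop("no native sequence for protein ", g$protein[1], call. = FALSE)
    best_idx <- integer(R)
    b <- 1L
    for (i in seq_len(R)) {
      if (g$ts[i] < g$ts[b]) b <- i
      best_idx[i] <- b
    }
    recov <- t(vapply(unique(best_idx), function(i) {
      s <- sequence_record(paste0("run", i), g$sequence[i], nat$positions)
      c(nsr = nsr_seq(s, nat), nssr = nssr_seq(s, nat, matrix))
    }, numeric(2)))
    rownames(recov) <- as.character(unique(best_idx))
    list(ts = g$ts[best_idx],
         nsr = recov[as.character(best_idx), "nsr"],
         nssr = recov[as.character(best_idx), "nssr"])
  })
  data.frame(
    run = seq_len(R),
    ts = rowMeans(vapply(per_group, `[[`, numeric(R), "ts")),
    nsr = rowMeans(vapply(per_group, `[[`, numeric(R), "nsr")),
    nssr = rowMeans(vapply(per_group, `[[`, numeric(R), "nssr"))
  )
}

#' Generation-wise top-k curves of one multi-state design run
#'
#' For each recorded generation, averages the fitness (total score over the
#' ensemble's states) and the nsr/nssr of the `k` top-scoring sequences of
#' the population.
#'
#' @param history List of `ga_population` objects, one per generation (see
#'   `record_populations` in [run_msd()]).
#' @param k Top count; must not exceed the population size (`k` equal to
#'   the population size averages over the whole population).
#' @param native Optional native `seq_record` for recovery columns.
#' @param matrix Substitution matrix for nssr.
#' @return Data frame with columns `generation`, `ts`, `nsr`, `nssr`.
#' @export
msd_curves <- function(history, k, native = NULL, matrix = blosum62()) {
  if (length(history) == 0L)
    stop("empty population history", call. = FALSE)
  rows <- lapply(history, function(pop) {
    stopifnot(inherits(pop, "ga_population"))
    if (k > length(pop$sequences))
      stop("k exceeds the population size", call. = FALSE)
    top <- pop$sequences[seq_len(k)]
    data.frame(generation = pop$generation,
               ts = mean(pop$fitness[seq_len(k)]),
               nsr = if (is.null(native)) NA_real_ else
                 mean(vapply(top, nsr_seq, numeric(1), s2 = native)),
               nssr = if (is.null(native)) NA_real_ else
                 nssr_set(top, native, matrix))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Average several per-generation traces (columns `generation` + values)
# after padding shorter runs by carrying their converged last row forward.
.mean_generation_traces <- function(traces, value_cols) {
  gmax <- max(vapply(traces, nrow, integer(1)))
  padded <- lapply(traces, function(tr) {
    if (nrow(tr) < gmax) {
      last <- tr[rep(nrow(tr), gmax - nrow(tr)), , drop = FALSE]
      tr <- rbind(tr, last)
    }
    tr[seq_len(gmax), value_cols, drop = FALSE]
  })
  out <- Reduce(`+`, padded) / length(padded)
  cbind(data.frame(generation = seq_len(gmax)), out)
}

#' Per-protein performance summary of SSD and MSD designs
#'
#' Mirrors the benchmark summary table: per protein, the single-state
#' values are the final best designs averaged over all conformations, the
#' multi-state values are the top-k final sequences averaged over all
#' ensembles; a grand `Average` row across proteins is appended.
#'
#' @param ssd_final Data frame with columns `protein`, `nsr`, `nssr`, `ts`:
#'   one row per conformation (its final best design).
#' @param msd_final Data frame with the same columns: one row per
#'   (ensemble, top-k sequence).
#' @return Data frame with columns `protein`, `nsr_ssd`, `nsr_msd`,
#'   `nssr_ssd`, `nssr_msd`, `ts_ssd`, `ts_msd`; the last row is the grand
#'   average.
#' @export
per_protein_summary <- function(ssd_final, msd_final) {
  req <- c("protein", "nsr", "nssr", "ts")
  if (!all(req %in% names(ssd_final)) || !all(req %in% names(msd_final)))
    stop("inputs must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  prot <- sort(unique(as.character(ssd_final$protein)))
  if (!setequal(prot, unique(as.character(msd_final$protein))))
    stop("SSD and MSD results cover different protein sets", call. = FALSE)
  agg <- function(df) {
    do.call(rbind, lapply(prot, function(p) {
      sub <- df[df$protein == p, , drop = FALSE]
      data.frame(protein = p, nsr = mean(sub$nsr), nssr = mean(sub$nssr),
                 ts = mean(sub$ts))
    }))
  }
  s <- agg(ssd_final)
  m <- agg(msd_final)
  out <- data.frame(protein = prot,
                    nsr_ssd = s$nsr, nsr_msd = m$nsr,
                    nssr_ssd = s$nssr, nssr_msd = m$nssr,
                    ts_ssd = s$ts, ts_msd = m$ts)
  avg <- data.frame(protein = "Average",
                    nsr_ssd = mean(out$nsr_ssd), nsr_msd = mean(out$nsr_msd),
                    nssr_ssd = mean(out$nssr_ssd),
                    nssr_msd = mean(out$nssr_msd),
                    ts_ssd = mean(out$ts_ssd), ts_msd = mean(out$ts_msd))
  rbind(out, avg)
}

#' Rank each protein's ensembles by recovery and group them across proteins
#'
#' Per protein, ensembles are sorted ascending by their nssr (mean over
#' their top-k final sequences) and assigned ranks `1..n_ens` (ties broken
#' by ensemble id); the set `ES_u` collects the rank-`u` ensemble of every
#' protein, so `ES_1` holds the worst-performing ensemble of each protein
#' and `ES_n` the best. The ES sets partition all ensembles and each
#' contains exactly one ensemble per protein.
#'
#' @param ens_nssr Data frame with columns `protein`, `ensemble`, `nssr`;
#'   every protein must have the same number of ensembles.
#' @return An object of class `ensemble_grouping`: list with `table` (the
#'   input plus `rank` and `es` columns) and `n_ens`.
#' @export
rank_ensembles <- function(ens_nssr) {
  req <- c("protein", "ensemble", "nssr")
  if (!all(req %in% names(ens_nssr)))
    stop("input must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  counts <- table(ens_nssr$protein)
  if (length(unique(counts)) != 1L)
    stop("unequal ensemble counts across proteins", call. = FALSE)
  n_ens <- unname(counts[1])
  parts <- split(ens_nssr, ens_nssr$protein)
  ranked <- lapply(parts, function(g) {
    ord <- order(g$nssr, as.character(g$ensemble))
    g$rank <- integer(nrow(g))
    g$rank[ord] <- seq_len(nrow(g))
    g
  })
  tab <- do.call(rbind, ranked)
  rownames(tab) <- NULL
  tab$es <- paste0("ES", tab$rank)
  structure(list(table = tab, n_ens = n_ens), class = "ensemble_grouping")
}

#' @export
print.ensemble_grouping <- function(x, ...) {
  cat(sprintf("<ensemble_grouping> %d protein(s) x %d rank group(s)\n",
              length(unique(x$table$protein)), x$n_ens))
  invisible(x)
}

#' Boxplot statistics of a metric per ES group
#'
#' Quartiles with whiskers at the lowest and highest datum still within
#' 1.5 interquartile ranges of the box.
#'
#' @param values Numeric values (e.g. nssr, one per ensemble or per
#'   sequence).
#' @param es Parallel character vector of ES labels.
#' @return Data frame with columns `es`, `n`, `whisker_lo`, `q1`, `median`,
#'   `q3`, `whisker_hi`.
#' @export
es_group_stats <- function(values, es) {
  stopifnot(length(values) == length(es))
  groups <- split(values, es)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo <- min(v[v >= q[1] - 1.5 * iqr])
    hi <- max(v[v <= q[3] + 1.5 * iqr])
    data.frame(es = g, n = length(v), whisker_lo = lo, q1 = q[1],
               median = q[2], q3 = q[3], whisker_hi = hi)
  }))
  out[order(out$es), , drop = FALSE]
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped; the exact null distribution is used for up
#' to 25 non-zero untied pairs and the normal approximation above. When all
#' differences are zero the result is flagged degenerate with p = 1.
#'
#' @param values_a,values_b Equal-length paired samples (n >= 5).
#' @return List with `statistic` (V, the positive-rank sum of
#'   `values_a - values_b`), `p_value`, `n_effective` (non-zero pairs) and
#'   `degenerate`.
#' @export
paired_signed_rank <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(values_a) < 5L)
    stop("need at least 5 pairs", call. = FALSE)
  d <- values_a - values_b
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(list(statistic = NA_real_, p_value = 1, n_effective = 0L,
                degenerate = TRUE))
  ht <- suppressWarnings(
    stats::wilcox.test(nz, alternative = "two.sided",
                       exact = length(nz) <= 25L, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_effective = length(nz), degenerate = FALSE)
}
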