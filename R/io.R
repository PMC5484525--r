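# File formats: FASTA design populations (via Biostrings), landscape JSON,
# shell files (a minimal resfile-like dialect), TSV tables, YAML run
# configuration, and atomic writes with seed/config manifests.

# All output files are written atomically: to a temporary sibling first,
# then renamed into place.
.write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path, call. = FALSE)
  invisible(path)
}

#' Write a design population (or sequence list) as FASTA
#'
#' One record per design; the header carries the id and, when available,
#' the fitness value (`>id fitness=...`). A `ga_population` is written in
#' ascending fitness order.
#'
#' @param x A `ga_population` or a list of `seq_record` objects.
#' @param path Output FASTA path.
#' @param fitness Optional numeric vector parallel to a sequence list.
#' @return The path, invisibly.
#' @export
write_population_fasta <- function(x, path, fitness = NULL) {
  if (inherits(x, "ga_population")) {
    fitness <- x$fitness
    x <- x$sequences
  }
  if (length(x) == 0L)
    stop("empty sequence set", call. = FALSE)
  seqs <- vapply(x, as.character, character(1))
  ids <- vapply(x, function(s) s$id, character(1))
  if (!is.null(fitness))
    ids <- sprintf("%s fitness=%.10g", ids, fitness)
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- ids
  .write_atomic(path, function(tmp)
    Biostrings::writeXStringSet(aa, tmp, width = 80L))
}

#' Read a design population from FASTA
#'
#' @param path FASTA file with one record per design.
#' @param positions Optional position labels shared by all records;
#'   defaults to `"A:1"`, `"A:2"`, ...
#' @return A list of `seq_record` objects; any `fitness=` header fields are
#'   attached as a numeric `fitness` attribute on the list.
#' @export
read_population_fasta <- function(path, positions = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L)
    stop("no sequences in ", path, call. = FALSE)
  headers <- names(aa)
  ids <- sub("[[:space:]].*$", "", headers)
  fit <- rep(NA_real_, length(aa))
  has <- grepl("fitness=", headers)
  fit[has] <- as.numeric(sub("^.*fitness=([-0-9.eE+]+).*$", "\\1",
                             headers[has]))
  out <- lapply(seq_along(aa), function(i)
    sequence_record(ids[i], as.character(aa[[i]]), positions))
  if (any(has)) attr(out, "fitness") <- fit
  out
}

#' Write a design/repack shell file
#'
#' A minimal resfile-like dialect: one line per position,
#' `chain resno role native_aa`, where role is `design` or `repack` and
#' native_aa is the one-letter native residue for design positions
#' (`.` when unknown). Lines starting with `#` are comments.
#'
#' @param shell A `design_shell`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_shell <- function(shell, path) {
  stopifnot(inherits(shell, "design_shell"))
  split_pos <- function(p) {
    chain <- sub(":.*$", "", p)
    resno <- sub("^[^:]*:", "", p)
    cbind(chain, resno)
  }
  nat <- if (is.null(shell$native_sequence)) {
    rep(".", length(shell$design_positions))
  } else shell$native_sequence$residues
  dp <- split_pos(shell$design_positions)
  lines <- c("# msdesign shell file: chain resno role native_aa",
             sprintf("%s %s design %s", dp[, 1], dp[, 2], nat))
  if (length(shell$repack_positions)) {
    rp <- split_pos(shell$repack_positions)
    lines <- c(lines, sprintf("%s %s repack .", rp[, 1], rp[, 2]))
  }
  .write_atomic(path, function(tmp) writeLines(lines, tmp))
}

#' Read a design/repack shell file
#'
#' @param path Shell file written by [write_shell()] (format documented
#'   there).
#' @param alphabet Design alphabet for the returned shell.
#' @return A `design_shell`; the native sequence is reconstructed when all
#'   design lines carry a residue code.
#' @export
read_shell <- function(path, alphabet = aa_alphabet()) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("no shell entries in ", path, call. = FALSE)
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(toks, length, integer(1)) != 4L)
  if (length(bad))
    stop("malformed shell line ", bad[1], " in ", path, call. = FALSE)
  tab <- do.call(rbind, toks)
  role <- tab[, 3]
  if (!all(role %in% c("design", "repack")))
    stop("shell roles must be 'design' or 'repack'", call. = FALSE)
  pos <- paste0(tab[, 1], ":", tab[, 2])
  design <- pos[role == "design"]
  repack <- pos[role == "repack"]
  nat_aa <- tab[role == "design", 4]
  native <- if (all(nat_aa %in% AA20))
    sequence_record("native_shell", nat_aa, design) else NULL
  design_shell(design, repack, native, alphabet = alphabet)
}

#' Serialize a synthetic landscape to JSON
#'
#' The JSON file carries everything needed to replay a benchmark run:
#' dimensions, alphabet, per-state additive tables, couplings, the planted
#' native and the generator seed.
#'
#' @param landscape A `synthetic_landscape`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  obj <- list(
    format = "msdesign_landscape_v1",
    id = landscape$id,
    L = landscape$L,
    alphabet = landscape$alphabet,
    positions = landscape$positions,
    margin = landscape$margin,
    divergence = landscape$divergence,
    coupling_density = landscape$coupling_density,
    rng_seed = landscape$rng_seed,
    planted_native = list(id = landscape$planted_native$id,
                          residues = landscape$planted_native$residues,
                          positions = landscape$planted_native$positions),
    states = lapply(names(landscape$h), function(sid)
      list(id = sid, h = unname(landscape$h[[sid]]))),
    couplings = lapply(landscape$couplings, function(cp)
      list(i = cp$i, j = cp$j, J = unname(cp$J)))
  )
  .write_atomic(path, function(tmp)
    jsonlite::write_json(obj, tmp, digits = NA, auto_unbox = TRUE))
}

#' Read a synthetic landscape from JSON
#'
#' @param path JSON file written by [write_landscape()].
#' @return A `synthetic_landscape`.
#' @export
read_landscape <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE)
  if (!identical(obj$format, "msdesign_landscape_v1"))
    stop(path, " is not an msdesign landscape file", call. = FALSE)
  dimn <- list(obj$positions, obj$alphabet)
  states <- obj$states
  # jsonlite simplifies the state list either to a data frame or to a list
  if (is.data.frame(states))
    states <- lapply(seq_len(nrow(states)), function(i)
      list(id = states$id[i], h = states$h[[i]]))
  h <- lapply(states, function(st) {
    m <- matrix(unlist(st$h), nrow = obj$L, byrow = FALSE)
    if (!all(dim(m) == c(obj$L, length(obj$alphabet))))
      stop("malformed additive table in ", path, call. = FALSE)
    dimnames(m) <- dimn
    m
  })
  names(h) <- vapply(states, function(st) st$id, character(1))
  cps <- obj$couplings
  couplings <- list()
  if (length(cps)) {
    if (is.data.frame(cps))
      cps <- lapply(seq_len(nrow(cps)), function(i)
        list(i = cps$i[i], j = cps$j[i], J = cps$J[[i]]))
    couplings <- lapply(cps, function(cp) {
      J <- matrix(unlist(cp$J), nrow = length(obj$alphabet))
      dimnames(J) <- list(obj$alphabet, obj$alphabet)
      list(i = cp$i, j = cp$j, J = J)
    })
  }
  structure(list(id = obj$id, L = obj$L, alphabet = obj$alphabet,
                 positions = obj$positions, margin = obj$margin,
                 divergence = obj$divergence,
                 coupling_density = obj$coupling_density,
                 rng_seed = obj$rng_seed,
                 planted_native = sequence_record(
                   obj$planted_native$id, obj$planted_native$residues,
                   obj$planted_native$positions),
                 h = h, couplings = couplings),
            class = "synthetic_landscape")
}

#' Write a data frame as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path) {
  .write_atomic(path, function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE))
}

#' Read a 20x20 potential table from TSV
#'
#' Expects a header row and first column of one-letter residue codes; the
#' table must be symmetric.
#'
#' @param path TSV file.
#' @return A symmetric numeric 20x20 matrix in standard residue order.
#' @export
read_potentials_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           row.names = 1L, check.names = FALSE)
  m <- as.matrix(tab)
  if (!setequal(rownames(m), AA20) || !setequal(colnames(m), AA20))
    stop("potential table must be indexed by the 20 standard codes",
         call. = FALSE)
  m <- m[AA20, AA20]
  if (!isTRUE(all.equal(m, t(m))))
    stop("potential table must be symmetric", call. = FALSE)
  m
}

# Stable hash of a configuration list (for provenance manifests).
.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# Every CLI output directory gets a manifest recording the package
# version, the resolved configuration, its hash and the rng seed.
.write_manifest <- function(dir, command, cfg, rng_seed) {
  manifest <- list(
    tool = "msdesign",
    version = as.character(utils::packageVersion("msdesign")),
    command = command,
    rng_seed = rng_seed,
    config_hash = .config_hash(cfg),
    config = cfg
  )
  .write_atomic(file.path(dir, "manifest.json"), function(tmp)
    jsonlite::write_json(manifest, tmp, digits = NA, auto_unbox = TRUE,
                         force = TRUE, pretty = TRUE))
}

#' Read a YAML run configuration
#'
#' @param path YAML file. Any `landscape`, `shell`, `designs`, `native` or
#'   `potentials` entries naming files are checked for existence at load
#'   time.
#' @return The configuration as a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg))
    stop("config must be a YAML mapping", call. = FALSE)
  for (key in c("landscape", "shell", "designs", "native", "potentials")) {
    if (!is.null(cfg[[key]]) && is.character(cfg[[key]]) &&
        !file.exists(cfg[[key]]))
      stop(sprintf("config entry '%s' names a missing file: %s", key,
                   cfg[[key]]), call. = FALSE)
  }
  cfg
}
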