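# Structure input and distance-based design/repack shell detection.
# PDB parsing is delegated to bio3d; this module normalizes its output to a
# small atom table and resolves alternate locations by occupancy.

#' Read a PDB structure into an atom table
#'
#' Parses ATOM/HETATM records of a PDB file. Of multi-model (NMR-style)
#' files only the requested model is kept; alternate locations are resolved
#' to the highest-occupancy copy (first on ties).
#'
#' @param path Path to a PDB file.
#' @param model Model index for multi-model files (default 1).
#' @return An object of class `structure_model`: list with `atoms` (data
#'   frame: record, chain, resno, insert, resid, elety, x, y, z,
#'   occupancy), `path` and `model`.
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path))
    stop("structure file not found: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model < 1L || model > n_models)
    stop(sprintf("model %d requested but file has %d model(s)", model,
                 n_models), call. = FALSE)
  xyz <- pdb$xyz[model, ]
  atoms <- data.frame(
    record = at$type,
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    x = xyz[seq(1, length(xyz), 3)],
    y = xyz[seq(2, length(xyz), 3)],
    z = xyz[seq(3, length(xyz), 3)],
    occupancy = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path, call. = FALSE)
  # resolve altlocs: highest occupancy per (chain, resno, insert, elety)
  if (any(atoms$alt != "")) {
    key <- paste(atoms$record, atoms$chain, atoms$resno, atoms$insert,
                 atoms$elety, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
      idx[which.max(atoms$occupancy[idx])]
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
  }
  atoms$alt <- NULL
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, path = path, model = as.integer(model)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s (model %d): %d atoms, %d HETATM\n",
              basename(x$path), x$model, nrow(x$atoms),
              sum(x$atoms$record == "HETATM")))
  invisible(x)
}

.is_heavy <- function(elety) {
  core <- sub("^[0-9]+", "", elety)
  !startsWith(core, "H")
}

.pos_label <- function(chain, resno, insert = "") {
  paste0(ifelse(chain == "", "_", chain), ":", resno,
         ifelse(insert == "", "", insert))
}

.ligand_atoms <- function(model, ligand) {
  if (is.character(ligand)) ligand <- list(resname = ligand)
  at <- model$atoms
  sel <- at$record == "HETATM" & at$resid == ligand$resname &
    at$resid != "HOH"
  if (!is.null(ligand$chain)) sel <- sel & at$chain == ligand$chain
  lig <- at[sel & .is_heavy(at$elety), , drop = FALSE]
  if (nrow(lig) == 0L)
    stop(sprintf("ligand '%s' not found in %s", ligand$resname,
                 basename(model$path)), call. = FALSE)
  lig
}

#' Detect design and repack shells around a ligand
#'
#' Distance-based shell detection: in each conformation, protein residues
#' with any heavy atom within `design_cutoff` of any ligand heavy atom
#' become design positions and residues within `repack_cutoff` become
#' repack positions; the returned shell is the union across all
#' conformations, with design membership overriding repack. This is an
#' approximation of protocol-level shell autodetection; the cutoffs are
#' package defaults, not derived from any packing algorithm.
#'
#' @param models List of `structure_model` objects (one per conformation).
#' @param ligand Ligand selector: a HETATM residue name, or a list with
#'   `resname` and optional `chain`. Water (HOH) is never a ligand.
#' @param design_cutoff,repack_cutoff Heavy-atom distance thresholds in
#'   Angstrom (defaults 6 and 8; `design_cutoff <= repack_cutoff`).
#' @return A `design_shell` whose native sequence is read off the first
#'   model containing each design position.
#' @export
detect_design_shell <- function(models, ligand, design_cutoff = 6,
                                repack_cutoff = 8) {
  if (design_cutoff > repack_cutoff)
    stop("design_cutoff must not exceed repack_cutoff", call. = FALSE)
  if (inherits(models, "structure_model")) models <- list(models)
  design <- character()
  repack <- character()
  native <- character()  # named by position label
  for (model in models) {
    lig <- .ligand_atoms(model, ligand)
    at <- model$atoms
    prot <- at[at$record == "ATOM" & at$resid != "HOH" &
                 .is_heavy(at$elety), , drop = FALSE]
    if (nrow(prot) == 0L) next
    lx <- as.matrix(lig[, c("x", "y", "z")])
    px <- as.matrix(prot[, c("x", "y", "z")])
    # min distance of each protein atom to any ligand heavy atom
    d2 <- outer(rowSums(px^2), rowSums(lx^2), `+`) - 2 * px %*% t(lx)
    mind <- sqrt(pmax(apply(d2, 1L, min), 0))
    pos <- .pos_label(prot$chain, prot$resno, prot$insert)
    res_min <- tapply(mind, pos, min)
    res_aa <- tapply(prot$resid, pos, `[`, 1L)
    design <- union(design, names(res_min)[res_min <= design_cutoff])
    repack <- union(repack, names(res_min)[res_min <= repack_cutoff &
                                             res_min > design_cutoff])
    new_nat <- res_aa[setdiff(names(res_aa), names(native))]
    native <- c(native, new_nat)
  }
  if (length(design) == 0L)
    stop("no residue within design_cutoff of the ligand", call. = FALSE)
  repack <- setdiff(repack, design)
  ord <- function(p) {
    chain <- sub(":.*$", "", p)
    resno <- as.integer(sub("[A-Za-z]*$", "", sub("^[^:]*:", "", p)))
    p[order(chain, resno)]
  }
  design <- ord(design)
  repack <- ord(repack)
  aa1 <- bio3d::aa321(unname(native[design]))
  if (any(!aa1 %in% AA20))
    stop("non-standard native residue(s) in the design shell: ",
         paste(unique(native[design][!aa1 %in% AA20]), collapse = ", "),
         call. = FALSE)
  native_seq <- sequence_record("native_shell", aa1, design)
  design_shell(design, repack, native_seq)
}

# ---------------------------------------------------------------------------
# Contact surrogate evaluator: a deterministic structure-based stand-in
# scorer built from a residue-pair contact potential plus a burial term.
# It makes structure states scorable end-to-end; it is a simple
# knowledge-based surrogate, with no claim of compatibility with any
# physics-based energy function.

#' Define a contact-surrogate scoring model
#'
#' The score of a sequence on a structure is
#' `sum_i burial(aa_i) * n_i + sum_(i,j) pair(aa_i, aa_j)` where `n_i` is
#' the number of C-alpha neighbors within `neighbor_cutoff` of position i
#' and the pair sum runs over designed position pairs whose side-chain
#' reference atoms (C-beta, or C-alpha for glycine) are within
#' `contact_cutoff`.
#'
#' @param pair_potential Symmetric 20x20 numeric matrix named by residue
#'   codes (default all zero).
#' @param burial_potential Named numeric vector over the 20 codes (default
#'   all zero).
#' @param contact_cutoff Reference-atom contact distance in Angstrom
#'   (default 8).
#' @param neighbor_cutoff C-alpha burial radius in Angstrom (default 10).
#' @return An object of class `contact_surrogate_model`.
#' @export
contact_surrogate_model <- function(pair_potential = NULL,
                                    burial_potential = NULL,
                                    contact_cutoff = 8,
                                    neighbor_cutoff = 10) {
  if (is.null(pair_potential))
    pair_potential <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  pair_potential <- pair_potential[AA20, AA20]
  if (!isTRUE(all.equal(pair_potential, t(pair_potential))) ||
      any(!is.finite(pair_potential)))
    stop("pair_potential must be a finite symmetric 20x20 table",
         call. = FALSE)
  if (is.null(burial_potential))
    burial_potential <- stats::setNames(numeric(20), AA20)
  burial_potential <- burial_potential[AA20]
  if (any(!is.finite(burial_potential)))
    stop("burial_potential must be finite over the 20 codes", call. = FALSE)
  stopifnot(contact_cutoff > 0, neighbor_cutoff > 0)
  structure(list(pair_potential = pair_potential,
                 burial_potential = burial_potential,
                 contact_cutoff = contact_cutoff,
                 neighbor_cutoff = neighbor_cutoff),
            class = "contact_surrogate_model")
}

# Per-structure geometry for the surrogate: neighbor counts and designed
# contact pairs, computed once per state and cached.
.surrogate_geometry <- function(model, shell, cfg) {
  at <- model$atoms
  prot <- at[at$record == "ATOM", , drop = FALSE]
  pos <- .pos_label(prot$chain, prot$resno, prot$insert)
  dpos <- shell$design_positions
  missing <- setdiff(dpos, unique(pos))
  if (length(missing))
    stop("design position(s) absent from structure ", basename(model$path),
         ": ", paste(missing, collapse = ", "), call. = FALSE)
  ca <- prot[prot$elety == "CA", , drop = FALSE]
  ca_pos <- .pos_label(ca$chain, ca$resno, ca$insert)
  refxyz <- t(vapply(dpos, function(p) {
    sub <- prot[pos == p, , drop = FALSE]
    cb <- sub[sub$elety == "CB", , drop = FALSE]
    ref <- if (nrow(cb)) cb[1L, ] else sub[sub$elety == "CA", ][1L, ]
    if (is.na(ref$x))
      stop("no CA/CB reference atom at position ", p, call. = FALSE)
    c(ref$x, ref$y, ref$z)
  }, numeric(3)))
  caxyz <- as.matrix(ca[, c("x", "y", "z")])
  # burial: CA neighbors within neighbor_cutoff of the position's CA
  nb <- vapply(dpos, function(p) {
    i <- match(p, ca_pos)
    if (is.na(i)) stop("no CA atom at position ", p, call. = FALSE)
    d <- sqrt(colSums((t(caxyz) - caxyz[i, ])^2))
    sum(d <= cfg$neighbor_cutoff) - 1L
  }, numeric(1))
  nd <- length(dpos)
  pairs <- NULL
  if (nd >= 2L) {
    dm <- as.matrix(stats::dist(refxyz))
    idx <- which(upper.tri(dm) & dm <= cfg$contact_cutoff, arr.ind = TRUE)
    if (nrow(idx)) pairs <- idx
  }
  list(nb = nb, pairs = pairs)
}

#' Contact-surrogate evaluator over structure states
#'
#' Wraps a [contact_surrogate_model()] as an evaluator for `"structure"`
#' states (whose payload is a PDB path). Geometry (neighbor counts and
#' contact pairs) is computed once per state and cached, so scoring a
#' sequence is a pure table lookup and fully deterministic.
#'
#' @param model A `contact_surrogate_model`.
#' @param shell The `design_shell` the sequences are aligned to.
#' @return An evaluator object of class `surrogate_evaluator`.
#' @export
surrogate_evaluator <- function(model, shell) {
  stopifnot(inherits(model, "contact_surrogate_model"),
            inherits(shell, "design_shell"))
  structure(list(model = model, shell = shell, cache = new.env()),
            class = c("surrogate_evaluator", "msd_evaluator"))
}

#' @export
score_sequence.surrogate_evaluator <- function(evaluator, state, sequence, ...) {
  key <- if (is.character(state$payload))
    paste0(state$payload, "#", state$id) else state$id
  geom <- evaluator$cache[[key]]
  if (is.null(geom)) {
    sm <- if (inherits(state$payload, "structure_model")) state$payload
          else read_structure(state$payload)
    geom <- .surrogate_geometry(sm, evaluator$shell, evaluator$model)
    evaluator$cache[[key]] <- geom
  }
  if (!identical(sequence$positions, evaluator$shell$design_positions))
    stop("sequence is not aligned to the evaluator shell", call. = FALSE)
  aa <- sequence$residues
  s <- sum(evaluator$model$burial_potential[aa] * geom$nb)
  if (!is.null(geom$pairs))
    s <- s + sum(evaluator$model$pair_potential[
      cbind(aa[geom$pairs[, 1]], aa[geom$pairs[, 2]])])
  unname(s)
}
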