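# Structure-derived binding-site annotation: distance-cutoff and
# vdW-margin labelling rules, plus sequence-identity clustering for
# redundancy reduction.

#' Bondi van der Waals radii (Angstrom)
#'
#' Default radius table for the vdW-margin labelling rule. Elements absent
#' from the table fall back to 1.70 A (carbon) with a warning.
#'
#' @return Named numeric vector of radii.
#' @export
vdw_table_bondi <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
}

#' Assemble a protein-ligand complex structure
#'
#' @param receptor_atoms,ligand_atoms Data frames with columns `element`,
#'   `x`, `y`, `z`, `residue_index` (receptor only; author numbering).
#'   Ligand atoms need no residue index.
#' @param receptor_sequence Character: receptor amino-acid sequence; residue
#'   `residue_index = i` maps to sequence position `i`.
#' @return A list of class `complex_structure`.
#' @export
complex_structure <- function(receptor_atoms, ligand_atoms, receptor_sequence) {
  for (df in list(receptor_atoms, ligand_atoms)) {
    need <- c("element", "x", "y", "z")
    if (!all(need %in% names(df))) {
      stop("atom tables need columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (any(!is.finite(as.matrix(df[, c("x", "y", "z")])))) {
      stop("non-finite atom coordinates", call. = FALSE)
    }
  }
  if (!"residue_index" %in% names(receptor_atoms)) {
    stop("receptor atoms need a residue_index column", call. = FALSE)
  }
  L <- nchar(receptor_sequence)
  idx <- receptor_atoms$residue_index
  if (any(idx < 1L | idx > L)) {
    stop("receptor atom residue_index outside sequence length ", L,
         call. = FALSE)
  }
  receptor_atoms$element <- toupper(receptor_atoms$element)
  ligand_atoms$element <- toupper(ligand_atoms$element)
  structure(list(receptor_atoms = receptor_atoms, ligand_atoms = ligand_atoms,
                 receptor_sequence = receptor_sequence),
            class = "complex_structure")
}

#' Read a protein-ligand complex from a PDB or mmCIF file
#'
#' Coordinates are parsed with \pkg{bio3d}. Protein (ATOM) records of the
#' selected chain form the receptor; HETATM records other than water form
#' the ligand. When several altloc conformers are present the
#' highest-occupancy one is kept. Receptor residues are renumbered 1..L in
#' order of appearance and the one-letter sequence is derived from them.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param chain Receptor chain id, or `NULL` for all protein chains.
#' @param ligand_resnames Optional character vector restricting which HETATM
#'   residue names count as the ligand.
#' @return A `complex_structure`.
#' @export
read_complex <- function(path, chain = NULL, ligand_resnames = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path, call. = FALSE)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  at <- pdb$atom
  # keep highest-occupancy altloc per (chain, resno, atom name)
  if (!is.null(at$o) && any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      ix[which.max(occ[ix])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1L, 1L), at$elesy)))
  is_prot <- at$type == "ATOM"
  is_het <- at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT", "DOD"))
  if (!is.null(chain)) is_prot <- is_prot & at$chain %in% chain
  if (!is.null(ligand_resnames)) is_het <- is_het & at$resid %in% ligand_resnames
  if (!any(is_het)) stop("no ligand (non-water HETATM) atoms in ", path,
                         call. = FALSE)
  if (!any(is_prot)) stop("no receptor (ATOM) records in ", path, call. = FALSE)

  rec <- at[is_prot, , drop = FALSE]
  res_key <- paste(rec$chain, rec$resno, rec$insert, sep = "|")
  res_order <- unique(res_key)
  res_index <- match(res_key, res_order)
  resid3 <- rec$resid[!duplicated(res_key)]
  seq1 <- bio3d::aa321(resid3)
  seq1[is.na(seq1) | seq1 == ""] <- "X"

  receptor_atoms <- data.frame(element = elem[is_prot],
                               x = rec$x, y = rec$y, z = rec$z,
                               residue_index = res_index,
                               stringsAsFactors = FALSE)
  lig <- at[is_het, , drop = FALSE]
  ligand_atoms <- data.frame(element = elem[is_het],
                             x = lig$x, y = lig$y, z = lig$z,
                             stringsAsFactors = FALSE)
  complex_structure(receptor_atoms, ligand_atoms,
                    paste(seq1, collapse = ""))
}

min_cross_distances <- function(A, B) {
  # |A| x |B| Euclidean distance matrix between two coordinate sets
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

is_heavy <- function(element) toupper(element) != "H"

#' Label binding residues by a distance cutoff
#'
#' A residue is labelled 1 iff any of its atoms lies within `cutoff`
#' Angstrom of any ligand atom. With `heavy_only = TRUE` both sides are
#' restricted to heavy (non-hydrogen) atoms — the convention of the 4.2 A
#' carbohydrate rule; the 6.5 A small-molecule rule counts all atoms.
#' Residues without atoms in the structure get `mask = 0`.
#'
#' @param structure A `complex_structure`.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @param heavy_only Restrict both sides to heavy atoms.
#' @return A [label_track()] over the receptor sequence (protein id is the
#'   attribute `protein_id` of the structure if set, else `"receptor"`).
#' @export
label_by_cutoff <- function(structure, cutoff = 6.5, heavy_only = FALSE) {
  stopifnot(inherits(structure, "complex_structure"))
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  rec <- structure$receptor_atoms
  lig <- structure$ligand_atoms
  if (heavy_only) {
    rec <- rec[is_heavy(rec$element), , drop = FALSE]
    lig <- lig[is_heavy(lig$element), , drop = FALSE]
  }
  if (nrow(lig) == 0L) stop("no ligand atoms left to compare", call. = FALSE)
  L <- nchar(structure$receptor_sequence)
  labels <- integer(L)
  mask <- integer(L)
  if (nrow(rec) > 0L) {
    D <- min_cross_distances(as.matrix(rec[, c("x", "y", "z")]),
                             as.matrix(lig[, c("x", "y", "z")]))
    min_by_res <- tapply(apply(D, 1L, min), rec$residue_index, min)
    idx <- as.integer(names(min_by_res))
    mask[idx] <- 1L
    labels[idx] <- as.integer(min_by_res <= cutoff)
  }
  label_track(structure_id(structure), labels, mask)
}

structure_id <- function(structure) {
  id <- attr(structure, "protein_id")
  if (is.null(id)) "receptor" else id
}

#' Label binding residues by the vdW-margin rule
#'
#' A residue is labelled 1 iff some receptor-atom/ligand-atom pair is closer
#' than `margin` plus the sum of the two atoms' van der Waals radii. This is
#' the contact definition used for protein- and nucleic-acid-partner
#' datasets (margin 0.5 A).
#'
#' @param structure A `complex_structure`.
#' @param margin Distance margin in Angstrom (>= 0; default 0.5).
#' @param vdw_table Named radius table; defaults to [vdw_table_bondi()].
#' @return A [label_track()] over the receptor sequence.
#' @export
label_by_vdw_margin <- function(structure, margin = 0.5,
                                vdw_table = vdw_table_bondi()) {
  stopifnot(inherits(structure, "complex_structure"))
  if (margin < 0) stop("margin must be nonnegative", call. = FALSE)
  if (any(vdw_table <= 0.5 | vdw_table >= 3.0)) {
    stop("vdW radii must lie in (0.5, 3.0) Angstrom", call. = FALSE)
  }
  rec <- structure$receptor_atoms
  lig <- structure$ligand_atoms
  if (nrow(lig) == 0L) stop("no ligand atoms", call. = FALSE)
  radius_of <- function(elements) {
    r <- vdw_table[toupper(elements)]
    if (anyNA(r)) {
      warning("unknown element(s) ",
              paste(unique(elements[is.na(r)]), collapse = ", "),
              " assigned fallback radius 1.70 A", call. = FALSE)
      r[is.na(r)] <- 1.70
    }
    unname(r)
  }
  L <- nchar(structure$receptor_sequence)
  labels <- integer(L)
  mask <- integer(L)
  if (nrow(rec) > 0L) {
    D <- min_cross_distances(as.matrix(rec[, c("x", "y", "z")]),
                             as.matrix(lig[, c("x", "y", "z")]))
    thresh <- outer(radius_of(rec$element), radius_of(lig$element), "+") + margin
    hit <- D < thresh
    res_hit <- tapply(apply(hit, 1L, any), rec$residue_index, any)
    idx <- as.integer(names(res_hit))
    mask[idx] <- 1L
    labels[idx] <- as.integer(res_hit)
  }
  label_track(structure_id(structure), labels, mask)
}

#' Pairwise global sequence identity
#'
#' Global (Needleman-Wunsch) alignment via
#' [Biostrings::pairwiseAlignment()] with match +1, mismatch -1, and affine
#' gaps costing 2 for the first gapped position and 1 for each further one.
#' Identity is the number of identical aligned positions divided by the
#' length of the shorter sequence (a BLASTClust-like denominator).
#'
#' @param seqA,seqB Nonempty amino-acid sequences.
#' @return Identity in `[0, 1]`.
#' @export
pairwise_identity <- function(seqA, seqB) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("sequences must be nonempty",
                                           call. = FALSE)
  letters21 <- c(AA_LETTERS, "X")
  sub <- matrix(-1, length(letters21), length(letters21),
                dimnames = list(letters21, letters21))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(seqA, seqB, type = "global",
                                       substitutionMatrix = sub,
                                       gapOpening = 1, gapExtension = 1)
  Biostrings::nmatch(aln) / min(nchar(seqA), nchar(seqB))
}

#' Greedy sequence-identity clustering
#'
#' Proteins are processed in decreasing length order (ties broken by id);
#' each joins the first existing representative with identity at or above
#' the threshold, otherwise it founds a new cluster. Representatives are
#' therefore pairwise below the threshold. This is a deterministic greedy
#' stand-in for BLASTClust-style redundancy reduction at 25-30% identity.
#'
#' @param proteins List of `protein_record`s.
#' @param identity_threshold Threshold in (0,1), e.g. 0.3.
#' @return Named character vector mapping each protein id to its
#'   representative's id.
#' @export
greedy_cluster <- function(proteins, identity_threshold = 0.3) {
  if (identity_threshold <= 0 || identity_threshold >= 1) {
    stop("identity_threshold must lie in (0,1)", call. = FALSE)
  }
  proteins <- as_protein_list(proteins)
  ids <- protein_ids(proteins)
  check_unique_ids(ids)
  lens <- vapply(proteins, protein_length, integer(1L))
  ord <- order(-lens, ids)
  reps <- character(0)
  rep_seq <- character(0)
  assignment <- character(length(proteins))
  names(assignment) <- ids
  for (i in ord) {
    s <- proteins[[i]]$sequence
    placed <- FALSE
    for (r in seq_along(reps)) {
      if (pairwise_identity(s, rep_seq[r]) >= identity_threshold) {
        assignment[ids[i]] <- reps[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, ids[i])
      rep_seq <- c(rep_seq, s)
      assignment[ids[i]] <- ids[i]
    }
  }
  assignment
}
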