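# Structure-derived labelling rules and identity clustering.

toy_structure <- function(receptor_z, ligand_z = 10, elements = "C",
                          seq = NULL) {
  n <- length(receptor_z)
  if (is.null(seq)) seq <- paste(rep("A", n), collapse = "")
  complex_structure(
    receptor_atoms = data.frame(element = elements, x = 0, y = 0,
                                z = receptor_z, residue_index = seq_len(n)),
    ligand_atoms = data.frame(element = "C", x = 0, y = 0, z = ligand_z),
    receptor_sequence = seq)
}

# Exhaustive pairwise-distance oracle for the cutoff rule.
oracle_cutoff <- function(structure, cutoff, heavy_only = FALSE) {
  rec <- structure$receptor_atoms
  lig <- structure$ligand_atoms
  if (heavy_only) {
    rec <- rec[toupper(rec$element) != "H", , drop = FALSE]
    lig <- lig[toupper(lig$element) != "H", , drop = FALSE]
  }
  L <- nchar(structure$receptor_sequence)
  labs <- integer(L)
  for (res in unique(rec$residue_index)) {
    ra <- rec[rec$residue_index == res, , drop = FALSE]
    hit <- FALSE
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(lig))) {
      d <- sqrt((ra$x[i] - lig$x[j])^2 + (ra$y[i] - lig$y[j])^2 +
                  (ra$z[i] - lig$z[j])^2)
      if (d <= cutoff) hit <- TRUE
    }
    labs[res] <- as.integer(hit)
  }
  labs
}

test_that("cutoff labelling matches direct distance arithmetic", {
  s1 <- toy_structure(0, ligand_z = 6.0)
  expect_identical(label_by_cutoff(s1, 6.5)$labels, 1L)
  expect_identical(label_by_cutoff(s1, 4.2)$labels, 0L)
  s3 <- toy_structure(c(0, 5, 9), ligand_z = 10)
  expect_identical(label_by_cutoff(s3, 6.5)$labels, c(0L, 1L, 1L))
  expect_identical(label_by_cutoff(s3, 6.5)$labels, oracle_cutoff(s3, 6.5))
  expect_identical(label_by_cutoff(s3, 4.2)$labels, oracle_cutoff(s3, 4.2))
})

test_that("cutoff labelling agrees with the oracle and is monotone in cutoff", {
  set.seed(42)
  for (rep in 1:5) {
    n_res <- 6L
    rec <- data.frame(element = sample(c("C", "N", "O", "H"), 18, TRUE),
                      x = runif(18, 0, 12), y = runif(18, 0, 12),
                      z = runif(18, 0, 12),
                      residue_index = rep(seq_len(n_res), each = 3L))
    lig <- data.frame(element = sample(c("C", "O", "H"), 4, TRUE),
                      x = runif(4, 0, 12), y = runif(4, 0, 12),
                      z = runif(4, 0, 12))
    s <- complex_structure(rec, lig, paste(rep("G", n_res), collapse = ""))
    for (heavy in c(FALSE, TRUE)) {
      l42 <- label_by_cutoff(s, 4.2, heavy_only = heavy)$labels
      l65 <- label_by_cutoff(s, 6.5, heavy_only = heavy)$labels
      expect_identical(l42, oracle_cutoff(s, 4.2, heavy))
      expect_identical(l65, oracle_cutoff(s, 6.5, heavy))
      expect_true(all(l42 <= l65))   # monotone in the cutoff
    }
  }
})

test_that("heavy-only mode ignores hydrogens on both sides", {
  s <- complex_structure(
    data.frame(element = c("H", "C"), x = 0, y = 0, z = c(0, -4),
               residue_index = c(1L, 1L)),
    data.frame(element = "C", x = 0, y = 0, z = 3),
    "A")
  expect_identical(label_by_cutoff(s, 4.2, heavy_only = FALSE)$labels, 1L)
  expect_identical(label_by_cutoff(s, 4.2, heavy_only = TRUE)$labels, 0L)
})

test_that("residues without atoms get mask 0 and no-ligand input errors", {
  s <- complex_structure(
    data.frame(element = "C", x = 0, y = 0, z = 0, residue_index = 2L),
    data.frame(element = "C", x = 0, y = 0, z = 1),
    "AAA")
  tr <- label_by_cutoff(s, 6.5)
  expect_identical(tr$mask, c(0L, 1L, 0L))
  expect_error(complex_structure(
    data.frame(element = "C", x = 0, y = 0, z = 0, residue_index = 1L),
    data.frame(element = character(), x = numeric(), y = numeric(),
               z = numeric()), "A") |> label_by_cutoff(6.5),
    "ligand")
})

test_that("vdW-margin rule matches Bondi-table arithmetic", {
  two_carbons <- function(d) complex_structure(
    data.frame(element = "C", x = 0, y = 0, z = 0, residue_index = 1L),
    data.frame(element = "C", x = 0, y = 0, z = d), "A")
  # threshold = 1.70 + 1.70 + 0.5 = 3.90 (strict inequality)
  expect_identical(label_by_vdw_margin(two_carbons(3.89))$labels, 1L)
  expect_identical(label_by_vdw_margin(two_carbons(3.91))$labels, 0L)
  expect_identical(label_by_vdw_margin(two_carbons(0), margin = 0)$labels, 1L)
  expect_error(label_by_vdw_margin(two_carbons(1), margin = -0.1),
               "nonnegative")
  # C vs N: 1.70 + 1.55 + 0.5 = 3.75
  cn <- complex_structure(
    data.frame(element = "C", x = 0, y = 0, z = 0, residue_index = 1L),
    data.frame(element = "N", x = 0, y = 0, z = 3.74), "A")
  expect_identical(label_by_vdw_margin(cn)$labels, 1L)
  unk <- complex_structure(
    data.frame(element = "ZZ", x = 0, y = 0, z = 0, residue_index = 1L),
    data.frame(element = "C", x = 0, y = 0, z = 3.89), "A")
  expect_warning(trk <- label_by_vdw_margin(unk), "fallback")
  expect_identical(trk$labels, 1L)   # fallback 1.70 behaves like carbon
})

test_that("pairwise identity uses the shorter-sequence denominator", {
  expect_equal(pairwise_identity("MKVA", "MKVA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  expect_equal(pairwise_identity("ACDEFG", "ACDEYG"), 5 / 6)
  # identical prefix against longer sequence: denominator is min length
  expect_equal(pairwise_identity("MKV", "MKVAAA"), 1.0)
  expect_error(pairwise_identity("", "MKV"), "nonempty")
})

test_that("greedy clustering joins identical sequences and is deterministic", {
  p <- list(protein_record("a", "MKVLINGKTLKGEITVE"),
            protein_record("b", "MKVLINGKTLKGEITVE"))
  cl <- greedy_cluster(p, 0.3)
  expect_length(unique(cl), 1L)

  q <- list(protein_record("a", paste(rep("A", 20), collapse = "")),
            protein_record("b", paste(rep("C", 20), collapse = "")))
  cl2 <- greedy_cluster(q, 0.3)
  expect_length(unique(cl2), 2L)
})

test_that("a redundant copy collapses while dissimilar sequences stay apart", {
  # four mutually dissimilar sequences plus a copy of the first
  seqs <- c(s1 = "MKVLINGKTLKGEITVEAHHHH",
            s2 = "WWPGCDYRRFFQQNNSSTTAAG",
            s3 = "DEDEDEDEDEDEDEDEDEDEDE",
            s4 = "KIKIKIKIKIKIKIKIKIKIKI",
            s5 = "MKVLINGKTLKGEITVEAHHHH")
  prots <- lapply(names(seqs), function(nm) protein_record(nm, seqs[[nm]]))
  # verify the premise with the identity function itself (exhaustive matrix)
  for (i in 1:4) for (j in setdiff(1:4, i)) {
    expect_lt(pairwise_identity(seqs[[i]], seqs[[j]]), 0.3)
  }
  cl <- greedy_cluster(prots, 0.3)
  expect_length(unique(cl), 4L)
  expect_identical(cl[["s5"]], cl[["s1"]])
  # deterministic: only a function of the input set
  expect_identical(cl, greedy_cluster(rev(prots), 0.3)[names(cl)])
})

test_that("PDB complexes are parsed into receptor and ligand atoms", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  N   GLY A   2       8.000   0.000   0.000  1.00  0.00           N",
    "ATOM      4  CA  GLY A   2       9.000   0.000   0.000  1.00  0.00           C",
    "HETATM    5  C1  LIG A  10       3.000   0.000   0.000  1.00  0.00           C",
    "HETATM    6  O   HOH A  11      50.000  50.000  50.000  1.00  0.00           O",
    "END")
  writeLines(lines, pdb)
  s <- read_complex(pdb)
  expect_identical(s$receptor_sequence, "AG")
  expect_identical(nrow(s$ligand_atoms), 1L)  # water excluded
  tr <- label_by_cutoff(s, 4.2)
  expect_identical(tr$labels, c(1L, 0L))      # res 1 within 3 A, res 2 at 5 A
})
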