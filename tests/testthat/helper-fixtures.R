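# Small in-code fixtures shared across test files.

# hand-written two-atom PDB text
write_two_atom_pdb <- function(path) {
  writeLines(c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  CA  GLY A 324       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  PRO B 198       4.000   2.000   3.000  1.00  0.00           C",
    "END"), path)
  path
}

# two-model PDB: model 0 at x = 1, model 1 at x = 9
write_two_model_pdb <- function(path) {
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       1.000   3.800   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       9.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       9.000   3.800   0.000  1.00  0.00           C",
    "ENDMDL",
    "END"), path)
  path
}

# altloc fixture: residue 1 CA has conformers A (occ 0.4) and B (occ 0.6)
write_altloc_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  ALA A   2       5.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  path
}

# small frame with explicit atoms for selection / distance tests
toy_frame <- function() {
  at <- atom_table(serial = 1:6,
                   name = c("CA", "CB", "CA", "CA", "CB", "CA"),
                   resname = "ALA",
                   resid = c(1, 1, 2, 1, 1, 2),
                   chain = c("A", "A", "A", "B", "B", "B"),
                   element = "C",
                   x = c(0, 1, 2, 10, 11, 12), y = 0, z = 0)
  md_frame(at, box = c(20, 20, 20))
}

rigid_transform <- function(xyz, axis = c(1, 2, 3), angle = 0.7,
                            shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(xyz %*% R, 2, shift, "+")
}
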