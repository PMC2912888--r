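# Shared fixtures, built in code and memoized for the test session.

.tf <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.tf[[key]])) .tf[[key]] <- force(expr)
  .tf[[key]]
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

tf_lib <- function() memo("lib", make_toy_rotamer_library(seed = 1))

# Small compact corpus with library-consistent random side chains.
tf_corpus <- function() memo("corpus", {
  seqs <- c("SKNDLEQV", "NQLKSEDV", "KDESQNLV", "QNSKLDEV")
  lapply(seq_along(seqs), function(k) {
    make_toy_structure(seqs[k], library = tf_lib(), random_sidechains = TRUE,
                       seed = k)
  })
})

tf_defs <- function() memo("defs", select_atom_pairs(tf_corpus()))

tf_tables <- function() memo("tables", {
  quiet(build_statistics(tf_corpus(), tf_defs(), tf_lib(), rng_seed = 3))
})

# Planted-geometry corpus at the generator defaults, plus explicit
# definitions on the planted atom pair.
asn_gln_defs <- function() {
  data.frame(key = "ASN|GLN", type_a = "ASN", type_b = "GLN",
             a1 = "ND2", a2 = "OD1", b1 = "NE2", b2 = "OE1",
             stringsAsFactors = FALSE)
}

tf_planted <- function() memo("planted", {
  make_planted_corpus(n_signal = 120, n_noise = 120, seed = 1)
})

tf_planted_tables <- function() memo("planted_tables", {
  quiet(build_statistics(tf_planted()$structures, asn_gln_defs(), tf_lib(),
                         rng_seed = 2))
})

# Hand-written 3-residue PDB text fixture (Ala-Gly-Ser).
write_mini_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.010   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.260   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       2.000  -0.770  -1.200  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       3.330   1.540   0.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       3.980   2.840   0.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.490   2.690   0.000  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       6.030   1.580   0.000  1.00  0.00           O",
    "ATOM     10  N   SER A   3       6.200   3.810   0.000  1.00  0.00           N",
    "ATOM     11  CA  SER A   3       7.650   3.800   0.000  1.00  0.00           C",
    "ATOM     12  C   SER A   3       8.210   5.210   0.000  1.00  0.00           C",
    "ATOM     13  O   SER A   3       7.460   6.190   0.000  1.00  0.00           O",
    "ATOM     14  CB  SER A   3       8.200   3.020   1.200  1.00  0.00           C",
    "ATOM     15  OG  SER A   3       9.610   3.000   1.150  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}
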