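# Independent oracles and in-code fixtures shared across tests.

# Horn's closed-form quaternion superposition: an implementation of rigid
# least-squares fitting entirely independent of the SVD/Kabsch path.
quaternion_fit_rmsd <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  P <- sweep(p, 2, cp); Q <- sweep(q, 2, cq)
  M <- crossprod(P, Q)  # sum p_i q_i^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  qv <- ev$vectors[, 1]
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  # Horn's R rotates P onto Q as q ~ R p
  moved <- t(R %*% t(P))
  sqrt(mean(rowSums((moved - Q)^2)))
}

random_rotation <- function() {
  u <- stats::rnorm(3)
  rotation_about_axis(u, stats::runif(1, 0, 180))
}

random_transform <- function() {
  rigid_transform(random_rotation(), stats::rnorm(3, sd = 10))
}

# minimal hand-written three-residue PDB fixture (with a zinc)
fixture_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00 10.00           O",
    "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00 10.00           N",
    "ATOM      6  CA  GLY A   2       3.988   2.835   0.000  1.00 10.00           C",
    "ATOM      7  C   GLY A   2       5.504   2.705   0.000  1.00 10.00           C",
    "ATOM      8  O   GLY A   2       6.030   1.593   0.000  1.00 10.00           O",
    "ATOM      9  N   SER A   3       6.184   3.844   0.000  1.00 10.00           N",
    "ATOM     10  CA  SER A   3       7.640   3.855   0.000  1.00 10.00           C",
    "ATOM     11  C   SER A   3       8.192   5.273   0.000  1.00 10.00           C",
    "ATOM     12  O   SER A   3       7.443   6.252   0.000  1.00 10.00           O",
    "ATOM     13  OG  SER A   3       8.145   3.157   1.135  1.00 10.00           O",
    "TER      14      SER A   3",
    "HETATM   15 ZN    ZN A 101       4.000   0.000   2.000  1.00 10.00          ZN",
    "HETATM   16  O   HOH A 201       6.000   6.000   1.000  1.00 10.00           O",
    "END")
  writeLines(lines, path)
  path
}

# structure_model built directly from an atom spec data.frame
toy_model <- function(df, id = "toy") {
  defaults <- data.frame(record = "ATOM", eleno = seq_len(nrow(df)),
                         elety = "CA", alt = "", resid = "ALA", chain = "A",
                         resno = seq_len(nrow(df)), insert = "",
                         x = 0, y = 0, z = 0, o = 1, b = 0, elesy = "C",
                         stringsAsFactors = FALSE)
  for (col in names(df)) defaults[[col]] <- df[[col]]
  clamshell:::new_structure_model(defaults, id = id)
}
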