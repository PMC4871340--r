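# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately literal (per-frame / per-component loops over
# the defining formulas) and never call the production code paths they
# check.

# small deterministic receptor + reference used across files
toy <- build_toy_receptor(n_residues = 10, n_segments = 2)

# write a tiny 3-residue PDB (one H per residues 1 and 2) and return its path
write_toy3_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.400   0.000   0.000  1.00  0.00           C",
    "ATOM      3  HA  ALA A   1       1.400   1.000   0.000  1.00  0.00           H",
    "ATOM      4  C   ALA A   1       2.100   1.200   0.000  1.00  0.00           C",
    "ATOM      5  N   GLY A   2       3.400   1.200   0.100  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       4.500   2.000   0.300  1.00  0.00           C",
    "ATOM      7  H   GLY A   2       3.500   0.300   0.200  1.00  0.00           H",
    "ATOM      8  C   GLY A   2       5.800   1.400   0.100  1.00  0.00           C",
    "ATOM      9  N   SER A   3       6.900   2.200   0.400  1.00  0.00           N",
    "ATOM     10  CA  SER A   3       8.100   1.500   0.600  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

# ensemble of pure Gaussian jitter about a reference
gaussian_ensemble <- function(reference, n_frames, sigma, seed = 1,
                              ligand_id = "toy", state = "inactive") {
  set.seed(seed)
  nat <- nrow(reference)
  co <- array(rnorm(n_frames * nat * 3, sd = sigma),
              dim = c(n_frames, nat, 3))
  co <- sweep(co, c(2, 3), reference, "+")
  new_ensemble(co, ligand_id, state)
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

# apply one rigid rotation+translation to a whole frame (atoms x 3)
rigid_move <- function(X, R, t) sweep(X %*% R, 2, t, "+")

# --- independent oracles ----------------------------------------------------

# literal per-frame evaluation of the RMSF definition (denominator T)
oracle_rmsf <- function(coords, idx0) {
  Tn <- dim(coords)[1]
  vapply(idx0 + 1L, function(a) {
    mu <- c(mean(coords[, a, 1]), mean(coords[, a, 2]), mean(coords[, a, 3]))
    acc <- 0
    for (f in seq_len(Tn))
      acc <- acc + sum((coords[f, a, ] - mu)^2)
    sqrt(acc / Tn)
  }, numeric(1))
}

# literal per-pair, per-component evaluation of the 3x3 Pearson submatrix
# and the root-sum-of-squares PCC
oracle_pcc <- function(coords, pairs0) {
  Tn <- dim(coords)[1]
  dev <- function(a, ax) coords[, a, ax] - mean(coords[, a, ax])
  apply(pairs0, 1, function(pr) {
    i <- pr[1] + 1L; j <- pr[2] + 1L
    ss <- 0
    for (ai in 1:3) for (bj in 1:3) {
      di <- dev(i, ai); dj <- dev(j, bj)
      vi <- sum(di^2) / Tn; vj <- sum(dj^2) / Tn
      if (vi <= 0 || vj <= 0) next
      rho <- (sum(di * dj) / Tn) / sqrt(vi * vj)
      ss <- ss + rho^2
    }
    sqrt(ss)
  })
}

# direct from-definition Pearson coefficient
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# analytic two-sided tail P(|r| > r0) for null Pearson at sample size n
pearson_null_tail <- function(r0, n) {
  1 - stats::pbeta(r0^2, 0.5, (n - 2) / 2)
}

# small 3-ligand efficacy table for reduced synthetic configs
tiny_efficacy <- function(n = 3) {
  data.frame(ligand_id = paste0("L", seq_len(n)),
             gprotein_emax = seq(0, 100, length.out = n),
             barrestin_emax = seq(0, 100, length.out = n),
             stringsAsFactors = FALSE)
}
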