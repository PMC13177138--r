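# Independent brute-force oracles and tiny fixture builders.  The oracles
# deliberately re-derive each quantity from its definition with plain loops,
# sharing no code with the package internals they check.

naive_O <- function(points, h, cutoff = 9) {
  n <- nrow(points)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- sqrt(sum((points[i, ] - points[j, ])^2))
      if (r <= cutoff) {
        u <- r / cutoff
        g <- 1 - 0.5 * (7 * u^2 - 9 * u^4 + 5 * u^6 - u^8)
        raw[i] <- raw[i] + (h[i] + h[j]) * g
      }
    }
  }
  raw / sum(raw)
}

naive_kl <- function(P, Q) {
  s <- 0
  for (i in seq_along(P)) {
    if (P[i] > 0) s <- s + P[i] * log(P[i] / Q[i]) / log(2)
  }
  s
}

naive_RD <- function(O, T_dist) {
  n <- length(O)
  R <- rep(1 / n, n)
  dt <- naive_kl(O, T_dist)
  dr <- naive_kl(O, R)
  if (dt + dr == 0) 0 else dt / (dt + dr)
}

naive_classify <- function(O, T_dist, f = 0.5) {
  d <- T_dist - O
  tau <- f * max(abs(d))
  out <- character(length(O))
  for (i in seq_along(O)) {
    out[i] <- if (d[i] > 0 && d[i] >= tau) "deficit"
      else if (d[i] < 0 && -d[i] >= tau) "excess"
      else "accordant"
  }
  out
}

random_distribution <- function(n) {
  v <- stats::rexp(n)
  v / sum(v)
}

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  rot <- qr.Q(qr_d)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  rot
}

# Hand-written 3-residue PDB text: GLY (CA only), ALA (CA + CB), SER (CA +
# two side-chain atoms), chain A.
write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   2       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      4  CA  SER A   3       6.000   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CB  SER A   3       6.000   2.000   0.000  1.00  0.00           C",
    "ATOM      6  OG  SER A   3       8.000   2.000   0.000  1.00  0.00           O",
    "END"
  ), path)
  path
}

# Same chain but with A/B altlocs on the ALA CB atom.
write_altloc_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB AALA A   2       1.000   2.000   3.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   2       9.000   9.000   9.000  0.50  0.00           C",
    "ATOM      5  CA  SER A   3       6.000   0.000   0.000  1.00  0.00           C",
    "ATOM      6  CB  SER A   3       6.000   2.000   0.000  1.00  0.00           C",
    "END"
  ), path)
  path
}

write_two_residue_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.000   0.000   0.000  1.00  0.00           C",
    "END"
  ), path)
  path
}
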