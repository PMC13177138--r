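test_that("principal-axis orientation canonicalizes rigid motions", {
  set.seed(21)
  # an already centred, axis-aligned cloud is a fixed point up to axis sign
  pts <- orient_to_principal_axes(cbind(rnorm(60, 0, 5), rnorm(60, 0, 3),
                                        rnorm(60, 0, 1)))
  ref <- orient_to_principal_axes(pts)
  expect_equal(abs(ref), abs(pts), tolerance = 1e-6)
  # any rigid motion maps to the same canonical coordinates up to axis sign
  for (i in 1:5) {
    moved <- pts %*% random_rotation() + matrix(rnorm(3), 60, 3, byrow = TRUE)
    out <- orient_to_principal_axes(moved)
    expect_equal(abs(out), abs(ref), tolerance = 1e-6)
  }
  expect_error(orient_to_principal_axes(matrix(1, 5, 3)), "degenerate")
  expect_error(orient_to_principal_axes(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               "degenerate")
})

test_that("compute_T evaluates the axis-aligned Gaussian and normalizes", {
  two <- rbind(c(-2, 0, 0), c(2, 0, 0))
  expect_equal(compute_T(two, sigma = c(1, 1, 1)), c(0.5, 0.5))
  pair <- rbind(c(0, 0, 0), c(5, 1, 1))
  Tp <- compute_T(pair, sigma = c(2, 2, 2))
  expect_gt(Tp[1], Tp[2])
  # five toy coordinates against the closed-form product of exponentials
  pts <- rbind(c(0, 0, 0), c(1, 2, 0), c(-3, 1, 2), c(2, -2, 1), c(0, 3, -1))
  s <- c(2, 3, 1.5)
  raw <- exp(-pts[, 1]^2 / (2 * s[1]^2)) *
    exp(-pts[, 2]^2 / (2 * s[2]^2)) *
    exp(-pts[, 3]^2 / (2 * s[3]^2))
  expect_equal(compute_T(pts, sigma = s), raw / sum(raw), tolerance = 1e-12)
  flat <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(compute_T(flat), "zero extent")
})

test_that("compute_O matches its definition and handles contact edge cases", {
  # two residues at exactly the cutoff: g(1) = 0, no contacts anywhere
  apart <- rbind(c(0, 0, 0), c(9, 0, 0))
  expect_error(compute_O(apart, c(0.5, 0.5), cutoff = 9), "no inter-residue contacts")
  # two identical-h residues within the cutoff share the sum symmetrically
  near <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(compute_O(near, c(0.7, 0.7), cutoff = 9), c(0.5, 0.5))
  # random instances against the brute-force double loop
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(3 * n, 0, 2.5), n, 3)
    h <- runif(n)
    expect_equal(compute_O(pts, h, cutoff = 9), naive_O(pts, h, 9),
                 tolerance = 1e-12)
  }
})

test_that("TM inverts T and M interpolates between them", {
  expect_equal(compute_TM(c(0.5, 0.3, 0.2)), c(0, 0.4, 0.6))
  Td <- c(0.6, 0.3, 0.1)
  TM <- compute_TM(Td)
  expect_equal(TM[which.max(Td)], 0)
  expect_equal(sum(TM), 1)
  expect_error(compute_TM(rep(0.25, 4)), "constant")

  expect_equal(compute_M(Td, TM, 0), Td)
  expect_equal(compute_M(Td, TM, 1), TM)
  expect_equal(compute_M(c(0.6, 0.4), c(0.3, 0.7), 0.5), c(0.45, 0.55))
  expect_error(compute_M(Td, TM, -0.1), "non-negative")
})

test_that("kl_divergence follows the closed form and its conventions", {
  P <- c(0.2, 0.3, 0.5)
  expect_equal(kl_divergence(P, P), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)  # one bit
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "undefined")
  set.seed(41)
  for (i in 1:20) {
    A <- random_distribution(10)
    B <- random_distribution(10)
    expect_equal(kl_divergence(A, B), naive_kl(A, B), tolerance = 1e-12)
  }
})

test_that("RD is 0 at perfect ordering, 1 at the uniform pole, and matches the oracle", {
  Td <- random_distribution(20)
  expect_equal(compute_RD(Td, Td), 0)
  n <- 20
  expect_equal(compute_RD(rep(1 / n, n), Td), 1)
  set.seed(51)
  for (i in 1:20) {
    O <- random_distribution(15)
    Tt <- random_distribution(15)
    rd <- compute_RD(O, Tt)
    expect_equal(rd, naive_RD(O, Tt), tolerance = 1e-12)
    expect_gte(rd, 0)
    expect_lte(rd, 1)
  }
})

test_that("RD decreases monotonically as an observed profile mixes toward T", {
  # instance family: multiplicative log-normal perturbations of T, the
  # regime an observed hydrophobicity profile of a T-shaped molecule lives in
  set.seed(61)
  for (i in 1:25) {
    n <- 30
    Td <- random_distribution(n)
    O <- prop.table(Td * exp(rnorm(n, 0, 0.8)))
    lam <- seq(0, 1, by = 0.05)
    rds <- vapply(lam, function(l) compute_RD((1 - l) * O + l * Td, Td),
                  numeric(1))
    expect_true(all(diff(rds) <= 1e-12))
    expect_equal(rds[length(rds)], 0)
  }
})

test_that("fit_K recovers a planted environment parameter", {
  set.seed(71)
  Td <- random_distribution(40)
  TM <- compute_TM(Td)
  for (k_star in c(0, 0.2, 0.6, 1.0, 1.5)) {
    O <- compute_M(Td, TM, k_star)
    expect_equal(fit_K(O, Td, TM), k_star, tolerance = 1.0001e-3)
  }
  # off-grid value lands within one refinement step
  O <- compute_M(Td, TM, 0.6037)
  expect_lt(abs(fit_K(O, Td, TM) - 0.6037), 1.0001e-3)
  # O = TM pins K at the interpolation endpoint
  expect_equal(fit_K(TM, Td, TM), 1, tolerance = 1.0001e-3)
})

test_that("residue classification flags deficits and excesses symmetrically", {
  Td <- random_distribution(10)
  expect_true(all(classify_residues(Td, Td) == "accordant"))
  # a single residue carrying the dominant deviation is the only one flagged
  O <- c(0.30, rep(0.7 / 9, 9))
  Tt <- c(0.10, rep(0.9 / 9, 9))
  st <- classify_residues(O, Tt, threshold_fraction = 1)
  expect_equal(which(st == "excess"), 1L)
  expect_equal(sum(st != "accordant"), 1L)
  set.seed(81)
  for (i in 1:20) {
    O <- random_distribution(12)
    Tt <- random_distribution(12)
    expect_equal(as.character(classify_residues(O, Tt, 0.5)),
                 naive_classify(O, Tt, 0.5))
  }
})

test_that("profiles emitted by a full analysis are valid distributions", {
  res <- fod_analysis(gen_structure(n = 80, seed = 5))
  for (col in c("T", "O", "TM", "M")) {
    v <- res$profile[[col]]
    expect_equal(sum(v), 1, tolerance = 1e-9)
    expect_true(all(v >= 0))
  }
  expect_gte(res$rd, 0)
  expect_lte(res$rd, 1)
  expect_gte(res$k_fit, 0)
  expect_equal(nrow(res$profile), res$n)
  g <- glance(res)
  expect_equal(g$rd, res$rd)
  expect_equal(nrow(tidy(res)), res$n)
})

test_that("RD and K are invariant under rigid motion of the structure", {
  model <- gen_structure(n = 120, seed = 9)
  base <- fod_analysis(model)
  set.seed(91)
  for (i in 1:3) {
    rot <- random_rotation()
    shift <- rnorm(3, 0, 20)
    pts <- as.matrix(model[, c("x", "y", "z")]) %*% rot
    moved <- model
    moved$x <- pts[, 1] + shift[1]
    moved$y <- pts[, 2] + shift[2]
    moved$z <- pts[, 3] + shift[3]
    res <- fod_analysis(moved)
    expect_equal(res$rd, base$rd, tolerance = 1e-9)
    expect_equal(res$k_fit, base$k_fit, tolerance = 1e-9)
  }
})

test_that("eliminating planted discordant residues lowers RD", {
  model <- gen_structure(n = 200, mode = "ideal_micelle", seed = 1)
  # plant three extreme outliers on the surface of an ideal micelle
  r <- sqrt(model$x^2 + model$y^2 + model$z^2)
  planted <- model$residue_index[order(-r)[1:3]]
  model$intrinsic_h[match(planted, model$residue_index)] <- 1
  full <- fod_analysis(model)
  reduced <- eliminate_and_recompute(model, planted)
  expect_lt(reduced$rd, full$rd)
  expect_equal(reduced$eliminated, sort(planted))
  expect_equal(reduced$n, 197L)
  # empty elimination set reproduces the full analysis
  noop <- eliminate_and_recompute(model, integer(0))
  expect_equal(noop$rd, full$rd)
  expect_equal(noop$k_fit, full$k_fit)
  # guard: too few residues must remain
  expect_error(eliminate_and_recompute(model, model$residue_index[-(1:2)]),
               "fewer than 3")
})
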