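# Fuzzy-oil-drop engine: T/O/TM/M hydrophobicity distributions, the RD order
# parameter, the environment parameter K, and residue classification.

.norm1 <- function(v) {
  s <- sum(v)
  if (s <= 0) stop("cannot normalize: non-positive total", call. = FALSE)
  v / s
}

#' Centre a point set and rotate it onto its principal axes
#'
#' Translates the points to their centroid and applies the proper rotation
#' that aligns the covariance eigenvectors with the coordinate axes, largest
#' variance on x.  This canonical frame is a prerequisite for the axis-wise
#' Gaussian used by [compute_T()].
#'
#' @param points Numeric n x 3 matrix of coordinates (Angstrom).
#' @return n x 3 matrix of oriented coordinates.
#' @export
orient_to_principal_axes <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  if (nrow(points) < 3L) stop("need at least 3 points", call. = FALSE)
  centred <- sweep(points, 2, colMeans(points))
  cv <- stats::cov(centred)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[1] <= 1e-12 || ev$values[2] <= 1e-12 * ev$values[1]) {
    stop("degenerate point set (collinear or coincident points)", call. = FALSE)
  }
  rot <- ev$vectors  # columns ordered by decreasing variance
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]  # keep a proper rotation
  out <- centred %*% rot
  dimnames(out) <- NULL
  out
}

#' Theoretical micelle-like hydrophobicity distribution T
#'
#' Evaluates a centred, axis-aligned 3D Gaussian at each residue's effective
#' point and normalizes to a discrete distribution: maximal hydrophobicity at
#' the molecular centre, vanishing at the surface.  By default each axis
#' sigma is set from the molecule's own extent as (max |coordinate|)/3, so
#' the density effectively reaches zero at the outermost residue (3-sigma
#' rule).
#'
#' @param points Oriented n x 3 matrix, from [orient_to_principal_axes()].
#' @param sigma Optional length-3 vector of positive axis sigmas (Angstrom);
#'   default derives them from the point extents.
#' @return Numeric vector summing to 1.
#' @export
compute_T <- function(points, sigma = NULL) {
  points <- as.matrix(points)
  if (is.null(sigma)) {
    sigma <- apply(abs(points), 2, max) / 3
  }
  if (any(sigma <= 0)) stop("zero extent along an axis: cannot fit Gaussian", call. = FALSE)
  z <- sweep(points, 2, sigma, "/")
  .norm1(exp(-rowSums(z^2) / 2))
}

# Levitt-style smooth contact decay on u = r/cutoff in [0, 1]; g(0)=1, g(1)=0.
contact_decay <- function(u) {
  g <- 1 - 0.5 * (7 * u^2 - 9 * u^4 + 5 * u^6 - u^8)
  g[u > 1] <- 0
  g
}

#' Observed hydrophobicity distribution O
#'
#' Collects, for each residue i, the distance-weighted hydrophobic
#' interaction with every other residue j within the cutoff:
#' `sum over j != i of (h_i + h_j) * g(r_ij / cutoff)`, where `g` is the
#' smooth polynomial contact-decay function with g(0) = 1 and g(1) = 0.  The
#' self term is excluded.  The raw sums are normalized to a distribution.
#'
#' @param points n x 3 coordinate matrix.
#' @param h Intrinsic hydrophobicities in \[0, 1\], length n.
#' @param cutoff Interaction cutoff in Angstrom (default 9).
#' @return Numeric vector summing to 1.
#' @export
compute_O <- function(points, h, cutoff = 9) {
  points <- as.matrix(points)
  stopifnot(length(h) == nrow(points), cutoff > 0)
  d <- as.matrix(stats::dist(points))
  w <- contact_decay(d / cutoff)
  diag(w) <- 0
  hh <- outer(h, h, "+")
  raw <- unname(rowSums(hh * w))
  if (sum(raw) <= 0) stop("no inter-residue contacts within cutoff", call. = FALSE)
  .norm1(raw)
}

#' Inverted (environment-dominated) distribution TM
#'
#' The membrane-like negation of T: hydrophobicity maximal at the surface and
#' zero at the centre, obtained as `max(T) - T` renormalized.
#'
#' @param T_dist Normalized theoretical distribution.
#' @return Numeric vector summing to 1.
#' @export
compute_TM <- function(T_dist) {
  raw <- max(T_dist) - T_dist
  if (sum(raw) <= 0) stop("constant T distribution: TM undefined", call. = FALSE)
  .norm1(raw)
}

#' Environment-modified target distribution M(K)
#'
#' Mixes the aqueous target T toward its inverted counterpart TM with weight
#' K: `M propto T + K * (TM - T)`, clipped below at zero and renormalized.
#' K = 0 returns T exactly; K = 1 returns TM; K > 1 extrapolates beyond TM,
#' expressing an environment contribution with no upper bound.
#'
#' @param T_dist,TM_dist Normalized distributions.
#' @param K Non-negative environment weight.
#' @return Numeric vector summing to 1.
#' @export
compute_M <- function(T_dist, TM_dist, K) {
  if (length(K) != 1L || !is.finite(K) || K < 0) {
    stop("K must be a single non-negative number", call. = FALSE)
  }
  raw <- pmax(T_dist + K * (TM_dist - T_dist), 0)
  .norm1(raw)
}

#' Kullback-Leibler divergence (base 2)
#'
#' `D(P || Q) = sum P_i log2(P_i / Q_i)` with the convention
#' `0 * log(0/q) = 0`.
#'
#' @param P,Q Normalized distributions of equal length.
#' @return Non-negative divergence in bits.
#' @export
kl_divergence <- function(P, Q) {
  stopifnot(length(P) == length(Q))
  pos <- P > 0
  if (any(Q[pos] <= 0)) {
    stop("D(P||Q) undefined: P > 0 where Q = 0", call. = FALSE)
  }
  sum(P[pos] * log2(P[pos] / Q[pos]))
}

# Floor exact zeros at 1e-12 and renormalize, so g(u)=0 contacts cannot
# produce infinities in the divergences.
.floor_zeros <- function(v, eps = 1e-12) {
  if (any(v <= 0)) .norm1(pmax(v, eps)) else v
}

#' Relative-distance order parameter RD
#'
#' Locates the observed distribution O between the micelle-like target T and
#' the uniform (unordered) reference R with `R_i = 1/n`:
#' `RD = D(O||T) / (D(O||T) + D(O||R))`.
#' RD = 0 means perfect micelle-like ordering (O = T); RD = 1 means O is as
#' close to uniform as it can be relative to T.  The degenerate case
#' O = T = R returns 0.
#'
#' @param O,T_dist Normalized distributions of equal length.
#' @return RD in \[0, 1\].
#' @export
compute_RD <- function(O, T_dist) {
  n <- length(O)
  stopifnot(length(T_dist) == n, n >= 2L)
  O <- .floor_zeros(O)
  T_dist <- .floor_zeros(T_dist)
  R <- rep(1 / n, n)
  d_t <- kl_divergence(O, T_dist)
  d_r <- kl_divergence(O, R)
  if (d_t + d_r == 0) return(0)
  d_t / (d_t + d_r)
}

#' Fit the environment parameter K
#'
#' Finds the K whose modified target M(K) is closest (in Kullback-Leibler
#' divergence) to the observed distribution O.  A coarse grid search
#' (default 0 to 2, step 0.01) is followed by one local refinement pass at
#' step 0.001 around the coarse optimum; ties break toward smaller K.  K has
#' no upper bound in principle; raise `k_max` to search further.
#'
#' @param O,T_dist,TM_dist Normalized distributions.
#' @param k_max Upper end of the coarse grid (default 2).
#' @param coarse_step,refine_step Grid resolutions.
#' @return The fitted K (non-negative scalar).
#' @export
fit_K <- function(O, T_dist, TM_dist, k_max = 2, coarse_step = 0.01,
                  refine_step = 0.001) {
  O <- .floor_zeros(O)
  obj <- function(k) kl_divergence(O, .floor_zeros(compute_M(T_dist, TM_dist, k)))
  search <- function(grid) {
    vals <- vapply(grid, obj, numeric(1))
    grid[which.min(vals)]  # grid ascending, so first minimum = smallest K
  }
  coarse <- search(seq(0, k_max, by = coarse_step))
  lo <- max(0, coarse - coarse_step)
  hi <- coarse + coarse_step
  search(seq(lo, hi, by = refine_step))
}

#' Classify residues as hydrophobicity deficit, excess or accordant
#'
#' Flags residue i as `deficit` when its observed hydrophobicity falls short
#' of the theoretical value (T_i - O_i at least tau) and as `excess` when it
#' overshoots (O_i - T_i at least tau), with the threshold
#' `tau = threshold_fraction * max |O - T|` scaled to the largest deviation
#' in the chain.  Deficit residues mark candidate binding cavities; excess
#' residues mark hydrophobic surface patches primed for interaction.  When
#' O = T exactly, every residue is accordant.
#'
#' @param O,T_dist Normalized distributions.
#' @param threshold_fraction Fraction of the maximum |O - T| used as the
#'   flagging threshold, in (0, 1\]; default 0.5.
#' @return Factor with levels `accordant`, `deficit`, `excess`.
#' @export
classify_residues <- function(O, T_dist, threshold_fraction = 0.5) {
  stopifnot(length(O) == length(T_dist),
            threshold_fraction > 0, threshold_fraction <= 1)
  d <- T_dist - O
  tau <- threshold_fraction * max(abs(d))
  status <- rep("accordant", length(O))
  status[d >= tau & d > 0] <- "deficit"
  status[-d >= tau & d < 0] <- "excess"
  factor(status, levels = c("accordant", "deficit", "excess"))
}

#' Full fuzzy-oil-drop analysis of a structure model
#'
#' Orients the effective points to their principal axes, computes the T, O,
#' TM and M distributions, the RD order parameter, the fitted environment
#' parameter K, and per-residue deficit/excess status.
#'
#' @param model A `structure_model` (from [read_structure()] or
#'   [gen_structure()]).
#' @param cutoff Contact cutoff for the O distribution, Angstrom.
#' @param threshold_fraction Flagging threshold for [classify_residues()].
#' @param k_max Upper end of the K search grid.
#' @return A `fod_result`: list with elements `rd`, `k_fit`, `n`, `profile`
#'   (tibble of per-residue T/O/TM/M/status), `eliminated`, `scale_name`,
#'   `cutoff`, `source_id`.  Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' model <- gen_structure(n = 50, seed = 1)
#' res <- fod_analysis(model)
#' glance(res)
#' @export
fod_analysis <- function(model, cutoff = 9, threshold_fraction = 0.5,
                         k_max = 2) {
  stopifnot(inherits(model, "structure_model"))
  if (nrow(model) < 3L) stop("need at least 3 residues", call. = FALSE)
  pts <- orient_to_principal_axes(effective_points(model))
  T_dist <- compute_T(pts)
  O <- compute_O(pts, model$intrinsic_h, cutoff = cutoff)
  TM <- compute_TM(T_dist)
  rd <- compute_RD(O, T_dist)
  k_fit <- fit_K(O, T_dist, TM, k_max = k_max)
  M <- compute_M(T_dist, TM, k_fit)
  status <- classify_residues(O, T_dist, threshold_fraction)
  profile <- tibble::tibble(
    chain = model$chain, residue_index = model$residue_index,
    residue_name = model$residue_name,
    T = T_dist, O = O, TM = TM, M = M, status = status
  )
  structure(
    list(rd = rd, k_fit = k_fit, n = nrow(model), profile = profile,
         eliminated = integer(0),
         scale_name = attr(model, "scale_name") %||% "unknown",
         cutoff = cutoff, threshold_fraction = threshold_fraction,
         source_id = attr(model, "source_id") %||% "unknown"),
    class = "fod_result"
  )
}

#' Eliminate flagged residues and recompute the analysis
#'
#' Removes the given residues from the model, re-orients the remaining
#' points, recomputes all distributions and refits RD and K.  This mirrors
#' the workflow where locally discordant residues (the information-carrying
#' non-micelle part) are removed to show that the remainder of the chain is
#' micelle-like.
#'
#' @param model A `structure_model`.
#' @param flagged Residue indices (values of `residue_index`) to remove; must
#'   be a strict subset leaving at least 3 residues.
#' @param ... Passed on to [fod_analysis()].
#' @return A `fod_result` with `eliminated` recording the removed indices.
#' @export
eliminate_and_recompute <- function(model, flagged, ...) {
  stopifnot(inherits(model, "structure_model"))
  keep <- !model$residue_index %in% flagged
  if (all(keep) && length(flagged) > 0) {
    warning("no residues matched the flagged indices", call. = FALSE)
  }
  if (sum(keep) < 3L) {
    stop("fewer than 3 residues would remain after elimination", call. = FALSE)
  }
  reduced <- model[keep, ]
  attr(reduced, "source_id") <- attr(model, "source_id")
  attr(reduced, "scale_name") <- attr(model, "scale_name")
  class(reduced) <- class(model)
  out <- fod_analysis(reduced, ...)
  out$eliminated <- sort(intersect(flagged, model$residue_index))
  out
}

#' @export
print.fod_result <- function(x, ...) {
  cat("<fod_result>  n =", x$n, " RD =", signif(x$rd, 6),
      " K =", signif(x$k_fit, 6), "\n")
  cat("  scale:", x$scale_name, " cutoff:", x$cutoff, "A\n")
  tab <- table(x$profile$status)
  cat("  status:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  if (length(x$eliminated)) {
    cat("  eliminated residues:", paste(x$eliminated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname fod_analysis
#' @param x A `fod_result`.
#' @export
tidy.fod_result <- function(x, ...) x$profile

#' @rdname fod_analysis
#' @export
glance.fod_result <- function(x, ...) {
  tibble::tibble(
    rd = x$rd, k_fit = x$k_fit, n = x$n,
    n_deficit = sum(x$profile$status == "deficit"),
    n_excess = sum(x$profile$status == "excess"),
    n_eliminated = length(x$eliminated),
    scale_name = x$scale_name, cutoff = x$cutoff,
    source_id = x$source_id
  )
}

#' Profile plot for a fuzzy-oil-drop result
#'
#' Draws the T, O and M distributions along the chain, marking
#' hydrophobicity-deficit residues in red and excess residues in blue on the
#' observed profile.
#'
#' @param object A `fod_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fod_result <- function(object, ...) {
  prof <- object$profile
  prof$pos <- seq_len(nrow(prof))
  long <- tidyr::pivot_longer(prof[, c("pos", "T", "O", "M")],
                              cols = c("T", "O", "M"),
                              names_to = "distribution", values_to = "value")
  flagged <- prof[prof$status != "accordant", ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$value,
                                     colour = .data$distribution)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = flagged,
      ggplot2::aes(x = .data$pos, y = .data$O, fill = .data$status),
      inherit.aes = FALSE, shape = 21, size = 2, colour = "black"
    ) +
    ggplot2::scale_fill_manual(values = c(deficit = "red", excess = "blue")) +
    ggplot2::labs(
      x = "residue position", y = "normalized hydrophobicity",
      title = sprintf("T/O/M profiles (RD = %.3f, K = %.3f)",
                      object$rd, object$k_fit)
    ) +
    ggplot2::theme_minimal()
}
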