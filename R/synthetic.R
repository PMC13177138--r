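# Synthetic fixtures with known ground truth: Gaussian point clouds whose
# hydrophobicity is micelle-like (RD near 0), inverted (surface-hydrophobic),
# or micelle-like with planted discordant residues; and default loop-network
# configurations.  Everything is seeded and reproducible, so every engine is
# testable without any download.

#' Generate a synthetic structure model with known micelle-likeness
#'
#' Samples `n` effective points from a centred anisotropic 3D Gaussian with
#' axis sigmas `sigma` and assigns intrinsic hydrophobicity directly from the
#' Gaussian field evaluated at each point (rescaled to \[0, 1\]), bypassing
#' any residue scale — the ground truth is thus independent of scale choice.
#'
#' Modes:
#' \describe{
#'   \item{`ideal_micelle`}{hydrophobicity proportional to the local Gaussian
#'     density: maximal in the core, low at the surface (RD near 0 by
#'     construction).}
#'   \item{`inverted`}{hydrophobicity proportional to the inverted field:
#'     hydrophobic surface, polar core (membrane-like negation).}
#'   \item{`planted_outliers`}{starts from `ideal_micelle`, then flips
#'     `n_outliers` randomly chosen residues to the opposite extreme
#'     (h -> 1 - h), maximal local discordance detectable by
#'     [classify_residues()].}
#' }
#'
#' Default sigmas (12, 10, 8) Angstrom give a small-protein-sized ellipsoid
#' in which the default 9 Angstrom contact cutoff yields a well-connected
#' interaction graph at n = 200.
#'
#' @param n Residue count, >= 3.
#' @param sigma Length-3 positive axis sigmas, Angstrom.
#' @param mode Generation mode, see above.
#' @param n_outliers Number of flipped residues (`planted_outliers` mode).
#' @param seed Integer seed; generation is deterministic given (spec, seed).
#' @return A `structure_model` (poly-alanine identities, chain "A",
#'   `scale_name = "synthetic-gaussian"`).
#' @examples
#' model <- gen_structure(n = 100, seed = 7)
#' fod_analysis(model)$rd
#' @export
gen_structure <- function(n = 200, sigma = c(12, 10, 8),
                          mode = c("ideal_micelle", "inverted",
                                   "planted_outliers"),
                          n_outliers = 0L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n >= 3, length(sigma) == 3L, all(sigma > 0),
            n_outliers >= 0, n_outliers < n)
  if (mode == "planted_outliers" && n_outliers == 0L) {
    stop("planted_outliers mode needs n_outliers >= 1", call. = FALSE)
  }
  withr::with_seed(seed, {
    pts <- cbind(stats::rnorm(n, 0, sigma[1]),
                 stats::rnorm(n, 0, sigma[2]),
                 stats::rnorm(n, 0, sigma[3]))
    dens <- exp(-rowSums(sweep(pts, 2, sigma, "/")^2) / 2)
    h <- switch(mode,
      ideal_micelle = dens,
      planted_outliers = dens,
      inverted = max(dens) - dens
    )
    rng <- range(h)
    h <- if (rng[2] > rng[1]) (h - rng[1]) / (rng[2] - rng[1]) else rep(0.5, n)
    if (mode == "planted_outliers") {
      flip <- sample.int(n, n_outliers)
      h[flip] <- 1 - h[flip]
    }
    new_structure_model(
      tibble::tibble(
        chain = "A", residue_index = seq_len(n), ins = "",
        residue_name = "ALA",
        x = pts[, 1], y = pts[, 2], z = pts[, 3], intrinsic_h = h
      ),
      source_id = sprintf("synthetic:%s:n%d:seed%d", mode, n, seed),
      scale_name = "synthetic-gaussian"
    )
  })
}

#' Write a structure model as a minimal PDB file
#'
#' Emits a poly-alanine chain with each residue's effective point written as
#' both its CA and CB atom, so reading the file back through
#' [read_structure()] recovers the same effective points (the CB is the only
#' side-chain atom, hence the side-chain mean).  Geometry is deliberately
#' schematic: this is a test fixture writer, not a model builder.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  ser <- 0L
  lines <- character(0)
  for (i in seq_len(nrow(model))) {
    for (atom in c("CA", "CB")) {
      ser <- ser + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        ser, atom, model$residue_name[i], substr(model$chain[i], 1, 1),
        model$residue_index[i], model$x[i], model$y[i], model$z[i]
      ))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a default loop-network fixture
#'
#' Chains `n_loops` copies of the documented default loop (effector rate 1.0,
#' decay 0.1, sensitivity 5.0, delay 3, initial concentration 0) with
#' unit-gain couplings loop1 -> loop2 -> loop3 in the requested mode, or no
#' couplings at all.
#'
#' @param n_loops Number of loops, 1 to 3.
#' @param coupling_mode `"effector"`, `"receptor"`, or `"none"`.
#' @param gain Coupling gain (default 1).
#' @return A `nf_system`.
#' @export
gen_loop_fixture <- function(n_loops = 2L,
                             coupling_mode = c("none", "effector", "receptor"),
                             gain = 1.0) {
  coupling_mode <- match.arg(coupling_mode)
  stopifnot(n_loops >= 1, n_loops <= 3)
  loops <- dplyr::bind_rows(lapply(seq_len(n_loops), function(i) {
    loop_spec(name = paste0("loop", i))
  }))
  couplings <- NULL
  if (coupling_mode != "none" && n_loops > 1L) {
    couplings <- dplyr::bind_rows(lapply(seq_len(n_loops - 1L), function(i) {
      coupling_spec(source = paste0("loop", i), target = paste0("loop", i + 1),
                    mode = coupling_mode, gain = gain)
    }))
  }
  nf_system(loops, couplings)
}

#' Write a loop-network fixture as a YAML config
#'
#' @param system A `nf_system`.
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_system_config <- function(system, path) {
  stopifnot(inherits(system, "nf_system"))
  cfg <- list(
    loops = purrr::transpose(as.list(system$loops)),
    couplings = if (nrow(system$couplings)) {
      purrr::transpose(as.list(system$couplings))
    }
  )
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}
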