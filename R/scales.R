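# Residue hydrophobicity scales, raw (publication) units.
# Kyte-Doolittle: J Mol Biol 157, 105-132 (1982).
.kyte_doolittle <- c(
  ALA =  1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS =  2.5,
  GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE =  4.5,
  LEU =  3.8, LYS = -3.9, MET =  1.9, PHE =  2.8, PRO = -1.6,
  SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL =  4.2
)

.builtin_scales <- list(kyte_doolittle = .kyte_doolittle)

#' Residue hydrophobicity scales
#'
#' Returns a named numeric vector mapping 3-letter residue codes to raw
#' hydrophobicity values.  All downstream analyses rescale the values
#' linearly so the scale minimum maps to 0 and the maximum to 1; any scale
#' with the same ranking therefore gives the same rescaled profile shape up
#' to the linear map.  The scale is a named, swappable input and its name is
#' recorded in every result for provenance.
#'
#' @param name Scale name; currently `"kyte_doolittle"`.
#' @return Named numeric vector of raw per-residue hydrophobicities.
#' @examples
#' hydrophobicity_scale()[c("ILE", "ARG")]
#' @export
hydrophobicity_scale <- function(name = "kyte_doolittle") {
  if (!name %in% names(.builtin_scales)) {
    stop("unknown hydrophobicity scale: '", name, "' (available: ",
         paste(names(.builtin_scales), collapse = ", "), ")", call. = FALSE)
  }
  .builtin_scales[[name]]
}

#' Assign rescaled intrinsic hydrophobicities to residues
#'
#' Looks each residue code up in a hydrophobicity scale and rescales the
#' values linearly onto \[0, 1\]: the scale's minimum maps to 0, its maximum
#' to 1.  The rescaling uses the full scale's range, not the range of the
#' residues present, so a chain without e.g. isoleucine still gets values
#' comparable across proteins.
#'
#' @param residue_names Character vector of 3-letter residue codes.
#' @param scale Named numeric vector (code -> raw value), e.g. from
#'   [hydrophobicity_scale()], or a single scale name.
#' @return Numeric vector in \[0, 1\], one value per residue.
#' @examples
#' assign_hydrophobicity(c("GLY", "ILE", "ARG"))
#' @export
assign_hydrophobicity <- function(residue_names, scale = "kyte_doolittle") {
  if (is.character(scale) && length(scale) == 1L && is.null(names(scale))) {
    scale <- hydrophobicity_scale(scale)
  }
  stopifnot(is.numeric(scale), !is.null(names(scale)))
  unknown <- setdiff(unique(residue_names), names(scale))
  if (length(unknown) > 0L) {
    stop("residue code(s) not in hydrophobicity scale: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lo <- min(scale)
  hi <- max(scale)
  if (hi <= lo) stop("degenerate hydrophobicity scale (constant values)", call. = FALSE)
  unname((scale[residue_names] - lo) / (hi - lo))
}
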