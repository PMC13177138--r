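.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Read a protein structure into a per-residue model
#'
#' Parses a PDB or mmCIF file, keeps one chain of standard amino-acid
#' residues, reduces every residue to a single effective point (the geometric
#' mean of its side-chain heavy atoms, or the C-alpha for glycine and
#' side-chain-less residues), and attaches an intrinsic hydrophobicity from a
#' named residue scale rescaled to \[0, 1\].
#'
#' Only altloc `" "` or `"A"` atoms are used, so alternate conformers reduce
#' deterministically to a single set of coordinates.  Waters, heteroatoms and
#' non-standard residues are dropped.  Residue order follows the order of
#' appearance in the file; author residue numbering and insertion codes are
#' kept as identity.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param chain Chain identifier; `NULL` takes the first chain in the file.
#' @param scale Hydrophobicity scale name or named numeric vector
#'   (see [assign_hydrophobicity()]).
#' @return A `structure_model`: a tibble with one row per residue and columns
#'   `chain`, `residue_index`, `ins`, `residue_name`, `x`, `y`, `z`,
#'   `intrinsic_h`, carrying `source_id` and `scale_name` attributes.
#' @export
read_structure <- function(path, chain = NULL, scale = "kyte_doolittle") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("cannot parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- tibble::as_tibble(pdb$atom)

  atoms <- dplyr::filter(
    atoms,
    .data$type == "ATOM",
    .data$resid %in% .standard_aa,
    is.na(.data$alt) | .data$alt %in% c("", " ", "A"),
    is.na(.data$elesy) | .data$elesy != "H"
  )
  if (nrow(atoms) == 0L) stop("no standard amino-acid atoms in file", call. = FALSE)

  if (is.null(chain)) {
    chain <- atoms$chain[1]
  } else if (!chain %in% atoms$chain) {
    stop("chain '", chain, "' not present in file", call. = FALSE)
  }
  atoms <- dplyr::filter(atoms, .data$chain == !!chain)

  atoms$ins <- ifelse(is.na(atoms$insert), "", atoms$insert)
  res_key <- paste(atoms$resno, atoms$ins)
  atoms$.res <- match(res_key, unique(res_key))  # file order, not numeric sort

  residues <- atoms |>
    dplyr::group_by(.data$.res) |>
    dplyr::group_map(function(df, key) {
      pt <- effective_atom(df[, c("elety", "x", "y", "z")],
                           residue = paste0(df$resid[1], df$resno[1]))
      tibble::tibble(
        chain = df$chain[1], residue_index = df$resno[1], ins = df$ins[1],
        residue_name = df$resid[1], x = pt[1], y = pt[2], z = pt[3]
      )
    }) |>
    dplyr::bind_rows()

  if (nrow(residues) < 3L) {
    stop("chain '", chain, "' has fewer than 3 standard residues", call. = FALSE)
  }

  scale_name <- if (is.character(scale) && is.null(names(scale))) scale else "custom"
  residues$intrinsic_h <- assign_hydrophobicity(residues$residue_name, scale)
  new_structure_model(residues, source_id = basename(path), scale_name = scale_name)
}

new_structure_model <- function(residues, source_id, scale_name) {
  stopifnot(all(c("chain", "residue_index", "residue_name",
                  "x", "y", "z", "intrinsic_h") %in% names(residues)))
  if (!"ins" %in% names(residues)) residues$ins <- ""
  out <- tibble::as_tibble(residues[, c("chain", "residue_index", "ins",
                                        "residue_name", "x", "y", "z",
                                        "intrinsic_h")])
  stopifnot(all(is.finite(out$x)), all(is.finite(out$y)), all(is.finite(out$z)),
            all(out$intrinsic_h >= 0 & out$intrinsic_h <= 1))
  attr(out, "source_id") <- source_id
  attr(out, "scale_name") <- scale_name
  class(out) <- c("structure_model", class(out))
  out
}

#' Effective point of one residue
#'
#' The per-residue reduction used before any spatial analysis: the arithmetic
#' mean of the side-chain heavy-atom coordinates.  Glycine, and residues whose
#' side-chain atoms are missing from the model, fall back to the C-alpha
#' coordinate (with a warning for non-glycine residues).
#'
#' @param atoms Data frame with columns `elety` (atom name), `x`, `y`, `z`.
#' @param residue Label used in diagnostics.
#' @return Numeric length-3 vector (x, y, z) in Angstrom.
#' @export
effective_atom <- function(atoms, residue = "residue") {
  stopifnot(all(c("elety", "x", "y", "z") %in% names(atoms)))
  side <- atoms[!atoms$elety %in% .backbone_atoms, , drop = FALSE]
  if (nrow(side) > 0L) {
    return(c(mean(side$x), mean(side$y), mean(side$z)))
  }
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) {
    stop(residue, ": no side-chain heavy atoms and no CA atom", call. = FALSE)
  }
  c(ca$x[1], ca$y[1], ca$z[1])
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", nrow(x), " residues, source: ",
      attr(x, "source_id") %||% "?", ", scale: ",
      attr(x, "scale_name") %||% "?", "\n", sep = "")
  NextMethod()
}

effective_points <- function(model) {
  as.matrix(model[, c("x", "y", "z")])
}
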