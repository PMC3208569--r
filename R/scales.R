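#' Bundled per-residue hydrophobicity scales
#'
#' Loads one of the scale tables shipped with the package: the
#' Kyte-Doolittle hydropathy index, or the Wimley-White whole-residue free
#' energies of transfer from water to the POPC bilayer interface
#' (`ww_interface`) or to n-octanol (`ww_octanol`). The Wimley-White values
#' are scale-native kcal/mol; Asp and Glu are the charged species and His is
#' neutral, as published.
#'
#' @param name Scale identifier.
#' @return Named numeric vector over the 20 canonical residues, with a
#'   `"scale"` attribute.
#' @examples
#' kd <- hydropathy_scale("kyte_doolittle")
#' kd[["I"]]  # 4.5, the most hydrophobic residue
#' @export
hydropathy_scale <- function(name = c("kyte_doolittle", "ww_interface",
                                      "ww_octanol")) {
  name <- match.arg(name)
  path <- system.file("extdata", "scales", paste0(name, ".tsv"),
                      package = "anclxome", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 20L, !anyDuplicated(tab$aa))
  v <- stats::setNames(tab$value, tab$aa)
  attr(v, "scale") <- name
  v
}

AA_CANONICAL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
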