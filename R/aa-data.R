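#' @keywords internal
#' @importFrom stats predict
"_PACKAGE"

#' Canonical one-letter amino-acid alphabet (alphabetical order)
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Kyte-Doolittle hydropathy index (Kyte & Doolittle 1982, J Mol Biol 157).
## Default scale for the target-residue hydrophobicity feature; users may
## substitute any 20-entry scale via read_hydrophobicity_scale().
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

## Theoretical maximum accessible surface areas per residue type, in A^2
## (Tien et al. 2013, PLoS ONE 8:e80635, "theoretical" column). Used to
## normalize absolute SASA into relative exposure.
MAX_ASA_TIEN2013 <- c(
  A = 129, C = 167, D = 193, E = 223, F = 240,
  G = 104, H = 224, I = 197, K = 236, L = 201,
  M = 224, N = 195, P = 159, Q = 225, R = 274,
  S = 155, T = 172, V = 174, W = 285, Y = 263
)

#' Hydrophobicity scales
#'
#' The per-variant feature table uses the hydrophobicity of the *target*
#' amino acid as one of its eight model features. The default scale is the
#' Kyte-Doolittle hydropathy index; any other scale can be supplied as a
#' two-column TSV (`aa`, `value`) covering all 20 canonical amino acids.
#'
#' @param path Path to a tab-separated file with columns `aa` (one-letter
#'   code) and `value` (numeric). A header line is required.
#' @return A named numeric vector of length 20 (names are the one-letter
#'   amino-acid codes), usable wherever a hydrophobicity scale is expected.
#' @examples
#' scale <- default_hydrophobicity()
#' scale["W"]
#' @export
read_hydrophobicity_scale <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("aa", "value") %in% names(tab))) {
    stop("hydrophobicity table must have columns 'aa' and 'value'")
  }
  scale <- stats::setNames(as.numeric(tab$value), toupper(tab$aa))
  missing <- setdiff(AA_ALPHABET, names(scale))
  if (length(missing) > 0) {
    stop("hydrophobicity scale missing amino acids: ",
         paste(missing, collapse = ", "))
  }
  scale[AA_ALPHABET]
}

#' @rdname read_hydrophobicity_scale
#' @export
default_hydrophobicity <- function() {
  KYTE_DOOLITTLE[AA_ALPHABET]
}

## internal: validate a scale vector
check_hydrophobicity_scale <- function(scale) {
  if (is.null(names(scale)) || !all(AA_ALPHABET %in% names(scale))) {
    stop("hydrophobicity scale must be a named vector covering all 20 amino acids")
  }
  if (any(!is.finite(scale[AA_ALPHABET]))) {
    stop("hydrophobicity scale contains non-finite values")
  }
  invisible(scale)
}
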