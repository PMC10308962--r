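#' Elemental composition of the 20 canonical amino acids
#'
#' Neutral free (non-polymerized) amino acid formulas. Sidechain ionization
#' is irrelevant for the carbon oxidation state because the metric ignores
#' charge, so the neutral species are tabulated.
#'
#' @return A data.frame with one row per amino acid and columns `aa`
#'   (three-letter code), `letter` (one-letter code), and element counts
#'   `c`, `h`, `n`, `o`, `s`.
#' @examples
#' head(amino_acid_formulas())
#' @export
amino_acid_formulas <- function() {
  df <- data.frame(
    aa = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
           "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
           "Tyr", "Val"),
    letter = c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
               "I", "L", "K", "M", "F", "P", "S", "T", "W",
               "Y", "V"),
    c = c(3, 6, 4, 4, 3, 5, 5, 2, 6, 6, 6, 6, 5, 9, 5, 3, 4, 11, 9, 5),
    h = c(7, 14, 8, 7, 7, 10, 9, 5, 9, 13, 13, 14, 11, 11, 9, 7, 9, 12,
          11, 11),
    n = c(1, 4, 2, 1, 1, 2, 1, 1, 3, 1, 1, 2, 1, 1, 1, 1, 1, 2, 1, 1),
    o = c(2, 2, 3, 4, 2, 3, 4, 2, 2, 2, 2, 2, 2, 2, 2, 3, 3, 2, 3, 2),
    s = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  df
}

# Internal cached copies (formulas never change at run time).
.aa <- local({
  df <- NULL
  function() {
    if (is.null(df)) df <<- amino_acid_formulas()
    df
  }
})

#' Names of the 20 canonical amino acids
#'
#' @return Character vector of three-letter codes in the fixed column order
#'   used throughout the package (alphabetical by three-letter code).
#' @export
aa_names <- function() .aa()$aa

#' Carbon oxidation state of each amino acid
#'
#' Computed from the elemental formulas rather than transcribed from a
#' table, so the per-amino-acid values and whole-formula arithmetic can
#' never drift apart.
#'
#' @return Named numeric vector of Zc for the 20 amino acids.
#' @examples
#' amino_acid_zc()[["Gly"]]  # +1
#' @export
amino_acid_zc <- function() {
  df <- .aa()
  z <- (-df$h + 3 * df$n + 2 * df$o + 2 * df$s) / df$c
  names(z) <- df$aa
  z
}
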