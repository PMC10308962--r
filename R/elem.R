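#' Construct an elemental formula
#'
#' A light container for a CcHhNnOoSs formula with a formal charge. Element
#' counts may be fractional (mean compositions of proteomes are fractional
#' by nature).
#'
#' @param c,h,n,o,s Non-negative element counts.
#' @param z Formal charge (default 0); ignored by [zc_formula()].
#' @return An object of class `elem_formula`: a named numeric vector with
#'   components `c`, `h`, `n`, `o`, `s`, `z`.
#' @examples
#' elemental_formula(c = 2, h = 5, n = 1, o = 2)  # glycine
#' @export
elemental_formula <- function(c = 0, h = 0, n = 0, o = 0, s = 0, z = 0) {
  x <- c(c = c, h = h, n = n, o = o, s = s, z = z)
  if (any(!is.finite(x))) stop("elemental formula entries must be finite")
  if (any(x[c("c", "h", "n", "o", "s")] < 0))
    stop("element counts must be non-negative")
  if (all(x[c("c", "h", "n", "o", "s")] == 0))
    stop("formula must contain at least one atom")
  structure(x, class = "elem_formula")
}

#' @export
print.elem_formula <- function(x, ...) {
  el <- c("C", "H", "N", "O", "S")
  cnt <- unclass(x)[c("c", "h", "n", "o", "s")]
  keep <- cnt > 0
  cat(paste0(el[keep], ifelse(cnt[keep] == 1, "", format(cnt[keep])),
             collapse = ""),
      if (x[["z"]] != 0) sprintf(" (charge %+g)", x[["z"]]), "\n", sep = "")
  invisible(x)
}

#' Average oxidation state of carbon
#'
#' Zc = (-h + 3n + 2o + 2s) / c for a composition CcHhNnOoSs. The formal
#' charge does not enter the metric.
#'
#' @param f An [elemental_formula()], or anything coercible to a numeric
#'   vector with named components `c`, `h`, `n`, `o`, `s`.
#' @return Dimensionless Zc.
#' @examples
#' zc_formula(elemental_formula(c = 2, h = 5, n = 1, o = 2))  # glycine, +1
#' zc_formula(elemental_formula(c = 3, h = 7, n = 1, o = 2))  # alanine, 0
#' @export
zc_formula <- function(f) {
  f <- unclass(f)
  if (f[["c"]] <= 0) stop("Zc is undefined for a formula with no carbon")
  (-f[["h"]] + 3 * f[["n"]] + 2 * f[["o"]] + 2 * f[["s"]]) / f[["c"]]
}

#' Construct an amino acid tally
#'
#' A tally holds per-amino-acid quantities for the 20 canonical residues.
#' Quantities may be fractional: mean compositions over proteins or species
#' require it.
#'
#' @param ... Named quantities, e.g. `aa_tally(Gly = 1, Ala = 3)`, or a
#'   single named numeric vector.
#' @return Class `aa_tally`: numeric vector of length 20 named by
#'   [aa_names()].
#' @examples
#' aa_tally(Gly = 1, Ala = 3)
#' @export
aa_tally <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.numeric(args[[1]]) &&
      !is.null(names(args[[1]]))) {
    q <- args[[1]]
  } else {
    q <- unlist(args)
  }
  out <- stats::setNames(numeric(20), aa_names())
  if (length(q)) {
    if (is.null(names(q)) || any(names(q) == ""))
      stop("amino acid quantities must be named")
    bad <- setdiff(names(q), aa_names())
    if (length(bad))
      stop("unknown amino acid(s): ", paste(bad, collapse = ", "))
    out[names(q)] <- out[names(q)] + as.numeric(q)
  }
  if (any(out < 0)) stop("amino acid quantities must be non-negative")
  structure(out, class = "aa_tally")
}

#' Total residue count of a tally
#' @param t An `aa_tally`.
#' @return Sum of the 20 quantities.
#' @export
n_residues <- function(t) sum(unclass(t))

#' @export
print.aa_tally <- function(x, ...) {
  v <- unclass(x)
  cat("amino acid tally (", format(sum(v)), " residues):\n", sep = "")
  print(v[v > 0])
  invisible(x)
}

#' Elemental formula of an amino acid tally
#'
#' Sums the free amino acid formulas; when `polymerized = TRUE`,
#' (n_residues - 1) waters are removed to give the peptide formula. Water
#' carries no carbon and its removal changes -h + 2o by zero, so Zc is
#' identical either way.
#'
#' @param t An `aa_tally` with at least one residue.
#' @param polymerized Subtract condensation waters?
#' @return An [elemental_formula()] (charge 0).
#' @examples
#' tally_formula(aa_tally(Gly = 2))                      # C4H10N2O4
#' tally_formula(aa_tally(Gly = 2), polymerized = TRUE)  # C4H8N2O3
#' @export
tally_formula <- function(t, polymerized = FALSE) {
  q <- unclass(t)
  nr <- sum(q)
  if (nr <= 0) stop("cannot compute the formula of an empty tally")
  df <- .aa()
  f <- c(c = sum(q * df$c), h = sum(q * df$h), n = sum(q * df$n),
         o = sum(q * df$o), s = sum(q * df$s))
  if (polymerized) {
    f[["h"]] <- f[["h"]] - 2 * (nr - 1)
    f[["o"]] <- f[["o"]] - (nr - 1)
  }
  elemental_formula(c = f[["c"]], h = f[["h"]], n = f[["n"]], o = f[["o"]],
                    s = f[["s"]])
}

#' Carbon oxidation state of an amino acid tally
#'
#' The carbon-weighted mean of the per-amino-acid Zc values: each residue
#' contributes in proportion to its number of carbon atoms. Algebraically
#' identical to applying [zc_formula()] to the summed formula (free or
#' polymerized).
#'
#' @param t An `aa_tally` with at least one residue.
#' @return Dimensionless Zc.
#' @examples
#' zc_tally(aa_tally(Gly = 1, Ala = 1))  # (2*1 + 3*0) / 5 = 0.4
#' @export
zc_tally <- function(t) {
  q <- unclass(t)
  if (sum(q) <= 0) stop("cannot compute Zc of an empty tally")
  df <- .aa()
  carbons <- q * df$c
  sum(carbons * amino_acid_zc()) / sum(carbons)
}

#' Normalize a tally to one residue
#'
#' Divides all quantities by the total so entries sum to 1. Zc is a ratio
#' and is unchanged by the rescaling.
#'
#' @param t An `aa_tally` with at least one residue.
#' @return An `aa_tally` whose quantities sum to 1.
#' @export
normalize_tally <- function(t) {
  q <- unclass(t)
  nr <- sum(q)
  if (nr <= 0) stop("cannot normalize an empty tally")
  structure(q / nr, class = "aa_tally")
}

#' Amino acid tally of a protein sequence
#'
#' Counts the 20 canonical residues in a one-letter sequence. Ambiguous or
#' non-standard letters (B, Z, X, J, U, O) and gap/stop characters are
#' dropped; the number dropped is attached as the `n_dropped` attribute and
#' reported via a message when `quiet = FALSE`.
#'
#' @param seq Character scalar, a protein sequence (case-insensitive).
#' @param quiet Suppress the dropped-residue message?
#' @return An `aa_tally` with attribute `n_dropped`.
#' @examples
#' sequence_tally("GGAX", quiet = TRUE)  # X dropped
#' @export
sequence_tally <- function(seq, quiet = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  df <- .aa()
  idx <- match(chars, df$letter)
  dropped <- sum(is.na(idx))
  counts <- tabulate(idx[!is.na(idx)], nbins = 20)
  if (dropped > 0 && !quiet)
    message("dropped ", dropped, " non-standard residue(s)")
  t <- structure(stats::setNames(as.numeric(counts), df$aa),
                 class = "aa_tally")
  attr(t, "n_dropped") <- dropped
  t
}

# Sum a list of tallies (internal).
sum_tallies <- function(tallies) {
  m <- vapply(tallies, unclass, numeric(20))
  structure(stats::setNames(rowSums(m), aa_names()), class = "aa_tally")
}

# Scale a tally by a scalar (internal).
scale_tally <- function(t, k) {
  structure(unclass(t) * k, class = "aa_tally")
}
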