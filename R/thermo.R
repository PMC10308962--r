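#' Default basis species for proteome formation reactions
#'
#' Six thermodynamic components: glutamine, glutamic acid, cysteine, H2O,
#' H+, and e-. Using H+ and e- (rather than O2) as components lets relative
#' stabilities be computed as a function of pH and Eh. The amino acid
#' components carry fixed log activities (Gln -3.2, Glu -4.5, Cys -3.6,
#' H2O 0); H+ activity comes from pH and e- activity from pe.
#'
#' @return data.frame with columns `species`, `c`, `h`, `n`, `o`, `s`,
#'   `charge`, `log_activity` (NA for H+ and e-, which vary).
#' @export
default_basis <- function() {
  data.frame(
    species = c("glutamine", "glutamic acid", "cysteine", "H2O", "H+", "e-"),
    c = c(5, 5, 3, 0, 0, 0),
    h = c(10, 9, 7, 2, 1, 0),
    n = c(2, 1, 1, 0, 0, 0),
    o = c(3, 4, 2, 1, 0, 0),
    s = c(0, 0, 1, 0, 0, 0),
    charge = c(0, 0, 0, 0, 1, -1),
    log_activity = c(-3.2, -4.5, -3.6, 0, NA, NA),
    stringsAsFactors = FALSE)
}

# 6x6 composition matrix (components x species) of a basis table; stops if
# singular.
basis_matrix <- function(basis) {
  A <- t(as.matrix(basis[, c("c", "h", "n", "o", "s", "charge")]))
  colnames(A) <- basis$species
  if (abs(det(A)) < 1e-9) stop("basis composition matrix is singular")
  A
}

#' Balance a formation reaction from basis species
#'
#' Solves the 6x6 linear system so that the stoichiometric coefficients on
#' the basis species reproduce the target's C, H, N, O, S and charge
#' exactly.
#'
#' @param target An [elemental_formula()] (charge honoured).
#' @param basis Basis table from [default_basis()] (or same layout).
#' @return Named numeric vector of six coefficients: target = sum(coeff *
#'   basis species).
#' @examples
#' balance_reaction(elemental_formula(h = 2), default_basis())  # H2 = 2H+ + 2e-
#' @export
balance_reaction <- function(target, basis = default_basis()) {
  A <- basis_matrix(basis)
  b <- unclass(target)[c("c", "h", "n", "o", "s", "z")]
  nu <- solve(A, as.numeric(b))
  names(nu) <- basis$species
  resid <- A %*% nu - as.numeric(b)
  if (max(abs(resid)) > 1e-9) stop("reaction balancing failed to converge")
  nu
}

#' Read / write a standard Gibbs energy table
#'
#' Column layout: species, kind (basis|proteome), c, h, n, o, s, charge,
#' dG0_J_mol (standard Gibbs energy of formation at 25 C, 1 bar; per
#' residue for proteomes), log_activity (basis species only).
#'
#' @param path CSV path.
#' @param gibbs A Gibbs table data.frame.
#' @return `read_gibbs` returns the table.
#' @export
read_gibbs <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "kind", "c", "h", "n", "o", "s", "charge",
            "dG0_J_mol", "log_activity")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("Gibbs table missing column(s): ",
                         paste(miss, collapse = ", "))
  g[, need]
}

#' @rdname read_gibbs
#' @export
write_gibbs <- function(gibbs, path) {
  utils::write.csv(gibbs, path, row.names = FALSE)
  invisible(path)
}

# Split a Gibbs table into basis (with formulas/log activities) and
# proteome parts; sanity-check the basis against species names.
gibbs_basis <- function(gibbs) {
  b <- gibbs[gibbs$kind == "basis", ]
  if (nrow(b) != 6) stop("Gibbs table must contain exactly 6 basis species")
  b
}

# Affine representation of the per-residue Gibbs energy of the formation
# reaction: dG(pH, pe) = const + RTln10 * (nu_Hplus * pH + nu_e * pe).
# Returns list(const, coef_pH, coef_pe) in J/mol per residue.
dg_affine <- function(species, gibbs, T_C = 25, target_log_activity = 0) {
  row <- gibbs[gibbs$species == species & gibbs$kind != "basis", ]
  if (nrow(row) == 0)
    stop("no Gibbs table entry for species: ", species)
  row <- row[1, ]
  basis <- gibbs_basis(gibbs)
  target <- elemental_formula(c = row$c, h = row$h, n = row$n, o = row$o,
                              s = row$s, z = row$charge)
  nu <- balance_reaction(target, basis)
  dG0r <- row$dG0_J_mol - sum(nu * basis$dG0_J_mol)
  RTln10 <- .R_GAS * (T_C + 273.15) * .LN10
  i_h <- which(basis$species == "H+")
  i_e <- which(basis$species == "e-")
  fixed <- setdiff(seq_len(6), c(i_h, i_e))
  if (anyNA(basis$log_activity[fixed]))
    stop("fixed basis species must carry log_activity values")
  const <- dG0r + RTln10 *
    (target_log_activity - sum(nu[fixed] * basis$log_activity[fixed]))
  list(const = const, coef_pH = RTln10 * nu[[i_h]],
       coef_pe = RTln10 * nu[[i_e]], nu = nu)
}

#' Electron activity (pe) from Eh
#'
#' pe = F Eh / (ln(10) R T), with Eh in volts internally.
#'
#' @param Eh_mV Redox potential in mV vs SHE.
#' @param T_C Temperature in degrees C.
#' @return pe (dimensionless).
#' @export
eh_to_pe <- function(Eh_mV, T_C = 25) {
  .FARADAY * (Eh_mV / 1000) / (.LN10 * .R_GAS * (T_C + 273.15))
}

#' Per-residue Gibbs energy of a proteome formation reaction
#'
#' The formation reaction of the per-residue proteome formula from the six
#' basis species is balanced exactly, and dG = dG0r + RT ln Q is evaluated
#' with a(H+) = 10^-pH, a(e-) = 10^-pe, fixed activities for the other
#' basis species, and unit activity for the proteome unless its table row
#' says otherwise.
#'
#' @param species Name of a non-basis entry in the Gibbs table.
#' @param gibbs Gibbs table (see [read_gibbs()]).
#' @param Eh_mV,pH Redox potential (mV vs SHE) and pH; vectorized with
#'   recycling.
#' @param T_C Temperature in degrees C (default 25).
#' @return Gibbs energy of the formation reaction in J/mol per residue.
#' @export
delta_g_per_residue <- function(species, gibbs, Eh_mV, pH, T_C = 25) {
  la <- gibbs$log_activity[gibbs$species == species &
                             gibbs$kind != "basis"][1]
  if (is.na(la)) la <- 0
  aff <- dg_affine(species, gibbs, T_C, target_log_activity = la)
  pe <- eh_to_pe(Eh_mV, T_C)
  aff$const + aff$coef_pH * pH + aff$coef_pe * pe
}

#' Water stability window
#'
#' Eh limits of liquid water at unit gas fugacity: the H2/H+ lower limit
#' and the O2/H2O upper limit. At 25 C these are -59.16 pH and
#' 1229 - 59.16 pH mV. The two limits are parallel (both Nernstian in pH).
#'
#' @param pH pH value(s).
#' @param T_C Temperature in degrees C (the 1229 mV O2/H2O standard
#'   potential is the 25 C value).
#' @return data.frame with columns `Eh_min_mV`, `Eh_max_mV`.
#' @examples
#' water_limits(7)  # about -414.1 and 814.9 mV
#' @export
water_limits <- function(pH, T_C = 25) {
  s <- nernst_slope(T_C)
  data.frame(Eh_min_mV = s * pH, Eh_max_mV = 1229 + s * pH)
}

#' Relative stability grid of proteomes on the Eh-pH plane
#'
#' At every grid node the proteome with the lowest per-residue Gibbs energy
#' of formation from the basis species is the "least unstable" (winner).
#' Exact ties are broken by the lowest input index.
#'
#' @param proteomes Character vector (>= 2) of proteome species names in
#'   the Gibbs table.
#' @param gibbs Gibbs table containing the 6 basis species and all
#'   `proteomes`.
#' @param Eh_range_mV,pH_range Axis limits, e.g. `c(-600, 1000)` and
#'   `c(0, 14)`.
#' @param n_Eh,n_pH Grid resolution (default 256 x 256).
#' @param T_C Temperature in degrees C.
#' @return A `stability_grid`: list with `Eh_mV`, `pH` (axes), `winner`
#'   (n_Eh x n_pH integer matrix of indices into `proteomes`), `dG_min`
#'   (J/mol per residue), `in_water` (logical mask), `proteomes`, `zc`
#'   (per-proteome Zc from the table formulas), `T_C`.
#' @export
stability_grid <- function(proteomes, gibbs,
                           Eh_range_mV = c(-600, 1000),
                           pH_range = c(0, 14),
                           n_Eh = 256, n_pH = 256, T_C = 25) {
  if (length(proteomes) < 2) stop("need at least two proteomes")
  if (n_Eh < 2 || n_pH < 2) stop("grid must be at least 2x2")
  Eh <- seq(Eh_range_mV[1], Eh_range_mV[2], length.out = n_Eh)
  pH <- seq(pH_range[1], pH_range[2], length.out = n_pH)
  pe <- eh_to_pe(Eh, T_C)
  affs <- lapply(proteomes, dg_affine, gibbs = gibbs, T_C = T_C)
  dG <- array(NA_real_, dim = c(n_Eh, n_pH, length(proteomes)))
  for (k in seq_along(affs)) {
    a <- affs[[k]]
    dG[, , k] <- a$const + outer(a$coef_pe * pe, a$coef_pH * pH, `+`)
  }
  winner <- apply(dG, c(1, 2), which.min)   # ties -> lowest index
  dG_min <- apply(dG, c(1, 2), min)
  wl <- water_limits(pH, T_C)
  in_water <- outer(Eh, wl$Eh_min_mV, `>=`) & outer(Eh, wl$Eh_max_mV, `<=`)
  zc <- vapply(proteomes, function(sp) {
    row <- gibbs[gibbs$species == sp & gibbs$kind != "basis", ][1, ]
    zc_formula(elemental_formula(c = row$c, h = row$h, n = row$n,
                                 o = row$o, s = row$s, z = row$charge))
  }, numeric(1))
  structure(list(Eh_mV = Eh, pH = pH, winner = winner, dG_min = dG_min,
                 in_water = in_water, proteomes = proteomes, zc = zc,
                 T_C = T_C),
            class = "stability_grid")
}

#' @export
print.stability_grid <- function(x, ...) {
  cat(sprintf("stability grid: %d proteomes on %d x %d nodes, Eh %g..%g mV, pH %g..%g\n",
              length(x$proteomes), length(x$Eh_mV), length(x$pH),
              min(x$Eh_mV), max(x$Eh_mV), min(x$pH), max(x$pH)))
  tab <- table(factor(x$proteomes[x$winner], levels = x$proteomes))
  print(tab)
  invisible(x)
}

#' Step profile of winner Zc along Eh at fixed pH
#'
#' Extracts, at the grid column nearest to `pH`, the ordered Eh segments
#' over which each proteome is the winner, with that proteome's Zc.
#'
#' @param grid A [stability_grid()] result.
#' @param pH pH at which to take the cross-section (must lie within the
#'   grid's pH range).
#' @param water_only Restrict to the water stability window?
#' @return data.frame with one row per segment: `Eh_from_mV`, `Eh_to_mV`,
#'   `proteome`, `zc`.
#' @export
zc_vs_eh_profile <- function(grid, pH, water_only = FALSE) {
  if (pH < min(grid$pH) || pH > max(grid$pH))
    stop("pH outside the grid range")
  j <- which.min(abs(grid$pH - pH))
  w <- grid$winner[, j]
  Eh <- grid$Eh_mV
  keep <- rep(TRUE, length(Eh))
  if (water_only) keep <- grid$in_water[, j]
  w <- w[keep]; Eh <- Eh[keep]
  if (!length(w)) stop("no grid nodes inside the water window at this pH")
  r <- rle(w)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  data.frame(Eh_from_mV = Eh[starts], Eh_to_mV = Eh[ends],
             proteome = grid$proteomes[r$values],
             zc = unname(grid$zc[r$values]))
}

#' Export a stability grid to CSV
#'
#' Writes the node table (Eh_mV, pH, winner, dG_min_J_mol, in_water) and,
#' optionally, a boundary-segment table of winner changes along Eh.
#'
#' @param grid A [stability_grid()].
#' @param path Node CSV path.
#' @param boundary_path Optional boundary CSV path.
#' @return `path`, invisibly.
#' @export
write_stability_grid <- function(grid, path, boundary_path = NULL) {
  nodes <- expand.grid(Eh_mV = grid$Eh_mV, pH = grid$pH,
                       KEEP.OUT.ATTRS = FALSE)
  nodes$winner <- grid$proteomes[as.vector(grid$winner)]
  nodes$dG_min_J_mol <- as.vector(grid$dG_min)
  nodes$in_water <- as.vector(grid$in_water)
  utils::write.csv(nodes, path, row.names = FALSE)
  if (!is.null(boundary_path)) {
    segs <- do.call(rbind, lapply(seq_along(grid$pH), function(j) {
      w <- grid$winner[, j]
      chg <- which(diff(w) != 0)
      if (!length(chg)) return(NULL)
      data.frame(pH = grid$pH[j],
                 Eh_boundary_mV = (grid$Eh_mV[chg] + grid$Eh_mV[chg + 1]) / 2,
                 from = grid$proteomes[w[chg]],
                 to = grid$proteomes[w[chg + 1]])
    }))
    if (is.null(segs))
      segs <- data.frame(pH = numeric(), Eh_boundary_mV = numeric(),
                         from = character(), to = character())
    utils::write.csv(segs, boundary_path, row.names = FALSE)
  }
  invisible(path)
}

#' Per-residue elemental formula of a tally
#'
#' The polymerized (peptide) formula divided by the number of residues:
#' the per-residue composition used for proteome entries in the Gibbs
#' table. Charge defaults to 0 (neutral ionization for stability
#' purposes).
#'
#' @param t An `aa_tally`.
#' @return An [elemental_formula()] with fractional counts.
#' @export
residue_formula <- function(t) {
  f <- unclass(tally_formula(t, polymerized = TRUE))
  nr <- n_residues(t)
  elemental_formula(c = f[["c"]] / nr, h = f[["h"]] / nr, n = f[["n"]] / nr,
                    o = f[["o"]] / nr, s = f[["s"]] / nr)
}
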