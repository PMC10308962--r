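# Shared fixture: 4-taxon synthetic DB and its demonstration Gibbs table.
thermo_db <- tiny_db(4)
thermo_gibbs <- make_gibbs_fixture(thermo_db)
thermo_prot <- thermo_gibbs$species[thermo_gibbs$kind == "proteome"]

test_that("reaction balancing solves hand-derived stoichiometries exactly", {
  basis <- default_basis()
  # a basis member balances to itself
  nu <- balance_reaction(elemental_formula(c = 5, h = 10, n = 2, o = 3),
                         basis)
  expect_equal(unname(nu), c(1, 0, 0, 0, 0, 0), tolerance = 1e-12)
  # H2 = 2 H+ + 2 e-
  expect_equal(unname(balance_reaction(elemental_formula(h = 2), basis)),
               c(0, 0, 0, 0, 2, 2), tolerance = 1e-12)
  # O2 = 2 H2O - 4 H+ - 4 e-
  expect_equal(unname(balance_reaction(elemental_formula(o = 2), basis)),
               c(0, 0, 0, 2, -4, -4), tolerance = 1e-12)
})

test_that("balanced coefficients recompose the target elements and charge", {
  basis <- default_basis()
  A <- t(as.matrix(basis[, c("c", "h", "n", "o", "s", "charge")]))
  targets <- list(
    elemental_formula(c = 3, h = 7, n = 1, o = 2),          # alanine
    elemental_formula(c = 2, h = 5, n = 1, o = 2, z = 1),   # charged
    elemental_formula(c = 4.1, h = 7.9, n = 1.2, o = 2.3, s = 0.04))
  for (tg in targets) {
    nu <- balance_reaction(tg, basis)
    expect_equal(as.numeric(A %*% nu),
                 as.numeric(unclass(tg)[c("c", "h", "n", "o", "s", "z")]),
                 tolerance = 1e-9)
  }
  singular <- basis
  singular[5, c("c", "h", "n", "o", "s", "charge")] <-
    singular[4, c("c", "h", "n", "o", "s", "charge")]
  expect_error(balance_reaction(elemental_formula(h = 2), singular),
               "singular")
})

test_that("a target identical to a basis species at its activity has dG = 0", {
  g <- thermo_gibbs
  gln <- g[g$species == "glutamine", ]
  gln$species <- "glutamine copy"
  gln$kind <- "proteome"
  g <- rbind(g, gln)  # keeps dG0 and log_activity -3.2
  expect_equal(delta_g_per_residue("glutamine copy", g, Eh_mV = 137,
                                   pH = 5.5), 0, tolerance = 1e-9)
  expect_error(delta_g_per_residue("nonexistent", thermo_gibbs, 0, 7),
               "nonexistent")
})

test_that("dG is affine in pH and in Eh, with the algebraic electron slope", {
  sp <- thermo_prot[1]
  ph <- seq(2, 12, 2)
  d_ph <- delta_g_per_residue(sp, thermo_gibbs, Eh_mV = 100, pH = ph)
  expect_equal(diff(d_ph, differences = 2), rep(0, length(ph) - 2),
               tolerance = 1e-8)
  eh <- seq(-400, 400, 100)
  d_eh <- delta_g_per_residue(sp, thermo_gibbs, Eh_mV = eh, pH = 7)
  expect_equal(diff(d_eh, differences = 2), rep(0, length(eh) - 2),
               tolerance = 1e-8)
  # raising Eh by one Nernst-slope magnitude shifts pe by exactly 1, so dG
  # changes by nu_e * RT ln10 (oracle from the reaction quotient algebra)
  row <- thermo_gibbs[thermo_gibbs$species == sp, ]
  nu <- balance_reaction(
    elemental_formula(c = row$c, h = row$h, n = row$n, o = row$o,
                      s = row$s, z = row$charge), default_basis())
  RTln10 <- 8.31446 * 298.15 * log(10)
  step <- abs(nernst_slope(25))
  expect_equal(delta_g_per_residue(sp, thermo_gibbs, 100 + step, 7) -
                 delta_g_per_residue(sp, thermo_gibbs, 100, 7),
               nu[["e-"]] * RTln10, tolerance = 1e-6)
})

test_that("water stability limits are parallel Nernstian lines", {
  expect_equal(unlist(water_limits(0)), c(Eh_min_mV = 0, Eh_max_mV = 1229),
               tolerance = 1e-6)
  wl7 <- water_limits(7)
  expect_equal(wl7$Eh_min_mV, -414.1, tolerance = 1e-3)
  expect_equal(wl7$Eh_max_mV, 814.9, tolerance = 1e-3)
  wl <- water_limits(seq(0, 14, 0.5))
  expect_equal(diff(range(wl$Eh_max_mV - wl$Eh_min_mV)), 0)
})

test_that("stability grid winners follow the lowest dG with index tie-break", {
  # two identical proteomes: index 1 wins everywhere by tie-break
  g <- thermo_gibbs
  twin <- g[g$species == thermo_prot[1], ]
  twin$species <- "twin"
  g2 <- rbind(g, twin)
  gr <- stability_grid(c(thermo_prot[1], "twin"), g2, n_Eh = 16, n_pH = 16)
  expect_true(all(gr$winner == 1))
  prof <- zc_vs_eh_profile(gr, 7)
  expect_equal(nrow(prof), 1)
  expect_error(stability_grid(thermo_prot[1], thermo_gibbs), "two")
  expect_error(zc_vs_eh_profile(gr, 99), "outside")
})

test_that("traced field boundaries match the analytic slope to <1%", {
  gr <- stability_grid(thermo_prot[1:2], thermo_gibbs,
                       Eh_range_mV = c(-600, 400), pH_range = c(2, 12),
                       n_Eh = 256, n_pH = 256)
  # trace the boundary: winner switch along Eh in every pH column
  b <- vapply(seq_along(gr$pH), function(j) {
    w <- gr$winner[, j]
    i <- which(diff(w) != 0)
    if (length(i) != 1) return(NA_real_)
    (gr$Eh_mV[i] + gr$Eh_mV[i + 1]) / 2
  }, numeric(1))
  ok <- !is.na(b)
  expect_gt(sum(ok), 200)
  traced <- stats::coef(stats::lm(b[ok] ~ gr$pH[ok]))[[2]]
  # analytic slope: -(d nu_H+ / d nu_e-) * ln10 RT / F
  nus <- lapply(thermo_prot[1:2], function(sp) {
    row <- thermo_gibbs[thermo_gibbs$species == sp, ]
    balance_reaction(elemental_formula(c = row$c, h = row$h, n = row$n,
                                       o = row$o, s = row$s, z = row$charge),
                     default_basis())
  })
  dH <- nus[[2]][["H+"]] - nus[[1]][["H+"]]
  dE <- nus[[2]][["e-"]] - nus[[1]][["e-"]]
  analytic <- nernst_slope(25) * dH / dE
  expect_equal(traced, analytic, tolerance = 0.01)
})

test_that("winner Zc steps upward along Eh and profiles collapse under Eh7", {
  gr <- stability_grid(thermo_prot, thermo_gibbs,
                       Eh_range_mV = c(-700, 1000), pH_range = c(0, 14),
                       n_Eh = 256, n_pH = 141)
  prof7 <- zc_vs_eh_profile(gr, 7, water_only = TRUE)
  expect_true(all(diff(prof7$zc) > 0))
  expect_lte(nrow(prof7), length(thermo_prot))
  # same winner sequence at pH 5 and 9; breakpoints line up after Eh -> Eh7
  eh_step <- diff(gr$Eh_mV[1:2])
  for (ph in c(5, 9)) {
    prof <- zc_vs_eh_profile(gr, ph, water_only = TRUE)
    expect_equal(prof$proteome, prof7$proteome)
    shifted <- eh_to_eh7(utils::head(prof$Eh_to_mV, -1), ph)
    expect_lt(max(abs(shifted - utils::head(prof7$Eh_to_mV, -1))),
              1.5 * eh_step)
  }
})

test_that("shifting basis energies re-ranks proteomes but a common proteome offset does not", {
  gr0 <- stability_grid(thermo_prot, thermo_gibbs, n_Eh = 32, n_pH = 32)
  # common constant on every proteome dG0: same winner everywhere
  g1 <- thermo_gibbs
  g1$dG0_J_mol[g1$kind == "proteome"] <-
    g1$dG0_J_mol[g1$kind == "proteome"] + 5000
  gr1 <- stability_grid(thermo_prot, g1, n_Eh = 32, n_pH = 32)
  expect_equal(gr1$winner, gr0$winner)
  # constant on a basis species enters each proteome via its own
  # stoichiometry: winners change
  g2 <- thermo_gibbs
  g2$dG0_J_mol[g2$species == "H2O"] <-
    g2$dG0_J_mol[g2$species == "H2O"] + 2000
  gr2 <- stability_grid(thermo_prot, g2, n_Eh = 32, n_pH = 32)
  expect_false(identical(gr2$winner, gr0$winner))
})

test_that("grid and boundary exports write well-formed CSVs", {
  gr <- stability_grid(thermo_prot[1:2], thermo_gibbs, n_Eh = 8, n_pH = 8)
  nodes_csv <- tempfile(fileext = ".csv")
  bnd_csv <- tempfile(fileext = ".csv")
  write_stability_grid(gr, nodes_csv, bnd_csv)
  nodes <- utils::read.csv(nodes_csv)
  expect_equal(nrow(nodes), 64)
  expect_setequal(unique(nodes$winner), thermo_prot[1:2])
  bnd <- utils::read.csv(bnd_csv)
  expect_true(all(c("pH", "Eh_boundary_mV") %in% names(bnd)))
})

test_that("Gibbs tables round-trip through CSV", {
  csv <- tempfile(fileext = ".csv")
  write_gibbs(thermo_gibbs, csv)
  g2 <- read_gibbs(csv)
  expect_equal(g2$dG0_J_mol, thermo_gibbs$dG0_J_mol)
  expect_equal(g2$species, thermo_gibbs$species)
})
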