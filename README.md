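# zc16S

Microbial communities live along redox gradients — sediment depth
profiles, hot-spring outflows, Winogradsky columns — and the protein
sequences their genomes encode may be chemically shaped by those
conditions over evolutionary time. **zc16S** is an R package for testing
that hypothesis. It estimates the average **carbon oxidation state
(Z<sub>C</sub>)** of *community reference proteomes* from 16S rRNA gene
taxonomic classifications, corrects field redox potentials to pH 7
(**Eh7**) with the Nernst slope, and provides the regression,
metastable-equilibrium, and sign-test machinery needed to ask whether
Z<sub>C</sub> tracks Eh7 within and across many survey datasets.

It is written for microbial ecologists and geobiologists who have RDP
Classifier output and sample metadata (Eh, pH, temperature, O₂) and want
a tested, reproducible path from those files to per-dataset slopes,
Eh–pH stability diagrams, and binomial meta-analysis tables.

## The quantities at the core

For a composition C<sub>c</sub>H<sub>h</sub>N<sub>n</sub>O<sub>o</sub>S<sub>s</sub>,

    Zc = (-h + 3n + 2o + 2s) / c

computed for amino acid tallies as the carbon-weighted mean of
per-amino-acid values. Field Eh measurements are compared across samples
after correction to pH 7,

    Eh7 = Eh + (dEh/dpH) * (7 - pH),   dEh/dpH = -ln(10) R T / F
                                                (-59.16 mV/pH at 25 °C),

and per-dataset associations are OLS slopes of Z<sub>C</sub> on Eh7 (in
1/V) reported as *m* ± MOE₉₅, tallied across datasets with exact
one-sided binomial tests against a 50% chance of a positive slope. A
metastable-equilibrium module ranks per-residue proteome formulas by
Gibbs energy of formation from six basis species (Gln, Glu, Cys, H₂O,
H⁺, e⁻) on an Eh–pH grid, and an incomplete-equilibrium simulation mixes
the resulting equilibrium Z<sub>C</sub> profile with random biological
variation (20%/80% weights).

## Worked example

Everything below runs without external data: the package ships a
synthetic-survey generator that emulates the inputs the pipeline expects.

```r
library(zc16S)

## parse RDP fixed-rank output (bundled demo file)
fx <- system.file("extdata", "demo.fixrank.tsv", package = "zc16S")
read_rdp_fixrank(fx)
#>   read_id   domain lowest_rank         lowest_taxon confidence
#> 1 read001 Bacteria       genus Escherichia/Shigella       0.95
#> 2 read002 Bacteria       genus                  Gp6       0.88
#> 3 read003 Bacteria       class        Cyanobacteria       0.95
#> 4 read006  Archaea       genus        Methanococcus       0.91
#> 5 read007 Bacteria       order        Clostridiales       0.97
#> 6 read008 Bacteria       genus Escherichia/Shigella       0.93
```

Two reads were dropped (one classified only to domain, one chloroplast).
`map_taxa()` would next resolve the RDP names against a reference
database, applying the built-in manual mappings (Escherichia/Shigella →
Escherichia, Gp6 → Luteitalea, class Cyanobacteria → phylum
Cyanobacteria, ...).

```r
## a synthetic reference database of 4 taxa with evenly spaced Zc
db <- make_reference_db(n_taxa = 4, zc_low = -0.25, zc_high = 0.05,
                        proteins_per_species = 25, seed = 1)
db_zc(db)[db$rank == "genus", c("rank", "taxon", "Zc")]
#>    rank    taxon    Zc
#> 1 genus Taxon_01 -0.25
#> 3 genus Taxon_02 -0.15
#> 5 genus Taxon_03 -0.05
#> 7 genus Taxon_04  0.05

## generate a 3-dataset survey (20 samples each, true slope 0.1/V,
## Zc noise 0.01, 10,000 reads/sample) and analyze it from the files
out <- tempfile()
make_survey(survey_spec(n_datasets = 3, samples_per_dataset = 20,
                        true_slope = 0.1, seed = 42), db, out_dir = out)
res <- analyze_survey_dir(out)
res$fits[, c("dataset", "environment", "N", "m", "moe95", "r")]
#>      dataset      environment  N      m  moe95     r
#> 1 dataset_01             soil 20 0.0979 0.0353 0.808
#> 2 dataset_02         sediment 20 0.1222 0.0288 0.903
#> 3 dataset_03 river & seawater 20 0.1018 0.0399 0.784
```

Each dataset's 95% CI (m ± moe95) covers the generator's true slope of
0.1/V: the pipeline — fixrank parsing, taxon mapping, community
assembly, the Eh7 correction (each sample's metadata carries raw Eh and
a random pH, so the correction is genuinely exercised), and regression —
recovers the planted signal. `tally_table(res$fits)` then produces the
per-environment binomial sign-test table; with the published
local-scale counts it reproduces the published P values, e.g.
`binom_tail(12, 10)` = 0.019 (soil) and `binom_tail(68, 50)` = 0.00007
(all bacterial datasets).

For the thermodynamic layer, `make_gibbs_fixture(db)` builds a
demonstration Gibbs table, `stability_grid()` computes the Eh–pH diagram
(winner Z<sub>C</sub> steps upward with Eh), `zc_vs_eh_profile()`
extracts step profiles that collapse across pH when replotted against
Eh7, and `run_equilibrium_sim()` reproduces the 20%-equilibrium mixture
slope (0.665/V × 0.2 = 0.133/V against a flat random pool).

A thin command-line wrapper with `zc`, `eh7`, `community`, `regress`,
`tally`, `stability`, `simulate`, and `synth` subcommands is installed at
`system.file("cli", "zc16S.R", package = "zc16S")`.

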