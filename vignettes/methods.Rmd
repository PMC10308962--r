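---
title: "Methods: linking redox potential to the carbon oxidation state of community reference proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking redox potential to the carbon oxidation state of community reference proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zc16S)
```

## The scientific question

Microbial genomes encode proteins whose elemental composition may, over
evolutionary time, drift toward a low-energy state for the redox conditions
the lineage inhabits. zc16S implements the quantitative machinery for
testing that idea with 16S rRNA survey data: it estimates the average
carbon oxidation state of the proteins a community would express if every
genome contributed equally, and asks whether that quantity co-varies with
the redox potential of the habitat.

## Carbon oxidation state

For a molecule with composition $\mathrm{C}_c\mathrm{H}_h\mathrm{N}_n
\mathrm{O}_o\mathrm{S}_s$ the average oxidation state of carbon is

$$Z_\mathrm{C} = \frac{-h + 3n + 2o + 2s}{c},$$

a dimensionless ratio that ignores formal charge. For amino acid tallies
the package computes $Z_\mathrm{C}$ as the carbon-weighted mean of
per-amino-acid values; this is algebraically identical to applying the
formula to the summed elemental composition, whether or not condensation
water is removed, because water carries no carbon and contributes
$-h + 2o = 0$. Both routes are implemented independently and the test
suite holds them to within $10^{-12}$ of each other on random fractional
tallies. Ambiguous residues (B, Z, X, J, U, O) in input sequences are
dropped with a recorded count: they are rare, carry no defined single
formula, and excluding them biases a mean composition far less than any
imputation would.

## Reference proteomes and community assembly

A species reference proteome is the arithmetic mean amino acid composition
over its protein sequences (sum divided by the number of sequences), so
short and long proteins count equally. Species with fewer than 500
sequences are excluded by default — enough sequences that one annotation
artifact cannot dominate the mean — but the threshold is configurable so
desk-scale fixtures can use small proteomes. Higher ranks (genus through
phylum) are unweighted means over member species, which keeps large
sequenced pan-genomes from dominating a genus. Both properties are tested:
duplicating every protein of one species changes no higher-rank proteome.

Per-sample communities come from RDP Classifier fixed-rank output. Each
read is reduced to its deepest named rank between genus and phylum; reads
classified only to root or domain, or assigned to Chloroplast or
Eukaryota, are dropped. Taxon names are matched to the reference database
by rank and name, with a built-in manual mapping table for known
RDP-to-NCBI disagreements (including cross-level moves such as class
Cyanobacteria to phylum Cyanobacteria); unmatched taxa are counted,
reported as a percentage, and omitted. The community reference proteome is
then the count-weighted mean composition, so doubling sequencing depth
changes nothing. Samples with fewer than 100 usable classified reads in a
domain are excluded (exactly 100 is kept), and an archaeal dataset
retaining fewer than four samples is dropped entirely. Confidence
re-thresholding is off by default — the classifier is assumed to have
applied its own 80% cutoff upstream — but can be re-enabled per file. The
100-read cutoff is applied to reads with usable lowest-level assignments;
applying it after database matching instead would make sample retention
depend on database coverage, which we judged less faithful to the intent
of a depth filter.

## The Eh7 correction and oxygen units

Electrode potentials depend on pH with the theoretical Nernst slope
$\mathrm{d}Eh/\mathrm{d}\mathrm{pH} = -\ln(10)RT/F$ (−59.16 mV per pH
unit at 25 °C), so measured Eh values are corrected to pH 7:

$$Eh_7 = Eh + \frac{\mathrm{d}Eh}{\mathrm{d}\mathrm{pH}}(7 -
\mathrm{pH}).$$

Missing pH or temperature defaults to 7 and 25 °C, which leaves Eh
unchanged in the pH case. Millivolts are the internal unit; regressions
take Eh7 in volts so slopes print in 1/V. Oxygen concentrations in mg/L
convert to µM through the molar mass of O$_2$ (31.9988 g/mol). Percent
saturation converts through a Henry's-law constant at the sample
temperature times an atmospheric O$_2$ partial pressure of 0.2128 bar;
the default correlation is a van't Hoff form anchored at
$K_H = 1.2\times10^{-3}$ mol L$^{-1}$ bar$^{-1}$ (298.15 K) with
$-\mathrm{d}\ln K_H/\mathrm{d}(1/T) = 1700$ K, compilation values for
O$_2$, valid for 0–50 °C. The correlation is an argument, not a constant,
so an alternative temperature dependence can be swapped in; the tests pin
only properties every valid correlation shares (about 258 µM at 25 °C
within 5%, monotone decrease with temperature).

## Metastable-equilibrium stability diagrams

Proteins are thermodynamically unstable in ambient water; what can be
ranked is their relative instability. The package writes, for each
per-residue proteome formula, a formation reaction from six basis species
— glutamine, glutamic acid, cysteine, H$_2$O, H$^+$, and e$^-$ — by
solving the 6×6 linear system that conserves C, H, N, O, S, and charge
exactly (residuals are checked at $10^{-9}$). Using H$^+$ and e$^-$ as
components makes pH and Eh the natural variables. The Gibbs energy of the
reaction is

$$\Delta G = \Delta G^\circ_r + RT\ln Q,$$

with fixed activities for the amino acid components ($\log a$: Gln −3.2,
Glu −4.5, Cys −3.6, H$_2$O 0), $a_{\mathrm{H}^+} = 10^{-\mathrm{pH}}$,
and $a_{e^-} = 10^{-\mathrm{pe}}$ where $\mathrm{pe} = F\,Eh/(\ln(10)RT)$.
At each node of an Eh–pH grid the proteome with the lowest per-residue
$\Delta G$ is the "least unstable" winner; exact ties go to the lowest
input index, deterministically. Because $\Delta G$ is affine in pH and pe,
field boundaries are straight lines with slope
$-(\Delta\nu_{\mathrm{H}^+}/\Delta\nu_{e^-})\ln(10)RT/F$; for neutral
per-residue formulas charge balance forces
$\nu_{\mathrm{H}^+} = \nu_{e^-}$, so boundaries are exactly Nernstian and
$Z_\mathrm{C}$–Eh profiles taken at different pH collapse onto one curve
under the Eh7 transform. The tests exploit both facts as analytic oracles.

Standard Gibbs energies of formation are data, not computation: the
group-additivity machinery that produced the published per-residue values
is a separate project, so the package consumes a Gibbs table (CSV) and
ships a generator for a synthetic demonstration table. That generator
chooses proteome $\Delta G^\circ_f$ values so the stability fields at
pH 7 succeed one another, in order of increasing $Z_\mathrm{C}$, at evenly
spaced Eh across the water window; the electron stoichiometry alone then
guarantees the stepwise increase of winner $Z_\mathrm{C}$ with Eh. Its
basis-species energies are synthetic demonstration values of literature
magnitude, and per-residue charge defaults to zero (ionization treatments
live in the upstream parameter set, out of scope here). The default grid
is 256 nodes per axis over pH 0–14 and Eh −0.6 to +1.0 V, which resolves
boundary slopes to better than 1% in the tests; diagrams are computed at
25 °C.

## Incomplete equilibrium: the mixing simulation

Real communities are not at metastable equilibrium. The simulation
quantifies how much signal survives dilution by random biological
variation: sample the equilibrium $Z_\mathrm{C}$–Eh7 step profile at
equally spaced Eh7 points, draw random taxon $Z_\mathrm{C}$ values from a
reference pool until an assignment has OLS slope within ±0.005/V of zero
(an order of magnitude below the smallest slope of scientific interest
here), and form the weighted mixture $w\,z_{eq} + (1-w)\,z_{rand}$ with
$w = 0.20$. Because OLS slopes are linear in the response, the mixture
slope is exactly $w$ times the equilibrium slope plus $(1-w)$ times the
random slope — with an equilibrium profile scaled to 0.665/V this yields
0.133/V, the size of the largest slopes seen in local surveys. The random
draw is seeded and the linearity identity is tested to $10^{-12}$.

## Statistics

Per-dataset associations are ordinary least squares of community
$Z_\mathrm{C}$ on Eh7 (volts), reported as slope ± MOE$_{95}$, the
half-width of the 95% confidence interval computed from the t quantile
with $N-2$ degrees of freedom (the t rather than normal quantile is a
deliberate choice; at survey sample sizes the difference is negligible,
and it degrades gracefully to a zero margin on exact fits). A fit is
"significant" when that interval excludes zero. Dataset outcomes are
combined with exact one-sided binomial tests: with $k$ positive slopes in
$n$ datasets, $P = \Pr(X \ge k)$ for $X \sim \mathrm{Bin}(n, 1/2)$.
P values print with three decimals at or above $10^{-3}$ and five
decimals below, matching published usage. Group comparisons of
$Z_\mathrm{C}$ use the pooled-variance two-sided t test.

## The synthetic survey generator

The generator exists so every stage — fixrank parsing, mapping, depth
filters, the Eh7 correction, regression, and tallying — can be exercised
end to end with known truth. It emulates the structure the analysis
assumes: community $Z_\mathrm{C}$ linear in Eh7 plus Gaussian noise,
induced mechanistically by mixing a reduced endmember taxon and an
oxidized endmember taxon, mirroring the redox-driven shift between
reduced-proteome and oxidized-proteome lineages seen along natural
gradients. Reference taxa are Gly/Leu mixtures (endmember $Z_\mathrm{C}$
+1 and −1) whose mixing fraction has a closed-form inverse,
$g = 3(z+1)/(2(z+2))$; a per-protein length is searched so integer
residue counts realize each target to $10^{-7}$. Default survey
conditions are 20 samples per dataset (a common inclusion threshold for
survey compilations), a 600 mV Eh7 span, slope 0.1/V (the order of the
largest local-scale slopes), $Z_\mathrm{C}$ noise 0.01, and 10,000
classified reads per sample (a typical post-subsampling depth). Each
sample's pH is drawn on 4–9 and its raw Eh back-computed through the
inverse Nernst correction, so the pipeline's own correction is on the
tested path.

Counts are multinomial draws around the exact mixing fraction; an "exact"
mode rounds instead, and — when the slope is nonzero — back-computes the
sample's Eh7 from the realized integer-count $Z_\mathrm{C}$ so that
(Eh7, $Z_\mathrm{C}$) lie exactly on the generator line. That is what
makes noise-free parameter recovery to $10^{-6}$ a meaningful test
despite integer read counts; with multinomial counts the count noise is
simply part of the per-sample scatter. What the generator does not
emulate: sequencing error, chimeras, primer bias, phylogenetic structure
in composition, unmapped taxa, or heteroscedastic noise. Passing tests
therefore demonstrate correctness of the estimator chain, not robustness
of the science to the biases of real amplicon data.

## Validation sizes and numerical choices

The recovery checks run 200 replicates per true slope (0, 0.016, and
0.1/V) for confidence-interval coverage, asserted within 90–99%, and 500
replicates for the type-I error of the significance filter, asserted at
5% ± 2%; each replicate is one 20-sample dataset. These sizes put the
Monte Carlo standard error near one percentage point, small enough to
detect a miscalibrated interval while keeping the whole suite quick on a
single CPU. Other numerical choices: reaction-balancing residuals are
rejected above $10^{-9}$; the Eh7 round-trip is exact to $10^{-9}$ mV;
stability ties break to the lowest index; the near-zero pool search is
seeded and errors out (rather than loosening itself) if the tolerance is
unreachable in the draw budget.

## Known limitations

Reference proteomes carry no expression information, so community
$Z_\mathrm{C}$ here is a genomic potential, not a measured phenotype; the
metaproteome module (spectral-count weighting) exists precisely to
compare the two. The stability model ranks only the supplied proteomes —
amino acids and smaller metabolites are excluded by construction — and
its demonstration Gibbs table is synthetic: scientific use requires a
user-supplied parameter set. The Henry correlation is a two-parameter
fit adequate for 0–50 °C air-saturation work, not a seawater-grade
solubility model (no salinity dependence). And the binomial layer treats
datasets as exchangeable trials, ignoring differences in size and power,
exactly as in the analysis tradition it reproduces.
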