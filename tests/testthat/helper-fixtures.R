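# Random tally with k distinct amino acids and fractional quantities.
random_tally <- function(k = 5) {
  aas <- sample(aa_names(), k)
  aa_tally(stats::setNames(stats::runif(k, 0.1, 10), aas))
}

# Small synthetic reference DB (fast: few short proteins per species).
tiny_db <- function(n_taxa = 4, zc_low = -0.25, zc_high = 0.05, seed = 1) {
  make_reference_db(n_taxa, zc_low, zc_high, proteins_per_species = 3,
                    seed = seed)
}

# Write fixrank lines to a temp file and return the path.
write_fixrank <- function(lines) {
  path <- tempfile(fileext = ".fixrank.tsv")
  writeLines(lines, path)
  path
}

# A fixrank row classified down to genus.
fixrank_row <- function(id, genus, domain = "Bacteria", conf = 0.95) {
  paste(id, "", "Root", "rootrank", "1.0", domain, "domain", "1.0",
        genus, "genus", format(conf), sep = "\t")
}
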