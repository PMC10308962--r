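test_that("fixrank parsing keeps the lowest usable rank and drops root/domain-only rows", {
  path <- write_fixrank(c(
    fixrank_row("r1", "Escherichia"),
    # classified to class only (genus field empty in fixrank layout)
    paste("r2", "", "Root", "rootrank", "1.0", "Bacteria", "domain", "1.0",
          "Gammaproteobacteria", "class", "0.9", sep = "\t"),
    # domain only
    paste("r3", "", "Root", "rootrank", "1.0", "Bacteria", "domain", "1.0",
          sep = "\t"),
    # chloroplast and eukaryote rows are omitted
    paste("r4", "", "Root", "rootrank", "1.0", "Bacteria", "domain", "1.0",
          "Chloroplast", "genus", "0.99", sep = "\t"),
    fixrank_row("r5", "Methanococcus", domain = "Archaea"),
    paste("r6", "", "Root", "rootrank", "1.0", "Eukaryota", "domain", "1.0",
          "Fungi", "phylum", "0.8", sep = "\t")))
  reads <- read_rdp_fixrank(path)
  expect_equal(reads$read_id, c("r1", "r2", "r5"))
  expect_equal(reads$lowest_rank, c("genus", "class", "genus"))
  expect_equal(reads$domain, c("Bacteria", "Bacteria", "Archaea"))
  expect_equal(attr(reads, "n_dropped"), 3L)
})

test_that("fixrank parse errors carry line numbers and empty files warn", {
  bad <- write_fixrank(c(fixrank_row("r1", "X"), "r2\tonly\ttwo"))
  expect_error(read_rdp_fixrank(bad), "line 2")
  empty <- write_fixrank(character(0))
  expect_warning(reads <- read_rdp_fixrank(empty), "empty")
  expect_equal(nrow(reads), 0)
})

test_that("optional confidence re-thresholding climbs to a higher rank", {
  path <- write_fixrank(paste(
    "r1", "", "Root", "rootrank", "1.0", "Bacteria", "domain", "1.0",
    "Firmicutes", "phylum", "0.99", "LowConfGenus", "genus", "0.45",
    sep = "\t"))
  expect_equal(read_rdp_fixrank(path)$lowest_rank, "genus")
  expect_equal(read_rdp_fixrank(path, conf_threshold = 0.8)$lowest_rank,
               "phylum")
})

test_that("manual taxonomy mapping covers renames and cross-level moves", {
  db <- data.frame(rank = c("genus", "genus", "phylum"),
                   taxon = c("Escherichia", "Luteitalea", "Cyanobacteria"),
                   stringsAsFactors = FALSE)
  for (aa in aa_names()) db[[aa]] <- 1
  db$n_species <- 1L; db$n_proteins <- 1L
  reads <- data.frame(
    read_id = paste0("r", 1:5),
    domain = "Bacteria",
    lowest_rank = c("genus", "genus", "class", "genus", "genus"),
    lowest_taxon = c("Escherichia/Shigella", "Gp6", "Cyanobacteria",
                     "Escherichia", "TotallyUnknown"),
    confidence = 0.95, stringsAsFactors = FALSE)
  mp <- map_taxa(reads, db)
  expect_equal(sum(mp$counts$count), 4)
  expect_equal(mp$counts$count[mp$counts$taxon == "Escherichia"], 2)
  expect_equal(mp$counts$count[mp$counts$taxon == "Luteitalea"], 1)
  expect_equal(mp$counts$rank[mp$counts$taxon == "Cyanobacteria"], "phylum")
  expect_equal(mp$report$pct_mapped, 80)
  expect_equal(mp$report$n_mapped, 4L)
})

test_that("community proteome is the count-weighted mean and scale invariant", {
  db <- tiny_db(3)
  t1 <- db_tally(db, "genus", "Taxon_01")
  t3 <- db_tally(db, "genus", "Taxon_03")
  one <- data.frame(rank = "genus", taxon = "Taxon_01", count = 7)
  expect_equal(unclass(community_reference_proteome(one, db)), unclass(t1))
  duo <- data.frame(rank = "genus", taxon = c("Taxon_01", "Taxon_03"),
                    count = c(5, 5))
  cm <- community_reference_proteome(duo, db)
  expect_equal(unclass(cm), (unclass(t1) + unclass(t3)) / 2)
  z <- zc_tally(cm)
  expect_gte(z, min(zc_tally(t1), zc_tally(t3)))
  expect_lte(z, max(zc_tally(t1), zc_tally(t3)))
  duo2 <- duo; duo2$count <- duo2$count * 2
  expect_equal(unclass(community_reference_proteome(duo2, db)), unclass(cm))
  expect_error(community_reference_proteome(
    data.frame(rank = "genus", taxon = "Taxon_01", count = 0), db),
    "no mapped counts")
})

test_that("read-depth and archaeal sample filters follow the stated cutoffs", {
  samples <- data.frame(
    sample_id = c("a", "b", "c", "d", "e", "f"),
    domain = c("Bacteria", "Bacteria", "Archaea", "Archaea", "Archaea",
               "Archaea"),
    n_classified = c(99, 100, 150, 200, 250, 80))
  flt <- filter_samples(samples)
  # 99 bacterial reads dropped, 100 retained (cutoff is "less than 100")
  expect_false("a" %in% flt$retained$sample_id)
  expect_true("b" %in% flt$retained$sample_id)
  # 3 archaeal samples remain after depth filtering -> all archaea dropped
  expect_false(any(flt$retained$domain == "Archaea"))
  expect_equal(sum(flt$excluded$domain == "Archaea"), 4)
  # with 4 remaining archaeal samples the domain is kept
  samples$n_classified[6] <- 120
  flt2 <- filter_samples(samples)
  expect_equal(sum(flt2$retained$domain == "Archaea"), 4)
})

test_that("metaproteome Zc weights compositions by spectral counts", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">protA some description", "GG",
               ">protB", "LLLL"), fa)
  # one protein, count 1 -> that protein's Zc
  one <- data.frame(protein_id = "protA", count = 1)
  expect_equal(metaproteome_zc(one, fa), 1)
  # counts 2:1 -> Zc of the 2:1 summed tally (independent oracle)
  duo <- data.frame(protein_id = c("protA", "protB"), count = c(2, 1))
  oracle <- zc_tally(aa_tally(Gly = 4, Leu = 4))
  expect_equal(metaproteome_zc(duo, fa), oracle, tolerance = 1e-12)
  # decoys rejected, unknown IDs rejected
  expect_error(metaproteome_zc(
    data.frame(protein_id = "REV_protA", count = 1), fa), "decoy")
  expect_error(metaproteome_zc(
    data.frame(protein_id = "missing", count = 1), fa), "missing")
})

test_that("read subsampling is deterministic under a seed", {
  reads <- data.frame(read_id = paste0("r", 1:50), domain = "Bacteria",
                      lowest_rank = "genus", lowest_taxon = "X",
                      confidence = 0.9)
  s1 <- subsample_reads(reads, 10, seed = 5)
  s2 <- subsample_reads(reads, 10, seed = 5)
  expect_equal(s1, s2)
  expect_equal(nrow(s1), 10)
  expect_equal(nrow(subsample_reads(reads, 100)), 50)
})

test_that("the bundled demo fixrank file parses as documented", {
  fx <- system.file("extdata", "demo.fixrank.tsv", package = "zc16S")
  reads <- read_rdp_fixrank(fx)
  expect_equal(nrow(reads), 6)
  expect_equal(attr(reads, "n_dropped"), 2L)
  expect_equal(sum(reads$lowest_taxon == "Escherichia/Shigella"), 2)
  expect_true("Archaea" %in% reads$domain)
})
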