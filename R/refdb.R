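#' Reference proteome ranks
#' @return The allowed taxonomic ranks, lowest to highest.
#' @export
ref_ranks <- function() {
  c("species", "genus", "family", "order", "class", "phylum")
}

#' Build a species-level reference proteome
#'
#' The reference proteome of a species is the arithmetic mean amino acid
#' composition over its protein sequences: the summed composition divided by
#' the number of sequences, so every protein contributes equally regardless
#' of length. Species with fewer proteins than `min_proteins` are not
#' averaged: the returned object carries `status = "filtered"` so callers
#' can report, rather than silently drop, the exclusion.
#'
#' @param proteins List of `aa_tally` objects, one per protein sequence.
#' @param taxon_name Species name.
#' @param min_proteins Minimum number of protein sequences for a species to
#'   be retained (default 500). Synthetic fixtures may lower it.
#' @return A `ref_proteome`: list with `taxon_name`, `rank`, `mean_tally`,
#'   `n_species`, `n_proteins`, `status` ("ok" or "filtered").
#' @examples
#' p <- list(aa_tally(Gly = 2), aa_tally(Ala = 6))
#' species_reference(p, "Demo sp.", min_proteins = 1)$mean_tally
#' @export
species_reference <- function(proteins, taxon_name = "unnamed species",
                              min_proteins = 500) {
  if (length(proteins) == 0) stop("no protein tallies supplied")
  np <- length(proteins)
  if (np < min_proteins) {
    return(structure(list(taxon_name = taxon_name, rank = "species",
                          mean_tally = NULL, n_species = 1L,
                          n_proteins = np, status = "filtered"),
                     class = "ref_proteome"))
  }
  mean_tally <- scale_tally(sum_tallies(proteins), 1 / np)
  structure(list(taxon_name = taxon_name, rank = "species",
                 mean_tally = mean_tally, n_species = 1L, n_proteins = np,
                 status = "ok"),
            class = "ref_proteome")
}

#' @export
print.ref_proteome <- function(x, ...) {
  cat(sprintf("reference proteome: %s [%s] (%d species, %d proteins, %s)\n",
              x$taxon_name, x$rank, x$n_species, x$n_proteins, x$status))
  if (!is.null(x$mean_tally))
    cat(sprintf("  Zc = %.4f, %.1f residues/protein\n",
                zc_tally(x$mean_tally), n_residues(x$mean_tally)))
  invisible(x)
}

#' Aggregate species reference proteomes to a higher rank
#'
#' The mean amino acid compositions of the member species are summed and
#' divided by the number of species (unweighted mean), so species with
#' different proteome sizes contribute equally to the higher-rank taxon.
#'
#' @param species_refs List of species-level `ref_proteome` objects with
#'   `status == "ok"`.
#' @param target_rank One of genus, family, order, class, phylum.
#' @param taxon_name Name of the higher-rank taxon.
#' @return A `ref_proteome` at `target_rank`.
#' @export
aggregate_rank <- function(species_refs, target_rank, taxon_name) {
  if (length(species_refs) == 0) stop("no member species supplied")
  target_rank <- match.arg(target_rank, setdiff(ref_ranks(), "species"))
  ok <- vapply(species_refs, function(r)
    inherits(r, "ref_proteome") && r$rank == "species" &&
      r$status == "ok", logical(1))
  if (!all(ok)) stop("all members must be retained species-level proteomes")
  ns <- length(species_refs)
  mean_tally <- scale_tally(
    sum_tallies(lapply(species_refs, `[[`, "mean_tally")), 1 / ns)
  structure(list(taxon_name = taxon_name, rank = target_rank,
                 mean_tally = mean_tally, n_species = as.integer(ns),
                 n_proteins = sum(vapply(species_refs, `[[`, integer(1),
                                         "n_proteins")),
                 status = "ok"),
            class = "ref_proteome")
}

#' Build a reference database from a protein FASTA file
#'
#' FASTA headers must carry the species label, extracted with
#' `header_regex` (first capture group). All sequences sharing a label form
#' one species pool. Species passing the `min_proteins` filter are averaged
#' with [species_reference()]; higher ranks are aggregated from a
#' `membership` table.
#'
#' @param fasta_file Path to a protein FASTA file.
#' @param header_regex Regular expression applied to each header; capture
#'   group 1 is the species name. Default takes the token after
#'   `species=`, e.g. `>prot1 species=Taxon_01`.
#' @param membership Optional data.frame with columns `species`, `rank`,
#'   `taxon` assigning each species to higher-rank taxa (one row per
#'   species x rank).
#' @param min_proteins Species filter passed to [species_reference()].
#' @return A `ref_db`: data.frame with columns `rank`, `taxon`, the 20
#'   amino acid columns, `n_species`, `n_proteins`, plus attribute
#'   `filtered` (data.frame of excluded species).
#' @export
build_reference_db <- function(fasta_file,
                               header_regex = "species=(\\S+)",
                               membership = NULL,
                               min_proteins = 500) {
  seqs <- Biostrings::readAAStringSet(fasta_file)
  if (length(seqs) == 0) stop("no sequences in ", fasta_file)
  headers <- names(seqs)
  m <- regmatches(headers, regexec(header_regex, headers))
  lab <- vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_,
                character(1))
  if (anyNA(lab))
    stop("could not extract a species label from ",
         sum(is.na(lab)), " FASTA header(s)")
  tallies <- fasta_tallies(seqs)
  pools <- split(tallies, lab)
  refs <- lapply(names(pools), function(sp)
    species_reference(pools[[sp]], sp, min_proteins = min_proteins))
  status <- vapply(refs, `[[`, character(1), "status")
  filtered <- data.frame(
    taxon = vapply(refs[status == "filtered"], `[[`, character(1),
                   "taxon_name"),
    n_proteins = vapply(refs[status == "filtered"], `[[`, integer(1),
                        "n_proteins"))
  refs <- refs[status == "ok"]
  if (length(refs) == 0) stop("all species were filtered (min_proteins = ",
                              min_proteins, ")")
  rows <- lapply(refs, ref_row)
  # higher-rank aggregation
  if (!is.null(membership)) {
    stopifnot(all(c("species", "rank", "taxon") %in% names(membership)))
    sp_names <- vapply(refs, `[[`, character(1), "taxon_name")
    for (rk in intersect(setdiff(ref_ranks(), "species"),
                         unique(membership$rank))) {
      sub <- membership[membership$rank == rk, ]
      for (tx in unique(sub$taxon)) {
        members <- refs[sp_names %in% sub$species[sub$taxon == tx]]
        if (length(members))
          rows <- c(rows, list(ref_row(aggregate_rank(members, rk, tx))))
      }
    }
  }
  db <- do.call(rbind, rows)
  rownames(db) <- NULL
  attr(db, "filtered") <- filtered
  class(db) <- c("ref_db", class(db))
  db
}

# Convert AAStringSet to a list of aa_tally (vectorized; internal).
fasta_tallies <- function(seqs) {
  counts <- Biostrings::alphabetFrequency(seqs)
  letters20 <- .aa()$letter
  lapply(seq_len(nrow(counts)), function(i) {
    structure(stats::setNames(as.numeric(counts[i, letters20]), aa_names()),
              class = "aa_tally")
  })
}

# One ref_db row from a ref_proteome (internal).
ref_row <- function(r) {
  out <- data.frame(rank = r$rank, taxon = r$taxon_name,
                    stringsAsFactors = FALSE)
  q <- unclass(r$mean_tally)
  for (aa in aa_names()) out[[aa]] <- q[[aa]]
  out$n_species <- r$n_species
  out$n_proteins <- r$n_proteins
  out
}

#' Look up a reference proteome tally in a reference database
#'
#' @param db A `ref_db` data.frame.
#' @param rank,taxon Key pair. Collisions across ranks are legal (a class
#'   and a phylum may share a name), so both are required.
#' @return An `aa_tally`, or NULL if absent.
#' @export
db_tally <- function(db, rank, taxon) {
  i <- which(db$rank == rank & db$taxon == taxon)
  if (length(i) == 0) return(NULL)
  structure(stats::setNames(as.numeric(db[i[1], aa_names()]), aa_names()),
            class = "aa_tally")
}

#' Per-taxon Zc of a reference database
#' @param db A `ref_db`.
#' @return The input with an added `Zc` column.
#' @export
db_zc <- function(db) {
  db$Zc <- vapply(seq_len(nrow(db)), function(i)
    zc_tally(db_tally(db, db$rank[i], db$taxon[i])), numeric(1))
  db
}

#' Write / read a reference database CSV
#'
#' Column order is fixed: rank, taxon, the 20 amino acid columns in
#' [aa_names()] order, n_species, n_proteins.
#'
#' @param db A `ref_db` data.frame.
#' @param path CSV path.
#' @return `read_reference_db` returns a `ref_db`.
#' @export
write_reference_db <- function(db, path) {
  cols <- c("rank", "taxon", aa_names(), "n_species", "n_proteins")
  utils::write.csv(as.data.frame(db)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(path) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rank", "taxon", aa_names(), "n_species", "n_proteins")
  miss <- setdiff(need, names(db))
  if (length(miss)) stop("reference DB missing column(s): ",
                         paste(miss, collapse = ", "))
  db <- db[, need]
  class(db) <- c("ref_db", class(db))
  db
}
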