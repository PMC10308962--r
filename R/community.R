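#' Read RDP Classifier fixed-rank output
#'
#' Parses the tab-separated fixrank layout: read id, an orientation field,
#' then (name, rank, confidence) triplets from rootrank down to genus. Each
#' read is reduced to its lowest assigned rank between genus and phylum.
#' Reads classified only to root or domain, or assigned to Chloroplast or
#' Eukaryota, are omitted.
#'
#' @param path Path to a fixrank TSV file.
#' @param conf_threshold Optional confidence cutoff re-applied to the
#'   per-rank confidences (default NA: the classifier's own 80% threshold
#'   is assumed to have been applied upstream, and the deepest named rank
#'   is used).
#' @return data.frame of classified reads: `read_id`, `domain`,
#'   `lowest_rank`, `lowest_taxon`, `confidence`. Attribute `n_dropped`
#'   counts omitted rows.
#' @export
read_rdp_fixrank <- function(path, conf_threshold = NA) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty fixrank file: ", path)
    out <- data.frame(read_id = character(), domain = character(),
                      lowest_rank = character(), lowest_taxon = character(),
                      confidence = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  usable_ranks <- c("genus", "family", "order", "class", "phylum")
  n <- length(fields)
  len <- lengths(fields)
  bad <- which(len < 5 | (len - 2) %% 3 != 0)
  if (length(bad))
    stop("malformed fixrank row at line ", bad[1], " of ", path)
  read_id <- domain <- lowest_rank <- lowest_taxon <- rep(NA_character_, n)
  confidence <- rep(NA_real_, n)
  # vectorize over rows of equal width (the rank columns are few)
  for (L in unique(len)) {
    idx <- which(len == L)
    M <- matrix(unlist(fields[idx], use.names = FALSE), ncol = L,
                byrow = TRUE)
    k <- (L - 2) / 3
    dom <- rep(NA_character_, length(idx))
    chloro <- rep(FALSE, length(idx))
    for (t in seq_len(k)) {
      name <- M[, 3 * t]
      rank <- M[, 3 * t + 1]
      conf <- suppressWarnings(as.numeric(M[, 3 * t + 2]))
      if (anyNA(conf))
        stop("malformed confidence at line ", idx[which(is.na(conf))[1]],
             " of ", path)
      keep <- nzchar(name)
      if (!is.na(conf_threshold)) keep <- keep & conf >= conf_threshold
      dom <- ifelse(is.na(dom) & keep & rank == "domain", name, dom)
      chloro <- chloro | (keep & name == "Chloroplast")
      hit <- keep & rank %in% usable_ranks  # deepest usable wins (t grows)
      lowest_rank[idx[hit]] <- rank[hit]
      lowest_taxon[idx[hit]] <- name[hit]
      confidence[idx[hit]] <- conf[hit]
    }
    drop <- is.na(dom) | dom == "Eukaryota" | chloro
    lowest_rank[idx[drop]] <- NA_character_
    read_id[idx] <- M[, 1]
    domain[idx] <- dom
  }
  ok <- !is.na(lowest_rank) & !is.na(domain)
  out <- data.frame(read_id = read_id[ok], domain = domain[ok],
                    lowest_rank = lowest_rank[ok],
                    lowest_taxon = lowest_taxon[ok],
                    confidence = confidence[ok], stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- as.integer(n - sum(ok))
  out
}

#' Built-in manual taxonomy mappings (RDP to NCBI)
#'
#' Within-level renames plus cross-level mappings needed because the RDP
#' and NCBI taxonomies disagree for some lineages (e.g. RDP genus
#' "Escherichia/Shigella" vs NCBI genus Escherichia; RDP class
#' Cyanobacteria vs NCBI phylum Cyanobacteria). No archaeal mappings are
#' included.
#'
#' @return data.frame with columns `rank_from`, `name_from`, `rank_to`,
#'   `name_to`.
#' @export
default_manual_map <- function() {
  df <- rbind(
    c("genus", "Escherichia/Shigella", "genus", "Escherichia"),
    c("genus", "Gp1", "genus", "Acidobacterium"),
    c("genus", "Gp6", "genus", "Luteitalea"),
    c("genus", "GpI", "genus", "Nostoc"),
    c("genus", "GpIIa", "genus", "Synechococcus"),
    c("genus", "GpVI", "genus", "Pseudanabaena"),
    c("family", "Family II", "family", "Synechococcaceae"),
    c("family", "Ruminococcaceae", "family", "Oscillospiraceae"),
    c("order", "Clostridiales", "order", "Eubacteriales"),
    c("order", "Rhizobiales", "order", "Hyphomicrobiales"),
    c("class", "Planctomycetacia", "class", "Planctomycetia"),
    c("phylum", "Cyanobacteria/Chloroplast", "phylum", "Cyanobacteria"),
    c("genus", "Subdivision3_genera_incertae_sedis", "family",
      "Verrucomicrobia subdivision 3"),
    c("genus", "Spartobacteria_genera_incertae_sedis", "class",
      "Spartobacteria"),
    c("class", "Cyanobacteria", "phylum", "Cyanobacteria"),
    c("class", "Actinobacteria", "phylum", "Actinobacteria"))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  names(df) <- c("rank_from", "name_from", "rank_to", "name_to")
  df
}

#' Read / write a manual-mapping CSV
#' @param path CSV with columns rank_from, name_from, rank_to, name_to.
#' @param map A mapping data.frame.
#' @return `read_manual_map` returns the mapping data.frame.
#' @export
read_manual_map <- function(path) {
  mm <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rank_from", "name_from", "rank_to", "name_to")
  if (!all(need %in% names(mm)))
    stop("manual map must have columns ", paste(need, collapse = ", "))
  mm[, need]
}

#' @rdname read_manual_map
#' @export
write_manual_map <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE)
  invisible(path)
}

#' Map classified reads onto a reference database
#'
#' Each (rank, taxon) pair is first matched directly against the reference
#' database; failing that, the manual mapping is applied and the result
#' rematched. Reads whose taxa match neither way are counted as unmapped
#' and omitted from downstream composition.
#'
#' @param reads data.frame from [read_rdp_fixrank()].
#' @param db A `ref_db`.
#' @param manual_map Mapping table (default [default_manual_map()]).
#' @return List with `counts` (data.frame: domain, rank, taxon, count, all
#'   mapped) and `report` (per-domain n_reads, n_mapped, pct_mapped).
#' @export
map_taxa <- function(reads, db, manual_map = default_manual_map()) {
  if (nrow(reads) == 0) {
    return(list(counts = data.frame(domain = character(), rank = character(),
                                    taxon = character(), count = integer()),
                report = data.frame(domain = character(), n_reads = integer(),
                                    n_mapped = integer(),
                                    pct_mapped = numeric())))
  }
  rank <- reads$lowest_rank
  taxon <- reads$lowest_taxon
  key <- paste(rank, taxon, sep = "\r")
  db_key <- paste(db$rank, db$taxon, sep = "\r")
  direct <- key %in% db_key
  # manual mapping for the misses
  mm_key <- paste(manual_map$rank_from, manual_map$name_from, sep = "\r")
  mi <- match(key, mm_key)
  use_mm <- !direct & !is.na(mi)
  rank[use_mm] <- manual_map$rank_to[mi[use_mm]]
  taxon[use_mm] <- manual_map$name_to[mi[use_mm]]
  mapped <- direct | (use_mm &
    paste(rank, taxon, sep = "\r") %in% db_key)
  if (!any(mapped)) {
    agg <- data.frame(domain = character(), rank = character(),
                      taxon = character(), count = integer())
  } else agg <- stats::aggregate(
    list(count = rep(1L, sum(mapped))),
    by = list(domain = reads$domain[mapped], rank = rank[mapped],
              taxon = taxon[mapped]),
    FUN = sum)
  report <- do.call(rbind, lapply(split(mapped, reads$domain), function(x)
    data.frame(n_reads = length(x), n_mapped = sum(x),
               pct_mapped = 100 * mean(x))))
  report <- cbind(domain = rownames(report), report)
  rownames(report) <- NULL
  list(counts = agg, report = report)
}

#' Community reference proteome of one sample
#'
#' The amino acid compositions of the matched reference proteomes are
#' multiplied by the mapped counts and divided by the total mapped count:
#' a count-weighted mean composition per classified read.
#'
#' @param counts data.frame with columns `rank`, `taxon`, `count` (one
#'   domain's mapped counts for one sample).
#' @param db A `ref_db` containing every (rank, taxon) in `counts`.
#' @return An `aa_tally`; its [zc_tally()] is the community Zc.
#' @export
community_reference_proteome <- function(counts, db) {
  counts <- counts[counts$count > 0, , drop = FALSE]
  if (nrow(counts) == 0) stop("sample has no mapped counts")
  tallies <- lapply(seq_len(nrow(counts)), function(i) {
    t <- db_tally(db, counts$rank[i], counts$taxon[i])
    if (is.null(t))
      stop("taxon not in reference DB: ", counts$rank[i], " ",
           counts$taxon[i])
    scale_tally(t, counts$count[i])
  })
  scale_tally(sum_tallies(tallies), 1 / sum(counts$count))
}

#' Filter samples by classified-read depth
#'
#' Samples with fewer than `min_reads` mapped lowest-level assignments in a
#' domain are dropped for that domain; if fewer than `min_samples` archaeal
#' samples remain in a dataset, its archaeal analysis is dropped entirely.
#'
#' @param samples data.frame with columns `sample_id`, `domain`,
#'   `n_classified` (one row per sample x domain).
#' @param min_reads Read-depth cutoff (default 100; a sample with exactly
#'   100 reads is retained).
#' @param min_samples Minimum remaining archaeal samples (default 4).
#' @return List with `retained` (subset of `samples`) and `excluded`
#'   (subset with an added `reason` column).
#' @export
filter_samples <- function(samples, min_reads = 100, min_samples = 4) {
  low <- samples$n_classified < min_reads
  excluded <- samples[low, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "fewer than min_reads classified"
  retained <- samples[!low, , drop = FALSE]
  arch <- retained$domain == "Archaea"
  if (any(arch) && sum(arch) < min_samples) {
    dropped <- retained[arch, , drop = FALSE]
    dropped$reason <- "fewer than min_samples archaeal samples"
    excluded <- rbind(excluded, dropped)
    retained <- retained[!arch, , drop = FALSE]
  }
  rownames(retained) <- rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded)
}

#' Metaproteome carbon oxidation state from spectral counts
#'
#' Each identified protein's amino acid composition is multiplied by its
#' number of peptide-spectrum matches; the weighted compositions are summed
#' and Zc of the total is returned. Contaminant and decoy entries must be
#' removed upstream: IDs carrying the given prefixes trigger an error.
#'
#' @param psm_counts data.frame with columns `protein_id`, `count`, or a
#'   path to such a TSV.
#' @param fasta_file Protein FASTA whose headers (first whitespace token)
#'   resolve the IDs.
#' @param decoy_prefixes ID prefixes treated as decoy/contaminant flags.
#' @return Zc of the spectral-count-weighted summed composition.
#' @export
metaproteome_zc <- function(psm_counts, fasta_file,
                            decoy_prefixes = c("REV_", "DECOY_", "CON_")) {
  if (is.character(psm_counts))
    psm_counts <- utils::read.delim(psm_counts, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "count") %in% names(psm_counts)))
  bad <- psm_counts$protein_id[
    grepl(paste0("^(", paste(decoy_prefixes, collapse = "|"), ")"),
          psm_counts$protein_id)]
  if (length(bad))
    stop("decoy/contaminant IDs present in counts: ",
         paste(bad, collapse = ", "))
  seqs <- Biostrings::readAAStringSet(fasta_file)
  ids <- sub("\\s.*$", "", names(seqs))
  idx <- match(psm_counts$protein_id, ids)
  if (anyNA(idx))
    stop("protein ID(s) not in FASTA: ",
         paste(psm_counts$protein_id[is.na(idx)], collapse = ", "))
  tallies <- fasta_tallies(seqs[idx])
  weighted <- Map(scale_tally, tallies, psm_counts$count)
  zc_tally(sum_tallies(weighted))
}

#' Subsample classified reads
#'
#' Draws `n` reads without replacement from a classified-read table, for
#' depth-parity experiments. Deterministic under `seed`.
#'
#' @param reads data.frame of classified reads.
#' @param n Number of reads to keep (if fewer are present, all are kept).
#' @param seed Integer seed.
#' @return Subsampled data.frame.
#' @export
subsample_reads <- function(reads, n, seed = 1L) {
  if (nrow(reads) <= n) return(reads)
  set.seed(seed)
  out <- reads[sort(sample.int(nrow(reads), n)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
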