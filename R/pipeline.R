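#' Per-sample community Zc from mapped counts
#'
#' @param counts data.frame with columns `sample_id`, `domain`, `rank`,
#'   `taxon`, `count` (mapped counts, e.g. from [map_taxa()] or
#'   [make_survey()]).
#' @param db A `ref_db`.
#' @return data.frame: `sample_id`, `domain`, `n_classified`, `Zc` (one
#'   row per sample x domain).
#' @export
per_sample_zc <- function(counts, db) {
  keys <- unique(counts[, c("sample_id", "domain")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- counts[counts$sample_id == keys$sample_id[i] &
                    counts$domain == keys$domain[i], , drop = FALSE]
    tal <- community_reference_proteome(sub, db)
    data.frame(sample_id = keys$sample_id[i], domain = keys$domain[i],
               n_classified = sum(sub$count), Zc = zc_tally(tal),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Process a directory of fixrank files into a per-sample Zc table
#'
#' Each `*.fixrank.tsv` file is one sample (sample id = file name stem).
#' Reads are parsed, mapped onto the reference DB (with manual-mapping
#' fallback), and reduced to per-domain community Zc.
#'
#' @param dir Directory of fixrank TSVs.
#' @param db A `ref_db`.
#' @param manual_map Mapping table (default [default_manual_map()]).
#' @param domain `"both"` (split by classifier-assigned domain, for
#'   universal primers) or `"Bacteria"` / `"Archaea"` (keep only that
#'   domain, for domain-specific primers).
#' @param conf_threshold Optional confidence re-threshold (see
#'   [read_rdp_fixrank()]).
#' @return data.frame: `sample_id`, `domain`, `n_classified`, `n_mapped`,
#'   `pct_mapped`, `Zc`. Here `n_classified` counts reads with usable
#'   lowest-level assignments and `n_mapped` those matched to the DB.
#' @export
process_fixrank_dir <- function(dir, db, manual_map = default_manual_map(),
                                domain = "both", conf_threshold = NA) {
  files <- list.files(dir, pattern = "\\.fixrank\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no *.fixrank.tsv files in ", dir)
  rows <- lapply(files, function(f) {
    sid <- sub("\\.fixrank\\.tsv$", "", basename(f))
    reads <- read_rdp_fixrank(f, conf_threshold)
    if (domain != "both")
      reads <- reads[reads$domain == domain, , drop = FALSE]
    mp <- map_taxa(reads, db, manual_map)
    if (nrow(mp$counts) == 0) return(NULL)
    doms <- unique(mp$counts$domain)
    do.call(rbind, lapply(doms, function(dm) {
      sub <- mp$counts[mp$counts$domain == dm, , drop = FALSE]
      rep_row <- mp$report[mp$report$domain == dm, ]
      tal <- community_reference_proteome(sub, db)
      data.frame(sample_id = sid, domain = dm,
                 n_classified = rep_row$n_reads,
                 n_mapped = rep_row$n_mapped,
                 pct_mapped = rep_row$pct_mapped,
                 Zc = zc_tally(tal), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Per-dataset regressions of Zc against Eh7
#'
#' Joins a per-sample Zc table with sample metadata and fits, for every
#' dataset x domain with at least `min_n` samples, an OLS regression of
#' community Zc on Eh7 expressed in volts.
#'
#' @param sample_tbl data.frame with `sample_id`, `domain`, `Zc` (e.g.
#'   from [per_sample_zc()] or [process_fixrank_dir()]).
#' @param metadata data.frame with `sample_id`, `dataset`, `environment`,
#'   and `Eh7_mV` (add it with [read_metadata()] or [eh_to_eh7()]).
#' @param min_n Minimum samples per fit (default 3).
#' @return data.frame: `dataset`, `domain`, `environment`, `N`, `m`
#'   (slope, 1/V), `moe95`, `r`, `intercept`.
#' @export
dataset_fits <- function(sample_tbl, metadata, min_n = 3) {
  if (is.null(metadata$Eh7_mV))
    metadata$Eh7_mV <- eh_to_eh7(metadata$Eh_mV, metadata$pH, metadata$T_C)
  merged <- merge(sample_tbl, metadata, by = "sample_id")
  keys <- unique(merged[, c("dataset", "domain")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- merged[merged$dataset == keys$dataset[i] &
                    merged$domain == keys$domain[i], , drop = FALSE]
    if (nrow(sub) < min_n) return(NULL)
    f <- ols_fit(sub$Eh7_mV / 1000, sub$Zc)
    data.frame(dataset = keys$dataset[i], domain = keys$domain[i],
               environment = sub$environment[1], N = f$N, m = f$m,
               moe95 = f$moe95, r = f$r, intercept = f$intercept,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Run the full survey analysis from files on disk
#'
#' Convenience wrapper: reads the reference DB, metadata, and fixrank
#' files written by [write_survey()] (or any pipeline-format inputs),
#' applies the read-depth sample filters, and returns per-sample Zc values
#' and per-dataset fits.
#'
#' @param dir Directory containing `*.fixrank.tsv`, `metadata.csv`,
#'   `reference_db.csv`.
#' @param manual_map Mapping table.
#' @param min_reads,min_samples Sample filters (see [filter_samples()]).
#' @return List with `samples` (filtered per-sample table), `fits`,
#'   `excluded`.
#' @export
analyze_survey_dir <- function(dir, manual_map = default_manual_map(),
                               min_reads = 100, min_samples = 4) {
  db <- read_reference_db(file.path(dir, "reference_db.csv"))
  metadata <- read_metadata(file.path(dir, "metadata.csv"))
  tbl <- process_fixrank_dir(dir, db, manual_map)
  flt <- filter_samples(tbl, min_reads, min_samples)
  fits <- dataset_fits(flt$retained, metadata)
  list(samples = flt$retained, fits = fits, excluded = flt$excluded)
}
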