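#' Generate a synthetic reference database spanning a Zc range
#'
#' Taxa are built by mixing a reduced endmember (leucine, Zc = -1) and an
#' oxidized endmember (glycine, Zc = +1) so that realized taxon Zc values
#' are evenly spaced on [zc_low, zc_high]. The glycine residue fraction for
#' target z is g = 3(z + 1) / (2(z + 2)) (exact one-dimensional mixing
#' solution); a per-protein length is then searched so the integer residue
#' counts realize the target to within `tol`. Each species contributes
#' `proteins_per_species` equal-composition proteins (shuffled sequences),
#' and species are aggregated to one-species genera so the survey
#' classifier interface works at genus level.
#'
#' @param n_taxa Number of taxa (>= 1).
#' @param zc_low,zc_high Target Zc range; must lie inside (-1, 1).
#' @param proteins_per_species Proteins per species (default 500, the
#'   reference-proteome inclusion threshold).
#' @param seed Integer seed (controls residue order within sequences).
#' @param fasta_file Optional path; if given, the protein FASTA is written
#'   (headers `>TaxonXX_pYYYY species=Taxon_XX`).
#' @param tol Maximum |realized - target| Zc (default 1e-7).
#' @return A `ref_db` with genus and species rows; attribute `truth` is a
#'   data.frame of target and realized Zc per taxon.
#' @export
make_reference_db <- function(n_taxa, zc_low = -0.25, zc_high = 0.05,
                              proteins_per_species = 500, seed = 1L,
                              fasta_file = NULL, tol = 1e-7) {
  stopifnot(n_taxa >= 1, proteins_per_species >= 1)
  if (n_taxa > 1 && !(zc_low < zc_high))
    stop("zc_low must be less than zc_high")
  if (zc_low <= -1 || zc_high >= 1)
    stop("targets outside the reachable (-1, 1) Gly/Leu mixing range")
  targets <- if (n_taxa == 1) mean(c(zc_low, zc_high)) else
    seq(zc_low, zc_high, length.out = n_taxa)
  set.seed(seed)
  taxa <- sprintf("Taxon_%02d", seq_len(n_taxa))
  fasta_lines <- character(0)
  refs <- vector("list", n_taxa)
  truth <- data.frame(taxon = taxa, target_zc = targets,
                      realized_zc = NA_real_, protein_length = NA_integer_,
                      n_gly = NA_integer_)
  for (i in seq_len(n_taxa)) {
    gl <- gly_leu_counts(targets[i], tol)
    L <- gl$L; G <- gl$G
    seqs <- vapply(seq_len(proteins_per_species), function(p)
      paste(sample(c(rep("G", G), rep("L", L - G))), collapse = ""),
      character(1))
    if (!is.null(fasta_file)) {
      hdr <- sprintf(">%s_p%04d species=%s", gsub("_", "", taxa[i]),
                     seq_len(proteins_per_species), taxa[i])
      fasta_lines <- c(fasta_lines, rbind(hdr, seqs))
    }
    tal <- aa_tally(Gly = G, Leu = L - G)
    sp <- species_reference(rep(list(tal), proteins_per_species),
                            paste(taxa[i], "sp."),
                            min_proteins = 1)
    refs[[i]] <- list(species = sp,
                      genus = aggregate_rank(list(sp), "genus", taxa[i]))
    truth$realized_zc[i] <- zc_tally(tal)
    truth$protein_length[i] <- L
    truth$n_gly[i] <- G
  }
  rows <- unlist(lapply(refs, function(r)
    list(ref_row(r$genus), ref_row(r$species))), recursive = FALSE)
  db <- do.call(rbind, rows)
  rownames(db) <- NULL
  class(db) <- c("ref_db", class(db))
  attr(db, "truth") <- truth
  if (!is.null(fasta_file)) writeLines(fasta_lines, fasta_file)
  db
}

# Find (protein length L, glycine count G) realizing a target Zc from a
# Gly/Leu mix to within tol (internal).
gly_leu_counts <- function(z, tol = 1e-7, L_max = 5000L) {
  g <- 3 * (z + 1) / (2 * (z + 2))   # exact glycine residue fraction
  best <- NULL
  best_err <- Inf
  for (L in 30:L_max) {
    G <- round(g * L)
    if (G < 0 || G > L) next
    realized <- (8 * G / L - 6) / (6 - 4 * G / L)
    err <- abs(realized - z)
    if (err < best_err) {
      best <- list(L = L, G = as.integer(G))
      best_err <- err
    }
    if (err < tol) return(best)
  }
  stop(sprintf("Zc target %.6f unreachable to within %g (best error %g)",
               z, tol, best_err))
}

#' Specify a synthetic 16S survey
#'
#' The generator emulates the statistical structure the downstream
#' analysis assumes: per-sample community Zc is linear in Eh7 with
#' Gaussian noise, induced by mixing a reduced and an oxidized endmember
#' taxon. Defaults reflect typical local-scale survey conditions: 20
#' samples per dataset, a 600 mV Eh7 span, slope 0.1/V (the order of the
#' largest local-scale slopes), Zc noise 0.01, and 10,000 classified reads
#' per sample.
#'
#' @param n_datasets Number of datasets.
#' @param samples_per_dataset Samples in each dataset.
#' @param eh7_range_mV Eh7 range the samples span.
#' @param true_slope Zc per volt.
#' @param noise_sd Gaussian Zc noise (0 for exact construction).
#' @param reads_per_sample Classified reads per sample, or `Inf` for exact
#'   fractional counts.
#' @param environments Environment labels recycled across datasets.
#' @param counts One of "multinomial" (reads drawn around the exact mixing
#'   fraction) or "exact" (deterministic rounding; with a nonzero slope,
#'   Eh7 is back-computed from the realized Zc so samples lie exactly on
#'   the generator line).
#' @param seed Integer seed.
#' @return A `survey_spec` list.
#' @export
survey_spec <- function(n_datasets = 5, samples_per_dataset = 20,
                        eh7_range_mV = c(-300, 300), true_slope = 0.1,
                        noise_sd = 0.01, reads_per_sample = 10000,
                        environments = c("soil", "sediment",
                                         "river & seawater", "lake & pond",
                                         "geothermal"),
                        counts = c("multinomial", "exact"), seed = 1L) {
  stopifnot(diff(eh7_range_mV) > 0, noise_sd >= 0, reads_per_sample >= 1,
            samples_per_dataset >= 3, n_datasets >= 1)
  structure(list(n_datasets = n_datasets,
                 samples_per_dataset = samples_per_dataset,
                 eh7_range_mV = eh7_range_mV, true_slope = true_slope,
                 noise_sd = noise_sd, reads_per_sample = reads_per_sample,
                 environments = environments,
                 counts = match.arg(counts), seed = as.integer(seed)),
            class = "survey_spec")
}

#' Generate a synthetic survey
#'
#' For each sample: Eh7 is drawn uniformly on the spec range; the target
#' community Zc is intercept + true_slope * Eh7(V) + N(0, noise_sd); taxon
#' counts for the two endmember genera are chosen so the count-weighted
#' community reference proteome hits the target; pH is drawn on [4, 9] and
#' the reported Eh is back-computed from Eh7 through the inverse Nernst
#' correction, so the pipeline's own pH correction is exercised.
#'
#' @param spec A [survey_spec()].
#' @param db A `ref_db` (genus rows are used; the lowest- and highest-Zc
#'   genera are the mixing endmembers).
#' @param out_dir Optional directory: writes per-sample fixrank TSVs,
#'   `metadata.csv`, `reference_db.csv`, and `truth.json`.
#' @return List with `metadata` (sample metadata incl. Eh_mV, pH, T_C),
#'   `counts` (per-sample taxon counts), `truth` (generator record incl.
#'   per-sample realized Zc and the Eh7 values actually encoded).
#' @export
make_survey <- function(spec, db, out_dir = NULL) {
  stopifnot(inherits(spec, "survey_spec"))
  gdb <- db_zc(db[db$rank == "genus", , drop = FALSE])
  if (nrow(gdb) < 2) stop("reference DB needs at least two genera")
  lo <- gdb[which.min(gdb$Zc), ]
  hi <- gdb[which.max(gdb$Zc), ]
  t_lo <- db_tally(db, "genus", lo$taxon)
  t_hi <- db_tally(db, "genus", hi$taxon)
  C_lo <- unclass(tally_formula(t_lo))[["c"]]
  C_hi <- unclass(tally_formula(t_hi))[["c"]]
  z_lo <- lo$Zc; z_hi <- hi$Zc
  mid_eh7_V <- mean(spec$eh7_range_mV) / 1000
  intercept <- mean(c(z_lo, z_hi)) - spec$true_slope * mid_eh7_V
  set.seed(spec$seed)
  n_total <- spec$n_datasets * spec$samples_per_dataset
  env <- rep_len(spec$environments, spec$n_datasets)
  meta_rows <- vector("list", n_total)
  count_rows <- vector("list", n_total)
  truth_rows <- vector("list", n_total)
  k <- 0L
  for (d in seq_len(spec$n_datasets)) {
    ds <- sprintf("dataset_%02d", d)
    for (j in seq_len(spec$samples_per_dataset)) {
      k <- k + 1L
      sid <- sprintf("%s_s%03d", ds, j)
      eh7 <- stats::runif(1, spec$eh7_range_mV[1], spec$eh7_range_mV[2])
      target <- intercept + spec$true_slope * eh7 / 1000 +
        stats::rnorm(1, 0, spec$noise_sd)
      if (target < z_lo || target > z_hi)
        stop("target Zc ", signif(target, 4),
             " outside the DB span; widen the Zc range or lower noise_sd")
      A <- C_hi * (z_hi - target)
      B <- C_lo * (target - z_lo)
      q_hi <- B / (A + B)
      if (is.finite(spec$reads_per_sample)) {
        if (spec$counts == "exact") {
          n_hi <- round(q_hi * spec$reads_per_sample)
        } else {
          n_hi <- stats::rbinom(1, spec$reads_per_sample, q_hi)
        }
        n_lo <- spec$reads_per_sample - n_hi
      } else {
        n_hi <- q_hi; n_lo <- 1 - q_hi
      }
      realized <- (n_hi * C_hi * z_hi + n_lo * C_lo * z_lo) /
        (n_hi * C_hi + n_lo * C_lo)
      # exact mode with a trend: encode the sample on the generator line
      eh7_used <- if (spec$counts == "exact" && spec$true_slope != 0)
        (realized - intercept) / spec$true_slope * 1000 else eh7
      pH <- stats::runif(1, 4, 9)
      meta_rows[[k]] <- data.frame(
        sample_id = sid, dataset = ds, environment = env[d],
        Eh_mV = eh7_to_eh(eh7_used, pH, 25), pH = pH, T_C = 25,
        O2_value = round(pmax(0, (eh7_used + 300) / 600 * 8), 3),
        O2_unit = "mg_L", stringsAsFactors = FALSE)
      count_rows[[k]] <- data.frame(
        sample_id = sid, domain = "Bacteria", rank = "genus",
        taxon = c(hi$taxon, lo$taxon), count = c(n_hi, n_lo),
        stringsAsFactors = FALSE)
      truth_rows[[k]] <- data.frame(
        sample_id = sid, dataset = ds, eh7_mV = eh7_used,
        target_zc = target, realized_zc = realized,
        stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta_rows)
  counts <- do.call(rbind, count_rows)
  truth <- list(spec = unclass(spec), intercept = intercept,
                endmembers = c(lo = lo$taxon, hi = hi$taxon),
                samples = do.call(rbind, truth_rows))
  out <- list(metadata = metadata, counts = counts, truth = truth)
  if (!is.null(out_dir)) write_survey(out, db, out_dir)
  out
}

#' Write a survey to disk in pipeline input formats
#'
#' One fixrank TSV per sample (`<sample_id>.fixrank.tsv`), `metadata.csv`,
#' `reference_db.csv`, and a `truth.json` generator record.
#'
#' @param survey Result of [make_survey()].
#' @param db The reference DB used.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_survey <- function(survey, db, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (any(survey$counts$count != round(survey$counts$count)))
    stop("cannot write fixrank files for fractional (exact-mode, Inf reads) counts")
  for (sid in unique(survey$counts$sample_id)) {
    sub <- survey$counts[survey$counts$sample_id == sid, ]
    taxa <- rep(sub$taxon, sub$count)
    doms <- rep(sub$domain, sub$count)
    ranks <- rep(sub$rank, sub$count)
    lines <- sprintf(
      "%s_r%06d\t\tRoot\trootrank\t1.0\t%s\tdomain\t1.0\t%s\t%s\t0.99",
      sid, seq_along(taxa), doms, taxa, ranks)
    writeLines(lines, file.path(out_dir, paste0(sid, ".fixrank.tsv")))
  }
  utils::write.csv(survey$metadata, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  write_reference_db(db, file.path(out_dir, "reference_db.csv"))
  jsonlite::write_json(survey$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Demonstration Gibbs table for a reference database
#'
#' Builds a Gibbs table whose proteome standard Gibbs energies are chosen
#' so that, on an Eh-pH diagram at pH 7, the relative stability fields of
#' the taxa succeed one another in order of increasing Zc at evenly spaced
#' Eh across the water window: a stepwise increase of winner Zc with Eh by
#' construction. Basis-species dG0f values are synthetic demonstration
#' values of literature magnitude; the construction is deterministic.
#'
#' @param db A `ref_db`; its genus rows become proteome entries (per
#'   residue formulas, charge 0).
#' @param seed Unused (kept for generator API uniformity).
#' @param T_C Temperature for the construction (default 25).
#' @return A Gibbs table data.frame (see [read_gibbs()] for the layout).
#' @export
make_gibbs_fixture <- function(db, seed = 1L, T_C = 25) {
  gdb <- db_zc(db[db$rank == "genus", , drop = FALSE])
  if (nrow(gdb) == 0) stop("reference DB has no genus rows")
  gdb <- gdb[order(gdb$Zc), ]
  basis <- default_basis()
  basis$kind <- "basis"
  basis$dG0_J_mol <- c(-529190, -723830, -340330, -237183, 0, 0)
  prot <- do.call(rbind, lapply(seq_len(nrow(gdb)), function(i) {
    f <- unclass(residue_formula(db_tally(gdb, "genus", gdb$taxon[i])))
    data.frame(species = gdb$taxon[i], kind = "proteome",
               c = f[["c"]], h = f[["h"]], n = f[["n"]], o = f[["o"]],
               s = f[["s"]], charge = 0, dG0_J_mol = 0,
               log_activity = NA_real_, stringsAsFactors = FALSE)
  }))
  gibbs <- rbind(basis[, c("species", "kind", "c", "h", "n", "o", "s",
                           "charge", "dG0_J_mol", "log_activity")], prot)
  # affine pieces with dG0 = 0, at pH 7: dG = c0 + slope * pe
  aff <- lapply(prot$species, dg_affine, gibbs = gibbs, T_C = T_C)
  slope <- vapply(aff, `[[`, numeric(1), "coef_pe")
  c0 <- vapply(seq_along(aff), function(i)
    aff[[i]]$const + aff[[i]]$coef_pH * 7, numeric(1))
  if (any(diff(slope) >= 0) && nrow(prot) > 1)
    stop("electron coefficients not strictly decreasing with Zc; ",
         "cannot order stability fields")
  wl <- water_limits(7, T_C)
  pe_lo <- eh_to_pe(wl$Eh_min_mV, T_C)
  pe_hi <- eh_to_pe(wl$Eh_max_mV, T_C)
  K <- nrow(prot)
  # desired intercepts (dG at pe = 0, pH 7): lowest-Zc proteome anchored at
  # +1000 J/mol at the reducing edge; equality at evenly spaced breakpoints
  want <- numeric(K)
  want[1] <- 1000 - slope[1] * pe_lo
  if (K > 1) {
    brk <- seq(pe_lo, pe_hi, length.out = K + 1)[2:K]
    for (i in 2:K)
      want[i] <- want[i - 1] + (slope[i - 1] - slope[i]) * brk[i - 1]
  }
  gibbs$dG0_J_mol[gibbs$kind == "proteome"] <- want - c0
  gibbs
}
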