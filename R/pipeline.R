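#' Read a study directory written by [write_study()]
#'
#' @param dir study directory.
#' @return list mirroring the `synthetic_study` layout (without the truth
#'   ledger, which is an output of simulation, not an input to analysis).
#' @export
read_study <- function(dir) {
  sheet <- read_sample_sheet(file.path(dir, "peak_samples.tsv"))
  peaks <- list()
  for (i in seq_len(nrow(sheet))) {
    r <- sheet[i, ]
    gr <- read_peak_file(file.path(dir, r$path), mark = r$mark,
                         stage = r$stage, genotype = r$genotype,
                         replicate = r$replicate)
    peaks[[r$mark]][[r$genotype]][[r$stage]][[r$replicate]] <- gr
  }
  counts <- read_count_table(file.path(dir, "rna_counts.tsv"))
  meta <- read_results_table(file.path(dir, "rna_samples.tsv"))
  genes <- read_results_table(file.path(dir, "genes.tsv"))
  exons <- read_results_table(file.path(dir, "exons.tsv"))
  gm <- gene_models(genes, exons)
  gene_lengths <- stats::setNames(genes$end - genes$start, genes$gene_id)
  rna <- count_matrix(counts, meta, gene_lengths)
  k27ac_counts <- read_count_table(file.path(dir, "k27ac_counts.tsv"))
  k27ac_regions <- read_peak_file(file.path(dir, "k27ac_regions.bed"))
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  pwms <- read_jaspar(file.path(dir, "motifs.jaspar"))
  risk <- readLines(file.path(dir, "risk_genes.txt"), warn = FALSE)
  list(peaks = peaks, rna = rna, gene_models = gm,
       k27ac_counts = k27ac_counts, k27ac_regions = k27ac_regions,
       genome = genome, pwms = pwms, risk_genes = risk)
}

# consensus peak sets for every (mark, genotype, stage) in a study
study_consensus <- function(study, cfg) {
  out <- list()
  for (mark in names(study$peaks)) {
    for (gt in names(study$peaks[[mark]])) {
      for (s in names(study$peaks[[mark]][[gt]])) {
        out[[mark]][[gt]][[s]] <-
          consensus_peaks(study$peaks[[mark]][[gt]][[s]], cfg)
      }
    }
  }
  out
}

#' Run the full analysis pipeline on a study
#'
#' Executes every stage in order — replicate consensus, temporal
#' classification, annotation, expression clustering, differential
#' expression (HET vs WT at D35), chromatin states and transitions,
#' differential H3K27ac binding, concordance integration, and motif
#' enrichment — and (optionally) writes all result tables to `out_dir`.
#' Deterministic for a fixed `cfg` and study.
#'
#' @param study a `synthetic_study` or the result of [read_study()].
#' @param cfg an [analysis_config()].
#' @param out_dir if non-`NULL`, result tables are written there.
#' @return named list of all intermediate and final results.
#' @export
run_pipeline <- function(study, cfg = analysis_config(), out_dir = NULL) {
  cons <- study_consensus(study, cfg)
  gm <- study$gene_models

  classes <- classify_temporal(cons$CHD2$WT, cfg)
  chd2_all <- suppressWarnings(do.call(c, unname(cons$CHD2$WT[STAGES])))
  stage_of <- rep(STAGES, vapply(cons$CHD2$WT[STAGES], length, 1L))
  S4Vectors::mcols(chd2_all)$name <- paste(
    stage_of, S4Vectors::mcols(chd2_all)$name, sep = ":")
  ann <- annotate_peaks(chd2_all, gm, cfg)

  unique_prom <- lapply(stats::setNames(STAGES, STAGES), function(s)
    stage_unique_promoter_genes(classes, ann, s))
  bound_by_stage <- lapply(stats::setNames(STAGES, STAGES), function(s) {
    keep <- ann$peak %in% classes$peak[classes$stage == s] &
      ann$promoter_proximal
    sort(unique(stats::na.omit(ann$gene_id[keep])))
  })

  rpkm_stage <- stage_mean_rpkm(study$rna, "WT")
  dyn <- filter_dynamic_genes(rpkm_stage, cfg)
  profiles <- relative_profiles(rpkm_stage[dyn, , drop = FALSE], cfg)
  model <- fit_clusters(profiles, cfg)

  wt35 <- study$rna$meta$sample[study$rna$meta$stage == "D35" &
                                  study$rna$meta$genotype == "WT"]
  het35 <- study$rna$meta$sample[study$rna$meta$stage == "D35" &
                                   study$rna$meta$genotype == "HET"]
  de <- differential_expression(study$rna, wt35, het35, cfg)

  histone_sets <- list()
  for (m in HISTONE_MARKS) {
    for (s in STAGES) {
      gt <- if (!is.null(cons[[m]]$WT[[s]])) "WT" else "HET"
      histone_sets[[paste(m, s, sep = ".")]] <- cons[[m]][[gt]][[s]]
    }
  }
  # states are called on TF peaks present throughout (callable at all stages)
  states <- call_states(chd2_all, histone_sets, cfg)
  transitions <- tabulate_transitions(states)

  wt_ac <- grep("_WT_", colnames(study$k27ac_counts), value = TRUE)
  het_ac <- grep("_HET_", colnames(study$k27ac_counts), value = TRUE)
  dbr_res <- differential_binding(study$k27ac_counts, wt_ac, het_ac, cfg)
  reg <- study$k27ac_regions
  reg_idx <- match(dbr_res$peak, S4Vectors::mcols(reg)$name)
  dbr_res$chrom <- as.character(GenomicRanges::seqnames(reg))[reg_idx]
  dbr_res$start <- GenomicRanges::start(reg)[reg_idx] - 1L
  dbr_res$end <- GenomicRanges::end(reg)[reg_idx]
  dbrs <- dbr_res[dbr_res$direction != "ns", , drop = FALSE]

  dist_unique_d35 <- cluster_distribution(unique_prom$D35, model)
  risk_overlap <- gene_list_overlap(bound_by_stage, study$risk_genes)
  conc <- concordant_triples(dbrs, de, classes, gm, cfg)

  d35_unique_peaks <- classes[classes$class == "D35", , drop = FALSE]
  fg_gr <- GenomicRanges::GRanges(
    d35_unique_peaks$chrom,
    IRanges::IRanges(d35_unique_peaks$start + 1L, d35_unique_peaks$end))
  S4Vectors::mcols(fg_gr)$name <- d35_unique_peaks$peak
  motif <- NULL
  if (length(fg_gr) >= 5L) {
    bg_gr <- make_background(fg_gr, study$genome, cfg)
    fg_seq <- extract_sequences(fg_gr, study$genome)
    bg_seq <- extract_sequences(bg_gr, study$genome)
    motif <- motif_enrichment(fg_seq, bg_seq, study$pwms,
                              quantile = cfg$motif_logodds_quantile)
  }

  res <- list(
    consensus = cons, classes = classes, annotations = ann,
    unique_promoter_genes = unique_prom, bound_by_stage = bound_by_stage,
    rpkm_stage = rpkm_stage, dynamic_genes = dyn, profiles = profiles,
    cluster_model = model, de = de, states = states,
    transitions = transitions, dbr = dbr_res, dbrs_significant = dbrs,
    cluster_distribution = dist_unique_d35, risk_overlap = risk_overlap,
    concordance = conc, motif = motif
  )
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (mark in names(res$consensus)) {
    for (gt in names(res$consensus[[mark]])) {
      for (s in names(res$consensus[[mark]][[gt]])) {
        write_peak_file(res$consensus[[mark]][[gt]][[s]],
                        file.path(out_dir, sprintf("consensus_%s_%s_%s.bed",
                                                   mark, gt, s)),
                        extra_cols = c("support", "source_ids"))
      }
    }
  }
  write_results_table(res$classes, file.path(out_dir, "temporal_classes.tsv"))
  write_results_table(res$annotations, file.path(out_dir, "annotations.tsv"))
  cl <- data.frame(gene = names(res$cluster_model$assignment),
                   cluster = unname(res$cluster_model$assignment))
  cl <- cbind(cl, res$profiles[cl$gene, , drop = FALSE])
  write_results_table(cl, file.path(out_dir, "clusters.tsv"))
  cen <- data.frame(cluster = seq_len(nrow(res$cluster_model$centroids)),
                    res$cluster_model$centroids)
  write_results_table(cen, file.path(out_dir, "centroids.tsv"))
  write_results_table(
    data.frame(k = as.integer(names(res$cluster_model$sse_by_k)),
               sse = unname(res$cluster_model$sse_by_k)),
    file.path(out_dir, "elbow_sse.tsv"))
  write_results_table(res$de, file.path(out_dir, "de_d35.tsv"))
  write_results_table(res$states, file.path(out_dir, "states.tsv"))
  write_results_table(res$transitions, file.path(out_dir, "transitions.tsv"))
  write_results_table(res$dbr, file.path(out_dir, "dbr_d35.tsv"))
  write_results_table(res$cluster_distribution,
                      file.path(out_dir, "cluster_distribution.tsv"))
  ro <- res$risk_overlap
  jsonlite::write_json(
    ro[c("n_risk", "n_bound_any", "pct_bound_any", "n_bound_all_stages")],
    file.path(out_dir, "risk_overlap.json"), auto_unbox = TRUE, digits = NA)
  write_results_table(res$concordance$records,
                      file.path(out_dir, "concordance.tsv"))
  sm <- res$concordance$summary
  sm$kinetics_counts <- as.list(stats::setNames(as.integer(sm$kinetics_counts),
                                                names(sm$kinetics_counts)))
  jsonlite::write_json(sm, file.path(out_dir, "concordance_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$motif)) {
    write_results_table(res$motif, file.path(out_dir, "motif_enrichment.tsv"))
  }
  invisible(out_dir)
}
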