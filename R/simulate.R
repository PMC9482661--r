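#' Generator parameters for the synthetic multi-omic study
#'
#' The defaults state the simulated world: a ~4 Mb three-chromosome genome
#' at 41% GC with ~600 genes; ~420 planted TF (CHD2-like) peaks spread over
#' the 7 temporal classes with a D0-heavy distribution; 4 replicates per
#' condition with 10 bp coordinate jitter and 10% per-replicate dropout
#' plus private noise peaks; histone marks statistically coupled to the
#' planted peaks (70% H3K27ac coupling); negative-binomial RNA counts
#' (dispersion 0.05) following 12 planted temporal archetypes; and a
#' heterozygous-genotype effect of log2FC -2 on a cell-cycle gene module
#' and +2 on a neuronal module at D35, mirrored in per-peak H3K27ac counts
#' at their promoters.
#'
#' @param seed integer RNG seed.
#' @param ... overrides for any default listed below.
#' @return named list of generator parameters.
#' @export
sim_params <- function(seed = 1L, ...) {
  p <- list(
    seed = as.integer(seed),
    chrom_lengths = c(chrS1 = 1600000L, chrS2 = 1300000L, chrS3 = 1100000L),
    gc = 0.41,
    n_genes = 600L,
    n_peaks = 420L,
    promoter_peak_frac = 0.6,
    peak_width = c(400L, 900L),
    class_weights = c("D0" = 0.30, "D15" = 0.09, "D35" = 0.07,
                      "D0+D15" = 0.10, "D0+D35" = 0.06, "D15+D35" = 0.10,
                      "D0+D15+D35" = 0.28),
    n_replicates = 4L,
    jitter_sd = 10,
    dropout = 0.1,
    noise_peaks_per_rep = 20L,
    k27ac_coupling = 0.7,
    k27ac_background = 0.1,
    k4me3_gene_frac = 0.8,
    repressed_gene_frac = 0.10,
    bivalent_gain_frac = 0.10,
    module_size = 40L,
    module_lfc = 2,
    neuronal_later_frac = 0.4,
    nb_dispersion = 0.05,
    rna_replicates = 4L,
    base_mean = c(meanlog = log(400), sdlog = 0.6),
    depth_range = c(0.8, 1.2),
    motif_consensus = "TGACGTCATC",
    motif_fg_rate = 0.8,
    cell_cycle_archetype = 2L,
    neuronal_archetype = 9L,
    marker_archetype = 6L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown sim parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$n_replicates >= 2L, p$jitter_sd >= 0,
            p$dropout >= 0, p$dropout < 1)
  stopifnot(abs(sum(p$class_weights) - 1) < 1e-6)
  p
}

#' The 12 planted temporal archetypes (D0-relative profiles)
#'
#' Rows are archetypes, columns D0/D15/D35. Shapes cover the canonical
#' differentiation repertoire: early/late/gradual down, early/late/gradual
#' up, a D15-peaking progenitor-marker shape, a D15 dip, transient shapes,
#' and a late cell-cycle-like decline. Minimum pairwise distance ~0.5 in
#' relative-profile space.
#' @return 12 x 3 numeric matrix.
#' @export
archetype_profiles <- function() {
  m <- rbind(
    c(1, 0.40, 0.10),  # 1 strong early down
    c(1, 0.90, 0.30),  # 2 late down (cell-cycle-like)
    c(1, 0.40, 0.90),  # 3 D15 dip, recovering
    c(1, 0.10, 1.80),  # 4 down then up
    c(1, 1.60, 0.40),  # 5 transient up then down
    c(1, 2.40, 1.00),  # 6 D15 peak (progenitor-marker-like)
    c(1, 1.00, 2.00),  # 7 late up
    c(1, 2.00, 2.20),  # 8 early up, sustained
    c(1, 1.00, 3.50),  # 9 strong late up (neuronal-like)
    c(1, 3.50, 3.60),  # 10 strong early up, sustained
    c(1, 3.20, 1.90),  # 11 strong D15 peak, partial retreat
    c(1, 0.20, 2.80)   # 12 sharp down then strong up
  )
  dimnames(m) <- list(paste0("archetype", 1:12), STAGES)
  m
}

random_genome <- function(chrom_lengths, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  out <- lapply(chrom_lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE, prob = probs), collapse = "")
  })
  stats::setNames(unlist(out), names(chrom_lengths))
}

# lay genes sequentially with random lengths and gaps (0-based half-open)
layout_genes <- function(chrom_lengths, n_genes) {
  rows <- list()
  gid <- 0L
  for (chr in names(chrom_lengths)) {
    pos <- 3000L
    while (pos < chrom_lengths[[chr]] - 6000L && gid < n_genes) {
      len <- sample(1500:3000, 1L)
      gid <- gid + 1L
      rows[[gid]] <- data.frame(
        gene_id = sprintf("G%04d", gid), chrom = chr,
        start = pos, end = pos + len,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE
      )
      pos <- pos + len + sample(1500:3500, 1L)
    }
  }
  do.call(rbind, rows)
}

simple_exons <- function(genes) {
  do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    len <- g$end - g$start
    data.frame(
      gene_id = g$gene_id,
      start = g$start + round(len * c(0.00, 0.45, 0.80)),
      end = g$start + round(len * c(0.30, 0.60, 1.00))
    )
  }))
}

peaks_to_granges <- function(df, name_col = "peak_id") {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  S4Vectors::mcols(gr)$name <- df[[name_col]]
  gr
}

# one jittered/dropped replicate realization of a planted peak table
realize_replicate <- function(planted, jitter_sd, dropout, chrom_lengths,
                              noise_n = 0L, noise_width = c(400L, 900L),
                              avoid = NULL, mark = NA, stage = NA,
                              genotype = NA, replicate = NA) {
  keep <- stats::runif(nrow(planted)) >= dropout
  df <- planted[keep, , drop = FALSE]
  if (nrow(df)) {
    js <- round(stats::rnorm(nrow(df), 0, jitter_sd))
    je <- round(stats::rnorm(nrow(df), 0, jitter_sd))
    df$start <- pmax(0L, as.integer(df$start + js))
    df$end <- as.integer(pmax(df$start + 50L, df$end + je))
  }
  if (noise_n > 0L) {
    got <- 0L; tries <- 0L
    ns <- ne <- integer(0); nc <- character(0)
    while (got < noise_n && tries < noise_n * 100L) {
      tries <- tries + 1L
      chr <- sample(names(chrom_lengths), 1L)
      w <- sample(noise_width[1]:noise_width[2], 1L)
      st <- sample.int(chrom_lengths[[chr]] - w, 1L)
      if (!is.null(avoid)) {
        clash <- avoid$chrom == chr & st < avoid$end + 1000L &
          st + w > avoid$start - 1000L
        if (any(clash)) next
      }
      got <- got + 1L
      nc <- c(nc, chr); ns <- c(ns, st); ne <- c(ne, st + w)
    }
    if (got) {
      df <- rbind(df[, c("peak_id", "chrom", "start", "end")],
                  data.frame(peak_id = sprintf("noise_%s_r%s_%03d",
                                               stage, replicate, seq_len(got)),
                             chrom = nc, start = ns, end = ne))
    }
  } else {
    df <- df[, c("peak_id", "chrom", "start", "end")]
  }
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = df$peak_id, score = 0, mark = mark, stage = stage,
    genotype = genotype, replicate = as.integer(replicate))
  sort_peaks(gr)
}

#' Simulate the full multi-layer synthetic study
#'
#' Generates a genome, gene models, planted TF and histone replicate peak
#' sets, RNA-seq count matrices with planted archetypes and genotype
#' effects, per-peak H3K27ac counts for differential binding, planted motif
#' instances, and a machine-readable truth ledger. Fully deterministic
#' given `params$seed`.
#'
#' @param params a [sim_params()] list.
#' @return object of class `synthetic_study`; see Details in the package
#'   vignette. Key elements: `genome` (named character), `gene_models`,
#'   `peaks` (nested list `[[mark]][[genotype]][[stage]][[replicate]]` of
#'   `GRanges`), `rna` (a [count_matrix()]), `k27ac_counts` (matrix) +
#'   `k27ac_regions` (`GRanges`), `pwms`, `risk_genes`, and `truth`.
#' @export
simulate_study <- function(params = sim_params()) {
  with_seed(params$seed, simulate_study_impl(params))
}

simulate_study_impl <- function(p) {
  genome <- random_genome(p$chrom_lengths, p$gc)
  genes <- layout_genes(p$chrom_lengths, p$n_genes)
  if (nrow(genes) < 20L) stop("genome too small for requested gene count")
  gm <- gene_models(genes, simple_exons(genes))
  genes <- gm$genes

  ## ---- planted TF peaks ------------------------------------------------
  n_prom <- round(p$promoter_peak_frac * p$n_peaks)
  n_inter <- p$n_peaks - n_prom
  if (n_prom > nrow(genes)) stop("genome too small for requested peak count")
  prom_genes <- sample(genes$gene_id, n_prom)
  gsub_ <- genes[match(prom_genes, genes$gene_id), ]
  w <- sample(p$peak_width[1]:p$peak_width[2], n_prom, replace = TRUE)
  centers <- gsub_$tss + round(stats::runif(n_prom, -300, 300))
  prom_peaks <- data.frame(
    chrom = gsub_$chrom,
    start = pmax(0L, as.integer(centers - w %/% 2)),
    end = as.integer(centers + w %/% 2),
    promoter_gene = prom_genes, stringsAsFactors = FALSE
  )
  # intergenic peaks: rejection-sample away from TSSs and other peaks
  inter <- list(); got <- 0L; tries <- 0L
  taken <- prom_peaks[, c("chrom", "start", "end")]
  while (got < n_inter && tries < n_inter * 1000L) {
    tries <- tries + 1L
    chr <- sample(names(p$chrom_lengths), 1L)
    ww <- sample(p$peak_width[1]:p$peak_width[2], 1L)
    st <- sample.int(p$chrom_lengths[[chr]] - ww, 1L)
    tss_near <- genes$chrom == chr & abs(genes$tss - st) < 3000L
    if (any(tss_near)) next
    clash <- taken$chrom == chr & st < taken$end + 2000L &
      st + ww > taken$start - 2000L
    if (any(clash)) next
    got <- got + 1L
    inter[[got]] <- data.frame(chrom = chr, start = st, end = st + ww,
                               promoter_gene = NA_character_)
    taken <- rbind(taken, data.frame(chrom = chr, start = st, end = st + ww))
  }
  if (got < n_inter) stop("infeasible placement: genome too small for peaks")
  peaks <- rbind(prom_peaks, do.call(rbind, inter))
  peaks$peak_id <- sprintf("planted_%04d", seq_len(nrow(peaks)))
  peaks$class <- sample(names(p$class_weights), nrow(peaks),
                        replace = TRUE, prob = p$class_weights)

  ## ---- gene modules and archetypes ------------------------------------
  arch <- archetype_profiles()
  prom_pool <- peaks$promoter_gene[!is.na(peaks$promoter_gene)]
  stopifnot(length(prom_pool) >= 2 * p$module_size)
  mod_genes <- sample(prom_pool, 2 * p$module_size)
  cc_genes <- mod_genes[seq_len(p$module_size)]
  neu_genes <- mod_genes[(p$module_size + 1):(2 * p$module_size)]
  genes$module <- "none"
  genes$module[genes$gene_id %in% cc_genes] <- "cell_cycle"
  genes$module[genes$gene_id %in% neu_genes] <- "neuronal"
  genes$archetype <- sample(seq_len(nrow(arch)), nrow(genes), replace = TRUE)
  genes$archetype[genes$module == "cell_cycle"] <- p$cell_cycle_archetype
  genes$archetype[genes$module == "neuronal"] <- p$neuronal_archetype
  genes$planted_lfc_d35 <- ifelse(genes$module == "cell_cycle", -p$module_lfc,
                                  ifelse(genes$module == "neuronal",
                                         p$module_lfc, 0))
  # module peak classes drive the binding-kinetics story: the repressed
  # (cell-cycle) module is bound throughout; a planted fraction of the
  # activated (neuronal) module is bound only later
  cc_idx <- which(peaks$promoter_gene %in% cc_genes)
  peaks$class[cc_idx] <- "D0+D15+D35"
  neu_idx <- which(peaks$promoter_gene %in% neu_genes)
  later <- stats::runif(length(neu_idx)) < p$neuronal_later_frac
  peaks$class[neu_idx] <- ifelse(later,
                                 sample(c("D15+D35", "D35"),
                                        length(neu_idx), replace = TRUE),
                                 "D0+D15+D35")
  peaks$module <- "none"
  peaks$module[cc_idx] <- "cell_cycle"
  peaks$module[neu_idx] <- "neuronal"
  peaks$k27ac_coupled <- stats::runif(nrow(peaks)) < p$k27ac_coupling
  peaks$k27ac_coupled[peaks$module != "none"] <- TRUE

  ## ---- motif planting --------------------------------------------------
  cons <- p$motif_consensus
  Lm <- nchar(cons)
  d35_unique <- which(peaks$class == "D35")
  planted_motif <- d35_unique[stats::runif(length(d35_unique)) < p$motif_fg_rate]
  peaks$motif_planted <- seq_len(nrow(peaks)) %in% planted_motif
  for (i in planted_motif) {
    off <- sample.int(max(1L, peaks$end[i] - peaks$start[i] - Lm), 1L)
    pos1 <- peaks$start[i] + off # 0-based offset -> 1-based substr start
    chr <- peaks$chrom[i]
    substr(genome[[chr]], pos1, pos1 + Lm - 1L) <- cons
  }
  count_mat <- function(consensus, strong = 0.94) {
    bases <- strsplit(consensus, "")[[1]]
    m <- matrix((1 - strong) / 3, nrow = 4, ncol = length(bases),
                dimnames = list(DNA_BASES, NULL))
    for (j in seq_along(bases)) m[bases[j], j] <- strong
    m * 100
  }
  pwms <- list(
    planted = pwm("planted_motif", count_mat(cons), tf_class = "bZIP-like"),
    decoyA = pwm("decoyA", count_mat("CACGTGACTG"), tf_class = "bHLH-like"),
    decoyB = pwm("decoyB", count_mat("GGGCGGGGCC"), tf_class = "ZF-like"),
    decoyC = pwm("decoyC", count_mat("TAATTAGCTA"), tf_class = "HD-like")
  )

  ## ---- replicate peak realizations ------------------------------------
  avoid <- peaks[, c("chrom", "start", "end")]
  stage_present <- function(df, s) df[grepl(s, df$class), , drop = FALSE]
  tf_sets <- list(WT = list())
  for (s in STAGES) {
    planted_s <- stage_present(peaks, s)
    tf_sets$WT[[s]] <- lapply(seq_len(p$n_replicates), function(r) {
      realize_replicate(planted_s, p$jitter_sd, p$dropout, p$chrom_lengths,
                        noise_n = p$noise_peaks_per_rep,
                        noise_width = p$peak_width, avoid = avoid,
                        mark = "CHD2", stage = s, genotype = "WT",
                        replicate = r)
    })
  }

  # histone planted tables
  k4_genes <- sample(genes$gene_id, round(p$k4me3_gene_frac * nrow(genes)))
  non_k4 <- setdiff(genes$gene_id, k4_genes)
  repressed_genes <- sample(non_k4, min(length(non_k4),
                                        round(p$repressed_gene_frac * nrow(genes))))
  bivalent_genes <- sample(k4_genes, round(p$bivalent_gain_frac * length(k4_genes)))
  prom_region <- function(gids, width = 800L, tag) {
    g <- genes[match(gids, genes$gene_id), ]
    data.frame(peak_id = sprintf("%s_%s", tag, g$gene_id), chrom = g$chrom,
               start = pmax(0L, g$tss - width %/% 2L),
               end = g$tss + width %/% 2L, stringsAsFactors = FALSE)
  }
  k4_planted <- prom_region(k4_genes, tag = "k4")
  k27me3_const <- prom_region(repressed_genes, width = 1200L, tag = "k27me3")
  k27me3_biv <- prom_region(bivalent_genes, width = 1200L, tag = "k27me3biv")
  # K27ac over coupled TF peaks at their bound stages, plus background
  bg_ac_genes <- lapply(STAGES, function(s) {
    pool <- setdiff(genes$gene_id, prom_pool)
    sample(pool, round(p$k27ac_background * length(pool)))
  })
  names(bg_ac_genes) <- STAGES

  hist_sets <- list()
  for (mark in HISTONE_MARKS) hist_sets[[mark]] <- list(WT = list(), HET = list())
  for (s in STAGES) {
    k4_s <- k4_planted
    k27me3_s <- if (s == "D0") k27me3_const else rbind(k27me3_const, k27me3_biv)
    ac_tf <- stage_present(peaks[peaks$k27ac_coupled, , drop = FALSE], s)
    ac_tf <- data.frame(peak_id = paste0("ac_", ac_tf$peak_id),
                        chrom = ac_tf$chrom, start = ac_tf$start,
                        end = ac_tf$end)
    ac_bg <- prom_region(bg_ac_genes[[s]], tag = paste0("acbg", s))
    ac_s <- rbind(ac_tf, ac_bg)
    for (gt in c("WT", "HET")) {
      hist_sets$H3K27ac[[gt]][[s]] <- lapply(seq_len(p$n_replicates),
        function(r) realize_replicate(ac_s, p$jitter_sd, p$dropout,
                                      p$chrom_lengths, mark = "H3K27ac",
                                      stage = s, genotype = gt, replicate = r))
    }
    hist_sets$H3K4me3$WT[[s]] <- lapply(seq_len(p$n_replicates),
      function(r) realize_replicate(k4_s, p$jitter_sd, p$dropout,
                                    p$chrom_lengths, mark = "H3K4me3",
                                    stage = s, genotype = "WT", replicate = r))
    hist_sets$H3K27me3$WT[[s]] <- lapply(seq_len(p$n_replicates),
      function(r) realize_replicate(k27me3_s, p$jitter_sd, p$dropout,
                                    p$chrom_lengths, mark = "H3K27me3",
                                    stage = s, genotype = "WT", replicate = r))
  }

  ## ---- RNA counts -------------------------------------------------------
  base <- pmin(5000, pmax(50, stats::rlnorm(nrow(genes),
                                            p$base_mean["meanlog"],
                                            p$base_mean["sdlog"])))
  genes$base_mean <- base
  prof <- arch[genes$archetype, , drop = FALSE]
  samples <- expand.grid(replicate = seq_len(p$rna_replicates),
                         genotype = c("WT", "HET"), stage = STAGES,
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_%s_r%d", samples$stage, samples$genotype,
                            samples$replicate)
  samples$depth <- stats::runif(nrow(samples), p$depth_range[1],
                                p$depth_range[2])
  size <- 1 / p$nb_dispersion
  counts <- matrix(0, nrow(genes), nrow(samples),
                   dimnames = list(genes$gene_id, samples$sample))
  expected_lib <- numeric(nrow(samples))
  for (j in seq_len(nrow(samples))) {
    s <- samples$stage[j]; gt <- samples$genotype[j]
    mu <- base * prof[, s] * samples$depth[j]
    if (gt == "HET" && s == "D35") mu <- mu * 2^genes$planted_lfc_d35
    mu <- pmax(mu, 0.01)
    counts[, j] <- stats::rnbinom(length(mu), mu = mu, size = size)
    expected_lib[j] <- sum(mu)
  }
  samples$expected_library <- expected_lib
  gene_lengths <- stats::setNames(genes$end - genes$start, genes$gene_id)
  rna <- count_matrix(counts, samples[, c("sample", "stage", "genotype",
                                          "replicate", "depth",
                                          "expected_library")],
                      gene_lengths)

  ## ---- per-peak H3K27ac counts at D35 (DBR layer) ----------------------
  ac_d35 <- stage_present(peaks[peaks$k27ac_coupled, , drop = FALSE], "D35")
  ac_bg35 <- prom_region(bg_ac_genes$D35, tag = "acbgD35")
  ac_bg35$module <- "none"; ac_bg35$promoter_gene <- sub("^acbgD35_", "", ac_bg35$peak_id)
  ac_feat <- rbind(
    data.frame(peak_id = paste0("ac_", ac_d35$peak_id), chrom = ac_d35$chrom,
               start = ac_d35$start, end = ac_d35$end,
               module = ac_d35$module, promoter_gene = ac_d35$promoter_gene),
    ac_bg35
  )
  ac_base <- stats::rlnorm(nrow(ac_feat), log(300), 0.5)
  ac_lfc <- ifelse(ac_feat$module == "cell_cycle", -p$module_lfc,
                   ifelse(ac_feat$module == "neuronal", p$module_lfc, 0))
  ac_samples <- sprintf("K27ac_D35_%s_r%d",
                        rep(c("WT", "HET"), each = p$n_replicates),
                        rep(seq_len(p$n_replicates), 2))
  ac_counts <- matrix(0, nrow(ac_feat), length(ac_samples),
                      dimnames = list(ac_feat$peak_id, ac_samples))
  for (j in seq_along(ac_samples)) {
    gt <- if (grepl("_WT_", ac_samples[j])) "WT" else "HET"
    mu <- ac_base * if (gt == "HET") 2^ac_lfc else 1
    ac_counts[, j] <- stats::rnbinom(length(mu), mu = pmax(mu, 0.01),
                                     size = size)
  }
  ac_regions <- peaks_to_granges(ac_feat)

  ## ---- risk gene list ---------------------------------------------------
  bound_genes <- unique(stats::na.omit(peaks$promoter_gene))
  n_risk_bound <- min(length(bound_genes), 52L)
  unbound <- setdiff(genes$gene_id, bound_genes)
  risk <- c(sample(bound_genes, n_risk_bound),
            sample(unbound, min(length(unbound), 50L)))
  risk <- sort(unique(risk))

  gm$genes <- genes
  truth <- list(
    params = p,
    genes = genes[, c("gene_id", "chrom", "start", "end", "strand",
                      "module", "archetype", "planted_lfc_d35", "base_mean")],
    peaks = peaks[, c("peak_id", "chrom", "start", "end", "class",
                      "promoter_gene", "module", "k27ac_coupled",
                      "motif_planted")],
    dbr = data.frame(peak_id = ac_feat$peak_id, chrom = ac_feat$chrom,
                     start = ac_feat$start, end = ac_feat$end,
                     module = ac_feat$module, gene_id = ac_feat$promoter_gene,
                     planted_lfc = ac_lfc, stringsAsFactors = FALSE),
    samples = samples,
    motif = list(consensus = cons,
                 planted_peaks = peaks$peak_id[peaks$motif_planted])
  )
  structure(list(
    genome = genome, gene_models = gm,
    peaks = c(list(CHD2 = tf_sets), hist_sets),
    rna = rna, k27ac_counts = ac_counts, k27ac_regions = ac_regions,
    pwms = pwms, risk_genes = risk, truth = truth
  ), class = "synthetic_study")
}

#' Write a synthetic study to disk in pipeline-consumable formats
#'
#' BED peak files per (mark, genotype, stage, replicate), a sample sheet,
#' TSV count matrices, FASTA genome, JASPAR PWMs, the risk-gene list, the
#' gene models, and the truth ledger as TSVs plus a flat params file.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- file.path(dir, "peaks")
  dir.create(pd, showWarnings = FALSE)
  sheet <- list()
  k <- 0L
  for (mark in names(study$peaks)) {
    for (gt in names(study$peaks[[mark]])) {
      for (s in names(study$peaks[[mark]][[gt]])) {
        reps <- study$peaks[[mark]][[gt]][[s]]
        for (r in seq_along(reps)) {
          fn <- sprintf("%s_%s_%s_r%d.bed", mark, gt, s, r)
          write_peak_file(reps[[r]], file.path(pd, fn))
          k <- k + 1L
          sheet[[k]] <- data.frame(sample = sub("\\.bed$", "", fn),
                                   mark = mark, stage = s, genotype = gt,
                                   replicate = r,
                                   path = file.path("peaks", fn))
        }
      }
    }
  }
  write_results_table(do.call(rbind, sheet), file.path(dir, "peak_samples.tsv"))
  write_count_table(study$rna$counts, file.path(dir, "rna_counts.tsv"))
  write_results_table(study$rna$meta, file.path(dir, "rna_samples.tsv"))
  write_count_table(study$k27ac_counts, file.path(dir, "k27ac_counts.tsv"),
                    id_col = "peak")
  write_peak_file(study$k27ac_regions, file.path(dir, "k27ac_regions.bed"))
  g <- study$gene_models$genes
  write_results_table(g, file.path(dir, "genes.tsv"))
  write_results_table(study$gene_models$exons, file.path(dir, "exons.tsv"))
  writeLines(study$risk_genes, file.path(dir, "risk_genes.txt"))
  fa <- Biostrings::DNAStringSet(study$genome)
  Biostrings::writeXStringSet(fa, file.path(dir, "genome.fa"))
  write_jaspar(study$pwms, file.path(dir, "motifs.jaspar"))
  td <- file.path(dir, "truth")
  dir.create(td, showWarnings = FALSE)
  write_results_table(study$truth$genes, file.path(td, "genes.tsv"))
  write_results_table(study$truth$peaks, file.path(td, "peaks.tsv"))
  write_results_table(study$truth$dbr, file.path(td, "dbr.tsv"))
  write_results_table(study$truth$samples, file.path(td, "samples.tsv"))
  p <- study$truth$params
  scal <- vapply(p, function(v) length(v) == 1L && !is.list(v), logical(1))
  lines <- c(
    vapply(names(p)[scal], function(k2) paste0(k2, ": ", format(p[[k2]])),
           character(1)),
    vapply(names(p)[!scal], function(k2)
      paste0(k2, ": [", paste(format(p[[k2]]), collapse = ", "), "]"),
      character(1))
  )
  writeLines(lines, file.path(td, "params.yaml"))
  writeLines(c(study$truth$motif$consensus, study$truth$motif$planted_peaks),
             file.path(td, "motif.txt"))
  invisible(dir)
}

#' Export a committed-size synthetic fixture
#'
#' `"tiny"` (about 60 peaks, 100 genes, 2 chromosomes) drives fast unit
#' tests; `"default"` is the full stated world, regenerated on demand.
#'
#' @param size `"tiny"` or `"default"`.
#' @param dir output directory; if `NULL`, the study is returned unwritten.
#' @param seed generator seed.
#' @return the `synthetic_study`, invisibly if written.
#' @export
export_fixture <- function(size = c("tiny", "default"), dir = NULL,
                           seed = 20240101L) {
  size <- match.arg(size)
  params <- if (size == "tiny") {
    sim_params(seed = seed,
               chrom_lengths = c(chrS1 = 300000L, chrS2 = 250000L),
               n_genes = 80L, n_peaks = 60L, noise_peaks_per_rep = 5L,
               module_size = 8L)
  } else {
    sim_params(seed = seed)
  }
  study <- simulate_study(params)
  if (!is.null(dir)) {
    write_study(study, dir)
    return(invisible(study))
  }
  study
}
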