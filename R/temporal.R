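STAGES <- c("D0", "D15", "D35")

# canonical class label for a membership subset, e.g. "D0+D35"
class_label <- function(stages) {
  paste(STAGES[STAGES %in% stages], collapse = "+")
}

#' Temporal binding classification of consensus peaks
#'
#' Links consensus peaks across the three differentiation stages with the
#' same reciprocal-fraction overlap predicate used for replicate consensus.
#' Each cross-stage connected component receives a membership label equal to
#' the set of stages contributing a peak (one of the 7 nonempty subsets of
#' D0/D15/D35); a peak with no cross-stage partner keeps its own stage as a
#' singleton ("unique") class. Chained overlaps (D0-D15 and D15-D35 without
#' a direct D0-D35 overlap) are classed via the component, i.e. all three
#' stages.
#'
#' @param peaks_by_stage named list `D0`/`D15`/`D35` of consensus `GRanges`.
#' @param cfg an [analysis_config()].
#' @return data.frame with `peak`, `stage`, `class` (membership label),
#'   `chrom`, `start` (0-based), `end`, plus a `component` id.
#' @export
classify_temporal <- function(peaks_by_stage, cfg = analysis_config()) {
  bad <- setdiff(names(peaks_by_stage), STAGES)
  if (length(bad)) stop("unknown stage key(s): ", paste(bad, collapse = ", "))
  if (!all(STAGES %in% names(peaks_by_stage))) {
    stop("all three stages (D0, D15, D35) must be present")
  }
  peaks_by_stage <- peaks_by_stage[STAGES]
  stage_of <- rep(STAGES, vapply(peaks_by_stage, length, 1L))
  all_peaks <- suppressWarnings(do.call(c, unname(peaks_by_stage)))
  n <- length(all_peaks)
  if (n == 0L) {
    return(data.frame(peak = character(0), stage = character(0),
                      class = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      component = integer(0)))
  }
  pairs <- overlap_pairs(all_peaks, all_peaks, cfg)
  pairs <- pairs[stage_of[pairs[, 1]] != stage_of[pairs[, 2]], , drop = FALSE]
  comp <- uf_components(n, pairs)
  membership <- tapply(stage_of, comp, function(s) class_label(unique(s)))
  nm <- S4Vectors::mcols(all_peaks)$name
  if (is.null(nm)) nm <- paste0("peak", seq_len(n))
  # disambiguate identical names across stages
  nm <- paste(stage_of, nm, sep = ":")
  data.frame(
    peak = nm,
    stage = stage_of,
    class = unname(membership[as.character(comp)]),
    chrom = as.character(GenomicRanges::seqnames(all_peaks)),
    start = GenomicRanges::start(all_peaks) - 1L,
    end = GenomicRanges::end(all_peaks),
    component = as.integer(comp),
    stringsAsFactors = FALSE
  )
}

# counts per membership class over the 7-subset taxonomy
temporal_class_counts <- function(classes) {
  comp <- classes[!duplicated(classes$component), ]
  table(factor(comp$class, levels = all_class_labels()))
}

all_class_labels <- function() {
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(STAGES, k, simplify = FALSE)), recursive = FALSE)
  vapply(subsets, class_label, character(1))
}

#' Build a gene model table
#'
#' Validates and normalizes a gene model data.frame. Coordinates are BED
#' 0-based half-open gene bodies; the TSS is the strand-aware first base and
#' the TTS the last. Exons are supplied as a separate table of blocks.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param exons data.frame with `gene_id`, `start`, `end` (0-based half-open).
#' @return list of class `gene_models` with `genes` (plus derived `tss`,
#'   `tts`, 1-based) and `exons`.
#' @export
gene_models <- function(genes, exons = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  stopifnot(all(need %in% names(genes)))
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("gene model lacking strand (+/- required)")
  }
  stopifnot(all(genes$start < genes$end))
  genes$tss <- ifelse(genes$strand == "+", genes$start + 1L, genes$end)
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start + 1L)
  if (is.null(exons)) {
    exons <- genes[, c("gene_id", "start", "end")]
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

# TSS anchor table for nearest_feature()
tss_table <- function(gm) {
  data.frame(gene_id = gm$genes$gene_id, chrom = gm$genes$chrom,
             tss = gm$genes$tss, strand = gm$genes$strand,
             stringsAsFactors = FALSE)
}

#' Annotate peaks to genomic features
#'
#' Assigns each peak (by its midpoint) one category with precedence
#' promoter > exon > intron > TTS > intergenic: promoter when the midpoint
#' lies within +/- `promoter_window_bp` of any TSS; exon/intron by midpoint
#' membership in a gene body; TTS within +/- `tts_window_bp` of a transcript
#' end. The nearest gene and signed TSS distance come from
#' [nearest_feature()]; `promoter_proximal` is `|distance| <=
#' promoter_window_bp`.
#'
#' @param peaks a `GRanges`.
#' @param gm a [gene_models()] object.
#' @param cfg an [analysis_config()].
#' @return data.frame: `peak`, `category`, `gene_id`, `distance`,
#'   `promoter_proximal`.
#' @export
annotate_peaks <- function(peaks, gm, cfg = analysis_config()) {
  stopifnot(inherits(gm, "gene_models"))
  nf <- nearest_feature(peaks, tss_table(gm))
  mid <- interval_midpoint(peaks) # 1-based
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  g <- gm$genes
  ex <- gm$exons
  n <- length(peaks)
  category <- rep("intergenic", n)
  # promoter: within window of ANY tss
  win <- cfg$promoter_window_bp
  is_promoter <- logical(n)
  in_exon <- logical(n)
  in_gene <- logical(n)
  near_tts <- logical(n)
  for (chr in unique(chrom)) {
    qi <- which(chrom == chr)
    gc <- g[g$chrom == chr, , drop = FALSE]
    if (nrow(gc) == 0L) next
    m <- mid[qi]
    # any-TSS promoter test via sorted anchors
    ts <- sort(gc$tss)
    lo <- findInterval(m, ts)
    near <- function(idx) idx >= 1 & idx <= length(ts) &
      abs(ts[pmax(1L, pmin(length(ts), idx))] - m) <= win
    is_promoter[qi] <- near(lo) | near(lo + 1L)
    tt <- sort(gc$tts)
    lo2 <- findInterval(m, tt)
    near2 <- function(idx) idx >= 1 & idx <= length(tt) &
      abs(tt[pmax(1L, pmin(length(tt), idx))] - m) <= cfg$tts_window_bp
    near_tts[qi] <- near2(lo2) | near2(lo2 + 1L)
    # gene-body / exon membership (0-based half-open bodies; midpoint m is
    # 1-based, so body covers m iff start < m <= end)
    for (k in seq_len(nrow(gc))) {
      inside <- m > gc$start[k] & m <= gc$end[k]
      in_gene[qi] <- in_gene[qi] | inside
    }
    exc <- ex[ex$gene_id %in% gc$gene_id, , drop = FALSE]
    for (k in seq_len(nrow(exc))) {
      inside <- m > exc$start[k] & m <= exc$end[k]
      in_exon[qi] <- in_exon[qi] | inside
    }
  }
  category[near_tts] <- "TTS"
  category[in_gene] <- "intron"
  category[in_gene & in_exon] <- "exon"
  category[is_promoter] <- "promoter"
  nm <- S4Vectors::mcols(peaks)$name
  if (is.null(nm)) nm <- paste0("peak", seq_len(n))
  data.frame(
    peak = nm, category = category, gene_id = nf$gene_id,
    distance = nf$distance,
    promoter_proximal = !is.na(nf$distance) & abs(nf$distance) <= win,
    stringsAsFactors = FALSE
  )
}

#' Genes with stage-unique promoter-proximal peaks
#'
#' Returns the deduplicated set of genes having at least one peak whose
#' temporal class is the singleton of `stage` and which is
#' promoter-proximal.
#'
#' @param classes output of [classify_temporal()] for the same peak universe.
#' @param annotations output of [annotate_peaks()]; `peak` ids must align
#'   with `classes$peak`.
#' @param stage one of `"D0"`, `"D15"`, `"D35"`.
#' @return character vector of gene ids.
#' @export
stage_unique_promoter_genes <- function(classes, annotations, stage) {
  stopifnot(stage %in% STAGES)
  m <- merge(classes[, c("peak", "class")],
             annotations[, c("peak", "gene_id", "promoter_proximal")],
             by = "peak")
  hit <- m$class == stage & m$promoter_proximal
  sort(unique(m$gene_id[hit & !is.na(m$gene_id)]))
}
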