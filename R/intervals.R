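#' Reciprocal-fraction overlap predicate
#'
#' The replicate-reproducibility rule used throughout the pipeline, modelled
#' on `bedtools intersect -f A -F B [-e]`: with `o` the overlap length in bp,
#' two intervals overlap iff `o > 0` and `o >= frac_a * len(a)` OR (either
#' mode) / AND (reciprocal mode) `o >= frac_b * len(b)`. Different
#' chromosomes never overlap; strand is ignored.
#'
#' @param a,b `GRanges` of equal length (compared pairwise) or one of length 1.
#' @param frac_a,frac_b required overlap fractions in (0, 1].
#' @param either if `TRUE`, either fraction criterion suffices.
#' @return logical vector.
#' @export
interval_overlaps <- function(a, b, frac_a = 0.25, frac_b = 0.25,
                              either = TRUE) {
  if (!(frac_a > 0 && frac_a <= 1) || !(frac_b > 0 && frac_b <= 1)) {
    stop("overlap fractions must be in (0, 1]")
  }
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same_chrom <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  o <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
  o <- pmax(o, 0L)
  hit_a <- o >= frac_a * GenomicRanges::width(a)
  hit_b <- o >= frac_b * GenomicRanges::width(b)
  same_chrom & o > 0L & (if (either) hit_a | hit_b else hit_a & hit_b)
}

# All (query, subject) index pairs passing the configured overlap predicate.
# Candidate pairs come from an interval-tree search; the fraction test is
# applied on top. Returns a two-column integer matrix.
overlap_pairs <- function(query, subject, cfg) {
  hits <- GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("query", "subject"))))
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  keep <- interval_overlaps(query[qi], subject[si],
                            frac_a = cfg$overlap_frac_query,
                            frac_b = cfg$overlap_frac_subject,
                            either = cfg$overlap_either)
  cbind(query = qi[keep], subject = si[keep])
}

# Union-find with path halving; ids are 1..n.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}
uf_components <- function(n, edges) {
  parent <- uf_new(n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ri <- uf_find(parent, edges[k, 1])
      rj <- uf_find(parent, edges[k, 2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), 1L)
}

#' Replicate-consensus (reproducible) peaks
#'
#' Builds a graph over all replicate peaks with edges between peaks from
#' distinct replicates that satisfy the reciprocal-fraction overlap
#' predicate, and emits one consensus peak per connected component spanning
#' at least `cfg$min_replicate_support` distinct replicates. Consensus
#' coordinates are the component's coordinate union by default (so every
#' supporting replicate peak is contained in the consensus interval).
#'
#' @param replicate_sets list of `GRanges`, one per replicate, all from one
#'   (mark, stage, genotype).
#' @param cfg an [analysis_config()].
#' @return a sorted `GRanges` with `mcols` `name`, `support` (distinct
#'   replicates) and `source_ids` (comma-joined supporter names).
#' @export
consensus_peaks <- function(replicate_sets, cfg = analysis_config()) {
  stopifnot(length(replicate_sets) >= 2L)
  for (m in c("mark", "stage", "genotype")) {
    vals <- unlist(lapply(replicate_sets, function(g) {
      v <- unique(S4Vectors::mcols(g)[[m]])
      v[!is.na(v)]
    }))
    if (length(unique(vals)) > 1L) {
      stop("replicate sets disagree on metadata field '", m, "'")
    }
  }
  rep_id <- rep(seq_along(replicate_sets),
                vapply(replicate_sets, length, 1L))
  all_peaks <- suppressWarnings(do.call(c, unname(replicate_sets)))
  n <- length(all_peaks)
  if (n == 0L) return(empty_consensus())
  pairs <- overlap_pairs(all_peaks, all_peaks, cfg)
  pairs <- pairs[rep_id[pairs[, 1]] != rep_id[pairs[, 2]], , drop = FALSE]
  comp <- uf_components(n, pairs)
  keep_comp <- tapply(rep_id, comp, function(r) length(unique(r)))
  keep_ids <- as.integer(names(keep_comp))[keep_comp >= cfg$min_replicate_support]
  if (length(keep_ids) == 0L) return(empty_consensus())
  out <- lapply(keep_ids, function(cid) {
    idx <- which(comp == cid)
    members <- all_peaks[idx]
    chrom <- as.character(GenomicRanges::seqnames(members))[1]
    coords <- switch(cfg$consensus_coords,
      union = c(min(GenomicRanges::start(members)),
                max(GenomicRanges::end(members))),
      intersection = c(max(GenomicRanges::start(members)),
                       min(GenomicRanges::end(members))),
      median = c(round(stats::median(GenomicRanges::start(members))),
                 round(stats::median(GenomicRanges::end(members))))
    )
    if (coords[1] > coords[2]) coords <- rev(coords)
    nm <- S4Vectors::mcols(members)$name
    list(chrom = chrom, start = coords[1], end = coords[2],
         support = length(unique(rep_id[idx])),
         source_ids = paste(sort(nm), collapse = ","))
  })
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(out, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(out, `[[`, numeric(1), "start"),
      end = vapply(out, `[[`, numeric(1), "end")
    )
  )
  S4Vectors::mcols(gr)$support <- vapply(out, `[[`, integer(1), "support")
  S4Vectors::mcols(gr)$source_ids <- vapply(out, `[[`, character(1), "source_ids")
  gr <- sort_peaks(gr)
  S4Vectors::mcols(gr)$name <- sprintf("consensus_%05d", seq_along(gr))
  mark <- unique(stats::na.omit(unlist(lapply(replicate_sets, function(g)
    S4Vectors::mcols(g)$mark))))
  stage <- unique(stats::na.omit(unlist(lapply(replicate_sets, function(g)
    S4Vectors::mcols(g)$stage))))
  S4Vectors::mcols(gr)$mark <- if (length(mark)) mark[1] else NA_character_
  S4Vectors::mcols(gr)$stage <- if (length(stage)) stage[1] else NA_character_
  gr
}

empty_consensus <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$support <- integer(0)
  S4Vectors::mcols(gr)$source_ids <- character(0)
  S4Vectors::mcols(gr)$name <- character(0)
  S4Vectors::mcols(gr)$mark <- character(0)
  S4Vectors::mcols(gr)$stage <- character(0)
  gr
}

# midpoint of a GRanges interval (1-based internal coordinates)
interval_midpoint <- function(gr) {
  (GenomicRanges::start(gr) + GenomicRanges::end(gr)) %/% 2L
}

#' Nearest TSS (or other anchored feature) lookup
#'
#' For each query interval, finds the feature whose anchor point (TSS)
#' minimizes the unsigned distance to the query midpoint. Ties are broken by
#' the lexicographically smaller feature id. The signed distance is negative
#' when the midpoint lies upstream of the anchor with respect to the
#' feature's strand.
#'
#' @param query a `GRanges`.
#' @param features a data.frame with columns `gene_id`, `chrom`, `tss`
#'   (1-based position of the anchor base) and `strand` (`+`/`-`).
#' @return data.frame with `gene_id` and signed `distance` per query; NA for
#'   queries on chromosomes absent from the feature table.
#' @export
nearest_feature <- function(query, features) {
  if (nrow(features) == 0L) stop("empty feature table")
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(features)))
  mid <- interval_midpoint(query)
  qchrom <- as.character(GenomicRanges::seqnames(query))
  out_gene <- rep(NA_character_, length(query))
  out_dist <- rep(NA_real_, length(query))
  for (chr in unique(qchrom)) {
    f <- features[features$chrom == chr, , drop = FALSE]
    qi <- which(qchrom == chr)
    if (nrow(f) == 0L) next
    # sort anchors; tie-break inside equal-distance groups by gene id
    o <- order(f$tss, f$gene_id)
    f <- f[o, , drop = FALSE]
    m <- mid[qi]
    idx_right <- findInterval(m, f$tss) # last anchor <= m (0 if none)
    pick <- integer(length(m))
    dist_u <- numeric(length(m))
    for (k in seq_along(m)) {
      lo <- idx_right[k]
      cand <- unique(pmax(1L, pmin(nrow(f), c(lo, lo + 1L))))
      d <- abs(f$tss[cand] - m[k])
      best <- min(d)
      # candidates at the minimal distance; include equal-tss duplicates
      at <- which(abs(f$tss - m[k]) == best)
      sel <- at[order(f$gene_id[at])][1]
      pick[k] <- sel
      dist_u[k] <- best
    }
    strand_sign <- ifelse(f$strand[pick] == "-", -1, 1)
    out_gene[qi] <- f$gene_id[pick]
    out_dist[qi] <- strand_sign * (m - f$tss[pick])
  }
  data.frame(gene_id = out_gene, distance = out_dist,
             stringsAsFactors = FALSE)
}
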