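#' Cluster-distribution enrichment of a gene set
#'
#' Distributes a query gene set across the fitted expression clusters and
#' tests per-cluster enrichment with the hypergeometric upper tail against
#' the clustered universe, BH-adjusted across the K clusters.
#'
#' @param query_genes character vector of gene ids; restricted to the
#'   clustered universe.
#' @param model a `cluster_model` from [fit_clusters()].
#' @return data.frame per cluster: `cluster`, `observed`, `universe_count`,
#'   `fold_enrichment`, `pvalue`, `qvalue`.
#' @export
cluster_distribution <- function(query_genes, model) {
  universe <- names(model$assignment)
  q <- intersect(unique(query_genes), universe)
  k <- nrow(model$centroids)
  sizes <- tabulate(model$assignment, nbins = k)
  if (length(q) == 0L) {
    warning("query has empty intersection with the clustered universe")
    obs <- integer(k)
  } else {
    obs <- tabulate(model$assignment[q], nbins = k)
  }
  n_u <- length(universe)
  n_q <- length(q)
  expected <- n_q * sizes / n_u
  fold <- ifelse(expected > 0, obs / expected, NA_real_)
  p <- stats::phyper(obs - 1L, sizes, n_u - sizes, n_q, lower.tail = FALSE)
  data.frame(
    cluster = seq_len(k), observed = obs, universe_count = sizes,
    fold_enrichment = fold, pvalue = p,
    qvalue = stats::p.adjust(p, method = "BH")
  )
}

#' Overlap of stage-bound gene sets with a curated risk-gene list
#'
#' @param bound_genes_by_stage named list `D0`/`D15`/`D35` of gene-id sets
#'   bound at each stage.
#' @param risk_list character vector of risk genes (same id namespace).
#' @return list: `n_risk`, `n_bound_any`, `pct_bound_any`,
#'   `n_bound_all_stages`, `per_stage` (named counts).
#' @export
gene_list_overlap <- function(bound_genes_by_stage, risk_list) {
  risk_list <- unique(risk_list)
  if (length(risk_list) == 0L) stop("empty risk list")
  stopifnot(all(STAGES %in% names(bound_genes_by_stage)))
  sets <- lapply(bound_genes_by_stage[STAGES], unique)
  any_bound <- intersect(risk_list, Reduce(union, sets))
  all_bound <- intersect(risk_list, Reduce(intersect, sets))
  list(
    n_risk = length(risk_list),
    n_bound_any = length(any_bound),
    pct_bound_any = 100 * length(any_bound) / length(risk_list),
    n_bound_all_stages = length(all_bound),
    per_stage = vapply(sets, function(s) length(intersect(risk_list, s)), 1L)
  )
}

KINETICS_LEVELS <- c("all_stages", "later_only", "other", "unbound")

# kinetics class from a temporal membership label ("D0+D15+D35" etc.)
kinetics_from_class <- function(class) {
  ifelse(class == "D0+D15+D35", "all_stages",
         ifelse(class %in% c("D15+D35", "D35"), "later_only", "other"))
}

#' Direction-concordant DBR x DEG x binding integration
#'
#' For each differentially bound region (DBR): assigns the nearest gene by
#' TSS distance from the DBR midpoint, looks up that gene's differential
#' expression direction, flags concordance (same non-ns direction), tests
#' whether the DBR overlaps a CHD2 consensus peak whose temporal class
#' contains D35 (bound in the terminal cell type), and classifies the
#' binding kinetics of that peak: `all_stages` for class D0+D15+D35,
#' `later_only` for D15+D35 or D35, `other` for any other D35-containing
#' class, `unbound` when no D35-class peak overlaps. When several
#' D35-containing peaks overlap one DBR, the peak with the largest overlap
#' is used.
#'
#' @param dbrs data.frame with `peak`, `chrom`, `start` (0-based), `end`,
#'   `direction` (`up`/`down`) — e.g. significant rows of
#'   [differential_binding()] joined to their intervals.
#' @param degs data.frame with `gene`, `direction` from
#'   [differential_expression()].
#' @param chd2_classes output of [classify_temporal()] on CHD2 consensus
#'   peaks (provides intervals and class per peak).
#' @param gm a [gene_models()] object (TSS table for nearest-gene lookup).
#' @param cfg an [analysis_config()].
#' @return list with `records` (one row per DBR: `dbr`, `dbr_direction`,
#'   `gene_id`, `deg_direction`, `concordant`, `chd2_bound_hcIN`,
#'   `kinetics`) and `summary` (named counts incl. the later-only fraction
#'   among bound concordant-up records).
#' @export
concordant_triples <- function(dbrs, degs, chd2_classes, gm,
                               cfg = analysis_config()) {
  stopifnot(all(c("peak", "chrom", "start", "end", "direction") %in%
                  names(dbrs)))
  stopifnot(all(dbrs$direction %in% c("up", "down")))
  dbr_gr <- GenomicRanges::GRanges(
    dbrs$chrom, IRanges::IRanges(dbrs$start + 1L, dbrs$end))
  nf <- nearest_feature(dbr_gr, tss_table(gm))
  deg_dir <- stats::setNames(degs$direction, degs$gene)
  gdir <- unname(deg_dir[nf$gene_id])
  gdir[is.na(gdir)] <- "ns"
  # D35-containing CHD2 peaks
  d35 <- chd2_classes[grepl("D35", chd2_classes$class), , drop = FALSE]
  bound <- logical(nrow(dbrs))
  kin <- rep("unbound", nrow(dbrs))
  if (nrow(d35)) {
    d35_gr <- GenomicRanges::GRanges(
      d35$chrom, IRanges::IRanges(d35$start + 1L, d35$end))
    pairs <- overlap_pairs(dbr_gr, d35_gr, cfg)
    if (nrow(pairs)) {
      ow <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(dbr_gr[pairs[, 1]]),
        GenomicRanges::ranges(d35_gr[pairs[, 2]])))
      # per DBR keep the largest-overlap partner (ties: first sorted peak)
      o <- order(pairs[, 1], -ow, pairs[, 2])
      pairs <- pairs[o, , drop = FALSE]
      first <- !duplicated(pairs[, 1])
      bound[pairs[first, 1]] <- TRUE
      kin[pairs[first, 1]] <- kinetics_from_class(d35$class[pairs[first, 2]])
    }
  }
  records <- data.frame(
    dbr = dbrs$peak, dbr_direction = dbrs$direction,
    gene_id = nf$gene_id, deg_direction = gdir,
    concordant = gdir != "ns" & gdir == dbrs$direction,
    chd2_bound_hcIN = bound, kinetics = kin,
    stringsAsFactors = FALSE
  )
  conc <- records[records$concordant, , drop = FALSE]
  down_down <- sum(conc$dbr_direction == "down")
  up_up <- sum(conc$dbr_direction == "up")
  down_down_bound <- sum(conc$dbr_direction == "down" & conc$chd2_bound_hcIN)
  up_up_bound <- sum(conc$dbr_direction == "up" & conc$chd2_bound_hcIN)
  up_bound <- conc[conc$dbr_direction == "up" & conc$chd2_bound_hcIN, ]
  later_frac <- if (nrow(up_bound)) {
    mean(up_bound$kinetics == "later_only")
  } else NA_real_
  summary <- list(
    n_dbrs = nrow(records),
    concordant_down_down = down_down,
    concordant_up_up = up_up,
    concordant_down_down_bound = down_down_bound,
    concordant_up_up_bound = up_up_bound,
    later_only_fraction_bound_up = later_frac,
    kinetics_counts = table(factor(records$kinetics,
                                   levels = KINETICS_LEVELS))
  )
  list(records = records, summary = summary)
}
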