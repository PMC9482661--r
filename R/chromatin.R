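HISTONE_MARKS <- c("H3K4me3", "H3K27ac", "H3K27me3")
STATE_LABELS <- c("active_promoter", "active", "bivalent", "repressed", "none")

# label from the three mark flags; bivalency is definitional
# (k4me3 AND k27me3). The k27ac+k27me3-without-k4 combination is not part
# of the active/bivalent taxonomy and resolves to repressed (warned once
# per call_states run).
derive_state_label <- function(k4me3, k27ac, k27me3) {
  label <- rep("none", length(k4me3))
  label[k27me3] <- "repressed"
  label[k27ac] <- "active"
  label[k4me3] <- "active_promoter"
  label[k4me3 & k27ac] <- "active_promoter"
  label[k27ac & k27me3 & !k4me3] <- "repressed"
  label[k4me3 & k27me3] <- "bivalent"
  label
}

#' Histone-mark coenrichment state calls
#'
#' For each query (e.g. CHD2 consensus) peak and each stage, flags each
#' histone mark as present iff the peak overlaps at least one consensus
#' peak of that mark at that stage under the reciprocal-fraction overlap
#' predicate. Bivalency is the intersection of H3K4me3 and H3K27me3; the
#' summary label is a pure function of the three flags.
#'
#' @param query_peaks a `GRanges` of peaks to call states on.
#' @param histone_sets named list of consensus `GRanges`, names
#'   `"<mark>.<stage>"` (e.g. `"H3K4me3.D0"`), covering all three marks at
#'   every requested stage.
#' @param cfg an [analysis_config()].
#' @param stages stages to call (default all three).
#' @return data.frame: `peak`, `stage`, `k4me3`, `k27ac`, `k27me3`,
#'   `bivalent`, `label`.
#' @export
call_states <- function(query_peaks, histone_sets, cfg = analysis_config(),
                        stages = STAGES) {
  need <- as.vector(outer(HISTONE_MARKS, stages, paste, sep = "."))
  miss <- setdiff(need, names(histone_sets))
  if (length(miss)) {
    stop("missing histone set(s): ", paste(miss, collapse = ", "))
  }
  nm <- S4Vectors::mcols(query_peaks)$name
  if (is.null(nm)) nm <- paste0("peak", seq_along(query_peaks))
  out <- list()
  conflict <- 0L
  for (s in stages) {
    flags <- sapply(HISTONE_MARKS, function(m) {
      subj <- histone_sets[[paste(m, s, sep = ".")]]
      hit <- logical(length(query_peaks))
      if (length(subj)) {
        pairs <- overlap_pairs(query_peaks, subj, cfg)
        hit[unique(pairs[, 1])] <- TRUE
      }
      hit
    })
    flags <- matrix(flags, ncol = 3,
                    dimnames = list(NULL, HISTONE_MARKS))
    label <- derive_state_label(flags[, "H3K4me3"], flags[, "H3K27ac"],
                                flags[, "H3K27me3"])
    conflict <- conflict +
      sum(flags[, "H3K27ac"] & flags[, "H3K27me3"] & !flags[, "H3K4me3"])
    out[[s]] <- data.frame(
      peak = nm, stage = s,
      k4me3 = flags[, "H3K4me3"], k27ac = flags[, "H3K27ac"],
      k27me3 = flags[, "H3K27me3"],
      bivalent = flags[, "H3K4me3"] & flags[, "H3K27me3"],
      label = label, stringsAsFactors = FALSE
    )
  }
  if (conflict > 0L) {
    warning(conflict, " peak-stage call(s) with H3K27ac+H3K27me3 but no ",
            "H3K4me3 resolved to 'repressed'")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tabulate chromatin-state transitions across differentiation
#'
#' Counts peaks over the ordered (D0, D15, D35) label triples. Every peak
#' must have a call at all three stages; marginal per-stage label counts are
#' recoverable by summation over the other two axes.
#'
#' @param states output of [call_states()] over all three stages.
#' @return data.frame with `D0`, `D15`, `D35`, `count` (all 125 cells).
#' @export
tabulate_transitions <- function(states) {
  tab <- stats::reshape(states[, c("peak", "stage", "label")],
                        idvar = "peak", timevar = "stage",
                        direction = "wide")
  names(tab) <- sub("^label\\.", "", names(tab))
  if (!all(STAGES %in% names(tab)) || anyNA(tab[, STAGES])) {
    stop("every peak needs a state call at all three stages")
  }
  counts <- table(
    D0 = factor(tab$D0, levels = STATE_LABELS),
    D15 = factor(tab$D15, levels = STATE_LABELS),
    D35 = factor(tab$D35, levels = STATE_LABELS)
  )
  df <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(df)[4] <- "count"
  df$count <- as.integer(df$count)
  df
}

#' Differential binding between genotypes on per-peak counts
#'
#' Runs the negative-binomial Wald machinery on a per-peak count matrix
#' over a union peak set, with `dbr_fold_threshold` / `dbr_fdr` cutoffs.
#' Direction `up` means higher signal in the mutant group.
#'
#' @param peak_counts peaks x samples count matrix (rownames are peak ids
#'   of the form `chrom:start-end` or arbitrary ids).
#' @param group_wt,group_mut sample ids of the wild-type and mutant groups.
#' @param cfg an [analysis_config()].
#' @return data.frame: `peak`, `base_mean`, `log2fc` (mutant vs WT),
#'   `pvalue`, `qvalue`, `direction` (`up`/`down`/`ns`).
#' @export
differential_binding <- function(peak_counts, group_wt, group_mut,
                                 cfg = analysis_config()) {
  if (nrow(peak_counts) == 0L) stop("empty union peak set")
  res <- nb_wald_test(peak_counts, group_wt, group_mut)
  res$qvalue <- stats::p.adjust(res$pvalue, method = "BH")
  lfc_cut <- log2(cfg$dbr_fold_threshold)
  res$direction <- ifelse(
    abs(res$log2fc) >= lfc_cut & res$qvalue < cfg$dbr_fdr,
    ifelse(res$log2fc > 0, "up", "down"), "ns")
  names(res)[names(res) == "feature"] <- "peak"
  res[, c("peak", "base_mean", "log2fc", "pvalue", "qvalue", "direction")]
}
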