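#' Analysis configuration
#'
#' Central container for every numeric threshold used by the pipeline. The
#' defaults are the study design this package models: reciprocal-fraction
#' peak overlap at 0.25/0.25 in either-mode (the `bedtools intersect
#' -f 0.25 -F 0.25 -e` rule), replicate support 2 of 4, promoters at +/- 2 kb
#' of the TSS, a 1.5-fold dynamic-gene filter, K = 12 expression clusters,
#' and a 2-fold / 1 CPM / BH FDR < 0.05 differential-expression rule.
#'
#' @param overlap_frac_query minimum overlap as a fraction of the query
#'   interval length, in (0, 1].
#' @param overlap_frac_subject minimum overlap as a fraction of the subject
#'   interval length, in (0, 1].
#' @param overlap_either if `TRUE`, satisfying either fraction suffices
#'   (bedtools `-e`); if `FALSE` both are required.
#' @param min_replicate_support minimum number of distinct replicates a
#'   consensus component must span.
#' @param n_replicates number of replicates per condition.
#' @param promoter_window_bp promoter half-window around the TSS, bp.
#' @param dynamic_fold_threshold strict fold-change cutoff for the dynamic
#'   gene filter between consecutive stages.
#' @param n_clusters number of k-means expression clusters (K).
#' @param de_fold_threshold fold-change cutoff for differential expression.
#' @param de_min_cpm minimum CPM for the expression filter.
#' @param de_fdr BH FDR cutoff for differential expression.
#' @param dbr_fold_threshold fold-change cutoff for differential binding.
#' @param dbr_fdr BH FDR cutoff for differential binding.
#' @param motif_logodds_quantile relative log-odds score quantile (of the
#'   achievable score range) used as the default PWM hit threshold.
#' @param rng_seed integer seed for all stochastic stages.
#' @param pseudo_count RPKM pseudo-count guarding fold ratios and
#'   D0-normalization.
#' @param tts_window_bp transcript-end (TTS) annotation half-window, bp.
#' @param consensus_coords coordinate rule for consensus peaks:
#'   `"union"`, `"intersection"`, or `"median"` of supporting replicate peaks.
#' @param kmeans_restarts number of k-means random restarts.
#' @return An object of class `analysis_config` (a validated named list).
#' @export
analysis_config <- function(overlap_frac_query = 0.25,
                            overlap_frac_subject = 0.25,
                            overlap_either = TRUE,
                            min_replicate_support = 2L,
                            n_replicates = 4L,
                            promoter_window_bp = 2000L,
                            dynamic_fold_threshold = 1.5,
                            n_clusters = 12L,
                            de_fold_threshold = 2,
                            de_min_cpm = 1,
                            de_fdr = 0.05,
                            dbr_fold_threshold = 2,
                            dbr_fdr = 0.05,
                            motif_logodds_quantile = 0.85,
                            rng_seed = 1L,
                            pseudo_count = 0.1,
                            tts_window_bp = 1000L,
                            consensus_coords = c("union", "intersection", "median"),
                            kmeans_restarts = 50L) {
  consensus_coords <- match.arg(consensus_coords)
  cfg <- list(
    overlap_frac_query = as.numeric(overlap_frac_query),
    overlap_frac_subject = as.numeric(overlap_frac_subject),
    overlap_either = isTRUE(as.logical(overlap_either)),
    min_replicate_support = as.integer(min_replicate_support),
    n_replicates = as.integer(n_replicates),
    promoter_window_bp = as.integer(promoter_window_bp),
    dynamic_fold_threshold = as.numeric(dynamic_fold_threshold),
    n_clusters = as.integer(n_clusters),
    de_fold_threshold = as.numeric(de_fold_threshold),
    de_min_cpm = as.numeric(de_min_cpm),
    de_fdr = as.numeric(de_fdr),
    dbr_fold_threshold = as.numeric(dbr_fold_threshold),
    dbr_fdr = as.numeric(dbr_fdr),
    motif_logodds_quantile = as.numeric(motif_logodds_quantile),
    rng_seed = as.integer(rng_seed),
    pseudo_count = as.numeric(pseudo_count),
    tts_window_bp = as.integer(tts_window_bp),
    consensus_coords = consensus_coords,
    kmeans_restarts = as.integer(kmeans_restarts)
  )
  validate_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_config <- function(cfg) {
  frac_ok <- function(x) is.numeric(x) && length(x) == 1L && x > 0 && x <= 1
  stopifnot(
    "overlap_frac_query must be in (0,1]" = frac_ok(cfg$overlap_frac_query),
    "overlap_frac_subject must be in (0,1]" = frac_ok(cfg$overlap_frac_subject),
    "min_replicate_support must be positive" = cfg$min_replicate_support >= 1L,
    "n_replicates must be positive" = cfg$n_replicates >= 1L,
    "promoter_window_bp must be positive" = cfg$promoter_window_bp >= 1L,
    "dynamic_fold_threshold must be positive" = cfg$dynamic_fold_threshold > 0,
    "n_clusters must be positive" = cfg$n_clusters >= 1L,
    "de_fold_threshold must be positive" = cfg$de_fold_threshold > 0,
    "de_min_cpm must be positive" = cfg$de_min_cpm > 0,
    "de_fdr must be in (0,1)" = cfg$de_fdr > 0 && cfg$de_fdr < 1,
    "dbr_fold_threshold must be positive" = cfg$dbr_fold_threshold > 0,
    "dbr_fdr must be in (0,1)" = cfg$dbr_fdr > 0 && cfg$dbr_fdr < 1,
    "motif_logodds_quantile must be in (0,1)" =
      cfg$motif_logodds_quantile > 0 && cfg$motif_logodds_quantile < 1,
    "pseudo_count must be positive" = cfg$pseudo_count > 0,
    "tts_window_bp must be positive" = cfg$tts_window_bp >= 1L
  )
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Write a configuration to a flat YAML file
#'
#' The on-disk format is the flat scalar subset of YAML: one `key: value`
#' pair per line. [read_config()] on the written file reproduces the
#' configuration exactly.
#'
#' @param cfg an `analysis_config`.
#' @param path output file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "true" else "false")
    if (is.character(v)) return(v)
    format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }
  lines <- vapply(names(cfg), function(k) paste0(k, ": ", fmt(cfg[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration from a flat YAML file
#'
#' @param path file written by [write_config()] (or hand-edited in the same
#'   flat `key: value` format; `#` comments and blank lines are ignored).
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  parse_scalar <- function(v) {
    if (v %in% c("true", "True", "TRUE")) return(TRUE)
    if (v %in% c("false", "False", "FALSE")) return(FALSE)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) {
      if (num == round(num) && abs(num) < .Machine$integer.max &&
          !grepl("[.eE]", v)) return(as.integer(num))
      return(num)
    }
    v
  }
  args <- stats::setNames(lapply(vals, parse_scalar), keys)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(analysis_config, args)
}

# Run an expression with a locally-seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
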