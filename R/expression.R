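#' Construct a count matrix container
#'
#' @param counts non-negative numeric matrix, genes x samples, with row and
#'   column names.
#' @param meta data.frame with one row per sample: `sample`, `stage`,
#'   `genotype`, `replicate`.
#' @param gene_lengths named numeric vector of gene lengths in bp (for RPKM);
#'   optional if RPKM is never requested.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, meta, gene_lengths = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (!all(colnames(counts) %in% meta$sample)) {
    stop("every sample id must have metadata")
  }
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  if (!is.null(gene_lengths)) {
    gene_lengths <- gene_lengths[rownames(counts)]
    if (any(is.na(gene_lengths)) || any(gene_lengths <= 0)) {
      stop("gene lengths must be positive and cover all genes")
    }
  }
  structure(list(counts = counts, meta = meta, gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' Counts per million
#' @param cm a [count_matrix()] or a plain counts matrix.
#' @return matrix of CPM values; each column sums to 1e6.
#' @export
compute_cpm <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size in sample(s): ",
                          paste(colnames(counts)[lib <= 0], collapse = ", "))
  sweep(counts, 2, lib, "/") * 1e6
}

#' Reads per kilobase per million
#' @param cm a [count_matrix()] with gene lengths.
#' @return matrix of RPKM values.
#' @export
compute_rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"), !is.null(cm$gene_lengths))
  cpm <- compute_cpm(cm)
  sweep(cpm, 1, cm$gene_lengths / 1000, "/")
}

#' Stage-mean RPKM for one genotype
#' @param cm a [count_matrix()].
#' @param genotype genotype to average over (default `"WT"`).
#' @return genes x 3 matrix with columns D0/D15/D35.
#' @export
stage_mean_rpkm <- function(cm, genotype = "WT") {
  rpkm <- compute_rpkm(cm)
  keep <- cm$meta$genotype == genotype
  stopifnot(any(keep))
  sub <- rpkm[, keep, drop = FALSE]
  stg <- cm$meta$stage[keep]
  out <- sapply(STAGES, function(s) rowMeans(sub[, stg == s, drop = FALSE]))
  colnames(out) <- STAGES
  out
}

#' Dynamic-gene filter
#'
#' Keeps genes whose direction-agnostic fold change strictly exceeds the
#' threshold on either consecutive stage transition (D0 to D15 or D15 to
#' D35). A pseudo-count guards ratios of zeros; a fold of exactly the
#' threshold is excluded (strict inequality).
#'
#' @param rpkm_by_stage genes x 3 matrix (columns D0/D15/D35).
#' @param cfg an [analysis_config()].
#' @return character vector of retained gene ids.
#' @export
filter_dynamic_genes <- function(rpkm_by_stage, cfg = analysis_config()) {
  x <- rpkm_by_stage + cfg$pseudo_count
  f1 <- pmax(x[, "D15"] / x[, "D0"], x[, "D0"] / x[, "D15"])
  f2 <- pmax(x[, "D35"] / x[, "D15"], x[, "D15"] / x[, "D35"])
  rownames(rpkm_by_stage)[f1 > cfg$dynamic_fold_threshold |
                            f2 > cfg$dynamic_fold_threshold]
}

#' D0-relative temporal profiles
#'
#' Divides each gene's stage profile by its D0 value (after the
#' pseudo-count guard), so the first coordinate is exactly 1 and the profile
#' is invariant to scaling the gene's expression by any positive constant.
#'
#' @param rpkm_by_stage genes x 3 matrix.
#' @param cfg an [analysis_config()].
#' @return genes x 3 matrix of relative profiles.
#' @export
relative_profiles <- function(rpkm_by_stage, cfg = analysis_config()) {
  x <- rpkm_by_stage + cfg$pseudo_count
  sweep(x, 1, x[, "D0"], "/")
}

#' Fit the temporal expression clustering
#'
#' k-means (Hartigan-Wong, multiple random restarts, seeded) on D0-relative
#' profiles at K = `cfg$n_clusters`, with a within-cluster SSE sweep over K
#' for elbow diagnostics. Cluster ids are arbitrary labels; interpret
#' clusters by centroid shape, not index.
#'
#' @param profiles genes x 3 matrix of D0-relative profiles.
#' @param cfg an [analysis_config()].
#' @param k_sweep K values for the SSE elbow diagnostic.
#' @return object of class `cluster_model`: `centroids`, `assignment`
#'   (named integer vector), `sse_by_k`, `k`.
#' @export
fit_clusters <- function(profiles, cfg = analysis_config(),
                         k_sweep = 2:15) {
  k <- cfg$n_clusters
  if (k > nrow(profiles)) stop("K exceeds the number of profiles")
  k_sweep <- k_sweep[k_sweep <= nrow(profiles)]
  fit <- with_seed(cfg$rng_seed, {
    sse <- vapply(k_sweep, function(kk) {
      kmeans_pp(profiles, kk, restarts = max(5L, cfg$kmeans_restarts %/% 5L))$tot.withinss
    }, numeric(1))
    final <- kmeans_pp(profiles, k, restarts = cfg$kmeans_restarts)
    list(sse = sse, final = final)
  })
  structure(list(
    centroids = fit$final$centers,
    assignment = stats::setNames(fit$final$cluster, rownames(profiles)),
    sse_by_k = stats::setNames(fit$sse, k_sweep),
    k = k
  ), class = "cluster_model")
}

#' Assign profiles to the nearest centroid of a fitted model
#' @param model a `cluster_model`.
#' @param profiles genes x 3 matrix.
#' @return named integer vector of cluster ids.
#' @export
assign_clusters <- function(model, profiles) {
  d <- as.matrix(stats::dist(rbind(model$centroids, profiles)))
  k <- nrow(model$centroids)
  dd <- d[-(1:k), 1:k, drop = FALSE]
  stats::setNames(max.col(-dd, ties.method = "first"), rownames(profiles))
}

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance to the nearest chosen center
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      centers[j, ] <- x[sample.int(n, 1L), ]
    } else {
      centers[j, ] <- x[sample.int(n, 1L, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

# restarted k-means with k-means++ initialization; keeps the lowest-SSE fit
kmeans_pp <- function(x, k, restarts = 50L, iter.max = 100L) {
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- kmeanspp_init(x, k)
    km <- suppressWarnings(
      tryCatch(stats::kmeans(x, centers = init, iter.max = iter.max),
               error = function(e) NULL))
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed to converge from any restart")
  best
}

# --- negative-binomial two-group Wald test (shared by DE and DBR) ---------

# DESeq-style median-of-ratios size factors; falls back to library-size
# ratios when no feature is positive in all samples.
size_factors <- function(counts) {
  logc <- log(counts)
  ok <- is.finite(rowSums(logc))
  if (any(ok)) {
    logmeans <- rowMeans(logc[ok, , drop = FALSE])
    sf <- apply(logc[ok, , drop = FALSE], 2, function(col)
      exp(stats::median(col - logmeans)))
  } else {
    lib <- colSums(counts)
    sf <- lib / exp(mean(log(lib)))
  }
  sf
}

# Per-feature NB dispersion: method-of-moments on size-factor-normalized
# counts using within-group residual variance, shrunk toward the positive
# median to stabilize small-n estimates.
estimate_dispersion <- function(norm_counts, group) {
  mu <- rowMeans(norm_counts)
  s2 <- numeric(nrow(norm_counts))
  df <- 0
  for (g in unique(group)) {
    cols <- group == g
    m <- rowMeans(norm_counts[, cols, drop = FALSE])
    s2 <- s2 + rowSums((norm_counts[, cols, drop = FALSE] - m)^2)
    df <- df + sum(cols) - 1L
  }
  s2 <- s2 / max(df, 1L)
  alpha <- (s2 - mu) / mu^2
  alpha[!is.finite(alpha)] <- NA
  prior <- stats::median(alpha[!is.na(alpha) & alpha > 0])
  if (!is.finite(prior)) prior <- 0.01
  alpha[is.na(alpha)] <- prior
  # shrink toward prior and floor at a small value; pmax with prior/4 keeps
  # severely underestimated dispersions from inflating Wald statistics
  pmax((alpha + prior) / 2, prior / 4, 1e-8)
}

# NB MLE of a group mean parameter q (counts y, size factors s, dispersion
# a): solves sum (y - s q) / (1 + a s q) = 0 by Newton iteration from the
# ratio estimator.
nb_group_mean <- function(y, s, a) {
  q <- sum(y) / sum(s)
  if (q == 0) return(0)
  if (a <= 0) return(q)
  for (it in 1:25) {
    mu <- s * q
    f <- sum((y - mu) / (1 + a * mu))
    fp <- sum(-s * (1 + a * y) / (1 + a * mu)^2)
    if (abs(fp) < 1e-12) break
    qn <- q - f / fp
    if (!is.finite(qn) || qn <= 0) qn <- q / 2
    if (abs(qn - q) < 1e-10 * (q + 1e-10)) { q <- qn; break }
    q <- qn
  }
  q
}

#' Two-group negative-binomial Wald test
#'
#' Per-feature NB model `y_ij ~ NB(s_j q_i, alpha)` with library-size
#' normalization (median-of-ratios size factors), moment-based dispersion
#' shrunk toward the dataset median, maximum-likelihood group means, and a
#' Wald test of `beta = log2(q_B / q_A)` using observed Fisher information.
#' Groups whose counts are all zero receive a half-count continuity
#' correction so the log fold change is finite.
#'
#' @param counts features x samples matrix of non-negative counts.
#' @param group_a,group_b column names (or indices) of the two groups.
#' @return data.frame: `feature`, `base_mean` (mean normalized count),
#'   `log2fc` (B vs A), `se`, `pvalue`.
#' @export
nb_wald_test <- function(counts, group_a, group_b) {
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("at least 2 samples per group are required")
  }
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  grp <- rep(c("A", "B"), c(length(group_a), length(group_b)))
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  alpha <- estimate_dispersion(norm, grp)
  a_cols <- which(grp == "A"); b_cols <- which(grp == "B")
  n <- nrow(sub)
  log2fc <- se <- p <- base_mean <- numeric(n)
  for (i in seq_len(n)) {
    y <- sub[i, ]; av <- alpha[i]
    qa <- nb_group_mean(y[a_cols], sf[a_cols], av)
    qb <- nb_group_mean(y[b_cols], sf[b_cols], av)
    # continuity correction for empty groups
    if (qa == 0) qa <- 0.5 / sum(sf[a_cols])
    if (qb == 0) qb <- 0.5 / sum(sf[b_cols])
    mu_a <- sf[a_cols] * qa
    mu_b <- sf[b_cols] * qb
    # information about log-mean per group: sum mu/(1+alpha*mu)
    ia <- sum(mu_a / (1 + av * mu_a))
    ib <- sum(mu_b / (1 + av * mu_b))
    v <- 1 / ia + 1 / ib
    beta <- log(qb / qa)
    z <- beta / sqrt(v)
    log2fc[i] <- beta / log(2)
    se[i] <- sqrt(v) / log(2)
    p[i] <- 2 * stats::pnorm(-abs(z))
    base_mean[i] <- mean(norm[i, ])
  }
  data.frame(feature = rownames(sub), base_mean = base_mean,
             log2fc = log2fc, se = se, pvalue = p,
             stringsAsFactors = FALSE)
}

#' Differential expression between two sample groups
#'
#' Applies the expression filter (drop genes with CPM below `de_min_cpm` in
#' more than half of the compared samples), runs the NB Wald test, adjusts
#' p-values by Benjamini-Hochberg, and calls direction `up`/`down` only for
#' genes passing both the fold-change and FDR cutoffs.
#'
#' @param cm a [count_matrix()].
#' @param group_a,group_b sample ids of the two groups (log2FC is B vs A).
#' @param cfg an [analysis_config()].
#' @return data.frame: `gene`, `base_mean`, `mean_cpm`, `log2fc`, `pvalue`,
#'   `qvalue`, `direction`.
#' @export
differential_expression <- function(cm, group_a, group_b,
                                    cfg = analysis_config()) {
  stopifnot(inherits(cm, "count_matrix"))
  samples <- c(group_a, group_b)
  stopifnot(all(samples %in% colnames(cm$counts)))
  cpm <- compute_cpm(cm$counts[, samples, drop = FALSE])
  low <- rowSums(cpm < cfg$de_min_cpm) > length(samples) / 2
  counts <- cm$counts[!low, samples, drop = FALSE]
  res <- nb_wald_test(counts, group_a, group_b)
  res$qvalue <- stats::p.adjust(res$pvalue, method = "BH")
  res$mean_cpm <- rowMeans(cpm[!low, , drop = FALSE])
  lfc_cut <- log2(cfg$de_fold_threshold)
  res$direction <- ifelse(
    abs(res$log2fc) >= lfc_cut & res$qvalue < cfg$de_fdr,
    ifelse(res$log2fc > 0, "up", "down"), "ns")
  names(res)[names(res) == "feature"] <- "gene"
  res[, c("gene", "base_mean", "mean_cpm", "log2fc", "pvalue", "qvalue",
          "direction")]
}
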