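mk_model <- function(assignment, k = max(assignment)) {
  structure(list(
    centroids = matrix(0, k, 3),
    assignment = assignment,
    sse_by_k = numeric(0), k = k
  ), class = "cluster_model")
}

test_that("cluster distribution: maximal-enrichment identity and tail oracle", {
  set.seed(81)
  assignment <- setNames(sample(1:5, 120, TRUE), sprintf("g%03d", 1:120))
  model <- mk_model(assignment, 5)
  q3 <- names(assignment)[assignment == 3]
  cd <- cluster_distribution(q3, model)
  expect_equal(cd$observed[3], length(q3))
  expect_equal(sum(cd$observed), length(q3))
  expect_equal(cd$observed[-3], rep(0L, 4))
  expect_equal(cd$fold_enrichment[3], 120 / length(q3))
  expect_lt(cd$pvalue[3], 1e-10)

  # hypergeometric tail by exhaustive summation: universe 120, cluster 12,
  # query 12, overlap 6
  a2 <- setNames(rep(1:10, each = 12), sprintf("h%03d", 1:120))
  model2 <- mk_model(a2, 10)
  cluster1 <- names(a2)[a2 == 1]
  query <- c(cluster1[1:6], names(a2)[a2 == 2][1:6])
  cd2 <- cluster_distribution(query, model2)
  expect_equal(cd2$observed[1], 6L)
  expect_equal(cd2$pvalue[1], brute_hyper_tail(6, 12, 120, 12),
               tolerance = 1e-12)
  expect_warning(cluster_distribution("absent_gene", model2), "empty")
})

test_that("risk-gene overlap matches set arithmetic", {
  bound <- list(D0 = c("a", "b", "c"), D15 = c("b", "c", "d"),
                D35 = c("c", "e"))
  expect_error(gene_list_overlap(bound, character(0)), "empty")
  ov <- gene_list_overlap(bound, c("x", "y"))
  expect_equal(ov$n_bound_any, 0L)
  expect_equal(ov$pct_bound_any, 0)
  ov <- gene_list_overlap(bound, c("c"))
  expect_equal(ov$pct_bound_any, 100)
  expect_equal(ov$n_bound_all_stages, 1L)

  set.seed(82)
  universe <- sprintf("u%04d", 1:1000)
  risk <- sample(universe, 100)
  sets <- list(D0 = sample(universe, 50), D15 = sample(universe, 60),
               D35 = sample(universe, 70))
  ov <- gene_list_overlap(sets, risk)
  expect_equal(ov$n_bound_any, length(intersect(risk, unique(unlist(sets)))))
  expect_equal(ov$n_bound_all_stages,
               length(intersect(risk, Reduce(intersect, sets))))
  expect_equal(unname(ov$per_stage),
               unname(vapply(sets, function(s)
                 length(intersect(risk, s)), 1L)))
})

# build a synthetic concordance instance with planted truth; returns the
# inputs plus the planted summary computed by construction
planted_concordance <- function(n_down = 30, n_up = 20, n_decoy = 50) {
  spacing <- 10000L
  total <- n_down + n_up + n_decoy
  pos <- seq_len(total) * spacing
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(total)), chrom = "c1",
    start = pos, end = pos + 2000L, strand = "+"
  )
  gm <- gene_models(genes)
  dbr_dir <- c(rep("down", n_down), rep("up", n_up),
               sample(c("up", "down"), n_decoy, TRUE))
  # DBRs centered at each gene's TSS
  dbrs <- data.frame(
    peak = sprintf("dbr%03d", seq_len(total)), chrom = "c1",
    start = pos - 300L, end = pos + 300L, direction = dbr_dir
  )
  deg_dir <- c(rep("down", n_down), rep("up", n_up), rep("ns", n_decoy))
  degs <- data.frame(gene = genes$gene_id, direction = deg_dir)
  # CHD2 peaks over the concordant DBRs only: down -> bound all stages,
  # up -> bound later only
  cls <- c(rep("D0+D15+D35", n_down),
           rep(c("D15+D35", "D35"), length.out = n_up))
  chd2 <- data.frame(
    peak = sprintf("chd2_%03d", seq_len(n_down + n_up)),
    stage = "D35", class = cls, chrom = "c1",
    start = pos[seq_len(n_down + n_up)] - 250L,
    end = pos[seq_len(n_down + n_up)] + 250L,
    component = seq_len(n_down + n_up)
  )
  list(dbrs = dbrs, degs = degs, chd2 = chd2, gm = gm,
       n_down = n_down, n_up = n_up)
}

test_that("concordant triples recover a planted design exactly", {
  set.seed(83)
  pc <- planted_concordance()
  res <- concordant_triples(pc$dbrs, pc$degs, pc$chd2, pc$gm,
                            analysis_config())
  expect_equal(res$summary$concordant_down_down, pc$n_down)
  expect_equal(res$summary$concordant_up_up, pc$n_up)
  expect_equal(res$summary$concordant_down_down_bound, pc$n_down)
  expect_equal(res$summary$concordant_up_up_bound, pc$n_up)
  expect_equal(res$summary$later_only_fraction_bound_up, 1)
  # single example rows
  r1 <- res$records[1, ]
  expect_true(r1$concordant)
  expect_equal(r1$kinetics, "all_stages")
  # decoys (ns genes) never enter the numerators
  decoy <- res$records[res$records$deg_direction == "ns", ]
  expect_true(all(!decoy$concordant))
  # kinetics partition sums to the record total
  expect_equal(sum(res$summary$kinetics_counts), nrow(res$records))
})

test_that("concordance summary equals a brute-force nested-loop join", {
  set.seed(84)
  for (inst in 1:25) {
    n <- sample(20:60, 1)
    spacing <- 5000L
    pos <- cumsum(sample(3000:8000, n, TRUE))
    genes <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "c1",
                        start = pos, end = pos + 1500L,
                        strand = sample(c("+", "-"), n, TRUE))
    gm <- gene_models(genes)
    tssv <- gm$genes$tss
    m <- sample(5:20, 1)
    ctr <- sample(pos, m, TRUE) + sample(-2000:2000, m, TRUE)
    dbrs <- data.frame(peak = sprintf("d%02d", 1:m), chrom = "c1",
                       start = ctr - 200L, end = ctr + 200L,
                       direction = sample(c("up", "down"), m, TRUE))
    degs <- data.frame(gene = genes$gene_id,
                       direction = sample(c("up", "down", "ns"), n, TRUE))
    k <- sample(3:10, 1)
    cctr <- sample(pos, k, TRUE) + sample(-500:500, k, TRUE)
    chd2 <- data.frame(peak = sprintf("c%02d", 1:k), stage = "D35",
                       class = sample(c("D0+D15+D35", "D15+D35", "D35",
                                        "D0+D35", "D0"), k, TRUE),
                       chrom = "c1", start = cctr - 300L, end = cctr + 300L,
                       component = 1:k)
    res <- concordant_triples(dbrs, degs, chd2, gm, analysis_config())
    # brute-force join
    brute_down <- 0L; brute_up <- 0L
    for (i in seq_len(m)) {
      mid <- (dbrs$start[i] + 1L + dbrs$end[i]) %/% 2L
      d <- abs(tssv - mid)
      best <- which(d == min(d))
      best <- best[order(gm$genes$gene_id[best])][1]
      gdir <- degs$direction[degs$gene == gm$genes$gene_id[best]]
      if (gdir != "ns" && gdir == dbrs$direction[i]) {
        if (gdir == "down") brute_down <- brute_down + 1L
        else brute_up <- brute_up + 1L
      }
    }
    expect_equal(res$summary$concordant_down_down, brute_down)
    expect_equal(res$summary$concordant_up_up, brute_up)
    expect_equal(sum(res$summary$kinetics_counts), m)
    # each DBR contributes at most one record
    expect_equal(nrow(res$records), m)
  }
})

test_that("planted genotype modules are recovered with high precision/recall", {
  st <- tiny_study()
  res <- tiny_pipeline()
  truth <- st$truth
  conc <- res$concordance$records
  # planted: cell_cycle module promoter peaks lose acetylation + expression
  cc_genes <- truth$genes$gene_id[truth$genes$module == "cell_cycle"]
  neu_genes <- truth$genes$gene_id[truth$genes$module == "neuronal"]
  got_down <- conc$gene_id[conc$concordant & conc$dbr_direction == "down"]
  got_up <- conc$gene_id[conc$concordant & conc$dbr_direction == "up"]
  precision_down <- mean(got_down %in% cc_genes)
  recall_down <- mean(cc_genes %in% got_down)
  precision_up <- mean(got_up %in% neu_genes)
  recall_up <- mean(neu_genes %in% got_up)
  expect_gte(precision_down, 0.9)
  expect_gte(recall_down, 0.9)
  expect_gte(precision_up, 0.9)
  expect_gte(recall_up, 0.9)
})
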