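gr1 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

interval_midpoint_test <- function(gr) {
  (GenomicRanges::start(gr) + GenomicRanges::end(gr)) %/% 2L
}

test_that("reciprocal-fraction predicate handles boundary and miss cases", {
  # [0,100) vs [75,200) in BED coords -> 1-based [1,100] vs [76,200], o = 25
  expect_true(interval_overlaps(gr1("chr1", 1, 100), gr1("chr1", 76, 200)))
  # o = 10 is below both fraction requirements
  expect_false(interval_overlaps(gr1("chr1", 1, 100), gr1("chr1", 91, 1000)))
  expect_false(interval_overlaps(gr1("chr1", 1, 100), gr1("chr2", 1, 100)))
  # reciprocal (AND) mode
  expect_true(interval_overlaps(gr1("c", 1, 100), gr1("c", 76, 200),
                                either = FALSE, frac_b = 0.2))
  expect_false(interval_overlaps(gr1("c", 1, 100), gr1("c", 76, 200),
                                 either = FALSE, frac_b = 0.25))
  expect_error(interval_overlaps(gr1("c", 1, 10), gr1("c", 1, 10),
                                 frac_a = 0), "0, 1")
})

test_that("predicate equals a per-base brute-force counter on random pairs", {
  set.seed(11)
  for (cfg_case in list(c(0.25, 0.25, TRUE), c(0.5, 0.1, FALSE))) {
    n <- 250
    s1 <- sample.int(5000, n); s2 <- sample.int(5000, n)
    e1 <- s1 + sample(1:400, n, TRUE); e2 <- s2 + sample(1:400, n, TRUE)
    c1 <- sample(c("c1", "c2"), n, TRUE); c2 <- sample(c("c1", "c2"), n, TRUE)
    got <- interval_overlaps(gr1(c1, s1, e1), gr1(c2, s2, e2),
                             frac_a = cfg_case[1], frac_b = cfg_case[2],
                             either = as.logical(cfg_case[3]))
    want <- vapply(seq_len(n), function(i) {
      brute_overlap(c1[i], s1[i], e1[i], c2[i], s2[i], e2[i],
                    cfg_case[1], cfg_case[2], as.logical(cfg_case[3]))
    }, logical(1))
    expect_identical(got, want)
  }
})

test_that("predicate is symmetric when fractions are equal", {
  set.seed(12)
  n <- 200
  s1 <- sample.int(3000, n); s2 <- sample.int(3000, n)
  a <- gr1("c1", s1, s1 + sample(1:300, n, TRUE))
  b <- gr1("c1", s2, s2 + sample(1:300, n, TRUE))
  expect_identical(interval_overlaps(a, b), interval_overlaps(b, a))
})

test_that("consensus keeps 2-of-4 supported peaks and drops singletons", {
  mk <- function(df, r) df_to_granges(df, replicate = r)
  shared <- data.frame(chrom = "c1", start = 101, end = 200, name = "s")
  private <- data.frame(chrom = "c1", start = 5001, end = 5100, name = "p")
  reps <- list(mk(rbind(shared, private), 1), mk(shared, 2),
               mk(data.frame(chrom = "c2", start = 1, end = 50, name = "x"), 3),
               mk(data.frame(chrom = "c2", start = 9001, end = 9100,
                             name = "y"), 4))
  cp <- consensus_peaks(reps, analysis_config())
  expect_equal(length(cp), 1L)
  expect_equal(S4Vectors::mcols(cp)$support, 2L)
  expect_equal(GenomicRanges::start(cp), 101)
  expect_equal(GenomicRanges::end(cp), 200)
  expect_equal(S4Vectors::mcols(cp)$source_ids, "s,s")
})

test_that("consensus equals the brute-force component search on random sets", {
  set.seed(21)
  cfg <- analysis_config()
  for (rep_i in 1:25) {
    reps <- random_replicate_sets()
    got <- consensus_peaks(lapply(seq_along(reps), function(r)
      df_to_granges(reps[[r]], replicate = r)), cfg)
    want <- brute_consensus(reps)
    expect_equal(length(got), nrow(want))
    expect_equal(as.character(GenomicRanges::seqnames(got)), want$chrom)
    expect_equal(GenomicRanges::start(got), want$start)
    expect_equal(GenomicRanges::end(got), want$end)
    expect_equal(S4Vectors::mcols(got)$support, want$support)
  }
})

test_that("consensus count is non-increasing in replicate support", {
  set.seed(22)
  reps <- lapply(1:4, function(r)
    df_to_granges(random_replicate_sets(1, 40)[[1]], replicate = r))
  counts <- vapply(1:4, function(k) {
    length(consensus_peaks(reps, analysis_config(min_replicate_support = k)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("every consensus interval contains its supporting peaks", {
  set.seed(23)
  reps_df <- random_replicate_sets(4, 40)
  reps <- lapply(seq_along(reps_df), function(r)
    df_to_granges(reps_df[[r]], replicate = r))
  cp <- consensus_peaks(reps, analysis_config())
  all_df <- do.call(rbind, reps_df)
  for (i in seq_along(cp)) {
    ids <- strsplit(S4Vectors::mcols(cp)$source_ids[i], ",")[[1]]
    sup <- all_df[all_df$name %in% ids, ]
    expect_true(all(sup$start >= GenomicRanges::start(cp)[i]))
    expect_true(all(sup$end <= GenomicRanges::end(cp)[i]))
  }
})

test_that("replicate sets with inconsistent metadata are rejected", {
  a <- df_to_granges(data.frame(chrom = "c1", start = 1, end = 100,
                                name = "a"), mark = "CHD2")
  b <- df_to_granges(data.frame(chrom = "c1", start = 1, end = 100,
                                name = "b"), mark = "H3K27ac")
  expect_error(consensus_peaks(list(a, b)), "metadata")
})

test_that("nearest_feature matches definition and exhaustive scan", {
  anchors <- data.frame(gene_id = c("gB", "gA"), chrom = "c1",
                        tss = c(1000L, 12000L), strand = c("+", "+"))
  q <- gr1("c1", 999, 1001) # midpoint 1000, exactly at gB's TSS
  nf <- nearest_feature(q, anchors)
  expect_equal(nf$gene_id, "gB")
  expect_equal(nf$distance, 0)
  # midpoint 500 bp 5' of the +-strand TSS -> negative distance
  q <- gr1("c1", 400, 600)
  expect_equal(nearest_feature(q, anchors)$distance, -500)
  # minus-strand sign flip
  anchors2 <- data.frame(gene_id = "gm", chrom = "c1", tss = 2000L,
                         strand = "-")
  expect_equal(nearest_feature(gr1("c1", 2400, 2600), anchors2)$distance,
               -500)
  expect_error(nearest_feature(q, anchors[0, ]), "empty")

  set.seed(31)
  anchors3 <- data.frame(gene_id = sprintf("g%03d", sample(100)),
                         chrom = sample(c("c1", "c2"), 100, TRUE),
                         tss = sample.int(50000, 100),
                         strand = sample(c("+", "-"), 100, TRUE))
  st <- sample.int(50000, 500)
  qs <- gr1(sample(c("c1", "c2"), 500, TRUE), st, st + 100)
  got <- nearest_feature(qs, anchors3)
  for (i in seq_len(500)) {
    want <- brute_nearest(interval_midpoint_test(qs[i]),
                          as.character(GenomicRanges::seqnames(qs))[i],
                          anchors3)
    expect_equal(got$gene_id[i], want$gene)
    expect_equal(got$distance[i], want$dist)
  }
})
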