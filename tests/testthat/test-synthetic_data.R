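test_that("same seed yields identical studies; different seeds differ", {
  p <- sim_params(seed = 5L, chrom_lengths = c(chrS1 = 300000L),
                  n_genes = 40L, n_peaks = 25L, module_size = 4L,
                  noise_peaks_per_rep = 3L)
  s1 <- simulate_study(p)
  s2 <- simulate_study(p)
  expect_identical(s1$truth$peaks, s2$truth$peaks)
  expect_identical(s1$rna$counts, s2$rna$counts)
  expect_identical(s1$genome, s2$genome)
  p3 <- p; p3$seed <- 6L
  s3 <- simulate_study(p3)
  expect_false(identical(s1$rna$counts, s3$rna$counts))
})

test_that("written studies are byte-identical for one seed", {
  p <- sim_params(seed = 5L, chrom_lengths = c(chrS1 = 300000L),
                  n_genes = 40L, n_peaks = 25L, module_size = 4L,
                  noise_peaks_per_rep = 3L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(simulate_study(p), d1)
  write_study(simulate_study(p), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 20)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("noiseless generation reproduces planted coordinates exactly", {
  st <- clean_study()
  cfg <- analysis_config()
  truth <- st$truth$peaks
  for (s in c("D0", "D15", "D35")) {
    cons <- consensus_peaks(st$peaks$CHD2$WT[[s]], cfg)
    planted_s <- truth[grepl(s, truth$class), ]
    planted_s <- planted_s[order(planted_s$chrom, planted_s$start), ]
    expect_equal(length(cons), nrow(planted_s))
    expect_equal(GenomicRanges::start(cons), planted_s$start + 1L)
    expect_equal(GenomicRanges::end(cons), planted_s$end)
    expect_true(all(S4Vectors::mcols(cons)$support == 4L))
  }
  # and classification recovers every planted class (100%)
  cons_all <- lapply(setNames(c("D0", "D15", "D35"), c("D0", "D15", "D35")),
                     function(s) consensus_peaks(st$peaks$CHD2$WT[[s]], cfg))
  classes <- classify_temporal(cons_all, cfg)
  comp <- classes[!duplicated(classes$component), ]
  expect_equal(nrow(comp), nrow(truth))
  m <- merge(comp, truth, by = c("chrom", "start"))
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(m$class.x == m$class.y))
})

test_that("RNA library sizes match their expectations within NB tolerance", {
  st <- tiny_study()
  phi <- st$truth$params$nb_dispersion
  arch <- archetype_profiles()
  meta <- st$rna$meta
  genes <- st$truth$genes
  obs <- colSums(st$rna$counts)
  for (j in seq_along(obs)) {
    mu <- genes$base_mean * arch[genes$archetype, meta$stage[j]] *
      meta$depth[j]
    if (meta$genotype[j] == "HET" && meta$stage[j] == "D35") {
      mu <- mu * 2^genes$planted_lfc_d35
    }
    mu <- pmax(mu, 0.01)
    expect_equal(sum(mu), meta$expected_library[j], tolerance = 1e-8)
    sd_tot <- sqrt(sum(mu + phi * mu^2))
    expect_lt(abs(obs[j] - sum(mu)), 6 * sd_tot)
  }
})

test_that("H3K27ac coupling parameter moves measured coenrichment", {
  base <- list(seed = 7L,
               chrom_lengths = c(chrS1 = 250000L, chrS2 = 200000L),
               n_genes = 60L, n_peaks = 40L, module_size = 4L,
               noise_peaks_per_rep = 0L, jitter_sd = 0, dropout = 0)
  lo <- simulate_study(do.call(sim_params, c(base, k27ac_coupling = 0.2)))
  hi <- simulate_study(do.call(sim_params, c(base, k27ac_coupling = 0.9)))
  frac_ac <- function(st) {
    cfg <- analysis_config()
    cons <- consensus_peaks(st$peaks$CHD2$WT$D0, cfg)
    sets <- list()
    for (m in c("H3K4me3", "H3K27ac", "H3K27me3")) {
      gt <- if (m == "H3K27ac") "WT" else "WT"
      sets[[paste0(m, ".D0")]] <- consensus_peaks(st$peaks[[m]]$WT$D0, cfg)
    }
    calls <- suppressWarnings(call_states(cons, sets, cfg, stages = "D0"))
    mean(calls$k27ac)
  }
  expect_gt(frac_ac(hi), frac_ac(lo) + 0.3)
})

test_that("coupled peaks carry acetylation more often than uncoupled ones", {
  st <- tiny_study()
  res <- tiny_pipeline()
  truth <- st$truth$peaks
  d0 <- res$states[res$states$stage == "D0", ]
  # map state calls back to planted peaks via the classified intervals
  cls <- res$classes[res$classes$stage == "D0", ]
  m <- merge(cls, truth, by = "chrom", suffixes = c("", ".t"))
  m <- m[m$start <= m$end.t & m$end >= m$start.t &
           grepl("D0", m$class.t), ]
  m <- m[!duplicated(m$peak), ]
  calls <- merge(m[, c("peak", "k27ac_coupled")], d0, by = "peak")
  frac_coupled <- mean(calls$k27ac[calls$k27ac_coupled])
  frac_uncoupled <- mean(calls$k27ac[!calls$k27ac_coupled])
  expect_gt(frac_coupled, frac_uncoupled + 0.3)
})

test_that("DE power rises with the planted effect size", {
  set.seed(96)
  cfg <- analysis_config()
  power_at <- function(lfc) {
    counts <- sim_nb_counts(150, 4, 4, mu = 300, phi = 0.05,
                            lfc = c(rep(lfc, 30), rep(0, 120)))
    meta <- data.frame(sample = colnames(counts), stage = "D35",
                       genotype = rep(c("WT", "HET"), each = 4),
                       replicate = rep(1:4, 2))
    de <- differential_expression(count_matrix(counts, meta),
                                  paste0("A", 1:4), paste0("B", 1:4), cfg)
    mean(de$direction[de$gene %in% paste0("f", 1:30)] ==
           if (lfc > 0) "up" else "down")
  }
  p1 <- power_at(1.1)
  p2 <- power_at(2)
  p3 <- power_at(3)
  expect_lte(p1, p2 + 0.05)
  expect_lte(p2, p3 + 0.05)
  expect_gt(p3, 0.9)
})

test_that("the tiny fixture loads from disk and passes format validation", {
  d <- withr::local_tempdir()
  st <- export_fixture("tiny", dir = d)
  study <- read_study(d)
  expect_setequal(names(study$peaks), c("CHD2", "H3K4me3", "H3K27ac",
                                        "H3K27me3"))
  expect_equal(dim(study$rna$counts), dim(st$rna$counts))
  expect_identical(unname(study$rna$counts), unname(st$rna$counts))
  # peak files re-read equal the in-memory replicate sets
  d0r1 <- study$peaks$CHD2$WT$D0[[1]]
  orig <- st$peaks$CHD2$WT$D0[[1]]
  expect_equal(GenomicRanges::start(d0r1), GenomicRanges::start(orig))
  expect_setequal(S4Vectors::mcols(d0r1)$name, S4Vectors::mcols(orig)$name)
  # genome FASTA round-trips
  expect_equal(as.character(study$genome[["chrS1"]]), st$genome[["chrS1"]])
  # truth ledger round-trips through its TSVs
  back <- read_results_table(file.path(d, "truth", "peaks.tsv"))
  expect_equal(back$peak_id, st$truth$peaks$peak_id)
  expect_equal(back$class, st$truth$peaks$class)
})
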