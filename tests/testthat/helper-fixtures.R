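# The tiny synthetic study is generated once per test run and shared.
.fixture_env <- new.env(parent = emptyenv())

tiny_study <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- export_fixture("tiny")
  }
  .fixture_env$tiny
}

tiny_pipeline <- function() {
  if (is.null(.fixture_env$tiny_res)) {
    .fixture_env$tiny_res <- suppressWarnings(
      run_pipeline(tiny_study(), analysis_config()))
  }
  .fixture_env$tiny_res
}

# a noiseless tiny study: no jitter, no dropout, no noise peaks
clean_study <- function() {
  if (is.null(.fixture_env$clean)) {
    .fixture_env$clean <- simulate_study(sim_params(
      seed = 20240102L,
      chrom_lengths = c(chrS1 = 250000L, chrS2 = 200000L),
      n_genes = 100L, n_peaks = 60L, module_size = 8L,
      jitter_sd = 0, dropout = 0, noise_peaks_per_rep = 0L))
  }
  .fixture_env$clean
}

# a 3-gene chromosome used by annotation oracle tests
toy_gene_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chrT",
    start = c(10000L, 40000L, 70000L),
    end = c(20000L, 52000L, 76000L),
    strand = c("+", "-", "+")
  )
  exons <- data.frame(
    gene_id = rep(c("gA", "gB", "gC"), each = 2),
    start = c(10000L, 17000L, 40000L, 50000L, 70000L, 74000L),
    end = c(12000L, 20000L, 43000L, 52000L, 71500L, 76000L)
  )
  gene_models(genes, exons)
}
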