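# Brute-force oracles, independent of the package's interval machinery.
# Intervals here are plain data.frames with 1-based closed start/end
# (matching the package's internal GRanges coordinates).

# per-base overlap counter + predicate
brute_overlap <- function(c1, s1, e1, c2, s2, e2,
                          fa = 0.25, fb = 0.25, either = TRUE) {
  if (c1 != c2) return(FALSE)
  o <- length(intersect(seq(s1, e1), seq(s2, e2)))
  la <- e1 - s1 + 1
  lb <- e2 - s2 + 1
  ha <- o >= fa * la
  hb <- o >= fb * lb
  o > 0 && (if (either) ha || hb else ha && hb)
}

# all-pairs component search over replicate peak tables
# reps: list of data.frames(chrom, start, end, name); returns data.frame of
# consensus intervals (union coords) with support
brute_consensus <- function(reps, fa = 0.25, fb = 0.25, either = TRUE,
                            min_support = 2) {
  df <- do.call(rbind, lapply(seq_along(reps), function(r) {
    d <- reps[[r]]
    if (nrow(d)) d$rep <- r
    d
  }))
  n <- nrow(df)
  if (is.null(n) || n == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), support = integer(0)))
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && df$rep[i] != df$rep[j]) {
        adj[i, j] <- brute_overlap(df$chrom[i], df$start[i], df$end[i],
                                   df$chrom[j], df$start[j], df$end[j],
                                   fa, fb, either)
      }
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb)) {
        m <- min(comp[c(i, nb)])
        if (any(comp[c(i, nb)] != m)) {
          comp[c(i, nb)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    sup <- length(unique(df$rep[idx]))
    if (sup < min_support) return(NULL)
    data.frame(chrom = df$chrom[idx[1]], start = min(df$start[idx]),
               end = max(df$end[idx]), support = sup)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), support = integer(0)))
  }
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# exhaustive nearest-anchor scan; anchors df(gene_id, chrom, tss, strand)
brute_nearest <- function(mid, chrom, anchors) {
  f <- anchors[anchors$chrom == chrom, , drop = FALSE]
  if (nrow(f) == 0) return(list(gene = NA, dist = NA))
  d <- abs(f$tss - mid)
  best <- which(d == min(d))
  best <- best[order(f$gene_id[best])][1]
  sgn <- if (f$strand[best] == "-") -1 else 1
  list(gene = f$gene_id[best], dist = sgn * (mid - f$tss[best]))
}

# hypergeometric upper-tail by exhaustive summation
brute_hyper_tail <- function(obs, cluster_size, universe, query_size) {
  ks <- obs:min(cluster_size, query_size)
  sum(vapply(ks, function(k) {
    exp(lchoose(cluster_size, k) +
          lchoose(universe - cluster_size, query_size - k) -
          lchoose(universe, query_size))
  }, numeric(1)))
}

# adjusted Rand index from two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxidx - expected)
}

# brute-force per-position PWM score on one strand
brute_pwm_scores <- function(seq, logodds) {
  bases <- strsplit(toupper(seq), "")[[1]]
  L <- ncol(logodds)
  npos <- length(bases) - L + 1
  vapply(seq_len(max(npos, 0)), function(i) {
    s <- 0
    for (j in seq_len(L)) {
      b <- bases[i + j - 1]
      if (!b %in% rownames(logodds)) return(-Inf)
      s <- s + logodds[b, j]
    }
    s
  }, numeric(1))
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random replicate peak tables on a small genome (1-based closed coords)
random_replicate_sets <- function(n_reps = 4, max_peaks = 30,
                                  chroms = c("c1", "c2"), span = 20000) {
  lapply(seq_len(n_reps), function(r) {
    n <- sample.int(max_peaks, 1)
    st <- sample.int(span, n, replace = TRUE)
    w <- sample(50:500, n, replace = TRUE)
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               start = st, end = st + w,
               name = sprintf("r%d_p%d", r, seq_len(n)),
               stringsAsFactors = FALSE)
  })
}

df_to_granges <- function(df, mark = "X", stage = "D0", genotype = "WT",
                          replicate = 1L) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = df$name, score = 0, mark = mark, stage = stage,
    genotype = genotype, replicate = as.integer(replicate))
  gr
}

# NB count matrix with planted two-group effects
sim_nb_counts <- function(n_feat, n_a, n_b, mu, phi, lfc = rep(0, n_feat)) {
  m <- matrix(0, n_feat, n_a + n_b)
  colnames(m) <- c(paste0("A", seq_len(n_a)), paste0("B", seq_len(n_b)))
  rownames(m) <- paste0("f", seq_len(n_feat))
  for (j in seq_len(n_a)) m[, j] <- rnbinom(n_feat, mu = mu, size = 1 / phi)
  for (j in seq_len(n_b)) {
    m[, n_a + j] <- rnbinom(n_feat, mu = mu * 2^lfc, size = 1 / phi)
  }
  m
}
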