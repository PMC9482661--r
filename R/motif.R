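DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param name motif name.
#' @param counts 4 x L matrix of per-position base counts or probabilities,
#'   rows A/C/G/T.
#' @param background base composition (sums to 1); default uniform.
#' @param pseudocount added to counts before normalization.
#' @param tf_class optional transcription-factor class tag carried as
#'   metadata (never inferred).
#' @return object of class `pwm` with probability matrix, log2-odds matrix,
#'   and achievable score range.
#' @export
pwm <- function(name, counts, background = rep(0.25, 4),
                pseudocount = 0.01, tf_class = NA_character_) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 4L, all(counts >= 0))
  stopifnot(length(background) == 4L,
            abs(sum(background) - 1) < 1e-6, all(background > 0))
  rownames(counts) <- DNA_BASES
  probs <- apply(counts + pseudocount, 2, function(col) col / sum(col))
  logodds <- log2(probs / background)
  structure(list(
    name = name, probs = probs, background = background,
    logodds = logodds,
    score_max = sum(apply(logodds, 2, max)),
    score_min = sum(apply(logodds, 2, min)),
    length = ncol(probs), tf_class = tf_class
  ), class = "pwm")
}

#' Default hit threshold for a PWM at a relative score quantile
#'
#' The threshold is `min + q * (max - min)` of the achievable log2-odds
#' score range (relative score quantile), the package's stand-in for
#' motif-specific published thresholds.
#'
#' @param x a [pwm()].
#' @param quantile relative score quantile in (0, 1).
#' @export
pwm_threshold <- function(x, quantile = 0.85) {
  stopifnot(inherits(x, "pwm"), quantile > 0, quantile < 1)
  x$score_min + quantile * (x$score_max - x$score_min)
}

#' Read JASPAR-format PWM files
#'
#' Plain-text JASPAR format: a `>name` header then four lines
#' `A [ 1 2 3 ]` etc. Multiple motifs per file are supported.
#'
#' @param path file path.
#' @param ... passed to [pwm()] (background, pseudocount).
#' @return list of `pwm` objects.
#' @export
read_jaspar <- function(path, ...) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no JASPAR motif headers in ", path)
  out <- list()
  for (i in seq_along(hdr)) {
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) < 4L) stop("motif block with fewer than 4 base rows")
    name <- sub("^>\\s*", "", lines[hdr[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    rows <- lapply(block[1:4], function(l) {
      nums <- regmatches(l, gregexpr("[0-9.]+", l))[[1]]
      as.numeric(nums)
    })
    L <- unique(vapply(rows, length, 1L))
    if (length(L) != 1L) stop("ragged JASPAR matrix for motif ", name)
    base_tags <- toupper(substr(block[1:4], 1, 1))
    mat <- do.call(rbind, rows)
    if (all(DNA_BASES %in% base_tags)) mat <- mat[match(DNA_BASES, base_tags), ]
    out[[name]] <- pwm(name, mat, ...)
  }
  out
}

#' Write PWMs in JASPAR plain-text format (counts scaled to 100)
#' @param pwms list of [pwm()] objects.
#' @param path output path.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    counts <- round(p$probs * 100, 2)
    c(paste0(">", p$name),
      vapply(1:4, function(i) {
        paste0(DNA_BASES[i], " [ ", paste(counts[i, ], collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

seq_to_index <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  m <- match(chars, DNA_BASES) # N and others -> NA
  m
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan a sequence with a PWM
#'
#' Log2-odds scoring of every position on both strands; positions covering
#' an `N` (or any non-ACGT base) score `-Inf`. A hit is a position with
#' score at or above the threshold. Reported positions are 1-based starts
#' on the forward sequence for both strands.
#'
#' @param seq a nucleotide string over A/C/G/T/N.
#' @param x a [pwm()].
#' @param threshold log2-odds hit threshold; default from [pwm_threshold()]
#'   at 0.85.
#' @return data.frame: `pos`, `strand`, `score`, sorted by position.
#' @export
scan_pwm <- function(seq, x, threshold = pwm_threshold(x)) {
  stopifnot(inherits(x, "pwm"))
  L <- x$length
  n <- nchar(seq)
  if (n < L) {
    return(data.frame(pos = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  scan_strand <- function(s) {
    idx <- seq_to_index(s)
    npos <- length(idx) - L + 1L
    scores <- numeric(npos)
    for (j in seq_len(L)) {
      b <- idx[j:(j + npos - 1L)]
      col <- x$logodds[, j]
      sc <- col[b]
      sc[is.na(b)] <- -Inf
      scores <- scores + sc
    }
    scores
  }
  fwd <- scan_strand(seq)
  rev <- scan_strand(revcomp(seq))
  hits_f <- which(fwd >= threshold)
  hits_r <- which(rev >= threshold)
  out <- data.frame(
    pos = c(hits_f, n - L + 2L - hits_r), # map rc positions back to forward
    strand = c(rep("+", length(hits_f)), rep("-", length(hits_r))),
    score = c(fwd[hits_f], rev[hits_r])
  )
  out[order(out$pos, out$strand), , drop = FALSE]
}

#' Motif enrichment of foreground vs background sequence sets
#'
#' Per motif, counts sequences with at least one hit in foreground and
#' background, tests foreground excess with a one-sided Fisher exact test
#' on the 2x2 table, and BH-adjusts across motifs.
#'
#' @param fg,bg character vectors (or `DNAStringSet`) of sequences; must be
#'   disjoint sets and nonempty.
#' @param pwms list of [pwm()] objects.
#' @param quantile relative score quantile for the hit threshold.
#' @return data.frame: `motif`, `fg_hits`, `bg_hits`, `fg_n`, `bg_n`,
#'   `pct_fg`, `odds_ratio`, `pvalue`, `qvalue`, `tf_class`, sorted by
#'   `qvalue`.
#' @export
motif_enrichment <- function(fg, bg, pwms, quantile = 0.85) {
  fg <- as.character(fg); bg <- as.character(bg)
  if (length(fg) == 0L || length(bg) == 0L) {
    stop("foreground and background must both be nonempty")
  }
  if (length(intersect(fg, bg))) stop("foreground and background overlap")
  res <- lapply(pwms, function(p) {
    thr <- pwm_threshold(p, quantile)
    fg_hit <- sum(vapply(fg, function(s) nrow(scan_pwm(s, p, thr)) > 0,
                         logical(1)))
    bg_hit <- sum(vapply(bg, function(s) nrow(scan_pwm(s, p, thr)) > 0,
                         logical(1)))
    tab <- matrix(c(fg_hit, length(fg) - fg_hit,
                    bg_hit, length(bg) - bg_hit), nrow = 2)
    ft <- stats::fisher.test(tab, alternative = "greater")
    data.frame(
      motif = p$name, fg_hits = fg_hit, bg_hits = bg_hit,
      fg_n = length(fg), bg_n = length(bg),
      pct_fg = 100 * fg_hit / length(fg),
      odds_ratio = unname(ft$estimate), pvalue = ft$p.value,
      tf_class = p$tf_class, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out[order(out$qvalue, out$pvalue, -out$pct_fg), ]
}

gc_content <- function(seqs) {
  vapply(as.character(seqs), function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    mean(chars %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Sample a length- and GC-matched background region set
#'
#' Draws `n_per` random regions per foreground peak with identical length,
#' from the same chromosome set, excluding any region overlapping the
#' foreground (under the configured predicate), and matching the
#' foreground peak's GC bin (5 equal-width bins over [0, 1]).
#'
#' @param fg foreground `GRanges`.
#' @param genome named `DNAStringSet` (or named character vector) covering
#'   the foreground chromosomes.
#' @param cfg an [analysis_config()] (seeds the sampler via `rng_seed`).
#' @param n_per background regions per foreground peak (default 2).
#' @param max_tries draw attempts per region before erroring.
#' @return `GRanges` of background regions with a `gc_bin` column.
#' @export
make_background <- function(fg, genome, cfg = analysis_config(),
                            n_per = 2L, max_tries = 2000L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chroms <- names(genome)
  miss <- setdiff(unique(as.character(GenomicRanges::seqnames(fg))), chroms)
  if (length(miss)) stop("genome lacks chromosome(s): ",
                         paste(miss, collapse = ", "))
  fg_seq <- extract_sequences(fg, genome)
  fg_gc_bin <- pmin(5L, findInterval(gc_content(fg_seq),
                                     seq(0, 1, by = 0.2)))
  lens <- GenomicRanges::width(fg)
  chrom_lens <- stats::setNames(Biostrings::width(genome), chroms)
  with_seed(cfg$rng_seed, {
    out_chrom <- character(0); out_start <- integer(0); out_len <- integer(0)
    out_bin <- integer(0)
    for (i in seq_along(fg)) {
      want_bin <- fg_gc_bin[i]
      L <- lens[i]
      got <- 0L
      tries <- 0L
      while (got < n_per) {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("insufficient eligible genome space for background sampling")
        }
        chr <- sample(chroms, 1L)
        if (chrom_lens[chr] < L + 1L) next
        st <- sample.int(chrom_lens[chr] - L, 1L) # 1-based start
        cand <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, st + L - 1L))
        pairs <- overlap_pairs(cand, fg, cfg)
        if (nrow(pairs)) next
        s <- as.character(Biostrings::subseq(genome[[chr]], st, st + L - 1L))
        bin <- min(5L, findInterval(gc_content(s), seq(0, 1, by = 0.2)))
        if (bin != want_bin) next
        got <- got + 1L
        out_chrom <- c(out_chrom, chr)
        out_start <- c(out_start, st)
        out_len <- c(out_len, L)
        out_bin <- c(out_bin, bin)
      }
    }
    gr <- GenomicRanges::GRanges(
      out_chrom, IRanges::IRanges(out_start, width = out_len))
    S4Vectors::mcols(gr)$gc_bin <- out_bin
    S4Vectors::mcols(gr)$name <- sprintf("bg_%05d", seq_along(gr))
    gr
  })
}

#' Extract interval sequences from a genome
#' @param gr a `GRanges`.
#' @param genome named `DNAStringSet` or named character vector.
#' @return character vector of sequences, named by peak name when present.
#' @export
extract_sequences <- function(gr, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  out <- vapply(seq_along(gr), function(i) {
    chr <- as.character(GenomicRanges::seqnames(gr))[i]
    as.character(Biostrings::subseq(genome[[chr]],
                                    GenomicRanges::start(gr)[i],
                                    GenomicRanges::end(gr)[i]))
  }, character(1))
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) names(out) <- nm
  out
}
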