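#' Read a BED6 or narrowPeak peak file
#'
#' Coordinates on disk are BED: 0-based half-open. Internally peaks are held
#' as `GRanges` (1-based closed), converted at this boundary; [write_peak_file()]
#' converts back, so read/write is a bijection on valid files.
#'
#' @param path path to a tab-separated BED6 or ENCODE narrowPeak file.
#' @param dialect `"bed6"`, `"narrowPeak"`, or `"auto"` (10 columns implies
#'   narrowPeak).
#' @param mark,stage,genotype,replicate optional metadata attached to every
#'   peak (columns in `mcols`).
#' @return a sorted `GRanges` with columns `name`, `score` and, for
#'   narrowPeak, `signal`, `pvalue`, `qvalue` and the absolute `summit`
#'   position (NA when the summit offset is -1).
#' @export
read_peak_file <- function(path, dialect = c("auto", "bed6", "narrowPeak"),
                           mark = NA_character_, stage = NA_character_,
                           genotype = NA_character_, replicate = NA_integer_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_peaks(mark, stage, genotype, replicate))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- vapply(fields, length, 1L)
  if (any(ncols < 3L)) {
    stop("line ", which(ncols < 3L)[1], ": fewer than 3 tab-separated columns")
  }
  if (dialect == "auto") dialect <- if (all(ncols >= 10L)) "narrowPeak" else "bed6"
  get_col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  chrom <- get_col(1L)
  start0 <- suppressWarnings(as.numeric(get_col(2L)))
  end <- suppressWarnings(as.numeric(get_col(3L)))
  bad <- which(is.na(start0) | is.na(end) | start0 != floor(start0) |
                 end != floor(end))
  if (length(bad)) stop("line ", bad[1], ": non-integer coordinate")
  bad <- which(start0 >= end | start0 < 0)
  if (length(bad)) {
    stop("line ", bad[1], ": invalid interval (start >= end or negative)")
  }
  name <- get_col(4L)
  name[is.na(name) | name == "."] <- paste0("peak", seq_along(chrom))[is.na(name) | name == "."]
  score <- suppressWarnings(as.numeric(get_col(5L, "0")))
  score[is.na(score)] <- 0
  strand <- get_col(6L, ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end),
    strand = strand
  )
  mc <- S4Vectors::DataFrame(name = name, score = score)
  if (dialect == "narrowPeak") {
    if (any(ncols < 10L)) {
      stop("line ", which(ncols < 10L)[1], ": narrowPeak requires 10 columns")
    }
    mc$signal <- as.numeric(get_col(7L))
    mc$pvalue <- as.numeric(get_col(8L))
    mc$qvalue <- as.numeric(get_col(9L))
    off <- suppressWarnings(as.integer(get_col(10L)))
    mc$summit <- ifelse(!is.na(off) & off >= 0L, start0 + off, NA_real_)
  }
  mc$mark <- mark
  mc$stage <- stage
  mc$genotype <- genotype
  mc$replicate <- as.integer(replicate)
  S4Vectors::mcols(gr) <- mc
  sort_peaks(gr)
}

empty_peaks <- function(mark = NA_character_, stage = NA_character_,
                        genotype = NA_character_, replicate = NA_integer_) {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$name <- character(0)
  S4Vectors::mcols(gr)$score <- numeric(0)
  S4Vectors::mcols(gr)$mark <- character(0)
  S4Vectors::mcols(gr)$stage <- character(0)
  S4Vectors::mcols(gr)$genotype <- character(0)
  S4Vectors::mcols(gr)$replicate <- integer(0)
  gr
}

# deterministic ordering: chrom lexical, then start, then end
sort_peaks <- function(gr) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr[o]
}

#' Write peaks to a BED file
#'
#' Emits BED 0-based half-open coordinates. Any metadata columns beyond the
#' BED6 set are appended as extra tab-separated columns in the given order.
#'
#' @param gr a `GRanges` with at least a `name` column.
#' @param path output path.
#' @param extra_cols names of `mcols` columns to append after column 6.
#' @export
write_peak_file <- function(gr, path, extra_cols = character(0)) {
  mc <- S4Vectors::mcols(gr)
  name <- if ("name" %in% names(mc)) mc$name else paste0("peak", seq_along(gr))
  score <- if ("score" %in% names(mc)) mc$score else 0
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = name, score = score, strand = strand
  )
  for (col in extra_cols) dt[[col]] <- mc[[col]]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Tab-separated with a header row; numeric columns are rendered so that
#' [read_results_table()] reproduces the records exactly (round-trip).
#'
#' @param records a data.frame (all records share one schema).
#' @param path output path.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  dt <- data.table::as.data.table(records)
  for (j in names(dt)) {
    if (is.factor(dt[[j]])) dt[[j]] <- as.character(dt[[j]])
    if (is.double(dt[[j]])) {
      dt[[j]] <- formatC(dt[[j]], format = "g", digits = 17)
      dt[[j]][dt[[j]] %in% c("NA", " NA")] <- NA_character_
    }
  }
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("results table not found: ", path)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = "NA"))
}

#' Read a sample metadata table
#'
#' TSV with header and columns `sample`, `mark`, `stage`, `genotype`,
#' `replicate`, and optionally `path`.
#' @param path TSV path.
#' @export
read_sample_sheet <- function(path) {
  ss <- read_results_table(path)
  need <- c("sample", "stage", "genotype", "replicate")
  miss <- setdiff(need, names(ss))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  ss
}

#' Read a gene-level count matrix from TSV
#'
#' Rows are gene IDs (first column), remaining columns are sample IDs.
#' @param path TSV path.
#' @return integer matrix, genes x samples.
#' @export
read_count_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a count (or any numeric) matrix as TSV with a gene-id first column
#' @param m numeric matrix with rownames.
#' @param path output path.
#' @param id_col name of the first column (default `"gene"`).
#' @export
write_count_table <- function(m, path, id_col = "gene") {
  dt <- data.table::data.table(id = rownames(m))
  data.table::setnames(dt, "id", id_col)
  for (j in colnames(m)) dt[[j]] <- m[, j]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
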