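#' Genomic intervals and peaks
#'
#' All coordinates in chipdep are 0-based, half-open (BED convention):
#' an interval covers bases `start .. end - 1` and `end - start` is its
#' length. Intervals are plain data frames with columns `chrom`
#' (character), `start` and `end` (integer-valued). Peaks extend
#' intervals with `summit_offset` (bp offset of the summit from
#' `start`), `score` (enrichment statistic, here -log10 of the minimum
#' bin p-value) and `p_value`.
#'
#' @param chrom character vector of chromosome names
#' @param start,end 0-based half-open coordinates
#' @return `genomic_intervals()` returns a validated interval
#'   data frame; `peaks()` additionally carries summit and evidence
#'   columns.
#' @examples
#' genomic_intervals("chr2L", 100, 350)
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer()) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, where = "interval set") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop(sprintf("%s: invalid interval at row %d (need 0 <= start < end, got [%s, %s))",
                 where, bad[1], format(df$start[bad[1]]), format(df$end[bad[1]])))
  }
  invisible(df)
}

#' @rdname genomic_intervals
#' @param summit_offset bp offset of the summit from `start`;
#'   must satisfy `0 <= summit_offset < end - start`
#' @param score enrichment score (-log10 minimum bin p-value for called
#'   peaks)
#' @param p_value calling p-value in (0, 1]
#' @export
peaks <- function(chrom = character(), start = integer(), end = integer(),
                  summit_offset = integer(), score = numeric(),
                  p_value = numeric()) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   summit_offset = as.numeric(summit_offset),
                   score = as.numeric(score), p_value = as.numeric(p_value),
                   stringsAsFactors = FALSE)
  validate_peaks(df)
  df
}

validate_peaks <- function(df, where = "peak set") {
  validate_intervals(df, where)
  bad <- which(!(df$summit_offset >= 0 & df$summit_offset < df$end - df$start))
  if (length(bad)) {
    stop(sprintf("%s: summit offset outside interval at row %d", where, bad[1]))
  }
  invisible(df)
}

#' Absolute summit positions of peaks
#' @param pk a peak data frame
#' @return numeric vector of absolute summit coordinates (0-based)
#' @export
summit_pos <- function(pk) pk$start + pk$summit_offset

# ---- BED / narrowPeak / chrom sizes I/O ----------------------------------

read_tab_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a BED3+ file as genomic intervals
#'
#' Lines starting with `#`, `track` or `browser` are skipped. Only the
#' first three columns are interpreted; coordinates must be 0-based
#' half-open with `start < end`.
#'
#' @param path path to a BED file
#' @return interval data frame (columns `chrom`, `start`, `end`),
#'   input order preserved
#' @export
read_bed <- function(path) {
  lx <- read_tab_lines(path)
  if (!length(lx$lines)) return(genomic_intervals())
  fields <- strsplit(lx$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    i <- which(nf < 3)[1]
    stop(sprintf("BED parse error at line %d of %s: fewer than 3 columns",
                 lx$lineno[i], path))
  }
  df <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                   start = as.numeric(vapply(fields, `[[`, "", 2L)),
                   end   = as.numeric(vapply(fields, `[[`, "", 3L)),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d of %s: need 0 <= start < end",
                 lx$lineno[bad[1]], path))
  }
  df
}

#' Write genomic intervals as BED3
#' @param intervals interval data frame
#' @param path output path
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  writeLines(sprintf("%s\t%d\t%d", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end)),
             path)
  invisible(path)
}

#' Read and write ENCODE narrowPeak files
#'
#' narrowPeak is BED6+4; column 10 is the summit offset from `start`
#' (-1 when unknown, mapped here to the interval midpoint with a
#' warning), column 8 the -log10 p-value. A write/read round trip is the
#' identity on `(chrom, start, end, summit_offset, score, p_value)`.
#'
#' @param path path to a 10-column narrowPeak file
#' @return peak data frame
#' @export
read_narrowpeak <- function(path) {
  lx <- read_tab_lines(path)
  if (!length(lx$lines)) return(peaks())
  fields <- strsplit(lx$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10)) {
    i <- which(nf != 10)[1]
    stop(sprintf("narrowPeak parse error at line %d of %s: expected 10 columns, got %d",
                 lx$lineno[i], path, nf[i]))
  }
  m <- do.call(rbind, fields)
  start <- as.numeric(m[, 2]); end <- as.numeric(m[, 3])
  summ <- as.numeric(m[, 10])
  neg <- summ == -1
  if (any(neg)) {
    warning(sprintf("%d narrowPeak record(s) with summit -1; using interval midpoint",
                    sum(neg)))
    summ[neg] <- floor((end[neg] - start[neg]) / 2)
  }
  bad <- which(summ < 0 | summ >= end - start)
  if (length(bad)) {
    stop(sprintf("narrowPeak parse error at line %d of %s: summit offset outside interval",
                 lx$lineno[bad[1]], path))
  }
  pk <- data.frame(chrom = m[, 1], start = start, end = end,
                   summit_offset = summ, score = as.numeric(m[, 7]),
                   p_value = 10^(-as.numeric(m[, 8])),
                   stringsAsFactors = FALSE)
  validate_peaks(pk, path)
  pk
}

#' @rdname read_narrowpeak
#' @param pk peak data frame
#' @export
write_narrowpeak <- function(pk, path) {
  validate_peaks(pk)
  writeLines(sprintf("%s\t%d\t%d\tpeak_%d\t%d\t.\t%s\t%s\t-1\t%d",
                     pk$chrom, as.integer(pk$start), as.integer(pk$end),
                     seq_len(nrow(pk)),
                     pmin(1000L, as.integer(round(pk$score * 10))),
                     format_num(pk$score), format_num(-log10(pk$p_value)),
                     as.integer(pk$summit_offset)),
             path)
  invisible(path)
}

format_num <- function(x) formatC(x, format = "g", digits = 17)

#' Read a chromosome-sizes table
#' @param path two-column TSV (name, length in bp)
#' @return named numeric vector of chromosome lengths
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$size, df$chrom)
}

# ---- coordinate arithmetic ------------------------------------------------

#' Standardized summit windows
#'
#' Returns the fixed-width window `[summit - flank, summit + flank)`
#' around each peak summit, clipped at chromosome bounds. These windows
#' are the unit of all signal quantification and overlap bookkeeping
#' downstream.
#'
#' @param pk peak data frame
#' @param flank half-width in bp (default 250, giving 500 bp windows)
#' @param chrom_sizes named vector of chromosome lengths used for
#'   clipping; unclipped if omitted
#' @return interval data frame aligned with `pk`
#' @export
summit_window <- function(pk, flank = 250, chrom_sizes = NULL) {
  if (!is.numeric(flank) || length(flank) != 1 || flank <= 0) {
    stop("flank must be a single positive number of bp")
  }
  s <- summit_pos(pk)
  start <- pmax(0, s - flank)
  end <- s + flank
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[pk$chrom]
    if (anyNA(lim)) stop("summit_window: peak on chromosome absent from chrom_sizes")
    end <- pmin(end, as.numeric(lim))
  }
  data.frame(chrom = pk$chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

# fast rbind for interval-like frames (avoids rownames bookkeeping)
bind_intervals <- function(...) {
  dfs <- list(...)
  dfs <- dfs[vapply(dfs, NROW, 0L) > 0]
  if (!length(dfs)) return(genomic_intervals())
  cols <- names(dfs[[1]])
  out <- lapply(cols, function(cl) unlist(lapply(dfs, `[[`, cl), use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

as_iranges_by_chrom <- function(df) {
  # half-open [start, end) -> 1-based closed [start+1, end]
  split(IRanges::IRanges(start = as.integer(df$start) + 1L,
                         end = as.integer(df$end)),
        df$chrom)
}

#' Pairwise and set overlap of half-open intervals
#'
#' `interval_overlaps()` compares two equal-length (or length-1
#' recycled) interval frames element-wise; `overlap_any()` flags, for
#' each query interval, whether it overlaps any subject interval by at
#' least `min_overlap` bp. Abutting intervals (shared endpoint in
#' half-open coordinates) do not overlap.
#'
#' @param a,b interval data frames compared element-wise
#' @param min_overlap minimum overlap in bp (>= 1)
#' @return logical vector
#' @export
interval_overlaps <- function(a, b, min_overlap = 1) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  a$chrom[ai] == b$chrom[bi] & ov >= min_overlap
}

#' @rdname interval_overlaps
#' @param query,subject interval data frames
#' @export
overlap_any <- function(query, subject, min_overlap = 1) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  out <- logical(nrow(query))
  if (!nrow(query) || !nrow(subject)) return(out)
  qs <- as_iranges_by_chrom(query)
  ss <- as_iranges_by_chrom(subject)
  qidx <- split(seq_len(nrow(query)), query$chrom)
  for (chr in names(qs)) {
    if (!chr %in% names(ss)) next
    hit <- IRanges::overlapsAny(qs[[chr]], ss[[chr]],
                                minoverlap = as.integer(min_overlap))
    out[qidx[[chr]]] <- hit
  }
  out
}
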