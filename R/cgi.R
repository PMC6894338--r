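#' G+C content of a sequence interval
#'
#' Percent G+C over the 1-based inclusive interval, computed over
#' non-N bases only (N is excluded from numerator and denominator).
#'
#' @param seq character scalar, normalised DNA.
#' @param start,end 1-based inclusive bounds; defaults cover the whole
#'   sequence.
#' @return percent in `[0, 100]`.
#' @examples
#' gcContent("ACGT")  # 50
#' @export
gcContent <- function(seq, start = 1L, end = nchar(seq)) {
  s <- .interval_chars(seq, start, end)
  n <- sum(s != "N")
  if (n == 0L) stop("interval contains only N bases", call. = FALSE)
  100 * sum(s == "G" | s == "C") / n
}

#' Observed/expected CpG ratio of a sequence interval
#'
#' The Gardiner-Garden & Frommer statistic
#' `(#CpG * L) / (#C * #G)` with `L` the non-N length of the interval.
#' Returns 0 when `#C * #G = 0`. N breaks dinucleotide counting (CN
#' and NG are not CpGs).
#'
#' @inheritParams gcContent
#' @return dimensionless ratio, >= 0.
#' @examples
#' obsExpCpG("CCGG")  # 1
#' @export
obsExpCpG <- function(seq, start = 1L, end = nchar(seq)) {
  s <- .interval_chars(seq, start, end)
  nC <- sum(s == "C"); nG <- sum(s == "G")
  if (nC == 0L || nG == 0L) return(0)
  cg <- sum(s[-length(s)] == "C" & s[-1L] == "G")
  L <- sum(s != "N")
  cg * L / (nC * nG)
}

.interval_chars <- function(seq, start, end) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (start < 1L || end > n || start > end)
    stop("interval [", start, ", ", end, "] outside sequence bounds 1..",
         n, call. = FALSE)
  strsplit(substr(seq, start, end), "", fixed = TRUE)[[1L]]
}

#' Detect CpG islands
#'
#' Sliding-window CpG-island detection under the classical composition
#' criteria: reported islands have length strictly greater than
#' `minLength`, G+C percent strictly greater than `minGC` and
#' observed/expected CpG ratio strictly greater than `minOE`.
#' Qualifying `window`-bp windows (step `step`) are merged when they
#' overlap or are adjacent; each merged interval is re-evaluated as a
#' whole and, if it fails, up to one window is trimmed from each flank
#' before the candidate is dropped.
#'
#' @param seq character scalar (normalised DNA) or a single named
#'   element of [readFasta()] output.
#' @param minLength minimum island length in bp (strict).
#' @param minGC minimum G+C percent (strict).
#' @param minOE minimum observed/expected CpG ratio (strict).
#' @param window sliding window size in bp.
#' @param step window step in bp.
#' @param seqId sequence name used in the output; defaults to the
#'   element name or `"seq"`.
#' @return [GenomicRanges::GRanges] with metadata columns `length_bp`,
#'   `gc_percent` and `obs_exp_cpg`; empty when the sequence is
#'   shorter than `window` (with a message) or no island qualifies.
#' @export
findCGIs <- function(seq, minLength = 200, minGC = 50, minOE = 0.6,
                     window = 200L, step = 1L, seqId = NULL) {
  seqId <- seqId %||% (if (!is.null(names(seq))) names(seq)[1L] else "seq")
  seq <- toupper(unname(seq[1L]))
  n <- nchar(seq)
  if (n < window) {
    message("sequence '", seqId, "' (", n, " bp) shorter than window (",
            window, " bp); no islands reported")
    return(.empty_cgi_granges())
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  isC <- ch == "C"; isG <- ch == "G"; notN <- ch != "N"
  isCpG <- c(isC[-n] & isG[-1L], FALSE)

  cumC <- c(0, cumsum(isC)); cumG <- c(0, cumsum(isG))
  cumN <- c(0, cumsum(notN)); cumCpG <- c(0, cumsum(isCpG))
  win_sum <- function(cum, s, e) cum[e + 1L] - cum[s]

  starts <- seq.int(1L, n - window + 1L, by = step)
  ends <- starts + window - 1L
  nC <- win_sum(cumC, starts, ends)
  nG <- win_sum(cumG, starts, ends)
  L <- win_sum(cumN, starts, ends)
  # CpG count within window: exclude a CpG straddling the window end
  cg <- win_sum(cumCpG, starts, ends) - (isCpG[ends])
  gc <- ifelse(L > 0, 100 * (nC + nG) / L, 0)
  oe <- ifelse(nC > 0 & nG > 0, cg * L / (nC * nG), 0)
  qual <- L > 0 & gc > minGC & oe > minOE

  qs <- starts[qual]
  if (length(qs) == 0L) return(.empty_cgi_granges())
  # merge qualifying windows that overlap or touch
  brk <- which(diff(qs) > window)
  run_start <- qs[c(1L, brk + 1L)]
  run_end <- qs[c(brk, length(qs))] + window - 1L

  passes <- function(s, e) {
    if (e - s + 1L <= minLength) return(FALSE)
    L <- win_sum(cumN, s, e)
    if (L == 0L) return(FALSE)
    nC <- win_sum(cumC, s, e); nG <- win_sum(cumG, s, e)
    gc <- 100 * (nC + nG) / L
    cg <- win_sum(cumCpG, s, e) - isCpG[e]
    oe <- if (nC > 0 && nG > 0) cg * L / (nC * nG) else 0
    gc > minGC && oe > minOE
  }

  keep_s <- integer(0); keep_e <- integer(0)
  for (i in seq_along(run_start)) {
    cand <- list(c(run_start[i], run_end[i]),
                 c(run_start[i], run_end[i] - window),
                 c(run_start[i] + window, run_end[i]),
                 c(run_start[i] + window, run_end[i] - window))
    for (se in cand) {
      if (se[1L] > se[2L]) next
      if (passes(se[1L], se[2L])) {
        keep_s <- c(keep_s, se[1L]); keep_e <- c(keep_e, se[2L])
        break
      }
    }
  }
  if (length(keep_s) == 0L) return(.empty_cgi_granges())
  o <- order(keep_s)
  keep_s <- keep_s[o]; keep_e <- keep_e[o]
  GenomicRanges::GRanges(
    seqnames = seqId,
    ranges = IRanges::IRanges(start = keep_s, end = keep_e),
    strand = "*",
    length_bp = keep_e - keep_s + 1L,
    gc_percent = vapply(seq_along(keep_s), function(i)
      gcContent(seq, keep_s[i], keep_e[i]), numeric(1L)),
    obs_exp_cpg = vapply(seq_along(keep_s), function(i)
      obsExpCpG(seq, keep_s[i], keep_e[i]), numeric(1L)))
}

.empty_cgi_granges <- function() {
  GenomicRanges::GRanges(
    seqnames = character(0), ranges = IRanges::IRanges(),
    strand = character(0),
    length_bp = integer(0), gc_percent = numeric(0),
    obs_exp_cpg = numeric(0))
}

#' Write CpG islands as BED plus a composition TSV
#'
#' BED output is 0-based half-open (conversion happens here, at the
#' boundary); the TSV keeps 1-based inclusive coordinates together
#' with `gc_percent` and `obs_exp_cpg`.
#'
#' @param islands [GenomicRanges::GRanges] from [findCGIs()].
#' @param bedPath,tsvPath output paths (either may be `NULL` to skip).
#' @return invisibly, a data.frame mirroring the TSV.
#' @export
writeCGIs <- function(islands, bedPath = NULL, tsvPath = NULL) {
  df <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(islands)),
    start = GenomicRanges::start(islands),
    end = GenomicRanges::end(islands),
    length_bp = islands$length_bp,
    gc_percent = islands$gc_percent,
    obs_exp_cpg = islands$obs_exp_cpg,
    stringsAsFactors = FALSE)
  if (!is.null(bedPath)) {
    bed <- data.frame(df$seq_id, df$start - 1L, df$end,
                      sprintf("CGI_%d", seq_len(nrow(df))))
    write.table(bed, bedPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsvPath))
    write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
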