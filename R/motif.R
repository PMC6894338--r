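#' Expand a parenthesised degenerate consensus
#'
#' Expands a consensus written with parenthesised alternative sets,
#' e.g. the TCS consensus `"(A/U)UU(A/G)UCU"`, into all concrete
#' words, lexicographically sorted without duplicates. RNA letters are
#' preserved in the expansions.
#'
#' @param consensus consensus string over concrete bases and
#'   `(X/Y/...)` groups.
#' @return character vector of concrete expansions.
#' @examples
#' expandConsensus("(A/U)UU(A/G)UCU")
#' @export
expandConsensus <- function(consensus) {
  rest <- consensus
  sets <- list()
  while (nzchar(rest)) {
    if (startsWith(rest, "(")) {
      close <- regexpr(")", rest, fixed = TRUE)
      if (close < 0L) stop("unbalanced '(' in consensus", call. = FALSE)
      inner <- substr(rest, 2L, close - 1L)
      alts <- strsplit(inner, "/", fixed = TRUE)[[1L]]
      if (length(alts) < 1L || any(nchar(alts) != 1L))
        stop("malformed alternative set '(", inner, ")'", call. = FALSE)
      sets[[length(sets) + 1L]] <- alts
      rest <- substr(rest, close + 1L, nchar(rest))
    } else {
      ch <- substr(rest, 1L, 1L)
      if (ch == ")") stop("unbalanced ')' in consensus", call. = FALSE)
      sets[[length(sets) + 1L]] <- ch
      rest <- substr(rest, 2L, nchar(rest))
    }
  }
  if (length(sets) == 0L) stop("empty consensus", call. = FALSE)
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  words <- do.call(paste0, rev(grid))
  sort(unique(words))
}

#' The TCS (translation control sequence) consensus
#'
#' The degenerate 3'UTR element `(A/U)UU(A/G)UCU` bound by Zar-family
#' RNA-binding proteins to control translation of targets such as the
#' WEE kinase mRNAs.
#'
#' @return the consensus string.
#' @export
tcsConsensus <- function() "(A/U)UU(A/G)UCU"

#' Scan sequences for all occurrences of a set of concrete motifs
#'
#' Overlap-tolerant exact scan of every expansion against every
#' sequence. Matching is performed in the unified T-alphabet so RNA
#' motifs match DNA 3'UTR sequences; reported motifs use RNA letters.
#' An N in the sequence never matches a motif position.
#'
#' @param utrs named character vector of sequences (DNA or RNA).
#' @param motifs concrete motif words (RNA or DNA letters), e.g. from
#'   [expandConsensus()]; or a consensus string containing `(`, which
#'   is expanded first.
#' @return data.frame `utr_id`, `motif` (RNA letters), `start`
#'   (1-based), sorted by utr (input order), start, motif.
#' @export
scanMotifs <- function(utrs, motifs = tcsConsensus()) {
  if (length(motifs) == 1L && grepl("(", motifs, fixed = TRUE))
    motifs <- expandConsensus(motifs)
  motifs_rna <- chartr("T", "U", toupper(motifs))
  motifs_dna <- chartr("U", "T", toupper(motifs))
  if (is.null(names(utrs))) names(utrs) <- paste0("utr", seq_along(utrs))
  k <- unique(nchar(motifs_dna))
  hits <- lapply(names(utrs), function(id) {
    s <- chartr("U", "T", toupper(utrs[[id]]))
    rows <- lapply(seq_along(motifs_dna), function(i) {
      st <- iupacFindAll(motifs_dna[i], s)
      if (length(st))
        data.frame(utr_id = id, motif = motifs_rna[i], start = st)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(utr_id = character(0), motif = character(0),
                      start = integer(0))
  out <- out[order(match(out$utr_id, names(utrs)), out$start, out$motif), ]
  rownames(out) <- NULL
  out
}

#' Per-UTR motif counts and occurrence histograms
#'
#' Totals hits across all motif expansions per UTR and tabulates how
#' many UTRs carry exactly k and at least k occurrences (k >= 2); the
#' exactly-k and at-least-k readings are both reported because a
#' "UTRs with k motifs" tally is ambiguous between them.
#'
#' @param hits data.frame from [scanMotifs()].
#' @param utrIds all scanned UTR ids (so zero-hit UTRs appear with
#'   count 0); defaults to the ids present in `hits`.
#' @return list with `perUTR` (utr_id, n_hits), `histExact` and
#'   `histAtLeast` (k, n_utrs, k >= 2 only).
#' @export
summariseMotifCounts <- function(hits, utrIds = unique(hits$utr_id)) {
  counts <- setNames(integer(length(utrIds)), utrIds)
  if (nrow(hits)) {
    tab <- table(factor(hits$utr_id, levels = utrIds))
    counts[] <- as.integer(tab)
  }
  perUTR <- data.frame(utr_id = utrIds, n_hits = unname(counts))
  ks <- sort(unique(counts[counts >= 2L]))
  histExact <- data.frame(k = as.integer(ks),
                          n_utrs = vapply(ks, function(k)
                            sum(counts == k), integer(1L)))
  histAtLeast <- data.frame(k = as.integer(ks),
                            n_utrs = vapply(ks, function(k)
                              sum(counts >= k), integer(1L)))
  list(perUTR = perUTR, histExact = histExact, histAtLeast = histAtLeast)
}

#' Same-motif duplicates within a sliding window
#'
#' Reports every pair of occurrences of the *same* concrete motif in
#' the same UTR that a single `window`-nt window can cover. Under the
#' default `"containment"` semantics both occurrences must fit
#' entirely inside one window (start difference <= window - motif
#' length); `"starts"` only requires the start difference to be
#' within the window.
#'
#' @param hits data.frame from [scanMotifs()].
#' @param window window size in nt, default 200.
#' @param semantics `"containment"` (default) or `"starts"`.
#' @return data.frame `utr_id`, `motif`, `first_start`,
#'   `second_start`, `span` (second_start + motif length -
#'   first_start).
#' @export
findWindowDuplicates <- function(hits, window = 200L,
                                 semantics = c("containment", "starts")) {
  semantics <- match.arg(semantics)
  empty <- data.frame(utr_id = character(0), motif = character(0),
                      first_start = integer(0), second_start = integer(0),
                      span = integer(0))
  if (nrow(hits) < 2L) return(empty)
  out <- lapply(split(hits, list(hits$utr_id, hits$motif), drop = TRUE),
    function(g) {
      if (nrow(g) < 2L) return(NULL)
      k <- nchar(chartr("U", "T", g$motif[1L]))
      st <- sort(g$start)
      pairs <- which(outer(st, st, function(a, b) b > a), arr.ind = TRUE)
      first <- st[pairs[, 1L]]; second <- st[pairs[, 2L]]
      maxdiff <- if (semantics == "containment") window - k else window
      keep <- (second - first) <= maxdiff
      if (!any(keep)) return(NULL)
      data.frame(utr_id = g$utr_id[1L], motif = g$motif[1L],
                 first_start = first[keep], second_start = second[keep],
                 span = second[keep] + k - first[keep])
    })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$utr_id, out$motif, out$first_start,
                   out$second_start), ]
  rownames(out) <- NULL
  out
}
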