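#' Normalise a nucleotide sequence
#'
#' Uppercases, strips whitespace, maps U to T (RNA input), and rejects
#' any character outside `A/C/G/T/N`. All downstream matching is done
#' in the unified T-alphabet; the caller's alphabet only affects how
#' motifs are reported (RNA letters for RNA input).
#'
#' @param x character vector of raw sequences.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return character vector of normalised residues (T-alphabet), with
#'   names preserved and attribute `alphabet` recording the source.
#' @examples
#' normalizeSequence("auugucu", "RNA")  # "ATTGTCT"
#' @export
normalizeSequence <- function(x, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (length(x) == 0L) stop("no sequence supplied", call. = FALSE)
  out <- vapply(x, function(s) {
    s <- toupper(gsub("[[:space:]]", "", s))
    if (!nzchar(s)) stop("empty sequence", call. = FALSE)
    if (alphabet == "RNA") {
      if (grepl("T", s, fixed = TRUE))
        stop("T found in RNA input", call. = FALSE)
      s <- chartr("U", "T", s)
    } else if (grepl("U", s, fixed = TRUE)) {
      stop("U found in DNA input", call. = FALSE)
    }
    bad <- regexpr("[^ACGTN]", s)
    if (bad > 0L)
      stop("non-IUPAC character '", substr(s, bad, bad),
           "' at position ", bad, call. = FALSE)
    s
  }, character(1L), USE.NAMES = TRUE)
  if (is.null(names(x))) names(out) <- NULL
  attr(out, "alphabet") <- alphabet
  out
}

#' Match a degenerate IUPAC pattern against an equal-length window
#'
#' TRUE iff every window character lies in the degeneracy set of the
#' corresponding pattern position (e.g. Y = \{C,T\}, R = \{A,G\}). An N
#' in the window only matches a pattern N, never a concrete letter.
#'
#' @param pattern degenerate IUPAC string.
#' @param window concrete string of the same length.
#' @return logical scalar.
#' @examples
#' iupacMatch("AY", "AC")  # TRUE
#' iupacMatch("AY", "AG")  # FALSE
#' @export
iupacMatch <- function(pattern, window) {
  if (nchar(pattern) != nchar(window))
    stop("pattern and window must have equal length", call. = FALSE)
  grepl(paste0("^", iupac_regex(toupper(pattern)), "$"), toupper(window))
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed. N maps to N. Degenerate primer
#' patterns are handled too (Y<->R etc.), so the same function serves
#' concrete sequences and IUPAC primers.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' revComp("AAC")   # "GTT"
#' revComp("TCGA")  # "TCGA" (TaqI site is palindromic)
#' @export
revComp <- function(x) {
  vapply(x, function(s) iupacRevComp(toupper(s)), character(1L),
         USE.NAMES = !is.null(names(x)))
}

#' Read a FASTA file of nucleotide sequences
#'
#' Multi-record FASTA (wrapped or unwrapped). Records are normalised
#' via [normalizeSequence()]; blank or duplicate ids and empty files
#' are format errors. Only the first whitespace-delimited token of
#' each header is used as the id.
#'
#' @param path file path.
#' @param alphabet `"DNA"` or `"RNA"` (RNA input is stored T-mapped).
#' @return named character vector of normalised sequences, in file
#'   order.
#' @export
readFasta <- function(path, alphabet = "DNA") {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with blank id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]),
         collapse = ", "), call. = FALSE)
  seqs <- as.character(set)
  names(seqs) <- ids
  normalizeSequence(seqs, alphabet)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named", call. = FALSE)
  set <- Biostrings::BStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' 1-based positions of CpG dinucleotides
#'
#' Positions of the C of each CpG in a DNA sequence. An N breaks the
#' dinucleotide: CN and NG are not CpGs.
#'
#' @param seq character scalar (normalised DNA).
#' @return increasing integer vector.
#' @export
cpgSites <- function(seq) {
  iupacFindAll("CG", toupper(seq))
}
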