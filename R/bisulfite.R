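#' Deterministic in-silico bisulfite conversion
#'
#' Converts every cytosine to thymine except the C of a methylated CpG
#' (beta >= 0.5 in the profile is treated as methylated for this
#' deterministic converter; use [simBisulfiteReads()] for stochastic
#' per-read states and incomplete conversion). `strand = "bottom"`
#' applies the same rule to the reverse complement; profile positions
#' stay in top-strand coordinates and refer to the CpG whose bottom
#' strand C sits opposite the G.
#'
#' @param seq normalised DNA sequence (character, length 1).
#' @param profile a [MethylationProfile-class]; positions must be CpGs
#'   of `seq`.
#' @param strand `"top"` or `"bottom"`.
#' @param seqId identifier of `seq` for the id check; defaults to the
#'   sequence name, skipping the check when unnamed.
#' @return converted sequence (character scalar).
#' @examples
#' p <- methylationProfile("x", 2L, 1)
#' bisulfiteConvert(c(x = "ACGTCT"), p)  # "ACGTTT"
#' @export
bisulfiteConvert <- function(seq, profile, strand = c("top", "bottom"),
                             seqId = NULL) {
  strand <- match.arg(strand)
  seqId <- seqId %||% (if (!is.null(names(seq))) names(seq)[1L] else NULL)
  if (!is.null(seqId) && seqId != profile@seqId)
    stop("profile is for '", profile@seqId, "', sequence is '", seqId, "'",
         call. = FALSE)
  s <- toupper(unname(seq[1L]))
  n <- nchar(s)
  pos <- cpgPositions(profile)
  if (length(pos) && (any(pos < 1L) || any(pos + 1L > n)))
    stop("profile positions outside sequence", call. = FALSE)
  if (length(pos)) {
    ok <- substring(s, pos, pos) == "C" &
      substring(s, pos + 1L, pos + 1L) == "G"
    if (any(!ok))
      stop("profile positions without CpG: ",
           paste(pos[!ok], collapse = ", "), call. = FALSE)
  }
  meth <- pos[betaValues(profile) >= 0.5]
  if (strand == "bottom") {
    s <- revComp(s)
    # bottom-strand C of a CpG at top position p sits opposite the G
    # (top p+1), i.e. at n - p in reverse-complement coordinates
    meth <- sort(n - meth)
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  keep <- logical(length(ch))
  keep[meth] <- TRUE
  ch[ch == "C" & !keep] <- "T"
  paste(ch, collapse = "")
}

#' Validate a bisulfite PCR primer against converted templates
#'
#' Bisulfite primers must bind only fully converted DNA and must work
#' for any methylation state, so CpG cytosines under the primer are
#' written as degenerate bases (Y on the top-strand product, R on the
#' bottom-strand/reverse primer). The primer passes when it has
#' exactly one perfect degenerate match, at the same locus, on both
#' the fully methylated and the fully unmethylated converted template.
#'
#' @param primer degenerate primer sequence (IUPAC; length >= 15).
#' @param template unconverted genomic template (normalised DNA,
#'   length-1 character, named or not).
#' @param orientation `"forward"` (matches the converted top strand)
#'   or `"reverse"` (matches the reverse complement of the converted
#'   top strand, i.e. the bottom strand of the PCR product).
#' @return list with per-profile components `methylated` and
#'   `unmethylated`, each `list(n_matches, loci)`, and overall `pass`.
#' @export
validateBisulfitePrimer <- function(primer,
                                    template,
                                    orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  primer <- toupper(primer)
  if (nchar(primer) < 15L)
    stop("primer shorter than 15 nt", call. = FALSE)
  tpl <- toupper(unname(template[1L]))
  res <- lapply(c(methylated = 1, unmethylated = 0), function(beta) {
    conv <- bisulfiteConvert(tpl, fullProfile(tpl, beta))
    subject <- if (orientation == "reverse") revComp(conv) else conv
    loci <- iupacFindAll(primer, subject)
    list(n_matches = length(loci), loci = loci)
  })
  pass <- res$methylated$n_matches == 1L &&
    res$unmethylated$n_matches == 1L &&
    res$methylated$loci == res$unmethylated$loci
  c(res, list(pass = pass, orientation = orientation))
}

#' In-silico PCR on a single template
#'
#' Finds the unique product delimited by a forward primer match on the
#' top strand and the reverse complement of the reverse primer
#' downstream of it. Primers may carry IUPAC degeneracy (Y/R for
#' bisulfite primers). Zero or multiple products are distinct errors
#' (conditions `pcrNoProduct` / `pcrMultipleProducts`), because CoBRA
#' interpretation assumes one amplicon.
#'
#' @param template normalised DNA (length-1 character).
#' @param fwd,rev primer sequences, written 5'->3' as ordered.
#' @return list with `start`, `end` (1-based inclusive on the
#'   template), `length`, and `amplicon` (top-strand sequence).
#' @export
inSilicoPCR <- function(template, fwd, rev) {
  tpl <- toupper(unname(template[1L]))
  fwd <- toupper(fwd); rev <- toupper(rev)
  fhits <- iupacFindAll(fwd, tpl)
  rsite <- iupacRevComp(rev)
  rhits <- iupacFindAll(rsite, tpl)
  if (length(fhits) == 0L)
    stop(structure(class = c("pcrNoProduct", "error", "condition"),
                   list(message = "no product: forward primer not found",
                        call = NULL)))
  products <- list()
  for (fs in fhits) {
    fe <- fs + nchar(fwd) - 1L
    for (rs in rhits) {
      re <- rs + nchar(rsite) - 1L
      if (rs > fe) products[[length(products) + 1L]] <- c(fs, re)
    }
  }
  if (length(products) == 0L)
    stop(structure(class = c("pcrNoProduct", "error", "condition"),
                   list(message = "no product: no reverse site downstream of a forward match",
                        call = NULL)))
  if (length(products) > 1L)
    stop(structure(class = c("pcrMultipleProducts", "error", "condition"),
                   list(message = sprintf("multiple products (%d primer pairings)",
                                          length(products)),
                        call = NULL)))
  se <- products[[1L]]
  list(start = se[1L], end = se[2L], length = se[2L] - se[1L] + 1L,
       amplicon = substr(tpl, se[1L], se[2L]))
}

#' Methylation-dependent restriction digest of a CoBRA amplicon
#'
#' Cuts after `cutOffset` bases of every occurrence of the recognition
#' sequence and returns the ordered fragment lengths, which always sum
#' to the amplicon length. An uncut amplicon yields one fragment.
#'
#' @param amplicon amplicon sequence (character scalar).
#' @param enzyme a [RestrictionEnzyme-class]; default [TaqI].
#' @return integer vector of fragment lengths, 5' to 3'.
#' @examples
#' cobraDigest("AATCGATT")  # 3, 5
#' @export
cobraDigest <- function(amplicon, enzyme = TaqI) {
  s <- toupper(unname(amplicon[1L]))
  if (!nzchar(s)) stop("empty amplicon", call. = FALSE)
  n <- nchar(s)
  sites <- iupacFindAll(enzyme@recognition, s)
  cuts <- sites + enzyme@cutOffset - 1L
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  as.integer(diff(c(0L, cuts, n)))
}

#' Beta value from methylated/unmethylated read counts
#'
#' @param methylated,unmethylated non-negative counts (vectorised).
#' @return beta = m / (m + u), in `[0, 1]`.
#' @export
methylationBeta <- function(methylated, unmethylated) {
  if (any(methylated < 0) || any(unmethylated < 0))
    stop("counts must be non-negative", call. = FALSE)
  tot <- methylated + unmethylated
  if (any(tot == 0)) stop("zero coverage: no reads", call. = FALSE)
  methylated / tot
}

#' Classify a beta value against a methylation threshold
#'
#' `beta >= threshold` is called methylated; the default threshold of
#' 0.20 (20%) is the empirical boundary separating methylated tumour
#' samples from unmethylated controls in CoBRA/pyrosequencing
#' quantification.
#'
#' @param beta numeric vector in `[0, 1]`.
#' @param threshold classification boundary, default 0.20.
#' @return character vector, `"methylated"` or `"unmethylated"`.
#' @export
classifyMethylation <- function(beta, threshold = 0.20) {
  if (any(beta < 0 | beta > 1)) stop("beta outside [0, 1]", call. = FALSE)
  ifelse(beta >= threshold, "methylated", "unmethylated")
}

#' Per-CpG beta quantification from simulated bisulfite reads
#'
#' For each CpG position, beta = #C / (#C + #T) over the reads that
#' cover the position (the pyrosequencing readout). CpGs with zero
#' coverage are flagged and carry `NA` beta.
#'
#' @param reads data.frame with columns `read_id`, `start` (1-based
#'   position of the read's first base on the region) and `seq`
#'   (converted read sequence), as emitted by [simBisulfiteReads()].
#' @param positions 1-based CpG positions on the region.
#' @return data.frame with `position`, `n_meth` (C), `n_unmeth` (T),
#'   `coverage`, `beta` (`NA` when uncovered) and `covered`.
#' @export
quantifyFromReads <- function(reads, positions) {
  stopifnot(all(c("read_id", "start", "seq") %in% names(reads)))
  positions <- as.integer(positions)
  ends <- reads$start + nchar(reads$seq) - 1L
  out <- lapply(positions, function(p) {
    cover <- which(reads$start <= p & ends >= p)
    base <- substring(reads$seq[cover], p - reads$start[cover] + 1L,
                      p - reads$start[cover] + 1L)
    nC <- sum(base == "C"); nT <- sum(base == "T")
    data.frame(position = p, n_meth = nC, n_unmeth = nT,
               coverage = length(cover),
               beta = if (nC + nT > 0) nC / (nC + nT) else NA_real_,
               covered = nC + nT > 0)
  })
  do.call(rbind, out)
}

#' Full CoBRA report for one template and primer pair
#'
#' Runs primer validation, in-silico PCR on the converted templates of
#' a set of methylation profiles, and the restriction digest of each
#' amplicon — the complete in-silico CoBRA assay.
#'
#' @param template unconverted genomic template.
#' @param fwd,rev bisulfite primer pair (degenerate Y/R allowed).
#' @param profiles named list of [MethylationProfile-class] objects;
#'   default fully methylated and fully unmethylated.
#' @param enzyme a [RestrictionEnzyme-class]; default [TaqI].
#' @return data.frame with one row per profile: amplicon length, site
#'   positions (comma-separated, within-amplicon), fragment lengths.
#' @export
cobraReport <- function(template, fwd, rev, profiles = NULL,
                        enzyme = TaqI) {
  tpl <- toupper(unname(template[1L]))
  if (is.null(profiles))
    profiles <- list(methylated = fullProfile(tpl, 1),
                     unmethylated = fullProfile(tpl, 0))
  rows <- lapply(names(profiles), function(nm) {
    conv <- bisulfiteConvert(tpl, profiles[[nm]])
    pcr <- inSilicoPCR(conv, fwd, rev)
    frags <- cobraDigest(pcr$amplicon, enzyme)
    sites <- iupacFindAll(enzyme@recognition, pcr$amplicon)
    data.frame(profile = nm, amplicon_length = pcr$length,
               amplicon_start = pcr$start, amplicon_end = pcr$end,
               sites = paste(sites, collapse = ","),
               fragments = paste(frags, collapse = ","),
               n_fragments = length(frags))
  })
  do.call(rbind, rows)
}
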