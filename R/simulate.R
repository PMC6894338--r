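# Seeded generators for every input class the pipeline consumes.
# Each is a pure function of (seed, parameters): identical calls
# reproduce inputs and truth manifests bit-for-bit.

.sample_bases <- function(n, pGC) {
  p <- c(A = (1 - pGC) / 2, C = pGC / 2, G = pGC / 2, T = (1 - pGC) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

# First-order Markov segment targeting a GC percent and an
# observed/expected CpG ratio: P(G | previous C) is scaled by the
# target ratio so that E[oe] ~= target.
.markov_segment <- function(len, targetGC, targetOE) {
  pG <- targetGC / 200
  pgc <- targetOE * pG
  if (pgc >= 1)
    stop("infeasible obs/exp target (", targetOE, ") at GC ", targetGC,
         call. = FALSE)
  base_p <- c(A = (1 - targetGC / 100) / 2, C = pG, G = pG,
              T = (1 - targetGC / 100) / 2)
  fromC <- base_p
  fromC["G"] <- pgc
  fromC[c("A", "C", "T")] <- base_p[c("A", "C", "T")] *
    (1 - pgc) / (1 - pG)
  ch <- character(len)
  ch[1L] <- sample(names(base_p), 1L, prob = base_p)
  for (i in 2L:len) {
    p <- if (ch[i - 1L] == "C") fromC else base_p
    ch[i] <- sample(names(p), 1L, prob = p)
  }
  paste(ch, collapse = "")
}

#' Simulate a genomic segment with planted CpG islands
#'
#' AT-rich background (GC about 35%) with island segments drawn to
#' hit a target G+C percent (within +/- 2) and observed/expected CpG
#' ratio (within +/- 0.1) by rejection sampling over a first-order
#' Markov chain.
#'
#' @param seed RNG seed.
#' @param length total sequence length in bp.
#' @param islands data.frame with columns `start`, `length`,
#'   `target_gc`, `target_oe`; islands must fit and not overlap. May
#'   have zero rows.
#' @param backgroundGC background G+C fraction percent (default 35).
#' @param maxTries rejection-sampling budget per island.
#' @return list with `seq` (named character), `truth` (data.frame of
#'   planted islands with achieved gc/oe) and `manifest`.
#' @export
simCGIGenome <- function(seed, length = 2000L, islands = NULL,
                         backgroundGC = 35, maxTries = 200L) {
  islands <- islands %||%
    data.frame(start = integer(0), length = integer(0),
               target_gc = numeric(0), target_oe = numeric(0))
  if (nrow(islands)) {
    ends <- islands$start + islands$length - 1L
    if (any(islands$start < 1L) || any(ends > length))
      stop("island outside sequence bounds", call. = FALSE)
    o <- order(islands$start)
    if (any(islands$start[o][-1L] <= ends[o][-nrow(islands)]))
      stop("islands overlap", call. = FALSE)
  }
  with_seed(seed, {
    ch <- .sample_bases(length, backgroundGC / 100)
    truth <- islands
    truth$end <- truth$start + truth$length - 1L
    truth$gc_percent <- truth$obs_exp_cpg <- numeric(nrow(truth))
    for (i in seq_len(nrow(islands))) {
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        seg <- .markov_segment(islands$length[i], islands$target_gc[i],
                               islands$target_oe[i])
        gc <- gcContent(seg)
        oe <- obsExpCpG(seg)
        if (abs(gc - islands$target_gc[i]) <= 2 &&
            abs(oe - islands$target_oe[i]) <= 0.1) {
          ch[islands$start[i]:truth$end[i]] <-
            strsplit(seg, "", fixed = TRUE)[[1L]]
          truth$gc_percent[i] <- gc
          truth$obs_exp_cpg[i] <- oe
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not achieve island composition targets (gc ",
             islands$target_gc[i], ", oe ", islands$target_oe[i],
             ") in ", maxTries, " tries", call. = FALSE)
    }
    list(seq = c(sim_genome = paste(ch, collapse = "")),
         truth = truth,
         manifest = list(generator = "simCGIGenome", seed = seed,
                         length = length, backgroundGC = backgroundGC,
                         islands = islands))
  })
}

#' Simulate a 3'UTR set with planted TCS motifs
#'
#' Plants a controlled total number of motif occurrences per UTR
#' (drawn from `countsTable`) into GC-rich background sequence, with
#' a stated fraction of UTRs carrying a same-motif duplicate inside
#' one `window`-nt window. Each UTR is re-scanned after planting and
#' regenerated if background or junction sequence created unintended
#' matches, so the emitted truth table is the exact scan result.
#'
#' @param seed RNG seed.
#' @param nUTRs number of UTRs.
#' @param lengthRange min/max UTR length (nt).
#' @param countsTable named integer vector mapping per-UTR total hit
#'   count to the number of UTRs with that count, e.g.
#'   `c("2" = 80, "3" = 15, "4" = 5)`; counts must sum to `nUTRs`
#'   (use `"0"` for motif-free UTRs).
#' @param duplicateFraction fraction of UTRs that carry a same-motif
#'   within-window duplicate (requires per-UTR count >= 2).
#' @param window duplicate window (nt).
#' @param consensus degenerate consensus to plant, default
#'   [tcsConsensus()].
#' @param maxTries regeneration budget per UTR.
#' @return list with `utrs` (named character vector), `truth`
#'   (data.frame utr_id, motif (RNA letters), start),
#'   `duplicateUTRs` (character vector of duplicate-positive ids) and
#'   `manifest`.
#' @export
simUTRSet <- function(seed, nUTRs = 100L, lengthRange = c(600L, 1200L),
                      countsTable = c("2" = 80L, "3" = 15L, "4" = 5L),
                      duplicateFraction = 0.2, window = 200L,
                      consensus = tcsConsensus(), maxTries = 100L) {
  if (sum(countsTable) != nUTRs)
    stop("countsTable must sum to nUTRs", call. = FALSE)
  motifs_rna <- expandConsensus(consensus)
  motifs_dna <- chartr("U", "T", motifs_rna)
  k <- nchar(motifs_dna[1L])
  if (nUTRs == 0L)
    return(list(utrs = setNames(character(0), character(0)),
                truth = data.frame(utr_id = character(0),
                                   motif = character(0),
                                   start = integer(0)),
                duplicateUTRs = character(0),
                manifest = list(generator = "simUTRSet", seed = seed,
                                nUTRs = 0L)))
  with_seed(seed, {
    counts <- sample(rep(as.integer(names(countsTable)), countsTable))
    eligible <- which(counts >= 2L)
    nDup <- round(duplicateFraction * nUTRs)
    if (nDup > length(eligible))
      stop("duplicateFraction requires more UTRs with >= 2 motifs",
           call. = FALSE)
    dupIdx <- sort(sample(eligible, nDup))
    ids <- sprintf("utr%03d", seq_len(nUTRs))
    utrs <- character(nUTRs)
    truth <- list()
    for (u in seq_len(nUTRs)) {
      L <- lengthRange[1L] +
        sample.int(lengthRange[2L] - lengthRange[1L] + 1L, 1L) - 1L
      cnt <- counts[u]
      isDup <- u %in% dupIdx
      done <- FALSE
      for (try in seq_len(maxTries)) {
        plant <- .plan_utr_plant(L, cnt, isDup, motifs_dna, k, window)
        if (is.null(plant)) next
        bg <- .sample_bases(L, 0.6)
        for (j in seq_len(nrow(plant))) {
          at <- plant$start[j]
          bg[at:(at + k - 1L)] <-
            strsplit(plant$motif_dna[j], "", fixed = TRUE)[[1L]]
        }
        seqstr <- paste(bg, collapse = "")
        got <- scanMotifs(setNames(seqstr, ids[u]), motifs_rna)
        want <- data.frame(
          utr_id = rep(ids[u], nrow(plant)),
          motif = chartr("T", "U", plant$motif_dna),
          start = plant$start)
        want <- want[order(want$start, want$motif), ]
        if (nrow(got) == nrow(want) &&
            all(got$start == want$start) && all(got$motif == want$motif)) {
          # a non-duplicate UTR must not contain an accidental
          # within-window same-motif pair
          dups <- findWindowDuplicates(got, window)
          if ((isDup && nrow(dups) > 0L) || (!isDup && nrow(dups) == 0L)) {
            utrs[u] <- seqstr
            truth[[u]] <- want
            done <- TRUE
            break
          }
        }
      }
      if (!done)
        stop("could not pack ", cnt, " motifs into a ", L, "-nt UTR",
             call. = FALSE)
    }
    names(utrs) <- ids
    truth <- do.call(rbind, truth) %||%
      data.frame(utr_id = character(0), motif = character(0),
                 start = integer(0))
    rownames(truth) <- NULL
    list(utrs = utrs, truth = truth, duplicateUTRs = ids[dupIdx],
         manifest = list(generator = "simUTRSet", seed = seed,
                         nUTRs = nUTRs, lengthRange = lengthRange,
                         countsTable = countsTable,
                         duplicateFraction = duplicateFraction,
                         window = window, consensus = consensus))
  })
}

# Choose motif identities and non-overlapping start positions for one
# UTR; NULL when the random attempt is infeasible. Non-duplicate UTRs
# get pairwise-distinct motifs (or same-motif pairs farther apart
# than the window); duplicate UTRs get one same-motif pair within the
# window.
.plan_utr_plant <- function(L, cnt, isDup, motifs_dna, k, window) {
  if (cnt == 0L) return(data.frame(start = integer(0),
                                   motif_dna = character(0)))
  maxStart <- L - k + 1L
  if (maxStart < 1L) return(NULL)
  pick_positions <- function(n, minGap) {
    for (i in 1:20) {
      st <- sort(sample(maxStart, n))
      if (n == 1L || all(diff(st) >= minGap)) return(st)
    }
    NULL
  }
  if (isDup) {
    if (cnt < 2L) return(NULL)
    dupMotif <- sample(motifs_dna, 1L)
    first <- sample.int(max(1L, maxStart - k), 1L)
    rng <- k:min(window - k, maxStart - first)
    gap <- rng[sample.int(length(rng), 1L)]
    pair <- c(first, first + gap)
    others <- if (cnt > 2L) {
      st <- pick_positions(cnt - 2L, k)
      if (is.null(st)) return(NULL)
      st
    } else integer(0)
    st <- c(pair, others)
    if (anyDuplicated(st)) return(NULL)
    # others must not overlap the pair
    allst <- sort(st)
    if (any(diff(allst) < k)) return(NULL)
    motifs <- c(dupMotif, dupMotif,
                sample(setdiff(motifs_dna, dupMotif), cnt - 2L,
                       replace = cnt - 2L > length(motifs_dna) - 1L))
    data.frame(start = st, motif_dna = motifs)
  } else {
    st <- pick_positions(cnt, k)
    if (is.null(st)) return(NULL)
    motifs <- sample(motifs_dna, cnt, replace = cnt > length(motifs_dna))
    # same-motif picks must sit farther apart than the window
    for (m in unique(motifs[duplicated(motifs)])) {
      pos <- st[motifs == m]
      if (any(diff(sort(pos)) <= window - k)) return(NULL)
    }
    data.frame(start = st, motif_dna = motifs)
  }
}

#' Simulate bisulfite reads over a region with per-CpG beta values
#'
#' Each read covers a uniformly placed window of the region; the
#' methylation state of every covered CpG is drawn Bernoulli(beta),
#' and every unmethylated cytosine (CpG or not) converts to T with
#' probability `efficiency` (failed conversions remain C and inflate
#' apparent methylation).
#'
#' @param seed RNG seed.
#' @param region normalised DNA sequence (length-1 character).
#' @param betas per-CpG beta values: a [MethylationProfile-class] or
#'   a numeric vector named by CpG position, or a single value
#'   recycled over all CpGs of the region.
#' @param nReads number of reads.
#' @param readLength read length (<= region length).
#' @param efficiency conversion efficiency in (0.8, 1].
#' @return list with `reads` (data.frame `read_id`, `start`, `seq`),
#'   `truth` (data.frame `read_id`, `position`, `methylated`) and
#'   `manifest`.
#' @export
simBisulfiteReads <- function(seed, region, betas = 0.5, nReads = 1000L,
                              readLength = NULL, efficiency = 1.0) {
  s <- toupper(unname(region[1L]))
  L <- nchar(s)
  readLength <- as.integer(readLength %||% L)
  if (readLength > L) stop("readLength exceeds region", call. = FALSE)
  if (efficiency <= 0.8 || efficiency > 1)
    stop("conversion efficiency must lie in (0.8, 1]", call. = FALSE)
  if (methods::is(betas, "MethylationProfile")) {
    cpg <- cpgPositions(betas)
    beta <- betaValues(betas)
  } else if (!is.null(names(betas))) {
    cpg <- as.integer(names(betas))
    beta <- as.numeric(betas)
  } else {
    cpg <- cpgSites(s)
    beta <- rep_len(as.numeric(betas), length(cpg))
  }
  if (any(beta < 0 | beta > 1)) stop("betas outside [0, 1]", call. = FALSE)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  isC <- ch == "C"
  cpgSet <- logical(L)
  cpgSet[cpg] <- TRUE
  betaAt <- numeric(L)
  betaAt[cpg] <- beta
  with_seed(seed, {
    starts <- if (L == readLength) rep(1L, nReads)
              else sample(L - readLength + 1L, nReads, replace = TRUE)
    reads <- character(nReads)
    truth <- vector("list", nReads)
    for (r in seq_len(nReads)) {
      idx <- starts[r]:(starts[r] + readLength - 1L)
      rc <- ch[idx]
      cpos <- which(isC[idx])                      # within-read C indices
      gpos <- idx[cpos]                            # genomic positions
      isCpGc <- cpgSet[gpos]
      meth <- logical(length(cpos))
      if (any(isCpGc))
        meth[isCpGc] <- runif(sum(isCpGc)) < betaAt[gpos[isCpGc]]
      converts <- !meth & (runif(length(cpos)) < efficiency)
      rc[cpos[converts]] <- "T"
      reads[r] <- paste(rc, collapse = "")
      if (any(isCpGc))
        truth[[r]] <- data.frame(read_id = sprintf("read%05d", r),
                                 position = gpos[isCpGc],
                                 methylated = meth[isCpGc])
    }
    list(reads = data.frame(read_id = sprintf("read%05d", seq_len(nReads)),
                            start = starts, seq = reads),
         truth = do.call(rbind, truth) %||%
           data.frame(read_id = character(0), position = integer(0),
                      methylated = logical(0)),
         manifest = list(generator = "simBisulfiteReads", seed = seed,
                         nReads = nReads, readLength = readLength,
                         efficiency = efficiency,
                         cpg_positions = cpg, beta = beta))
  })
}

#' Simulate a right-censored survival cohort with a methylation step
#' effect
#'
#' Methylation beta values come from a bimodal Beta mixture (an
#' unmethylated low mode and a hypermethylated high mode); the hazard
#' is exponential with a step at a planted beta cutoff:
#' `h = log(2)/baselineMedianMonths * hazardRatio^[beta >= cutoff]`.
#' Censoring is independent exponential with its rate solved so the
#' expected censored fraction matches `censorFraction`.
#'
#' @param seed RNG seed.
#' @param n cohort size (>= 2).
#' @param cutoff planted beta cutoff in (0, 1).
#' @param hazardRatio hazard ratio of the high-methylation group
#'   (> 0; > 1 means higher methylation is deleterious).
#' @param baselineMedianMonths median survival of the low group.
#' @param censorFraction target fraction of censored records.
#' @param mixture list with `shape_low`, `shape_high` (each length-2
#'   Beta shapes) and `p_high` (mixing weight of the high mode).
#' @return list with `cohort` (data.frame `subject_id`, `time`,
#'   `event`, `covariate`), `truth` (adds the latent group and event
#'   time) and `manifest`.
#' @export
simSurvivalCohort <- function(seed, n = 500L, cutoff = 0.30,
                              hazardRatio = 3, baselineMedianMonths = 60,
                              censorFraction = 0.2,
                              mixture = list(shape_low = c(2, 8),
                                             shape_high = c(8, 2),
                                             p_high = 0.5)) {
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (hazardRatio <= 0) stop("hazardRatio must be > 0", call. = FALSE)
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)",
                                       call. = FALSE)
  if (mixture$p_high %in% c(0, 1)) {
    # single-mode mixture: the cutoff must still split the support
    sh <- if (mixture$p_high == 1) mixture$shape_high else mixture$shape_low
    m <- sh[1L] / sum(sh)
    if (abs(m - cutoff) > 0.4)
      stop("degenerate mixture: cutoff far outside the single mode",
           call. = FALSE)
  }
  with_seed(seed, {
    highMode <- runif(n) < mixture$p_high
    beta <- numeric(n)
    beta[!highMode] <- rbeta(sum(!highMode), mixture$shape_low[1L],
                             mixture$shape_low[2L])
    beta[highMode] <- rbeta(sum(highMode), mixture$shape_high[1L],
                            mixture$shape_high[2L])
    h0 <- log(2) / baselineMedianMonths
    highGroup <- beta >= cutoff
    rate <- h0 * hazardRatio^highGroup
    evtime <- rexp(n, rate)
    if (censorFraction > 0) {
      pHigh <- mean(highGroup)
      r1 <- h0 * hazardRatio; r0 <- h0
      f <- function(lc) pHigh * lc / (lc + r1) +
        (1 - pHigh) * lc / (lc + r0) - censorFraction
      lc <- stats::uniroot(f, c(1e-8, 1e4))$root
      ctime <- rexp(n, lc)
      event <- as.integer(evtime <= ctime)
      time <- pmin(evtime, ctime)
    } else {
      event <- rep(1L, n)
      time <- evtime
    }
    cohort <- data.frame(subject_id = sprintf("s%04d", seq_len(n)),
                         time = time, event = event, covariate = beta)
    truth <- cbind(cohort, high_group = highGroup,
                   mode_high = highMode, event_time = evtime)
    list(cohort = cohort, truth = truth,
         manifest = list(generator = "simSurvivalCohort", seed = seed,
                         n = n, cutoff = cutoff,
                         hazardRatio = hazardRatio,
                         baselineMedianMonths = baselineMedianMonths,
                         censorFraction = censorFraction,
                         mixture = mixture))
  })
}
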