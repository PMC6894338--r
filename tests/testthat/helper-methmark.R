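# Shared fixtures and independent oracles.

random_dna <- function(n, pGC = 0.5) {
  p <- c((1 - pGC) / 2, pGC / 2, pGC / 2, (1 - pGC) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Brute-force motif scanner: sliding substring comparison, written
# independently of the package's regex-based matcher.
bf_scan <- function(seq, motifs_dna) {
  s <- chartr("U", "T", toupper(seq))
  k <- nchar(motifs_dna[1L])
  n <- nchar(s)
  if (n < k) return(data.frame(motif = character(0), start = integer(0)))
  subs <- substring(s, 1:(n - k + 1L), k:n)
  out <- lapply(motifs_dna, function(m) {
    st <- which(subs == m)
    if (length(st)) data.frame(motif = m, start = st)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(motif = character(0), start = integer(0))
  else out[order(out$start, out$motif), ]
}

# Exhaustive label-permutation p-value for the two-group log-rank
# statistic (feasible for n <= 10).
perm_logrank_p <- function(time, event, group) {
  obs <- logrankTest(time, event, group)$statistic
  n <- length(time)
  nA <- sum(group == unique(group)[1L])
  combos <- utils::combn(n, nA)
  stats <- apply(combos, 2L, function(idx) {
    g <- rep("B", n)
    g[idx] <- "A"
    logrankTest(time, event, g)$statistic
  })
  mean(stats >= obs - 1e-9)
}

# The printed six-guide layout planted on a synthetic promoter:
# guide 5' bases at offsets -402, -230, -133, -3, +120, +386 from a
# TSS at position 501, each followed by an AGG PAM.
synthetic_guide_promoter <- function(seed = 42L) {
  guides <- c(g1 = "ACTTTCGCTCACTTAGCCAG", g2 = "TGGTTCCCTTACGGATCAGC",
              g3 = "GTAGGGAGAAGGACGAAGAG", g4 = "GTCGCCTATTTAGGGTGCGG",
              g5 = "CGCGGCCACCAAGGGCAAGG", g6 = "CCGCGGTACAGTGCTCGCTG")
  offsets <- c(-402L, -230L, -133L, -3L, 120L, 386L)
  tss <- 501L
  pos <- ifelse(offsets < 0L, tss + offsets, tss + offsets - 1L)
  withr::with_seed(seed, {
    ch <- strsplit(random_dna(1000, pGC = 0.3), "", fixed = TRUE)[[1L]]
    for (i in seq_along(pos)) {
      ch[pos[i]:(pos[i] + 19L)] <-
        strsplit(guides[[i]], "", fixed = TRUE)[[1L]]
      ch[(pos[i] + 20L):(pos[i] + 22L)] <- c("A", "G", "G")
    }
    list(region = paste(ch, collapse = ""), tss = tss, guides = guides,
         offsets = setNames(offsets, names(guides)))
  })
}
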