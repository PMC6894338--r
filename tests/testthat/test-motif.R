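test_that("consensus expansion follows the product rule", {
  expect_equal(expandConsensus("(A/U)UU(A/G)UCU"),
               c("AUUAUCU", "AUUGUCU", "UUUAUCU", "UUUGUCU"))
  expect_equal(expandConsensus("AUG"), "AUG")
  expect_length(expandConsensus("(A/C/G/U)U"), 4)
  expect_error(expandConsensus("(A/U"), "unbalanced")
  expect_error(expandConsensus("A)U"), "unbalanced")
  expect_error(expandConsensus("(AU/G)C"), "malformed")
})

test_that("scanning is overlap-tolerant and alphabet-invariant", {
  expect_equal(scanMotifs(c(u = "GGAUUGUCUGG"))$start, 3L)
  expect_equal(scanMotifs(c(u = "GGAUUGUCUGG"))$motif, "AUUGUCU")
  h <- scanMotifs(c(u = "UUUAUCUUUAUCU"))
  expect_equal(h$start, c(1L, 7L))
  expect_equal(h$motif, rep("UUUAUCU", 2))
  # DNA input produces identical hits, still reported in RNA letters
  hd <- scanMotifs(c(u = "TTTATCTTTATCT"))
  expect_equal(hd, h)
  # N never matches a motif position
  expect_equal(nrow(scanMotifs(c(u = "TTTNTCTTT"))), 0)
})

test_that("the WEE-style printed motif layout is recovered exactly", {
  # UTRs built synthetically with motifs planted at the printed
  # coordinates: 559/988/1043/1156 of a 1164-nt UTR and 525/592 of a
  # 951-nt UTR
  plant <- function(len, at, motifs, seed) {
    withr::with_seed(seed, {
      repeat {
        ch <- strsplit(random_dna(len, pGC = 0.6), "", fixed = TRUE)[[1]]
        for (i in seq_along(at))
          ch[at[i]:(at[i] + 6L)] <- strsplit(motifs[i], "", fixed = TRUE)[[1]]
        s <- paste(ch, collapse = "")
        got <- scanMotifs(c(x = s))
        if (nrow(got) == length(at) && all(got$start == sort(at))) return(s)
      }
    })
  }
  wee1 <- plant(1164L, c(559L, 988L, 1043L, 1156L),
                c("TTTGTCT", "TTTATCT", "ATTGTCT", "ATTGTCT"), 21)
  wee2 <- plant(951L, c(525L, 592L), c("TTTATCT", "TTTATCT"), 22)
  hits <- scanMotifs(c(WEE1 = wee1, WEE2 = wee2))
  h1 <- hits[hits$utr_id == "WEE1", ]
  expect_equal(h1$start, c(559L, 988L, 1043L, 1156L))
  expect_equal(h1$motif, c("UUUGUCU", "UUUAUCU", "AUUGUCU", "AUUGUCU"))
  h2 <- hits[hits$utr_id == "WEE2", ]
  expect_equal(h2$start, c(525L, 592L))

  # exactly one duplicate event per UTR, with the hand-computed spans
  dups <- findWindowDuplicates(hits)
  expect_equal(nrow(dups), 2)
  d1 <- dups[dups$utr_id == "WEE1", ]
  expect_equal(d1$motif, "AUUGUCU")
  expect_equal(d1$span, 1156L + 7L - 1043L)  # 120
  d2 <- dups[dups$utr_id == "WEE2", ]
  expect_equal(d2$span, 592L + 7L - 525L)    # 74
})

test_that("duplicate events need the same motif inside one window", {
  hits <- data.frame(utr_id = "u", motif = "AUUGUCU",
                     start = c(1L, 300L))
  expect_equal(nrow(findWindowDuplicates(hits)), 0)
  hits2 <- data.frame(utr_id = "u", motif = c("AUUGUCU", "UUUGUCU"),
                      start = c(10L, 20L))
  expect_equal(nrow(findWindowDuplicates(hits2)), 0)
  # containment boundary: start difference 193 is in, 194 is out
  hits3 <- data.frame(utr_id = "u", motif = "AUUGUCU",
                      start = c(1L, 194L))
  expect_equal(nrow(findWindowDuplicates(hits3)), 1)
  hits4 <- data.frame(utr_id = "u", motif = "AUUGUCU",
                      start = c(1L, 195L))
  expect_equal(nrow(findWindowDuplicates(hits4)), 0)
  # the starts semantics admits the wider pair
  expect_equal(nrow(findWindowDuplicates(hits4, semantics = "starts")), 1)
})

test_that("count summaries report exact and at-least histograms", {
  hits <- data.frame(
    utr_id = c("a", "a", "b", "b", "c", "c", "c"),
    motif = "UUUGUCU",
    start = c(1, 300, 1, 300, 1, 300, 600))
  s <- summariseMotifCounts(hits, utrIds = c("a", "b", "c", "d"))
  expect_equal(s$perUTR$n_hits, c(2L, 2L, 3L, 0L))
  expect_equal(s$histExact, data.frame(k = c(2L, 3L), n_utrs = c(2L, 1L)))
  expect_equal(s$histAtLeast, data.frame(k = c(2L, 3L), n_utrs = c(3L, 1L)))
})

test_that("scanner agrees with the brute-force comparator", {
  motifs_rna <- expandConsensus(tcsConsensus())
  motifs_dna <- chartr("U", "T", motifs_rna)
  withr::with_seed(31, {
    for (i in 1:60) {
      s <- random_dna(sample(7:2000, 1), pGC = runif(1, 0.2, 0.7))
      got <- scanMotifs(c(x = s), motifs_rna)
      want <- bf_scan(s, motifs_dna)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        expect_equal(got$start, want$start)
        expect_equal(chartr("U", "T", got$motif), want$motif)
      }
    }
  })
})

test_that("enlarging the window never loses duplicate events", {
  utr <- simUTRSet(17, nUTRs = 20L,
                   countsTable = c("2" = 14L, "3" = 4L, "4" = 2L),
                   duplicateFraction = 0.25)
  hits <- scanMotifs(utr$utrs)
  nprev <- -1L
  for (w in c(100L, 200L, 400L, 1000L)) {
    nw <- nrow(findWindowDuplicates(hits, window = w))
    expect_gte(nw, nprev)
    nprev <- nw
  }
})
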