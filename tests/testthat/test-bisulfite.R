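test_that("deterministic conversion retains only methylated CpG cytosines", {
  pm <- methylationProfile("x", 2L, 1)
  pu <- methylationProfile("x", 2L, 0)
  expect_equal(bisulfiteConvert(c(x = "ACGTCT"), pm), "ACGTTT")
  expect_equal(bisulfiteConvert(c(x = "ACGTCT"), pu), "ATGTTT")
  noC <- "AGGTTAGT"
  expect_equal(bisulfiteConvert(noC, methylationProfile("seq", integer(0))),
               noC)
  # fully unmethylated conversion leaves no C at all
  withr::with_seed(2, {
    for (i in 1:10) {
      s <- random_dna(150)
      conv <- bisulfiteConvert(s, fullProfile(s, 0))
      expect_false(grepl("C", conv, fixed = TRUE))
      convM <- bisulfiteConvert(s, fullProfile(s, 1))
      expect_equal(which(strsplit(convM, "")[[1]] == "C"), cpgSites(s))
    }
  })
  expect_error(bisulfiteConvert(c(y = "ACGT"), pm), "profile is for")
  expect_error(methylationProfile("x", 3L, 1, seq = "ACGT"), "without a CpG")
})

test_that("bottom-strand conversion mirrors the top-strand rule", {
  s <- "AACGTT"  # CpG at 3 (top); bottom C sits opposite the G
  convM <- bisulfiteConvert(s, methylationProfile("seq", 3L, 1),
                            strand = "bottom")
  convU <- bisulfiteConvert(s, methylationProfile("seq", 3L, 0),
                            strand = "bottom")
  # revComp(AACGTT) = AACGTT; methylated keeps the C at position 3
  expect_equal(convM, "AACGTT")
  expect_equal(convU, "AATGTT")
})

test_that("CoBRA site logic holds exhaustively over 4-mers and states", {
  # converted sequence contains TCGA at p iff original has [C|T]CGA
  # at p with the CpG at p+1 methylated
  bases <- c("A", "C", "G", "T")
  mers <- expand.grid(bases, bases, bases, bases,
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(mers))) {
    w <- paste0("AA", paste(mers[r, ], collapse = ""), "AA")
    cpgs <- cpgSites(w)
    states <- expand.grid(rep(list(c(0, 1)), length(cpgs)))
    for (srow in seq_len(max(1L, nrow(states)))) {
      beta <- if (length(cpgs)) as.numeric(states[srow, ]) else numeric(0)
      prof <- methylationProfile("w", cpgs, beta)
      conv <- bisulfiteConvert(w, prof)
      for (p in 1:5) {
        hasSite <- substr(conv, p, p + 3) == "TCGA"
        orig <- substr(w, p, p + 3)
        cpgMeth <- (p + 1) %in% cpgs &&
          length(beta) && beta[match(p + 1, cpgs)] >= 0.5
        expected <- grepl("^[CT]CGA$", orig) && cpgMeth
        expect_identical(hasSite, expected)
      }
    }
  }
})

test_that("bisulfite primers validate only when CpGs sit under degenerate bases", {
  asy <- syntheticCobraTemplate()
  fwd <- validateBisulfitePrimer(asy$fwd, asy$template, "forward")
  expect_true(fwd$pass)
  expect_equal(fwd$methylated$n_matches, 1L)
  expect_equal(fwd$methylated$loci, fwd$unmethylated$loci)
  rev <- validateBisulfitePrimer(asy$rev, asy$template, "reverse")
  expect_true(rev$pass)
  # a primer with a concrete non-CpG C cannot bind converted DNA
  badPrimer <- sub("Y", "C", sub("^GG", "GC", asy$fwd))
  bad <- validateBisulfitePrimer(badPrimer, asy$template, "forward")
  expect_false(bad$pass)
  expect_error(validateBisulfitePrimer("ACGTACGT", asy$template), "15")
})

test_that("in-silico PCR returns the unique inclusive-span product", {
  tpl <- paste0(strrep("A", 100), "GGTTAGGATTGGTTAGGATT",
                strrep("T", 160), "GGATTAGGTTGGATTAGGTT",
                strrep("A", 200))
  fwd <- "GGTTAGGATTGGTTAGGATT"
  rev <- revComp("GGATTAGGTTGGATTAGGTT")
  res <- inSilicoPCR(tpl, fwd, rev)
  expect_equal(res$start, 101L)
  expect_equal(res$end, 300L)
  expect_equal(res$length, 200L)
  expect_equal(nchar(res$amplicon), 200L)
  expect_error(inSilicoPCR(tpl, "CCCCCCCCCCCCCCCCCCCC", rev),
               class = "pcrNoProduct")
  tpl2 <- paste0(tpl, substr(tpl, 101, 320))
  expect_error(inSilicoPCR(tpl2, fwd, rev), class = "pcrMultipleProducts")
})

test_that("the synthetic CoBRA assay yields 186 bp with a TaqI cut at 89", {
  asy <- syntheticCobraTemplate()
  rep <- cobraReport(asy$template, asy$fwd, asy$rev)
  meth <- rep[rep$profile == "methylated", ]
  unmeth <- rep[rep$profile == "unmethylated", ]
  expect_equal(meth$amplicon_length, 186L)
  expect_equal(meth$sites, "89")
  expect_equal(meth$fragments, "89,97")
  expect_equal(unmeth$fragments, "186")
})

test_that("digest fragments always sum to the amplicon length", {
  expect_equal(cobraDigest("AATCGATT"), c(3L, 5L))
  expect_equal(cobraDigest("AAAATTTT"), 8L)
  # two planted sites -> three fragments
  amp <- paste0(strrep("A", 20), "TCGA", strrep("T", 30), "TCGA",
                strrep("G", 10))
  expect_length(cobraDigest(amp), 3)
  withr::with_seed(9, {
    for (i in 1:25) {
      s <- random_dna(sample(10:400, 1))
      frags <- cobraDigest(s)
      expect_equal(sum(frags), nchar(s))
      enz <- restrictionEnzyme("test", "GATC", sample(0:4, 1))
      expect_equal(sum(cobraDigest(s, enz)), nchar(s))
    }
  })
})

test_that("beta computation and 20% classification boundary", {
  expect_equal(methylationBeta(50, 50), 0.5)
  expect_equal(methylationBeta(0, 100), 0)
  expect_equal(classifyMethylation(0.19), "unmethylated")
  expect_equal(classifyMethylation(0.20), "methylated")
  expect_equal(classifyMethylation(0.5), "methylated")
  expect_error(methylationBeta(0, 0), "zero coverage")
  expect_error(methylationBeta(-1, 5), "non-negative")
})

test_that("read quantification recovers the simulated beta", {
  region <- paste0(strrep("GATTA", 6), "ACGTT", strrep("GATTA", 6))
  cpg <- cpgSites(region)
  sim <- simBisulfiteReads(101, region, betas = 0.7, nReads = 1000)
  q <- quantifyFromReads(sim$reads, cpg)
  expect_equal(q$coverage, 1000L)
  expect_lt(abs(q$beta - 0.7), 0.05)
  # truth agreement: estimated beta equals the drawn state frequency
  drawn <- mean(sim$truth$methylated[sim$truth$position == cpg])
  expect_equal(q$beta, drawn)
})

test_that("incomplete conversion inflates apparent methylation at beta 0", {
  region <- paste0(strrep("GATTA", 6), "ACGTT", strrep("GATTA", 6))
  cpg <- cpgSites(region)
  sim <- simBisulfiteReads(77, region, betas = 0, nReads = 4000,
                           efficiency = 0.95)
  q <- quantifyFromReads(sim$reads, cpg)
  expect_lt(abs(q$beta - 0.05), 0.02)
})

test_that("zero-coverage CpGs are flagged with absent beta", {
  reads <- data.frame(read_id = "r1", start = 1L, seq = "TTTT")
  q <- quantifyFromReads(reads, c(2L, 50L))
  expect_false(q$covered[2])
  expect_true(is.na(q$beta[2]))
})
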