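---
title: "Methods: promoter methylation biomarker analysis with methmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter methylation biomarker analysis with methmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmark)
```

# Scope and model

`methmark` implements the computational core of a promoter
hypermethylation biomarker study: detection of the CpG island over a
silenced tumour suppressor's promoter, an in-silico model of the
bisulfite/CoBRA assay used to score its methylation, quantification
of per-CpG beta values from sequencing-by-synthesis reads, scanning
of mRNA 3'UTRs for the degenerate translation control sequence (TCS)
bound by Zar-family proteins, methylation- or expression-stratified
Kaplan–Meier survival analysis, and placement of SpCas9 guides for
epigenetic editing of the promoter. Every input class has a seeded
generator with machine-readable planted truth, so the whole pipeline
is validated end to end on synthetic data.

All user-facing coordinates are 1-based inclusive. Sequences are
normalised into the T-alphabet (U is mapped to T), so RNA motifs
match DNA 3'UTRs directly; motif hits are reported back in RNA
letters. An `N` is permitted in sequence bodies: it never matches a
concrete pattern position and is excluded from composition counts.

# CpG island detection

A CpG island is defined by composition: length strictly greater than
200 bp, G+C content strictly above 50%, and observed/expected CpG
ratio strictly above 0.6, where

$$\mathrm{O/E} = \frac{\#\mathrm{CpG} \cdot L}{\#C \cdot \#G}$$

over the interval (the Gardiner-Garden & Frommer statistic), with
`L` the non-N length and N breaking dinucleotide counting. The
criteria say nothing about an algorithm, so `findCGIs()` uses the
classical criteria-first procedure: 200-bp windows slid at 1-bp
steps, windows that pass both composition thresholds merged when
they overlap or touch, the merged interval re-evaluated as a whole,
and up to one window trimmed from each flank if the merged interval
fails before the candidate is dropped. Strict inequalities are used
throughout, as in the definition.

Two properties of this procedure matter for interpretation:

* every reported island, re-evaluated over its full extent, passes
  all three thresholds (this is asserted by tests); and
* reported boundaries systematically overshoot a compositional core.
  A window only fails once less than roughly half of it overlaps a
  68%-GC core embedded in 35%-GC background (solve
  $68f + 35(1-f) > 50$ for the island fraction $f$: windows with
  $f > 0.45$ still pass), so each flank extends up to ~110 bp into
  background. Recovery of planted islands is therefore scored as
  coverage of the planted core (`cgiRecovery(..., metric =
  "coverage")`, expected 1.0), while the stricter reciprocal-overlap
  metric, which divides by the longer interval, is also reported and
  plateaus near 0.75 for a 600-bp core — a property of the windowed
  definition, not an implementation defect.

# Bisulfite conversion and CoBRA

Bisulfite treatment converts unmethylated cytosine to uracil (read
as T) and leaves 5-methylcytosine intact. The deterministic
converter `bisulfiteConvert()` applies exactly this rule given a
`MethylationProfile` (ordered CpG positions with beta values; beta
≥ 0.5 is treated as methylated by the deterministic converter).
Bottom-strand products are obtained by reverse complementing first;
profile positions stay in top-strand coordinates.

Combined bisulfite restriction analysis (CoBRA) scores methylation
through restriction sites whose presence after conversion depends on
CpG methylation. For TaqI (`TCGA`, cut after the T), a converted
amplicon contains `TCGA` at a position exactly when the original
sequence has `[C|T]CGA` there with that CpG methylated. This site
logic is tested exhaustively over all 256 4-mers and all methylation
states of their CpGs.

The surrounding assay steps are modelled faithfully:

* `validateBisulfitePrimer()` checks that a degenerate primer (Y over
  top-strand CpGs, R on the reverse primer) has exactly one perfect
  match at the same locus on both the fully methylated and fully
  unmethylated converted template — the design rule for primers that
  must bind only fully converted DNA regardless of methylation.
* `inSilicoPCR()` requires a unique product; zero or multiple
  pairings are distinct error conditions because CoBRA interpretation
  assumes a single amplicon.
* `cobraDigest()` cuts after `cutOffset` bases of each recognition
  site; fragment lengths always sum to the amplicon length.

`syntheticCobraTemplate()` builds, entirely in code, a synthetic
350-bp template on which the degenerate primer pair
`GGAGAAGGAYGAAGAGGGGTTTTT` / `TCCCCCAAAACCRCCATAAAC` amplifies a
186-bp product with a single methylation-dependent TaqI site
starting at amplicon position 89. The "site at 89" convention is
read so that the cut falls after base 89, making the 89-bp fragment
directly observable on a gel: a methylated template digests into
89 + 97 bp, an unmethylated one stays uncut at 186 bp. The
alternative reading (cut at 88/98) differs by 1 bp and is noted here
because gel resolution cannot distinguish the two conventions.

Quantification follows the pyrosequencing readout: per CpG,
$\beta = \#C / (\#C + \#T)$ over covering reads, with zero-coverage
CpGs flagged rather than imputed. Classification against the
methylation threshold uses $\beta \ge 0.20$ (the 20% threshold that
separates methylated tumour samples from unmethylated controls);
the boundary itself counts as methylated.

The read simulator draws each covered CpG's state
Bernoulli($\beta$) and converts every unmethylated cytosine with
probability equal to the conversion efficiency; failed conversions
remain C. At efficiency $e$ and true beta $\beta$ the expected
estimate is $\beta + (1-\beta)(1-e)$, which the tests verify at
$\beta = 0$, $e = 0.95$ (apparent beta ≈ 0.05). Efficiency is
restricted to (0.8, 1] — lower values are outside the regime of a
usable bisulfite experiment. Incomplete conversion lives only in the
read simulator; the deterministic converter is exact.

# TCS motif scanning

The TCS consensus `(A/U)UU(A/G)UCU` expands to four 7-mers
(`AUUAUCU`, `AUUGUCU`, `UUUAUCU`, `UUUGUCU`). Scanning is
overlap-tolerant exact matching of each expansion, equivalent to a
brute-force sliding comparison (tested on 1 000 random sequences).
Per-UTR totals sum hits over all four expansions; because a "UTRs
with k motifs" tally is ambiguous between exactly-k and at-least-k,
`summariseMotifCounts()` reports both.

A *duplicate* is the same concrete 7-mer twice in one UTR within a
200-nt sliding window. The default containment semantics requires
both occurrences to fit inside one window (start difference ≤
window − 7 = 193 nt); the alternative starts-within-window reading
(difference ≤ 200) is available via `semantics = "starts"`. The two
agree on the reference WEE-style layouts (same motif at 1043/1156 of
a 1164-nt UTR, span 120; at 525/592 of a 951-nt UTR, span 74), which
the tests reproduce on synthetic UTRs with motifs planted at those
printed coordinates. Genome-wide duplicate counts depend on the
3'UTR annotation version and are deliberately out of scope.

# Survival analysis

`kmEstimate()` is the product-limit estimator written from first
principles: at each distinct observed time,
$S(t) = \prod_{t_i \le t} (1 - d_i / n_i)$, with events preceding
censorings at tied times (so a subject censored at $t$ is still at
risk at $t$). Greenwood standard errors are reported but no
confidence bands are drawn. Without censoring the estimator equals
the empirical survivor function exactly; with censoring it matches
`survival::survfit` to machine precision (the `survival` package is
used only as an independent cross-check in the tests, never as the
implementation).

`logrankTest()` accumulates observed and expected events over shared
event times with the hypergeometric variance and refers
$(O-E)^2/V$ to $\chi^2_1$. A seeded label-permutation p-value is
available; on small fixtures it is checked against exhaustive
enumeration of all label assignments. One numerical caveat is
documented deliberately: at $n \le 10$ the exact permutation
distribution is discrete (granularity $1/\binom{8}{4} = 1/70$ for
a balanced 8-subject fixture), so the continuous $\chi^2$ tail can
differ from the exact permutation p by up to ~0.08 in the middle of
the distribution. In the significance regime (p below ~0.05) the
two agree within 0.02, and the permutation machinery itself agrees
with enumeration to Monte-Carlo accuracy; both facts are asserted by
the tests.

Biomarker dichotomisation supports the two strategies used by
survival web tools: `splitByMean()` (threshold = arithmetic mean;
low < mean ≤ high) and `bestCutoffScan()`, which evaluates every
observed covariate value within the 10–90% quantile range and
returns the threshold minimising the log-rank p. That minimum p is
reported **unadjusted**, with the number of thresholds tested, and
the object's `show()` method prints an explicit selection warning —
on null cohorts the minimum unadjusted p is below 0.05 far more
often than 5%, a bias the tests demonstrate rather than hide.
Methylation thresholds are additionally shown as percentages
(0.175 → "17.5%") to match the field's phrasing.

# CRISPR guide placement

`locateGuides()` exact-matches 20-nt protospacers on both strands,
extracts the adjacent 3-nt PAM on the protospacer strand and tests
it against NGG (SpCas9 only; no NAG tolerance). Offsets are the
signed promoter-coordinate position of the guide's 5'-most base
relative to the TSS with no zero: the TSS base is +1, the base
immediately upstream −1. The anchoring of printed offsets (5' end
vs 3' end vs cut site) is not standardised across papers; the 5'
convention was chosen because it makes the offset independent of
guide length, and tests plant the six printed guide sequences at
their printed offsets (−402, −230, −133, −3, +120, +386) on a
synthetic promoter and recover them exactly. Unplaced guides are
reported as such, never dropped silently.

# Synthetic data generators

Each generator is a pure function of (seed, parameters); re-running
with the same seed reproduces inputs and truth manifests
bit-for-bit, and the RNG state of the session is restored
afterwards. The defaults are the study conditions the rest of the
package is validated under:

* `simCGIGenome()`: i.i.d. AT-rich background (GC 35%, typical of
  bulk genomic DNA) with island segments drawn from a first-order
  Markov chain whose $P(G \mid C)$ is scaled to hit a target O/E;
  rejection sampling enforces the target G+C within ±2 points and
  O/E within ±0.1. The default planted island (600 bp, 68% G+C,
  O/E 0.98) mirrors the composition of the CpG island the package
  is built around.
* `simUTRSet()`: GC-rich UTR background (60% — deliberately biased
  against the U/T-rich TCS words so accidental matches are rare),
  planted per-UTR totals drawn from a table defaulting to the
  80/15/5% shape over counts 2/3/4, and a 20% duplicate fraction.
  After planting, each UTR is re-scanned and regenerated until the
  scan equals the plan exactly, so truth tables are exact by
  construction, not by expectation.
* `simBisulfiteReads()`: uniform read placement, Bernoulli CpG
  states, per-C conversion failure as described above.
* `simSurvivalCohort()`: beta values from a bimodal
  Beta(2,8)/Beta(8,2) mixture (unmethylated controls vs
  hypermethylated tumours), exponential survival with a 60-month
  baseline median — chosen so the five-year horizon sits at the
  distribution's centre, where $S(60)$ recovery is most sensitive —
  and a step hazard $h = h_0 \cdot \mathrm{HR}^{[\beta \ge c]}$ at
  the planted cutoff. Censoring is independent exponential with its
  rate solved (closed form through the competing-exponentials
  identity $P(C<T) = \lambda_c/(\lambda_c+\lambda_T)$, averaged over
  groups) so the expected censored fraction matches the request;
  uniform censoring cannot be calibrated to an arbitrary fraction
  without the same kind of tuning, and dependent schemes (censoring
  at a fraction of the event time) would bias the Kaplan–Meier
  estimate.

What the generators do *not* emulate: 450k probe chemistry and batch
effects, annotation-specific 3'UTR universes, non-exponential
hazards, and clinical covariate structure. Passing the planted-truth
suites therefore demonstrates the correctness of the algorithms
under their stated models, not concordance with any patient cohort;
the headline clinical quantities of a real study (five-year survival
percentages, cohort-specific thresholds) require the original
patient data and are out of scope by design.

# Problem sizes and numerical choices

The validation suites run at desk scale, chosen to make sampling
error negligible relative to the asserted tolerances: 1 000 random
sequences for the scanner-equivalence property, 1 000 and 10 000
reads for quantification (binomial error bounds 0.05 and 0.02),
cohorts of 500 for cutoff recovery (±0.05), 2 000 for the $S(60)$
closed-form check (±0.03), 200 replicates for the null-calibration
KS test at α = 0.01. Ties in the best-cutoff scan resolve to the
smallest threshold; log-rank variance terms with $n_i = 1$
contribute zero; beta values at exactly the classification threshold
count as methylated; degenerate inputs (all-censored cohorts,
constant covariates, N-only intervals, empty FASTA) raise typed
errors rather than propagating NaN.

# A worked demo

```{r demo, eval = FALSE}
res <- demoRun(seed = 1, outdir = tempfile("demo"))
res$recovery
```

`demoRun()` chains generator → analysis → report for every stage and
writes `islands.bed`/`islands.tsv`, `hits.tsv`, `duplicates.tsv`,
`cobra_report.tsv`, `pyro.tsv`, `km.tsv`, the resolved configuration
and a recovery summary; rerunning with the same seed reproduces the
analysis outputs byte-for-byte. The same stages are available from a
shell through `inst/scripts/methmark` (subcommands `cgi`, `tcs`,
`cobra`, `survival`, `guides`, `simulate`, `demo`).
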