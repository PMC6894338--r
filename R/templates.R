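#' Synthetic CoBRA assay template
#'
#' Builds, fully in code, a synthetic 350-bp genomic template that
#' reproduces the printed layout of the CoBRA assay this package
#' models: the degenerate bisulfite primer pair
#' `GGAGAAGGAYGAAGAGGGGTTTTT` / `TCCCCCAAAACCRCCATAAAC` amplifies a
#' 186-bp product whose single TaqI site (TCGA) starts at amplicon
#' position 89 and depends on the methylation state of its CpG: a
#' methylated template digests into 89 + 97 bp fragments, an
#' unmethylated one stays uncut at 186 bp. The template is synthetic —
#' flanks and spacers are C-free filler so the assay's three CpGs
#' (one under each primer's degenerate base, one in the TaqI site)
#' are the only CpGs present.
#'
#' @return list with `template` (named character sequence), `fwd`,
#'   `rev` (primer strings), `ampliconStart`, `ampliconLength`,
#'   `taqiSiteInAmplicon`.
#' @export
syntheticCobraTemplate <- function() {
  filler <- function(n) {
    base <- strrep("GATTAGGTTAGGATTGATTG", ceiling(n / 20))
    substr(base, 1L, n)
  }
  fwd_site <- "GGAGAAGGACGAAGAGGGGTTTTT"  # CpG under the primer's Y
  rev_site <- "GTTTATGGCGGTTTTGGGGGA"     # revcomp of the rev primer, CpG under Y
  tpl <- paste0(filler(100), fwd_site, filler(64), "TCGA", filler(73),
                rev_site, filler(64))
  stopifnot(nchar(tpl) == 350L)
  list(template = c(synthetic_cobra_template = tpl),
       fwd = "GGAGAAGGAYGAAGAGGGGTTTTT",
       rev = "TCCCCCAAAACCRCCATAAAC",
       ampliconStart = 101L,
       ampliconLength = 186L,
       taqiSiteInAmplicon = 89L)
}
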