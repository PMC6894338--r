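#' MethylationProfile: per-CpG methylation states of one sequence
#'
#' Ordered 1-based positions of the C of each CpG together with a
#' methylation level (beta value) in `[0, 1]` per position; binary
#' methylated/unmethylated states are represented as beta 1/0.
#'
#' @slot seqId sequence identifier.
#' @slot positions strictly increasing integer positions.
#' @slot beta numeric in `[0, 1]`, one value per position.
#' @exportClass MethylationProfile
setClass("MethylationProfile",
  representation(seqId = "character", positions = "integer",
                 beta = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@seqId) != 1L || !nzchar(object@seqId))
      msg <- c(msg, "seqId must be a single non-empty string")
    if (length(object@positions) != length(object@beta))
      msg <- c(msg, "positions and beta must have equal length")
    if (length(object@positions) && any(diff(object@positions) <= 0L))
      msg <- c(msg, "positions must be strictly increasing")
    if (length(object@beta) &&
        (anyNA(object@beta) || any(object@beta < 0 | object@beta > 1)))
      msg <- c(msg, "beta values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Construct a MethylationProfile, validated against its sequence
#'
#' When `seq` is supplied, every position must carry a CpG (C at the
#' position, G immediately after).
#'
#' @param seqId sequence identifier.
#' @param positions 1-based positions of CpG cytosines.
#' @param beta methylation level per position in `[0, 1]`; recycled if
#'   scalar. Logical input is coerced (TRUE = 1).
#' @param seq optional normalised DNA sequence to validate against.
#' @return a [MethylationProfile-class] object.
#' @examples
#' methylationProfile("p", c(2L, 7L), 1)
#' @export
methylationProfile <- function(seqId, positions, beta = 1, seq = NULL) {
  positions <- as.integer(positions)
  beta <- rep_len(as.numeric(beta), length(positions))
  if (!is.null(seq) && length(positions)) {
    seq <- toupper(unname(seq[1L]))
    ok <- substring(seq, positions, positions) == "C" &
      substring(seq, positions + 1L, positions + 1L) == "G"
    if (any(!ok))
      stop("positions without a CpG in '", seqId, "': ",
           paste(positions[!ok], collapse = ", "), call. = FALSE)
  }
  new("MethylationProfile", seqId = as.character(seqId),
      positions = positions, beta = beta)
}

#' Profile covering every CpG of a sequence at a constant beta
#'
#' @param seq named or unnamed normalised DNA sequence (length 1).
#' @param beta constant methylation level; 1 = fully methylated,
#'   0 = fully unmethylated.
#' @param seqId identifier; defaults to the sequence name or `"seq"`.
#' @return a [MethylationProfile-class] covering all CpGs.
#' @export
fullProfile <- function(seq, beta = 1, seqId = NULL) {
  seqId <- seqId %||% (if (!is.null(names(seq))) names(seq)[1L] else "seq")
  methylationProfile(seqId, cpgSites(seq[1L]), beta, seq = seq)
}

#' @describeIn MethylationProfile-class positions accessor
#' @param object,x a `MethylationProfile`.
#' @export
setGeneric("cpgPositions", function(x) standardGeneric("cpgPositions"))

#' @rdname MethylationProfile-class
#' @export
setMethod("cpgPositions", "MethylationProfile", function(x) x@positions)

#' @describeIn MethylationProfile-class beta-value accessor
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname MethylationProfile-class
#' @export
setMethod("betaValues", "MethylationProfile", function(x) x@beta)

setMethod("show", "MethylationProfile", function(object) {
  cat("MethylationProfile for '", object@seqId, "': ",
      length(object@positions), " CpGs, mean beta ",
      if (length(object@beta)) round(mean(object@beta), 3) else NA,
      "\n", sep = "")
})

#' RestrictionEnzyme: recognition site and cut offset
#'
#' `cutOffset` counts bases of the recognition site after which the
#' top strand is cut: TaqI (T^CGA) has recognition `TCGA` and offset 1.
#'
#' @slot name enzyme name.
#' @slot recognition concrete DNA recognition sequence.
#' @slot cutOffset integer in `[0, nchar(recognition)]`.
#' @exportClass RestrictionEnzyme
setClass("RestrictionEnzyme",
  representation(name = "character", recognition = "character",
                 cutOffset = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!grepl("^[ACGT]+$", object@recognition))
      msg <- c(msg, "recognition must be a concrete DNA string")
    if (object@cutOffset < 0L ||
        object@cutOffset > nchar(object@recognition))
      msg <- c(msg, "cutOffset must lie in [0, nchar(recognition)]")
    if (length(msg)) msg else TRUE
  })

#' @rdname RestrictionEnzyme-class
#' @param name,recognition,cutOffset see slots.
#' @export
restrictionEnzyme <- function(name, recognition, cutOffset) {
  new("RestrictionEnzyme", name = as.character(name),
      recognition = toupper(recognition), cutOffset = as.integer(cutOffset))
}

#' @rdname RestrictionEnzyme-class
#' @format `TaqI` is the enzyme used for CoBRA scoring here: T^CGA.
#' @export
TaqI <- restrictionEnzyme("TaqI", "TCGA", 1L)

setMethod("show", "RestrictionEnzyme", function(object) {
  r <- object@recognition
  cat("RestrictionEnzyme ", object@name, ": ",
      substr(r, 1, object@cutOffset), "^",
      substr(r, object@cutOffset + 1L, nchar(r)), "\n", sep = "")
})

#' KaplanMeier: product-limit survival estimate
#'
#' Step-function estimate with at-risk/event/censor tallies at each
#' distinct observed time, plus Greenwood standard errors.
#'
#' @slot time distinct observed times, increasing.
#' @slot nRisk number at risk just before each time.
#' @slot nEvent events at each time.
#' @slot nCensor censorings at each time.
#' @slot surv survival estimate S(t) after each time.
#' @slot se Greenwood standard error of S(t).
#' @slot n total number of subjects.
#' @exportClass KaplanMeier
setClass("KaplanMeier",
  representation(time = "numeric", nRisk = "integer", nEvent = "integer",
                 nCensor = "integer", surv = "numeric", se = "numeric",
                 n = "integer"),
  validity = function(object) {
    msg <- character(0)
    k <- length(object@time)
    if (any(lengths(list(object@nRisk, object@nEvent, object@nCensor,
                         object@surv, object@se)) != k))
      msg <- c(msg, "all per-time slots must share one length")
    if (k && any(diff(object@time) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (k && any(diff(object@surv) > 1e-12))
      msg <- c(msg, "survival must be non-increasing")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "KaplanMeier", function(object) {
  cat("KaplanMeier estimate: n = ", object@n, ", ",
      sum(object@nEvent), " events over ", length(object@time),
      " distinct times\n", sep = "")
  if (length(object@time)) {
    last <- length(object@time)
    cat("  S(", object@time[last], ") = ",
        signif(object@surv[last], 4), "\n", sep = "")
  }
})

#' @describeIn KaplanMeier-class tidy per-time table
#' @param x a `KaplanMeier`.
#' @export
setGeneric("kmTable", function(x) standardGeneric("kmTable"))

#' @rdname KaplanMeier-class
#' @export
setMethod("kmTable", "KaplanMeier", function(x)
  data.frame(time = x@time, n_risk = x@nRisk, n_event = x@nEvent,
             n_censor = x@nCensor, surv = x@surv, se = x@se))

#' SurvivalCutoff: biomarker dichotomisation result
#'
#' @slot threshold covariate value splitting low (< threshold) from
#'   high (>= threshold).
#' @slot method `"mean_split"` or `"best_cutoff"`.
#' @slot nLow,nHigh group sizes.
#' @slot statistic log-rank chi-square (1 df).
#' @slot p unadjusted log-rank p-value.
#' @slot nTested number of candidate thresholds evaluated (1 for the
#'   mean split).
#' @exportClass SurvivalCutoff
setClass("SurvivalCutoff",
  representation(threshold = "numeric", method = "character",
                 nLow = "integer", nHigh = "integer",
                 statistic = "numeric", p = "numeric",
                 nTested = "integer"),
  validity = function(object) {
    if (object@nLow < 1L || object@nHigh < 1L)
      "both groups must be non-empty" else TRUE
  })

setMethod("show", "SurvivalCutoff", function(object) {
  cat("SurvivalCutoff (", object@method, "): threshold = ",
      signif(object@threshold, 4), " (", round(100 * object@threshold, 1),
      "% if a beta value)\n  groups ", object@nLow, " low / ",
      object@nHigh, " high; log-rank chi-square = ",
      signif(object@statistic, 4), ", unadjusted p = ",
      signif(object@p, 3), "\n", sep = "")
  if (object@nTested > 1L)
    cat("  NOTE: minimum over ", object@nTested,
        " candidate thresholds; p is NOT adjusted for this selection\n",
        sep = "")
})

#' @describeIn SurvivalCutoff-class threshold accessor
#' @param x a `SurvivalCutoff`.
#' @export
setGeneric("cutoffThreshold", function(x) standardGeneric("cutoffThreshold"))

#' @rdname SurvivalCutoff-class
#' @export
setMethod("cutoffThreshold", "SurvivalCutoff", function(x) x@threshold)

#' @describeIn SurvivalCutoff-class unadjusted log-rank p accessor
#' @export
setGeneric("cutoffP", function(x) standardGeneric("cutoffP"))

#' @rdname SurvivalCutoff-class
#' @export
setMethod("cutoffP", "SurvivalCutoff", function(x) x@p)
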