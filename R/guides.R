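#' Locate CRISPR guide protospacers relative to a TSS
#'
#' Exact-match search for 20-nt protospacers on both strands of a
#' promoter region, extraction of the adjacent 3-nt PAM on the
#' protospacer strand, SpCas9 NGG validation, and signed offsets of
#' each guide's 5'-most base relative to the transcription start
#' site. Offsets use promoter-style counting with no zero: the TSS
#' base is +1 and the base immediately upstream is -1.
#'
#' @param region promoter sequence (normalised DNA, length-1
#'   character, named or not).
#' @param tss 1-based position of the TSS within `region`.
#' @param guides named character vector of 20-mers (plain ACGT).
#' @return data.frame with one row per placement (or one `NA` row per
#'   unplaced guide): `guide_id`, `protospacer`, `strand`, `position`
#'   (1-based position of the guide's 5' base in region coordinates),
#'   `offset`, `pam`, `pam_valid`, `placed`.
#' @examples
#' region <- paste0(strrep("A", 50), "GATTACAGATTACAGATTAC", "AGG",
#'                  strrep("A", 50))
#' locateGuides(region, tss = 120, c(g1 = "GATTACAGATTACAGATTAC"))
#' @export
locateGuides <- function(region, tss, guides) {
  s <- toupper(unname(region[1L]))
  n <- nchar(s)
  if (n < 23L) stop("region shorter than 23 nt", call. = FALSE)
  if (tss < 1L || tss > n) stop("TSS outside region", call. = FALSE)
  if (is.null(names(guides)))
    names(guides) <- paste0("guide", seq_along(guides))
  guides <- toupper(guides)
  bad <- !grepl("^[ACGT]{20}$", guides)
  if (any(bad))
    stop("guides must be 20-mers over ACGT: ",
         paste(names(guides)[bad], collapse = ", "), call. = FALSE)
  offset_of <- function(pos) ifelse(pos >= tss, pos - tss + 1L, pos - tss)
  rows <- lapply(names(guides), function(id) {
    g <- guides[[id]]
    plus <- iupacFindAll(g, s)
    minus <- iupacFindAll(revComp(g), s)
    out <- list()
    for (st in plus) {
      # + strand: protospacer 5' base at st, PAM immediately 3'
      pam <- if (st + 22L <= n) substr(s, st + 20L, st + 22L) else NA_character_
      out[[length(out) + 1L]] <- data.frame(
        guide_id = id, protospacer = g, strand = "+",
        position = st, offset = offset_of(st),
        pam = pam,
        pam_valid = !is.na(pam) && grepl("^.GG$", pam),
        placed = TRUE)
    }
    for (st in minus) {
      # - strand: guide's 5' base maps to region position st + 19;
      # the PAM lies 3' of the protospacer on the minus strand, i.e.
      # region positions st-3..st-1, read reverse-complemented
      pos5 <- st + 19L
      pam <- if (st - 3L >= 1L) revComp(substr(s, st - 3L, st - 1L))
             else NA_character_
      out[[length(out) + 1L]] <- data.frame(
        guide_id = id, protospacer = g, strand = "-",
        position = pos5, offset = offset_of(pos5),
        pam = pam,
        pam_valid = !is.na(pam) && grepl("^.GG$", pam),
        placed = TRUE)
    }
    if (length(out) == 0L)
      out[[1L]] <- data.frame(
        guide_id = id, protospacer = g, strand = NA_character_,
        position = NA_integer_, offset = NA_integer_,
        pam = NA_character_, pam_valid = NA, placed = FALSE)
    do.call(rbind, out)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
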