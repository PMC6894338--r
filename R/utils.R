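# Internal helpers shared across modules.

# IUPAC degeneracy sets, T-alphabet. N is fully degenerate in a
# pattern; an N in the *subject* never satisfies a concrete pattern
# position (handled by the regex construction below, which never puts
# N inside a character class unless the pattern position is N).
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so generators are pure functions of (seed, params).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Translate a degenerate IUPAC pattern into a concrete regex.
iupac_regex <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(.IUPAC))
  if (length(bad))
    stop("non-IUPAC character '", chars[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  paste(vapply(chars, function(ch) {
    set <- .IUPAC[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

# All (overlap-tolerant) 1-based start positions of a degenerate
# pattern in a concrete subject. Both in the unified T-alphabet.
iupacFindAll <- function(pattern, subject) {
  rx <- paste0("(?=", iupac_regex(pattern), ")")
  m <- gregexpr(rx, subject, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# Reverse complement of a possibly degenerate pattern (character in,
# character out); concrete sequences go through revComp().
iupacRevComp <- function(pattern) {
  chars <- rev(strsplit(pattern, "", fixed = TRUE)[[1L]])
  comp <- .IUPAC_COMPLEMENT[chars]
  if (anyNA(comp)) stop("non-IUPAC character in pattern", call. = FALSE)
  paste(comp, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
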