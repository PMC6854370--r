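# Internal helpers: sequence primitives, IUPAC matching, seeded evaluation.
# All genomic coordinates in this package are 0-based half-open unless a
# writer states otherwise (human-readable TSV reports are 1-based inclusive).

BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Allowed-base lookup for one IUPAC pattern character. "N" additionally
# matches an ambiguous N in the subject; other codes expand per IUPAC.
.iupac_allowed <- function(ch) {
  ch <- toupper(ch)
  map <- Biostrings::IUPAC_CODE_MAP
  if (!ch %in% names(map)) {
    stop("invalid IUPAC code in pattern: '", ch, "'", call. = FALSE)
  }
  allowed <- strsplit(map[[ch]], "")[[1]]
  if (ch == "N") allowed <- c(allowed, "N")
  allowed
}

# Does `seq_chars` (character vector, one base each) match the IUPAC
# `pattern` (single string)? Lengths must agree.
.iupac_match <- function(seq_chars, pattern) {
  pat <- strsplit(toupper(pattern), "")[[1]]
  stopifnot(length(seq_chars) == length(pat))
  all(vapply(seq_along(pat),
             function(i) seq_chars[i] %in% .iupac_allowed(pat[i]),
             logical(1)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. All stochastic operations in
# the package funnel through this so a single integer seed fixes output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Split a string into single characters.
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Assert a scalar probability.
.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a probability in [0,1]", call. = FALSE)
  }
  invisible(x)
}

# Intersection test for closed integer intervals [a1,a2] and [b1,b2].
.intervals_touch <- function(a1, a2, b1, b2) a1 <= b2 && b1 <= a2
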