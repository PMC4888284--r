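#' @keywords internal
"_PACKAGE"

# DNA alphabet used throughout; N is the only degenerate base accepted.
BASES <- c("A", "C", "G", "T")

regsig_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "regsig_error")))
}

regsig_warn <- function(msg, class = "regsig_warning") {
  warning(warningCondition(msg, class = c(class, "regsig_warning")))
}

#' Reverse complement of a DNA string
#'
#' Complements A/C/G/T (and N to N) and reverses. Used for minus-strand
#' coordinate handling in scanning, terminator detection and site extraction.
#'
#' @param x A character scalar over `{A,C,G,T,N}` (case-insensitive).
#' @return The reverse complement, upper-cased.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTNacgtn", "TGCANTGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Fast per-character reverse complement for character vectors of single bases.
revcomp_chars <- function(chars) {
  rev(chartr("ACGTN", "TGCAN", chars))
}

# Encode a DNA string as integers 1..4 (A,C,G,T); N (or any other IUPAC
# code) becomes 5.
encode_dna <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  idx <- match(chars, BASES)
  idx[is.na(idx)] <- 5L
  idx
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Validate a DNA string, allowing only A,C,G,T,N after upper-casing.
check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", toupper(x))
  if (any(bad)) {
    regsig_error(
      sprintf("%s contains characters outside {A,C,G,T,N}", what),
      "regsig_content_error"
    )
  }
  invisible(toupper(x))
}
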