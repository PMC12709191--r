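# Internal helpers shared across modules. Coordinates are 0-based, half-open
# internally; every user-facing table reports 1-based inclusive positions.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors (alphabet
#' A, C, G, T, N).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GTGTGGGTGTG")
revcomp <- function(x) {
  stopifnot(is.character(x))
  rev1 <- function(s) {
    if (!nzchar(s)) return(s)
    intToUtf8(rev(utf8ToInt(s)))
  }
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(x, rev1, character(1), USE.NAMES = FALSE))
}

# Evaluate expr with a temporary RNG state seeded from `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Random DNA of length n from the current RNG stream.
rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Positions (1-based, within the comparison window) at which two equal-length
# strings differ. Raw comparison keeps this O(n) in C.
mismatch_positions <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  which(ra != rb)
}

hamming <- function(a, b) length(mismatch_positions(a, b))

# substr() wrapper for 0-based half-open coordinates.
substr0 <- function(x, start0, end0) substr(x, start0 + 1L, end0)

stop2 <- function(...) stop(..., call. = FALSE)
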