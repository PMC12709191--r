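# Recognition of yeast telomeric repeat sequence. The G-rich strand of a
# budding-yeast telomere is an irregular TG1-3 repeat: runs of G no longer
# than 3 separated by single Ts. The complementary C-rich strand is the
# C1-3A analogue. A string is "consistent" with the pattern when it uses
# only the two letters of the strand family and contains no run violation
# (no TT / no GGGG on the G strand; no AA / no CCCC on the C strand). Both
# families are closed under reversal and complementation, which gives the
# exact strand symmetry is_telomeric(s) == match_G  <=>
# is_telomeric(revcomp(s)) == match_C.

# For each position i, length of the longest pattern-consistent substring
# ending at i. `good` is the 2-letter family, `single` the letter limited to
# runs of 1, `triple` the letter limited to runs of 3.
.telomeric_dp <- function(chars, single, triple) {
  n <- length(chars)
  L <- integer(n)
  run <- 0L   # current run length of `triple`
  for (i in seq_len(n)) {
    c <- chars[i]
    if (c == triple) {
      run <- run + 1L
      L[i] <- if (run > 3L) 3L else if (i > 1L) L[i - 1L] + 1L else 1L
      if (run > 3L) L[i] <- 3L
    } else if (c == single) {
      run <- 0L
      if (i > 1L && chars[i - 1L] == single) L[i] <- 1L
      else L[i] <- if (i > 1L) L[i - 1L] + 1L else 1L
    } else {
      run <- 0L
      L[i] <- 0L
    }
  }
  L
}

# Longest pattern-consistent run anywhere, and the pattern-consistent prefix
# length, for one strand family.
.telomeric_scan <- function(seq, strand = c("G", "C")) {
  strand <- match.arg(strand)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- if (strand == "G") .telomeric_dp(chars, "T", "G")
       else .telomeric_dp(chars, "A", "C")
  if (length(L) == 0L) return(c(run = 0L, prefix = 0L))
  pref <- which(L == seq_along(L))
  c(run = max(L), prefix = if (length(pref)) max(pref) else 0L)
}

#' Telomeric-repeat recognition
#'
#' Tests whether a sequence looks like yeast telomeric repeat on either
#' strand: `match_G_strand` for TG1-3 (runs of up to three Gs separated by
#' single Ts), `match_C_strand` for the C1-3A complement. The longest
#' pattern-consistent run must reach both `min_len` and `min_fraction` of
#' the comparison window `min(nchar(seq), 30)`; when both strands match, the
#' longer run wins (ties go to the G strand).
#'
#' @param seq DNA string (non-empty).
#' @param min_len Minimum length of the telomeric run (default 8 nt).
#' @param min_fraction Minimum fraction of the comparison window covered by
#'   the run (default 0.9).
#' @return One of `"match_G_strand"`, `"match_C_strand"`, `"no_match"`.
#' @export
#' @examples
#' is_telomeric("GTGTGGGTGTG")  # Tel11, a minimal Cdc13 binding site
#' is_telomeric("ACACCCACAC")
is_telomeric <- function(seq, min_len = 8L, min_fraction = 0.9) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  w <- min(nchar(seq), 30L)
  need <- max(min_len, min_fraction * w)
  g <- .telomeric_scan(seq, "G")
  c <- .telomeric_scan(seq, "C")
  g_ok <- g[["run"]] >= need - 1e-9
  c_ok <- c[["run"]] >= need - 1e-9
  if (g_ok && (!c_ok || g[["run"]] >= c[["run"]])) return("match_G_strand")
  if (c_ok) return("match_C_strand")
  "no_match"
}

# Length of the telomeric prefix (either strand family) of a junction-
# oriented clip; used to split tract-then-target clips (Class C candidates).
telomeric_prefix_len <- function(seq, min_len = 8L) {
  g <- .telomeric_scan(seq, "G")[["prefix"]]
  c <- .telomeric_scan(seq, "C")[["prefix"]]
  p <- max(g, c)
  if (p >= min_len) p else 0L
}

#' Synthesise an irregular TG1-3 telomeric tract
#'
#' Concatenates repeat units `T G^k` with `k` drawn uniformly from
#' `{1, 2, 3}` and truncates to the requested length (so the expected G
#' fraction is 2/3). The result is accepted by [is_telomeric()] on the
#' G strand.
#'
#' @param length Tract length in nt (>= 1).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return DNA string of the requested length.
#' @export
make_tg_tract <- function(length, seed = NULL) {
  stopifnot(length >= 1L)
  gen <- function() {
    n_units <- ceiling(length / 2)  # each unit is 2-4 nt
    ks <- sample(1:3, n_units, replace = TRUE)
    units <- vapply(ks, function(k) paste0("T", strrep("G", k)), character(1))
    substr(paste(units, collapse = ""), 1L, length)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
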