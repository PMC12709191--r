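# Sliding-window telomere-likeness scan: percentage of T+G nucleotides and
# the G/T ratio along the strand running 3'-5' (for a left arm, the reverse
# complement of the reference top strand). Used to nominate SiRTA-like
# sequences; elevated G/T ratio against the local background is the signal.

#' Sliding-window T+G composition
#'
#' Exact character counts over windows tiling the supplied strand. The
#' caller supplies the 3'-5' (TG-rich) strand; use [revcomp()] on the
#' reference top strand for a left arm.
#'
#' @param seq DNA string (the strand to scan).
#' @param window Window size in nt (default 50: resolves SiRTA-scale
#'   features while smoothing base-level noise).
#' @param step Step size in nt (default 10).
#' @return Data frame of `TGWindow`s: `start`, `end` (1-based inclusive on
#'   the scanned strand), `tg_percent`, `gt_ratio` (`Inf` sentinel when the
#'   window has no T).
#' @export
tg_windows <- function(seq, window = 50L, step = 10L) {
  n <- nchar(seq)
  if (window > n) stop2("window (", window, ") exceeds sequence length (", n, ")")
  stopifnot(step >= 1L)
  r <- charToRaw(toupper(seq))
  isG <- cumsum(c(0L, r == charToRaw("G")))
  isT <- cumsum(c(0L, r == charToRaw("T")))
  starts <- seq(1L, n - window + 1L, by = step)
  g <- isG[starts + window] - isG[starts]
  t <- isT[starts + window] - isT[starts]
  data.frame(start = starts, end = starts + window - 1L,
             tg_percent = 100 * (g + t) / window,
             gt_ratio = ifelse(t == 0L, Inf, g / t))
}

#' Rank telomere-like intervals from a window scan
#'
#' Windows passing both thresholds are merged when they overlap (or abut)
#' and the merged intervals are ranked by peak G/T ratio (the `Inf`
#' sentinel ranks highest), then peak T+G percentage, with deterministic
#' leftmost tie-break.
#'
#' @param windows Data frame from [tg_windows()] (one contiguous scan).
#' @param min_tg_percent Minimum `tg_percent` (default 75).
#' @param min_gt_ratio Minimum `gt_ratio` (default 1).
#' @return Ranked data frame: `start`, `end`, `peak_gt_ratio`,
#'   `peak_tg_percent`, `n_windows`, `rank`.
#' @export
rank_tg_peaks <- function(windows, min_tg_percent = 75, min_gt_ratio = 1) {
  hit <- windows[windows$tg_percent >= min_tg_percent &
                 windows$gt_ratio >= min_gt_ratio, , drop = FALSE]
  if (!nrow(hit)) {
    return(data.frame(start = integer(), end = integer(),
                      peak_gt_ratio = numeric(), peak_tg_percent = numeric(),
                      n_windows = integer(), rank = integer()))
  }
  hit <- hit[order(hit$start), , drop = FALSE]
  grp <- cumsum(c(1L, hit$start[-1L] > cummax(hit$end[-nrow(hit)]) + 1L))
  merged <- do.call(rbind, lapply(split(hit, grp), function(h) {
    data.frame(start = min(h$start), end = max(h$end),
               peak_gt_ratio = max(h$gt_ratio),
               peak_tg_percent = max(h$tg_percent), n_windows = nrow(h))
  }))
  ord <- order(-merged$peak_gt_ratio, -merged$peak_tg_percent, merged$start)
  merged <- merged[ord, , drop = FALSE]
  merged$rank <- seq_len(nrow(merged))
  rownames(merged) <- NULL
  merged
}
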