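# Independent oracles. Deliberately different code paths from the package
# implementation: a per-character state machine for the telomeric
# recognizer, a Biostrings Hamming scan for clip placement, and an
# exhaustive offset/length enumeration for microhomology.

# --- telomeric recognizer oracle -------------------------------------------
# Longest run of the two-letter family with bounded run lengths, tracked
# with an explicit state machine (single letter limited to runs of 1, other
# letter to runs of 3).
oracle_telomeric_run <- function(seq, family = c("G", "C")) {
  family <- match.arg(family)
  one <- if (family == "G") "T" else "A"
  three <- if (family == "G") "G" else "C"
  chars <- strsplit(seq, "")[[1]]
  best <- 0L; cur <- 0L; run3 <- 0L; prev <- ""
  for (c in chars) {
    if (c == three) {
      run3 <- if (prev == three) run3 + 1L else 1L
      cur <- if (run3 > 3L) 3L else cur + 1L
    } else if (c == one) {
      run3 <- 0L
      cur <- if (prev == one) 1L else cur + 1L
    } else {
      run3 <- 0L; cur <- 0L
    }
    prev <- c
    if (cur > best) best <- cur
  }
  best
}

oracle_is_telomeric <- function(seq, min_len = 8L, min_fraction = 0.9) {
  w <- min(nchar(seq), 30L)
  need <- max(min_len, min_fraction * w)
  g <- oracle_telomeric_run(seq, "G")
  c <- oracle_telomeric_run(seq, "C")
  g_ok <- g >= need - 1e-9
  c_ok <- c >= need - 1e-9
  if (g_ok && (!c_ok || g >= c)) "match_G_strand"
  else if (c_ok) "match_C_strand"
  else "no_match"
}

# --- clip placement oracle --------------------------------------------------
# Brute-force sliding-window Hamming comparison over both strands using
# Biostrings::neditStartingAt.
oracle_hits <- function(clip_seq, genome, max_mismatch) {
  len <- nchar(clip_seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") clip_seq else revcomp(clip_seq)
    pat <- Biostrings::DNAString(s)
    for (chrom in names(genome$sequences)) {
      subj <- Biostrings::DNAString(genome$sequences[[chrom]])
      n <- length(subj)
      if (n < len) next
      d <- Biostrings::neditStartingAt(pat, subj,
                                       starting.at = seq_len(n - len + 1L),
                                       with.indels = FALSE)
      hit <- which(d <= max_mismatch)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = hit - 1L, strand = strand,
          mismatches = as.integer(d[hit]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$mismatches, out$chrom, out$start, out$strand), ,
      drop = FALSE]
}

norm_hits <- function(d) {
  d <- d[order(d$mismatches, d$chrom, d$start, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# --- microhomology oracle ---------------------------------------------------
# Exhaustive scan over every (start_a, start_b, length) window, scored
# match +1 / mismatch -1; ties resolved by span, then offsets (same total
# order as the implementation claims).
oracle_microhomology <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- list(score = -Inf, span = 0L, off_a = 0L, off_b = 0L)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      K <- min(na - i, nb - j) + 1L
      sc <- cumsum(ifelse(ca[i:(i + K - 1L)] == cb[j:(j + K - 1L)], 1L, -1L))
      for (L in seq_len(K)) {
        s <- sc[L]
        better <- s > best$score ||
          (s == best$score && (L > best$span ||
            (L == best$span && (i < best$off_a ||
              (i == best$off_a && j < best$off_b)))))
        if (better) best <- list(score = s, span = L, off_a = i, off_b = j)
      }
    }
  }
  best$identity <- (best$span + best$score) / (2 * best$span)
  best
}
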