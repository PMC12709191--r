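# Reference sequences, feature annotations and repair-region geometry.
# All downstream modules receive coordinates through these types; nothing
# else re-derives region boundaries.

FEATURE_KINDS <- c(
  "HO_cut_site", "URA3_marker", "SiRTA", "SiRTA_stim", "SiRTA_core",
  "X_element", "Yprime_element", "ITS", "essential_gene", "telomere"
)

#' Construct a Genome object
#'
#' A `Genome` is a named set of uppercase DNA sequences (alphabet A, C, G, T,
#' N). It stands in for a reference assembly; sequence names are chromosome
#' names.
#'
#' @param sequences Named character vector (or list) of DNA sequences.
#' @return An object of class `Genome`.
#' @export
genome <- function(sequences) {
  nm0 <- names(sequences)
  sequences <- vapply(sequences, as.character, character(1),
                      USE.NAMES = FALSE)
  names(sequences) <- nm0
  if (length(sequences) == 0L) stop2("a Genome needs at least one sequence")
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) stop2("all sequences must be named")
  if (anyDuplicated(nm)) stop2("duplicate chromosome names: ",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L)) stop2("empty sequence for: ",
                                         paste(nm[nchar(sequences) == 0L], collapse = ", "))
  bad <- vapply(sequences, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    stop2("sequence(s) contain characters outside A/C/G/T/N: ",
          paste(nm[bad], collapse = ", "))
  }
  structure(list(sequences = sequences), class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome with", length(x$sequences), "sequence(s):\n")
  for (nm in names(x$sequences)) {
    cat(sprintf("  %s  %s nt\n", nm, format(nchar(x$sequences[[nm]]), big.mark = ",")))
  }
  invisible(x)
}

#' Load a reference genome from FASTA
#'
#' Reads a (multi-record) FASTA file and returns a [genome()] with uppercased
#' sequences. Records containing characters outside A/C/G/T/N are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A `Genome`.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  # enforce the closed A/C/G/T/N alphabet up front (readDNAStringSet would
  # silently drop unknown letters), naming the offending record
  raw <- readLines(path, warn = FALSE)
  rec <- "<no record>"
  for (ln in raw) {
    if (startsWith(ln, ">")) rec <- sub("^>\\s*", "", ln)
    else if (grepl("[^ACGTNacgtn]", ln)) {
      stop2("record '", rec, "' in ", path,
            " contains characters outside the A/C/G/T/N alphabet")
    }
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop2("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0L) stop2("empty FASTA file: ", path)
  seqs <- as.character(set)
  # first whitespace-delimited token of the header is the chromosome name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome(seqs)
}

#' Write a Genome to FASTA
#'
#' @param genome A `Genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(genome, path) {
  stopifnot(inherits(genome, "Genome"))
  set <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

genome_seq <- function(genome, chrom) {
  s <- genome$sequences[[chrom]]
  if (is.null(s)) stop2("chromosome not in genome: ", chrom)
  s
}

genome_length <- function(genome, chrom) nchar(genome_seq(genome, chrom))

# Extract genome[chrom, start0:end0) on the top strand.
genome_slice <- function(genome, chrom, start0, end0) {
  len <- genome_length(genome, chrom)
  if (start0 < 0 || end0 > len || start0 >= end0) {
    stop2(sprintf("slice [%d,%d) out of bounds for %s (length %d)",
                  start0, end0, chrom, len))
  }
  substr0(genome_seq(genome, chrom), start0, end0)
}

#' Construct an annotation set
#'
#' An `AnnotationSet` is a validated data frame of genomic features with
#' columns `chrom`, `start`, `end` (0-based, half-open), `kind`, `strand`
#' and `label`. `kind` is drawn from the closed set of assay landmarks:
#' `r paste(FEATURE_KINDS, collapse = ", ")`.
#'
#' @param df Data frame with at least chrom/start/end/kind.
#' @param genome Optional `Genome` used for bounds checking.
#' @return An `AnnotationSet` (data frame subclass).
#' @export
annotation_set <- function(df = NULL, genome = NULL) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     kind = character(), strand = character(), label = character(),
                     stringsAsFactors = FALSE)
  }
  if (is.null(df$strand)) df$strand <- "+"
  if (is.null(df$label)) df$label <- ""
  df <- df[, c("chrom", "start", "end", "kind", "strand", "label")]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (nrow(df)) {
    bad_kind <- !df$kind %in% FEATURE_KINDS
    if (any(bad_kind)) {
      stop2("unknown feature kind(s) ", paste(unique(df$kind[bad_kind]), collapse = ", "),
            "; valid kinds: ", paste(FEATURE_KINDS, collapse = ", "))
    }
    if (any(!df$strand %in% c("+", "-"))) stop2("strand must be '+' or '-'")
    bad <- which(df$start < 0L | df$end <= df$start)
    if (length(bad)) stop2("invalid coordinates (need 0 <= start < end) at row(s) ",
                           paste(bad, collapse = ", "))
    if (!is.null(genome)) {
      for (i in seq_len(nrow(df))) {
        len <- genome_length(genome, df$chrom[i])
        if (df$end[i] > len) {
          stop2(sprintf("row %d: feature [%d,%d) exceeds length of %s (%d)",
                        i, df$start[i], df$end[i], df$chrom[i], len))
        }
      }
    }
  }
  class(df) <- c("AnnotationSet", "data.frame")
  df
}

#' Load feature annotations from a BED-like file
#'
#' Expects 4-6 tab-separated columns: chrom, start, end, kind and optionally
#' strand and label. Coordinates are 0-based, half-open (BED convention).
#'
#' @param path Path to the annotation file.
#' @param genome Optional `Genome` for bounds checking.
#' @return An `AnnotationSet`.
#' @export
load_annotations <- function(path, genome = NULL) {
  if (!file.exists(path)) stop2("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(annotation_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 4L)) {
    stop2("annotation row(s) with fewer than 4 columns: line ",
          paste(which(n < 4L), collapse = ", "))
  }
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
    kind = vapply(parts, `[`, "", 4L),
    strand = vapply(parts, function(p) if (length(p) >= 5L) p[5L] else "+", ""),
    label = vapply(parts, function(p) if (length(p) >= 6L) p[6L] else "", ""),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$start) || anyNA(df$end)) {
    stop2("non-numeric coordinates at line ",
          paste(which(is.na(df$start) | is.na(df$end)), collapse = ", "))
  }
  tryCatch(annotation_set(df, genome), error = function(e) {
    stop2("in ", path, ": ", conditionMessage(e))
  })
}

#' Write an annotation set to a BED-like file
#'
#' Inverse of [load_annotations()]; writing then re-loading reproduces the
#' set exactly.
#'
#' @param annotations An `AnnotationSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- as.data.frame(annotations)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   df$chrom, df$start, df$end, df$kind, df$strand, df$label)
  writeLines(lines, path)
  invisible(path)
}

features_of_kind <- function(annotations, kind, chrom = NULL) {
  df <- annotations[annotations$kind %in% kind, , drop = FALSE]
  if (!is.null(chrom)) df <- df[df$chrom == chrom, , drop = FALSE]
  df
}

#' Construct a repair region
#'
#' The repair region is the interval on the broken chromosome between the
#' integrated HO cut site and the most distal essential gene; every viable
#' GCR breakpoint falls inside it. `orientation = "left"` means the telomere
#' lies at low coordinates (a left chromosome arm, the default for the
#' assayed SiRTAs); `"right"` flips the geometry.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open boundaries.
#' @param orientation `"left"` or `"right"`.
#' @return A `RepairRegion`.
#' @export
repair_region <- function(chrom, start, end, orientation = c("left", "right")) {
  orientation <- match.arg(orientation)
  start <- as.integer(start); end <- as.integer(end)
  if (start >= end) stop2("repair region needs start < end")
  structure(list(chrom = chrom, start = start, end = end,
                 orientation = orientation),
            class = "RepairRegion")
}

#' @export
print.RepairRegion <- function(x, ...) {
  cat(sprintf("RepairRegion %s:%s-%s (%s nt, %s arm; reported 1-based %s-%s)\n",
              x$chrom, x$start, x$end, format(x$end - x$start, big.mark = ","),
              x$orientation, x$start + 1L, x$end))
  invisible(x)
}

#' Derive the repair region from annotations
#'
#' The region spans from the telomere-proximal boundary of the (single)
#' `HO_cut_site` feature to the far boundary of the most distal
#' `essential_gene` on the chromosome: for a left arm,
#' `[HO_cut_site.start, essential_gene.end)`.
#'
#' @param annotations An `AnnotationSet`.
#' @param chrom Chromosome to use.
#' @param orientation `"left"` (telomere at low coordinates, default) or
#'   `"right"`.
#' @return A `RepairRegion`.
#' @export
repair_region_span <- function(annotations, chrom,
                               orientation = c("left", "right")) {
  orientation <- match.arg(orientation)
  ho <- features_of_kind(annotations, "HO_cut_site", chrom)
  if (nrow(ho) == 0L) stop2("no HO_cut_site feature on ", chrom)
  if (nrow(ho) > 1L) stop2("expected exactly one HO_cut_site on ", chrom,
                           ", found ", nrow(ho))
  ess <- features_of_kind(annotations, "essential_gene", chrom)
  if (nrow(ess) == 0L) stop2("no essential_gene feature on ", chrom)
  if (orientation == "left") {
    # most distal essential gene = closest to the telomere = smallest start
    gene <- ess[which.min(ess$start), ]
    repair_region(chrom, ho$start, gene$end, orientation)
  } else {
    gene <- ess[which.max(ess$end), ]
    repair_region(chrom, gene$start, ho$end, orientation)
  }
}

region_length <- function(region) region$end - region$start

#' Fraction of a repair region occupied by a feature
#'
#' Returns `100 * overlap / region length`, the quantity the assay uses to
#' compare a feature's physical share of the repair region with its share of
#' split reads.
#'
#' @param feature One-row `AnnotationSet` (or list with chrom/start/end).
#' @param region A `RepairRegion`.
#' @return Percentage in (0, 100].
#' @export
region_fraction <- function(feature, region) {
  stopifnot(inherits(region, "RepairRegion"))
  if (is.data.frame(feature)) {
    stopifnot(nrow(feature) == 1L)
    feature <- as.list(feature)
  }
  if (!identical(feature$chrom, region$chrom)) {
    stop2("feature is on ", feature$chrom, ", region on ", region$chrom)
  }
  ov <- min(feature$end, region$end) - max(feature$start, region$start)
  if (ov <= 0L) stop2("feature does not overlap the repair region")
  100 * ov / region_length(region)
}

# Does 0-based interval [s,e) overlap any feature of the given kinds?
overlaps_kind <- function(annotations, chrom, s, e, kinds) {
  df <- features_of_kind(annotations, kinds, chrom)
  any(df$start < e & df$end > s)
}
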