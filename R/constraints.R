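## Sequence design constraints and their scanners.
##
## Hard constraints applied during domestication: forbidden motifs on either
## strand (type IIS recognition sites by default), no repeated k-mer of a
## minimum length, no long inverted repeat (hairpin stem) within a local
## window, and optionally a minimum GC fraction over a sliding window.

#' Design constraint bundle
#'
#' @param avoid_patterns Motifs forbidden on both strands. Default: BsaI
#'   (GGTCTC), BsmBI (CGTCTC) and BbsI (GAAGAC) recognition sites.
#' @param unique_kmer_k No k-mer of this length may occur twice (default 12).
#' @param hairpin_stem_min Minimum inverted-repeat stem length that counts
#'   as a hairpin (default 20).
#' @param hairpin_window Both hairpin arms must fall within a span of this
#'   many bp for the hairpin to count (default 250).
#' @param gc_min Minimum GC fraction per sliding window, or `NULL` to
#'   disable.
#' @param gc_window Sliding-window width for the GC constraint (default 60).
#' @param gc_boost Weight of the GC objective relative to codon usage
#'   during optimization (default 4).
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(avoid_patterns = c("GGTCTC", "CGTCTC", "GAAGAC"),
                               unique_kmer_k = 12L,
                               hairpin_stem_min = 20L,
                               hairpin_window = 250L,
                               gc_min = NULL,
                               gc_window = 60L,
                               gc_boost = 4) {
  stopifnot(unique_kmer_k >= 8L, hairpin_window > hairpin_stem_min)
  if (!is.null(gc_min)) stopifnot(gc_min > 0, gc_min < 1)
  structure(list(avoid_patterns = toupper(avoid_patterns),
                 unique_kmer_k = as.integer(unique_kmer_k),
                 hairpin_stem_min = as.integer(hairpin_stem_min),
                 hairpin_window = as.integer(hairpin_window),
                 gc_min = gc_min, gc_window = as.integer(gc_window),
                 gc_boost = gc_boost),
            class = "design_constraints")
}

## All occurrences of any pattern (or its reverse complement) in `seq`.
## Returns data.frame(start, end, pattern) with 1-based inclusive spans.
find_pattern_hits <- function(seq, patterns) {
  pats <- unique(c(patterns, revcomp(patterns)))
  out <- lapply(pats, function(p) {
    st <- find_fixed(seq, p)
    if (!length(st)) return(NULL)
    data.frame(start = st, end = st + nchar(p) - 1L, pattern = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      pattern = character(0), stringsAsFactors = FALSE)
  }
  out[order(out$start), , drop = FALSE]
}

## Duplicated k-mers: for each k-mer occurring more than once, the span of
## its *second* occurrence (the one a repair should edit).
find_duplicate_kmers <- function(seq, k) {
  km <- seq_kmers(seq, k)
  dup_idx <- which(duplicated(km))
  if (!length(dup_idx)) {
    return(data.frame(start = integer(0), end = integer(0),
                      kmer = character(0), stringsAsFactors = FALSE))
  }
  ## collapse runs of overlapping duplicated k-mers into one span each
  runs <- split(dup_idx, cumsum(c(1L, diff(dup_idx) != 1L)))
  do.call(rbind, lapply(runs, function(r) {
    data.frame(start = r[1], end = r[length(r)] + k - 1L, kmer = km[r[1]],
               stringsAsFactors = FALSE)
  }))
}

## Inverted repeats (hairpin stems): positions i < j such that the
## `stem`-mer at i is the reverse complement of the `stem`-mer at j, arms
## non-overlapping, and the whole span fits inside `window` bp. A stem of
## length >= stem implies a stem of exactly `stem`, so scanning one length
## suffices. Returns data.frame(start, end) spans of the downstream arm.
find_hairpins <- function(seq, stem, window) {
  n <- nchar(seq)
  if (n < 2L * stem) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  km <- seq_kmers(seq, stem)
  rcseq <- revcomp(seq)
  ## rc of the k-mer starting at i is the k-mer of rcseq starting n-i-stem+2
  kmrc <- substring(rcseq, n - seq_along(km) - stem + 2L,
                    n - seq_along(km) + 1L)
  pos_by_kmer <- split(seq_along(km), km)
  hits <- list()
  cand <- which(km %in% kmrc)
  for (i in cand) {
    js <- pos_by_kmer[[kmrc[i]]]
    js <- js[js >= i + stem & (js + stem - 1L) - i + 1L <= window]
    if (length(js)) {
      j <- js[1]
      hits[[length(hits) + 1L]] <- data.frame(start = j, end = j + stem - 1L)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(0), end = integer(0)))
  unique(do.call(rbind, hits))
}

## GC windows below gc_min: data.frame(start, end, gc) per violating
## maximal run of windows.
find_low_gc_windows <- function(seq, gc_min, window) {
  prof <- window_gc(seq, window)
  bad <- which(prof < gc_min - 1e-9)
  if (!length(bad)) {
    return(data.frame(start = integer(0), end = integer(0), gc = numeric(0)))
  }
  runs <- split(bad, cumsum(c(1L, diff(bad) != 1L)))
  do.call(rbind, lapply(runs, function(r) {
    data.frame(start = r[1], end = min(r[length(r)] + window - 1L, nchar(seq)),
               gc = min(prof[r]))
  }))
}

## All constraint violations of `seq` (excluding GC unless gc_min set).
## Returns data.frame(start, end, type, detail).
find_violations <- function(seq, constraints, include_gc = TRUE) {
  v <- list()
  ph <- find_pattern_hits(seq, constraints$avoid_patterns)
  if (nrow(ph)) {
    v$pattern <- data.frame(start = ph$start, end = ph$end, type = "pattern",
                            detail = ph$pattern, stringsAsFactors = FALSE)
  }
  dk <- find_duplicate_kmers(seq, constraints$unique_kmer_k)
  if (nrow(dk)) {
    v$kmer <- data.frame(start = dk$start, end = dk$end, type = "kmer",
                         detail = dk$kmer, stringsAsFactors = FALSE)
  }
  hp <- find_hairpins(seq, constraints$hairpin_stem_min,
                      constraints$hairpin_window)
  if (nrow(hp)) {
    v$hairpin <- data.frame(start = hp$start, end = hp$end, type = "hairpin",
                            detail = "inverted repeat",
                            stringsAsFactors = FALSE)
  }
  if (include_gc && !is.null(constraints$gc_min)) {
    lg <- find_low_gc_windows(seq, constraints$gc_min, constraints$gc_window)
    if (nrow(lg)) {
      v$gc <- data.frame(start = lg$start, end = lg$end, type = "gc",
                         detail = sprintf("GC %.3f", lg$gc),
                         stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, v)
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      type = character(0), detail = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}
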