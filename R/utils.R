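#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T, case preserved on
#'   complementation).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Fraction of G+C bases
#'
#' @param x Character vector of DNA sequences.
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  ifelse(n == 0L, NA_real_, gc / n)
}

## Run `code` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Derive a stream-specific child seed from a user seed, kept within the
## 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483647L)
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters: %s",
                 what, substr(x[bad][1], 1, 30)), call. = FALSE)
  }
  invisible(x)
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3", call. = FALSE)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence
#'
#' Standard genetic code; `*` marks stop codons.
#'
#' @param cds DNA string with length divisible by 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  assert_dna(toupper(cds), "CDS")
  paste(Biostrings::GENETIC_CODE[split_codons(toupper(cds))], collapse = "")
}

## All k-mers of a sequence as a character vector (1-based start positions).
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

## Sliding-window GC profile: GC fraction of every `window`-length window.
window_gc <- function(seq, window) {
  n <- nchar(seq)
  if (n < window) return(gc_content(seq))
  isgc <- as.integer(strsplit(chartr("ACGT", "0110", seq), "",
                              fixed = TRUE)[[1]])
  cs <- c(0L, cumsum(isgc))
  (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}
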