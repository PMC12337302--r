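## Seeded synthetic-data generators.
##
## These make every stage of the design pipeline testable without external
## data: random stop-free coding sequences of specified length and GC,
## Watson-Crick-dominant ligation matrices with a tunable mismatch rate, and
## (in amplicon.R) nanopore-like reads. All generators are deterministic
## given their seed.

#' Random domesticated coding sequence
#'
#' Generates a CDS that starts with ATG, ends with a stop codon, contains no
#' internal stops, is free of BsaI/BsmBI/BbsI recognition sites on either
#' strand, and has global GC within +/- 2% of the request.
#'
#' @param length_nt Total length in nucleotides (divisible by 3, >= 9).
#' @param gc Target GC fraction (default 0.5).
#' @param seed Integer seed (mandatory).
#' @return A DNA string.
#' @export
random_cds <- function(length_nt, gc = 0.5, seed) {
  stopifnot(length_nt %% 3L == 0L, length_nt >= 9L)
  if (gc < 0.1 || gc > 0.9) {
    stop("requested GC outside the attainable range for a stop-free CDS",
         call. = FALSE)
  }
  sites <- unlist(lapply(TYPE_IIS_ENZYMES, `[[`, "site"))
  forbidden <- unique(c(sites, revcomp(sites)))
  stops <- c("TAA", "TAG", "TGA")
  with_seed(seed, {
    for (attempt in 1:200) {
      n_inner <- length_nt / 3L - 2L
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      bases <- sample(DNA_BASES, n_inner * 3L, replace = TRUE,
                      prob = p[DNA_BASES])
      codons <- apply(matrix(bases, nrow = 3L), 2, paste, collapse = "")
      ## resample internal stop codons
      while (any(codons %in% stops)) {
        i <- which(codons %in% stops)
        codons[i] <- vapply(i, function(j) {
          paste(sample(DNA_BASES, 3L, replace = TRUE, prob = p[DNA_BASES]),
                collapse = "")
        }, character(1))
      }
      stop_codon <- if (gc >= 0.5) "TGA" else "TAA"
      seq <- paste0("ATG", paste(codons, collapse = ""), stop_codon)
      seq <- purge_fixture_sites(seq, forbidden, p)
      if (is.null(seq)) next
      if (abs(gc_content(seq) - gc) <= 0.02) return(seq)
    }
    stop(sprintf("could not attain GC %.2f at length %d", gc, length_nt),
         call. = FALSE)
  })
}

## Resample codons overlapping forbidden sites until none remain (or give
## up). Internal to the generator; protein identity is NOT preserved here --
## this builds new random sequence, not edits of a real gene.
purge_fixture_sites <- function(seq, forbidden, p) {
  stops <- c("TAA", "TAG", "TGA")
  for (round in 1:50) {
    hits <- find_pattern_hits(seq, forbidden)
    if (!nrow(hits)) return(seq)
    pos <- hits$start[1]
    codon_idx <- ((pos - 1L) %/% 3L) + 1L
    n_codons <- nchar(seq) / 3L
    if (codon_idx <= 1L || codon_idx >= n_codons) {
      ## site overlaps the start or stop codon: shuffle the neighbor instead
      codon_idx <- max(2L, min(n_codons - 1L, codon_idx))
    }
    repeat {
      new_codon <- paste(sample(DNA_BASES, 3L, replace = TRUE,
                                prob = p[DNA_BASES]), collapse = "")
      if (!new_codon %in% stops) break
    }
    substr(seq, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L) <- new_codon
  }
  NULL
}

#' Synthetic Watson-Crick-dominant ligation matrix
#'
#' Every overhang ligates its reverse complement `correct_count` times;
#' off-target mass totalling `mismatch_rate * correct_count` per row (in
#' expectation) is spread over partners at Hamming distance 1 from the true
#' partner, mimicking the single-mismatch-dominated structure of measured
#' ligation error. The result is symmetrized.
#'
#' @param correct_count Counts on each Watson-Crick cell (default 1000).
#' @param mismatch_rate Expected off-target mass per row relative to
#'   `correct_count`, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A symmetrized `overhang_matrix`.
#' @export
synthetic_ligation_matrix <- function(correct_count = 1000,
                                      mismatch_rate = 0.02, seed = 1) {
  stopifnot(mismatch_rate >= 0, mismatch_rate < 1)
  kmers <- all_overhangs()
  n <- length(kmers)
  m <- matrix(0, n, n, dimnames = list(kmers, kmers))
  m[cbind(kmers, revcomp(kmers))] <- correct_count
  if (mismatch_rate > 0) {
    with_seed(seed, {
      for (o in kmers) {
        partners <- hamming1_neighbors(revcomp(o))
        lam <- mismatch_rate * correct_count / length(partners)
        m[o, partners] <- m[o, partners] + stats::rpois(length(partners), lam)
      }
    })
  }
  symmetrize_matrix(new_overhang_matrix(
    m, symmetrized = FALSE,
    source_label = sprintf("synthetic (correct=%g, mismatch=%g, seed=%d)",
                           correct_count, mismatch_rate, seed)))
}

hamming1_neighbors <- function(kmer) {
  out <- character(0)
  for (i in 1:4) {
    for (b in setdiff(DNA_BASES, substr(kmer, i, i))) {
      x <- kmer
      substr(x, i, i) <- b
      out <- c(out, x)
    }
  }
  out
}
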