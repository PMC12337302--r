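## Codon usage tables.
##
## A codon table maps each codon to its amino acid and its relative usage
## frequency among synonyms (per-amino-acid frequencies sum to 1). Tables
## can be read from TSV (codon, amino acid, frequency -- the layout used by
## public codon-usage databases) or built from per-codon weights. The
## package ships no organism's measured table; `flat_codon_table()` gives a
## neutral default and `wobble_codon_table()` a tunable synthetic profile
## with a third-position A/T (or G/C) bias, emulating the shape of plant
## nuclear codon usage for testing.

#' Construct a codon usage table
#'
#' @param freqs Named numeric vector: codon -> relative frequency. All 64
#'   codons must be present; frequencies are renormalized per amino acid.
#' @param source_label Free-text provenance.
#' @return A `codon_table`: data.frame with columns `codon`, `aa`, `freq`.
#' @export
codon_table <- function(freqs, source_label = "custom") {
  code <- Biostrings::GENETIC_CODE
  missing <- setdiff(names(code), names(freqs))
  if (length(missing)) {
    stop(sprintf("codon table missing codon %s", missing[1]), call. = FALSE)
  }
  df <- data.frame(codon = names(code), aa = unname(code),
                   freq = unname(freqs[names(code)]),
                   stringsAsFactors = FALSE)
  if (any(df$freq < 0) || anyNA(df$freq)) {
    stop("codon frequencies must be non-negative numbers", call. = FALSE)
  }
  for (a in unique(df$aa)) {
    i <- df$aa == a
    tot <- sum(df$freq[i])
    if (tot <= 0) stop(sprintf("amino acid %s has zero total frequency", a),
                       call. = FALSE)
    df$freq[i] <- df$freq[i] / tot
  }
  structure(df, source_label = source_label,
            class = c("codon_table", "data.frame"))
}

#' Read a codon table from TSV
#'
#' Expects columns `codon`, `aa`, `freq` (header required; extra columns
#' ignored).
#' @param path TSV path.
#' @param source_label Provenance label (defaults to the file name).
#' @return A `codon_table`.
#' @export
read_codon_table <- function(path, source_label = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "freq") %in% names(df)))
  codon_table(stats::setNames(df$freq, toupper(df$codon)), source_label)
}

#' Flat codon table (equal use of all synonyms)
#' @return A `codon_table`.
#' @export
flat_codon_table <- function() {
  code <- Biostrings::GENETIC_CODE
  codon_table(stats::setNames(rep(1, length(code)), names(code)),
              source_label = "flat (uniform synonym usage)")
}

#' Synthetic wobble-biased codon table
#'
#' Weights each codon by its third-position base: `at_weight` for A/T,
#' 1 for G/C. `at_weight > 1` yields an A/T-ending preference of the kind
#' seen in many plant nuclear genomes; `< 1` a GC-rich profile. This is a
#' synthetic stand-in for a measured organism table, intended for tests and
#' examples.
#'
#' @param at_weight Relative weight of A/T-ending codons (default 2).
#' @return A `codon_table`.
#' @export
wobble_codon_table <- function(at_weight = 2) {
  code <- Biostrings::GENETIC_CODE
  third <- substr(names(code), 3, 3)
  w <- ifelse(third %in% c("A", "T"), at_weight, 1)
  codon_table(stats::setNames(w, names(code)),
              source_label = sprintf("synthetic wobble-biased (AT x%g)",
                                     at_weight))
}

#' Random codon table (for property tests)
#' @param seed Integer seed.
#' @return A `codon_table` with seeded random synonym frequencies.
#' @export
random_codon_table <- function(seed) {
  code <- Biostrings::GENETIC_CODE
  with_seed(seed, {
    codon_table(stats::setNames(stats::runif(length(code), 0.05, 1),
                                names(code)),
                source_label = sprintf("random (seed=%d)", seed))
  })
}

synonyms_of <- function(table, codon) {
  table$codon[table$aa == table$aa[table$codon == codon]]
}

codon_freq <- function(table) stats::setNames(table$freq, table$codon)
codon_aa <- function(table) stats::setNames(table$aa, table$codon)

## Relative adaptiveness w(codon) = freq / max freq among synonyms.
codon_w <- function(table) {
  w <- numeric(nrow(table))
  for (a in unique(table$aa)) {
    i <- table$aa == a
    w[i] <- table$freq[i] / max(table$freq[i])
  }
  stats::setNames(w, table$codon)
}
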