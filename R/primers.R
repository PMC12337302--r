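## Orthogonal index-primer design.
##
## Index primers retrieve one target's fragments from the synthesis pool,
## so the primer set must be mutually orthogonal: 18-mers at exactly 50%
## GC, free of the assembly enzymes' recognition sites, Tm-matched near
## 60 C under a nearest-neighbor model, and filtered for pairwise
## cross-hybridization.

NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_AT <- c(dH = 2.3, dS = 4.1)
NN_INIT_GC <- c(dH = 0.1, dS = -2.8)

#' Nearest-neighbor melting temperature
#'
#' Unified duplex nearest-neighbor thermodynamics with terminal initiation
#' terms and an entropic monovalent-salt correction
#' (`0.368 * (N - 1) * ln[Na+]`). Default conditions (500 nM each strand,
#' 200 mM monovalent-equivalent salt) approximate a PCR mix and put 50%-GC
#' 18-mers near the 60 C design setpoint.
#'
#' @param seq DNA string (>= 8 nt, unambiguous).
#' @param dnac_nM Concentration of each strand in nM (default 500).
#' @param na_mM Monovalent-equivalent cation concentration in mM
#'   (default 200).
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, dnac_nM = 500, na_mM = 200) {
  seq <- toupper(seq)
  if (nchar(seq) < 8L) stop("sequence too short for NN Tm", call. = FALSE)
  assert_dna(seq, "primer")
  steps <- seq_kmers(seq, 2L)
  dH <- sum(NN_DH[steps])
  dS <- sum(NN_DS[steps])
  for (term in c(substr(seq, 1, 1), substr(seq, nchar(seq), nchar(seq)))) {
    init <- if (term %in% c("G", "C")) NN_INIT_GC else NN_INIT_AT
    dH <- dH + init["dH"]
    dS <- dS + init["dS"]
  }
  dS <- dS + 0.368 * (nchar(seq) - 1L) * log(na_mM / 1000)
  k <- (dnac_nM - dnac_nM / 2) * 1e-9
  unname(1000 * dH / (dS + 1.987 * log(k)) - 273.15)
}

max_homopolymer <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

#' Generate index-primer candidates
#'
#' Rejection-samples 18-mers with exactly 9 G/C bases, no forbidden
#' recognition site on either strand, homopolymer runs of at most 4, and
#' nearest-neighbor Tm within `tm_target +/- tm_tol`.
#'
#' @param n Number of candidates.
#' @param seed Integer seed.
#' @param tm_target Tm setpoint in C (default 60).
#' @param tm_tol Allowed deviation (default 1.5).
#' @param avoid_patterns Forbidden motifs (default type IIS sites).
#' @return Data frame: `sequence`, `gc`, `tm`.
#' @export
generate_primer_candidates <- function(n, seed,
                                       tm_target = 60, tm_tol = 1.5,
                                       avoid_patterns = c("GGTCTC", "CGTCTC",
                                                          "GAAGAC")) {
  pats <- unique(c(avoid_patterns, revcomp(avoid_patterns)))
  out <- character(n)
  got <- 0L
  with_seed(seed, {
    while (got < n) {
      gc_pos <- sample(18L, 9L)
      bases <- character(18L)
      bases[gc_pos] <- sample(c("G", "C"), 9L, replace = TRUE)
      bases[-gc_pos] <- sample(c("A", "T"), 9L, replace = TRUE)
      s <- paste(bases, collapse = "")
      if (max_homopolymer(s) > 4L) next
      if (any(vapply(pats, grepl, logical(1), x = s, fixed = TRUE))) next
      tm <- melting_temperature(s)
      if (abs(tm - tm_target) > tm_tol) next
      got <- got + 1L
      out[got] <- s
    }
  })
  data.frame(sequence = out, gc = gc_content(out),
             tm = vapply(out, melting_temperature, numeric(1),
                         USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

## Longest common substring length of two short strings (DP).
longest_common_substring <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- 0L
  prev <- integer(length(B))
  for (i in seq_along(A)) {
    cur <- integer(length(B))
    match_i <- A[i] == B
    cur[match_i] <- c(0L, prev)[which(match_i)] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  best
}

## Length of the complementary run anchored at the 3' end of `a` against
## any position of `b` (i.e. longest suffix of a that is a substring of
## rc(b)).
three_prime_run <- function(a, b_rc) {
  n <- nchar(a)
  run <- 0L
  for (k in seq_len(n)) {
    if (grepl(substr(a, n - k + 1L, n), b_rc, fixed = TRUE)) run <- k
    else break
  }
  run
}

#' Cross-hybridization score of a primer pair
#'
#' `longest complementary run + 3'-anchored complementary run of each
#' primer`: the longest stretch of `a` complementary to `b` anywhere, plus
#' the complementary runs anchored at each 3' terminus (so 3'-terminal
#' complementarity is counted twice -- primer extension starts there).
#' Symmetric in `a`/`b`; higher is worse.
#'
#' @param a,b Primer sequences.
#' @return Non-negative score.
#' @export
cross_hybridization_score <- function(a, b) {
  a <- toupper(a)
  b <- toupper(b)
  b_rc <- revcomp(b)
  a_rc <- revcomp(a)
  longest_common_substring(a, b_rc) +
    three_prime_run(a, b_rc) + three_prime_run(b, a_rc)
}

#' Select an orthogonal index set
#'
#' Greedy removal: while more than `k` candidates remain, drop the
#' candidate with the largest aggregate pairwise cross-hybridization score.
#' Errors if fewer than `k` survivors have all pairwise scores below the
#' hard dimer threshold.
#'
#' @param candidates Character vector of primer sequences (or the data
#'   frame from [generate_primer_candidates()]).
#' @param k Number of primers to retain.
#' @param dimer_threshold Hard cap on any retained pairwise score
#'   (default 24).
#' @return Character vector of `k` primers, attribute `max_pair_score`.
#' @export
select_index_set <- function(candidates, k, dimer_threshold = 24) {
  seqs <- if (is.data.frame(candidates)) candidates$sequence else candidates
  n <- length(seqs)
  if (n < k) stop("fewer candidates than requested set size", call. = FALSE)
  S <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      S[i, j] <- S[j, i] <- cross_hybridization_score(seqs[i], seqs[j])
    }
  }
  alive <- rep(TRUE, n)
  agg <- rowSums(S)
  while (sum(alive) > k) {
    worst <- which(alive)[which.max(agg[alive])]
    alive[worst] <- FALSE
    agg <- agg - S[, worst]
  }
  keep <- which(alive)
  sub <- S[keep, keep]
  if (any(sub[upper.tri(sub)] >= dimer_threshold)) {
    bad <- unique(keep[which(sub >= dimer_threshold, arr.ind = TRUE)])
    achievable <- k - length(bad)
    stop(sprintf(
      "only %d primers satisfy the dimer threshold %g; requested %d",
      achievable, dimer_threshold, k), call. = FALSE)
  }
  structure(seqs[keep], max_pair_score = max(sub[upper.tri(sub)], 0))
}
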