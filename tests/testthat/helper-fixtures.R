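# Shared fixtures and independent oracles for the suite.

# 16-overhang toy alphabet: 8 reverse-complement pairs (no palindromes),
# including the fixed part termini AATG/GCTT and their partners.
toy_alphabet <- function() {
  c("AATG", "CATT", "GCTT", "AAGC",
    "ACGG", "CCGT", "ATCC", "GGAT",
    "CTTG", "CAAG", "GACA", "TGTC",
    "TCAG", "CTGA", "AGGC", "GCCT")
}

# cached matrices so slow generators run once per session
.fixture_env <- new.env(parent = emptyenv())
fixture_matrix <- function(rate = 0.03, seed = 2) {
  key <- sprintf("m_%g_%d", rate, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- synthetic_ligation_matrix(
      correct_count = 1000, mismatch_rate = rate, seed = seed)
  }
  .fixture_env[[key]]
}

fixture_hingeset <- function(size = 20, rate = 0.03, seed = 5) {
  key <- sprintf("h_%d_%g_%d", size, rate, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- optimize_hingeset(
      size, fixture_matrix(rate), ga_config(seed = seed,
                                            generations_max = 120))
  }
  .fixture_env[[key]]
}

# Independent oracle: junction fidelity by explicit double loop over the
# pool, straight from the definition.
oracle_junction_fidelity <- function(o, members, m) {
  mm <- unclass(m)
  pool <- unique(c(members, revcomp(members)))
  on <- mm[o, revcomp(o)] + mm[revcomp(o), o]
  denom <- 0
  for (p in pool) denom <- denom + mm[o, p] + mm[revcomp(o), p]
  on / denom
}

oracle_set_fidelity <- function(members, m) {
  out <- 1
  for (o in members) out <- out * oracle_junction_fidelity(o, members, m)
  out
}

# Independent oracle: Levenshtein distance by full DP matrix.
oracle_levenshtein <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  D <- matrix(0L, length(A) + 1L, length(B) + 1L)
  D[, 1] <- 0:length(A)
  D[1, ] <- 0:length(B)
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      D[i + 1, j + 1] <- min(D[i, j] + (A[i] != B[j]),
                             D[i, j + 1] + 1L, D[i + 1, j] + 1L)
    }
  }
  D[length(A) + 1L, length(B) + 1L]
}

# All valid member sets of a given size from a toy alphabet (orientation
# canonicalized by reverse-complement pair; fidelity is rc-invariant).
toy_all_sets <- function(size, alphabet = toy_alphabet(),
                         fixed = c("AATG", "GCTT")) {
  canon <- unique(pmin(alphabet, revcomp(alphabet)))
  canon_fixed <- pmin(fixed, revcomp(fixed))
  rest <- setdiff(canon, canon_fixed)
  extra <- size - length(fixed)
  if (extra == 0) return(list(fixed))
  combos <- utils::combn(rest, extra, simplify = FALSE)
  lapply(combos, function(x) c(fixed, x))
}

random_valid_set <- function(size, alphabet = all_overhangs(),
                             fixed = c("AATG", "GCTT")) {
  members <- fixed
  pool <- alphabet[!is_palindromic(alphabet)]
  while (length(members) < size) {
    x <- sample(pool, 1L)
    if (!x %in% members && !revcomp(x) %in% members) members <- c(members, x)
  }
  members
}
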