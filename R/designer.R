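## Protein-preserving sequence design.
##
## All operations here edit coding sequences only through synonymous codon
## swaps. The engine is a per-codon local search: scan for constraint
## violations, enumerate synonymous swaps in codons overlapping the first
## violation, and apply the swap that most reduces a lexicographic energy
## (hard-violation count, then windowed GC deficit), tie-broken by codon
## usage. Seeded random "kicks" escape local minima; the search errors out
## naming the stuck window if it cannot satisfy the constraints.

validate_cds <- function(cds, what = "CDS") {
  cds <- toupper(cds)
  assert_dna(cds, what)
  if (nchar(cds) %% 3L != 0L) {
    stop(sprintf("%s length not divisible by 3", what), call. = FALSE)
  }
  aa <- translate_cds(cds)
  inner <- substr(aa, 1, nchar(aa) - 1L)
  if (grepl("*", inner, fixed = TRUE)) {
    stop(sprintf("%s contains an internal stop codon", what), call. = FALSE)
  }
  cds
}

#' Codon-optimize a protein or coding sequence
#'
#' `best_codon` uses each amino acid's most frequent codon (CAI = 1 under
#' the same table). `match_usage` apportions synonym counts to match the
#' table's relative frequencies as closely as integer counts allow
#' (largest-remainder quotas), then shuffles the assignment across positions
#' with the seed.
#'
#' @param protein_or_cds Amino-acid string, or a DNA CDS (auto-detected:
#'   A/C/G/T only and length divisible by 3); a CDS is first translated.
#' @param table A `codon_table`.
#' @param mode `"match_usage"` (default) or `"best_codon"`.
#' @param seed Integer seed (used by `match_usage` position shuffling).
#' @return A CDS string encoding the same protein.
#' @export
codon_optimize <- function(protein_or_cds, table, mode = "match_usage",
                           seed = 1) {
  mode <- match.arg(mode, c("match_usage", "best_codon"))
  x <- toupper(protein_or_cds)
  if (!grepl("[^ACGT]", x) && nchar(x) %% 3L == 0L) {
    aa <- strsplit(translate_cds(validate_cds(x)), "", fixed = TRUE)[[1]]
  } else {
    aa <- strsplit(x, "", fixed = TRUE)[[1]]
    bad <- setdiff(aa, c(unique(table$aa)))
    if (length(bad)) {
      stop(sprintf("unknown amino acid %s", bad[1]), call. = FALSE)
    }
  }
  codons <- character(length(aa))
  if (mode == "best_codon") {
    best <- vapply(split(table, table$aa),
                   function(d) d$codon[which.max(d$freq)], character(1))
    codons <- best[aa]
  } else {
    with_seed(seed, {
      for (a in unique(aa)) {
        pos <- which(aa == a)
        d <- table[table$aa == a, ]
        counts <- apportion_counts(length(pos), d$freq)
        pool <- rep(d$codon, counts)
        codons[pos] <- if (length(pool) > 1L) sample(pool) else pool
      }
    })
  }
  paste(codons, collapse = "")
}

## Largest-remainder apportionment of n items over probabilities p.
apportion_counts <- function(n, p) {
  p <- p / sum(p)
  quota <- n * p
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_order <- order(quota - counts, decreasing = TRUE)
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1L
  }
  as.integer(counts)
}

## Lexicographic design energy: hard violations, then GC deficit.
design_energy <- function(seq, constraints) {
  v <- find_violations(seq, constraints, include_gc = FALSE)
  deficit <- 0
  if (!is.null(constraints$gc_min)) {
    prof <- window_gc(seq, constraints$gc_window)
    deficit <- sum(pmax(0, constraints$gc_min - prof))
  }
  list(nv = nrow(v), deficit = deficit, first = if (nrow(v)) v[1, ] else NULL)
}

energy_less <- function(a, b) {
  if (a$nv != b$nv) return(a$nv < b$nv)
  a$deficit < b$deficit - 1e-12
}

## Core repair loop (see file header). Returns list(seq, edits).
repair_sequence <- function(seq, constraints, table, seed,
                            max_passes = 400L, max_kicks = 30L) {
  freq <- codon_freq(table)
  syn_by_codon <- split(table$codon, table$aa)[codon_aa(table)]
  names(syn_by_codon) <- table$codon
  edits <- 0L
  kicks <- 0L
  with_seed(derive_seed(seed, 7L), {
    for (pass in seq_len(max_passes)) {
      en <- design_energy(seq, constraints)
      target_span <- NULL
      if (en$nv > 0) {
        target_span <- c(en$first$start, en$first$end)
      } else if (en$deficit > 1e-12) {
        lg <- find_low_gc_windows(seq, constraints$gc_min,
                                  constraints$gc_window)
        target_span <- c(lg$start[1], lg$end[1])
      } else {
        return(list(seq = seq, edits = edits))
      }
      cod_idx <- codon_range(target_span[1], target_span[2], nchar(seq))
      cand <- enumerate_swaps(seq, cod_idx, syn_by_codon)
      improved <- FALSE
      if (length(cand)) {
        ens <- lapply(cand, design_energy, constraints = constraints)
        better <- which(vapply(ens, energy_less, logical(1), b = en))
        if (length(better)) {
          ## among improving swaps pick lowest energy, then highest usage
          scores <- vapply(better, function(i) {
            ens[[i]]$nv * 1e6 + ens[[i]]$deficit * 1e3 -
              freq[attr(cand[[i]], "new_codon")] * 1e-3
          }, numeric(1))
          pick <- better[which.min(scores)]
          seq <- cand[[pick]]
          edits <- edits + 1L
          improved <- TRUE
        }
      }
      if (!improved) {
        kicks <- kicks + 1L
        if (kicks > max_kicks || !length(cand)) {
          stop(sprintf(
            "cannot satisfy design constraints in window [%d, %d] (%s)",
            target_span[1], target_span[2],
            if (en$nv > 0) en$first$type else "gc"), call. = FALSE)
        }
        seq <- cand[[sample.int(length(cand), 1L)]]
        edits <- edits + 1L
      }
    }
  })
  stop("constraint repair did not converge", call. = FALSE)
}

## Codon indices overlapping a [start, end] nucleotide span.
codon_range <- function(start, end, n) {
  lo <- max(1L, (start - 1L) %/% 3L + 1L)
  hi <- min(n %/% 3L, (end - 1L) %/% 3L + 1L)
  lo:hi
}

## All single synonymous swaps over the given codon indices; each candidate
## carries attr "new_codon". Start codon (index 1) and the final stop are
## never touched except to another stop.
enumerate_swaps <- function(seq, cod_idx, syn_by_codon) {
  out <- list()
  n_codons <- nchar(seq) %/% 3L
  for (ci in cod_idx) {
    if (ci == 1L) next  # keep the start codon
    cur <- substr(seq, (ci - 1L) * 3L + 1L, ci * 3L)
    syns <- setdiff(syn_by_codon[[cur]], cur)
    for (s in syns) {
      x <- seq
      substr(x, (ci - 1L) * 3L + 1L, ci * 3L) <- s
      attr(x, "new_codon") <- s
      out[[length(out) + 1L]] <- x
    }
  }
  out
}

#' Domesticate a coding sequence
#'
#' Removes forbidden motifs (type IIS sites by default) from both strands,
#' repeated k-mers, and long inverted repeats, using only synonymous codon
#' swaps; prefers solutions with fewer codons changed (greedy single-swap
#' repair).
#'
#' @param cds CDS string.
#' @param constraints A `design_constraints` (GC constraint ignored here;
#'   use [gc_tune()]).
#' @param table A `codon_table` (swap preference follows usage frequency).
#' @param seed Integer seed.
#' @return CDS string satisfying all hard constraints; attributes `edits`
#'   (codons changed).
#' @export
domesticate <- function(cds, constraints = design_constraints(),
                        table = flat_codon_table(), seed = 1) {
  cds <- validate_cds(cds)
  cons <- constraints
  cons$gc_min <- NULL
  res <- repair_sequence(cds, cons, table, seed)
  structure(res$seq, edits = res$edits)
}

#' Enforce a minimum windowed GC content
#'
#' Re-optimizes codon usage (`match_usage`), then raises every sliding
#' window of `gc_window` bp to at least `gc_min` GC through synonymous
#' swaps, weighting the GC objective `gc_boost`-fold over codon usage, and
#' finally re-repairs any hard-constraint violations the GC pass introduced.
#' Windows may fall short of `gc_min` by at most the documented tolerance
#' of 0.02.
#'
#' @param cds CDS string.
#' @param gc_min Minimum window GC fraction; `0` (or `NULL`) disables GC
#'   enforcement and returns the usage-only optimization.
#' @param constraints A `design_constraints`.
#' @param table A `codon_table`.
#' @param seed Integer seed.
#' @return CDS string; attribute `edits`.
#' @export
gc_tune <- function(cds, gc_min, constraints = design_constraints(),
                    table = flat_codon_table(), seed = 1) {
  cds <- validate_cds(cds)
  base <- codon_optimize(cds, table, "match_usage", seed)
  base <- domesticate(base, constraints, table, seed)
  if (is.null(gc_min) || gc_min <= 0) return(base)

  cons <- constraints
  cons$gc_min <- gc_min
  check_gc_feasible(base, gc_min, cons$gc_window, table)
  seq <- gc_greedy_raise(base, cons, table)
  res <- repair_sequence(seq, cons, table, seed)
  out <- res$seq
  prof <- window_gc(out, cons$gc_window)
  if (any(prof < gc_min - 0.02 - 1e-9)) {
    w <- which(prof < gc_min - 0.02)[1]
    stop(sprintf("window starting at %d stuck below GC %.2f", w, gc_min),
         call. = FALSE)
  }
  structure(out, edits = attr(base, "edits") + res$edits)
}

## Error if some window cannot reach gc_min even with all GC-maximal
## synonyms (boundary codons approximated by their global GC-max synonym).
check_gc_feasible <- function(seq, gc_min, window, table) {
  gc_of <- gc_content(table$codon)
  maxgc_syn <- vapply(split(table, table$aa), function(d) {
    d$codon[which.max(gc_content(d$codon))]
  }, character(1))
  codons <- split_codons(seq)
  maxseq <- paste(maxgc_syn[codon_aa(table)[codons]], collapse = "")
  prof <- window_gc(maxseq, window)
  if (any(prof < gc_min - 1e-9)) {
    w <- which(prof < gc_min)[1]
    stop(sprintf(
      "window starting at %d cannot reach GC %.2f under synonymous coding",
      w, gc_min), call. = FALSE)
  }
  invisible(TRUE)
}

## Greedy GC raising: repeatedly swap, inside the worst deficient window,
## the synonymous codon whose swap scores highest under
## gc_boost * (GC bases gained) + log2(freq_new / freq_old).
gc_greedy_raise <- function(seq, constraints, table, max_steps = 5000L) {
  freq <- codon_freq(table)
  aa_of <- codon_aa(table)
  syn <- split(table$codon, table$aa)
  w <- constraints$gc_window
  for (step in seq_len(max_steps)) {
    lg <- find_low_gc_windows(seq, constraints$gc_min, w)
    if (!nrow(lg)) return(seq)
    worst <- lg[which.min(lg$gc), ]
    cod_idx <- codon_range(worst$start, worst$end, nchar(seq))
    best <- NULL
    best_score <- -Inf
    for (ci in cod_idx) {
      if (ci == 1L) next
      cur <- substr(seq, (ci - 1L) * 3L + 1L, ci * 3L)
      for (s in setdiff(syn[[aa_of[cur]]], cur)) {
        dgc <- (nchar(gsub("[^GC]", "", s)) -
                  nchar(gsub("[^GC]", "", cur)))
        if (dgc <= 0) next
        score <- constraints$gc_boost * dgc + log2(freq[s] / freq[cur])
        if (score > best_score) {
          best_score <- score
          best <- list(ci = ci, s = s)
        }
      }
    }
    if (is.null(best)) {
      stop(sprintf("window starting at %d cannot be raised to GC %.2f",
                   worst$start, constraints$gc_min), call. = FALSE)
    }
    substr(seq, (best$ci - 1L) * 3L + 1L, best$ci * 3L) <- best$s
  }
  stop("GC raising did not converge", call. = FALSE)
}

#' Sequence composition and codon-usage metrics
#'
#' @param cds CDS string (any DNA for `gc` alone).
#' @param table A `codon_table` (for CAI and GC3s).
#' @param gc_window Window width for the GC profile (default 60).
#' @return List: `gc`, `gc3s` (GC at third positions of degenerate codons),
#'   `cai` (geometric-mean relative adaptiveness; stops and single-codon
#'   amino acids excluded), `length_nt`, `length_aa`, `window_gc`.
#' @export
sequence_metrics <- function(cds, table = flat_codon_table(),
                             gc_window = 60L) {
  cds <- toupper(cds)
  if (nchar(cds) == 0L) stop("empty sequence", call. = FALSE)
  out <- list(gc = gc_content(cds), length_nt = nchar(cds))
  if (nchar(cds) %% 3L == 0L && !grepl("[^ACGT]", cds)) {
    codons <- split_codons(cds)
    aa_of <- codon_aa(table)
    n_syn <- table(table$aa)
    degenerate <- codons[n_syn[aa_of[codons]] > 1L & aa_of[codons] != "*"]
    if (length(degenerate)) {
      third <- substr(degenerate, 3, 3)
      out$gc3s <- mean(third %in% c("G", "C"))
    } else {
      out$gc3s <- NA_real_
    }
    w <- codon_w(table)
    use <- degenerate
    out$cai <- if (length(use)) exp(mean(log(w[use]))) else NA_real_
    out$length_aa <- length(codons) - 1L
  }
  out$window_gc <- window_gc(cds, gc_window)
  out
}
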