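## Splice-site prediction and removal ("deintronization").
##
## Cryptic splice donors/acceptors in a transgene can truncate its mRNA in
## planta. The pipeline therefore scans coding sequences for predicted
## donor (exon|GTAAGT-like) and acceptor (polypyrimidine-YAG|exon-like)
## junctions and purges them by synonymous mutation. The default predictor
## is a log-odds position-weight model of the canonical plant motifs; any
## external model can be plugged in as a function
## `function(seq) -> data.frame(position, kind, score)` (0-based positions
## of the first intronic base for donors / first exonic base after the AG
## for acceptors).

donor_pwm <- function() {
  ## columns: exon -3..-1 (MAG consensus), intron +1..+6 (GTAAGT)
  p <- cbind(
    c(A = .40, C = .35, G = .15, T = .10),
    c(A = .60, C = .10, G = .15, T = .15),
    c(A = .10, C = .05, G = .80, T = .05),
    c(A = .003, C = .002, G = .992, T = .003),
    c(A = .003, C = .002, G = .003, T = .992),
    c(A = .60, C = .12, G = .16, T = .12),
    c(A = .70, C = .08, G = .12, T = .10),
    c(A = .08, C = .06, G = .80, T = .06),
    c(A = .18, C = .16, G = .21, T = .45))
  log2(p / 0.25)
}

acceptor_pwm <- function() {
  py <- c(A = .10, C = .40, G = .10, T = .40)
  p <- cbind(
    matrix(rep(py, 12), nrow = 4,
           dimnames = list(names(py), NULL)),
    c(A = .05, C = .45, G = .05, T = .45),   # Y
    c(A = .992, C = .003, G = .002, T = .003),  # A
    c(A = .003, C = .002, G = .992, T = .003))  # G
  log2(p / 0.25)
}

#' Default position-weight-matrix splice predictor
#'
#' @param threshold_frac Fraction of each motif's maximum log-odds score
#'   used as the call threshold (default 0.7).
#' @return A `splice_predictor` object.
#' @export
pwm_splice_predictor <- function(threshold_frac = 0.7) {
  structure(list(donor = donor_pwm(), acceptor = acceptor_pwm(),
                 threshold_frac = threshold_frac),
            class = "splice_predictor")
}

pwm_max_score <- function(lom) sum(apply(lom, 2, max))

pwm_scan <- function(seq, lom) {
  n <- nchar(seq)
  L <- ncol(lom)
  if (n < L) return(numeric(0))
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)
  S <- numeric(n - L + 1L)
  for (j in seq_len(L)) {
    S <- S + lom[cbind(idx[j:(n - L + j)], j)]
  }
  S
}

#' Predict splice donor and acceptor sites
#'
#' Scans the sequence (conceptually in sliding windows of `window` bp; the
#' union over windows equals a full scan) and reports every position whose
#' motif score reaches the threshold.
#'
#' @param seq DNA string.
#' @param predictor A `splice_predictor` or a function
#'   `function(seq) -> data.frame(position, kind, score)`.
#' @param window Scan window size (default 200; bookkeeping only, the scan
#'   is exhaustive).
#' @param threshold Absolute score threshold; default
#'   `threshold_frac * max score` per motif.
#' @return Data frame: `position` (0-based; first intron base for donors,
#'   first exon base after the acceptor AG), `kind`, `score`,
#'   `window_start`, `window_end`.
#' @export
predict_splice_sites <- function(seq, predictor = pwm_splice_predictor(),
                                 window = 200L, threshold = NULL) {
  seq <- toupper(seq)
  if (is.function(predictor)) {
    out <- predictor(seq)
  } else {
    out <- list()
    for (kind in c("donor", "acceptor")) {
      lom <- predictor[[kind]]
      thr <- if (is.null(threshold)) {
        predictor$threshold_frac * pwm_max_score(lom)
      } else threshold
      S <- pwm_scan(seq, lom)
      hit <- which(S >= thr)
      if (length(hit)) {
        ## motif start (1-based) -> 0-based site position
        position <- if (kind == "donor") hit + 3L - 1L else hit + 15L - 1L
        out[[kind]] <- data.frame(position = position, kind = kind,
                                  score = S[hit], motif_start = hit,
                                  stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, out)
    if (is.null(out)) {
      out <- data.frame(position = integer(0), kind = character(0),
                        score = numeric(0), motif_start = integer(0),
                        stringsAsFactors = FALSE)
    }
  }
  out$window_start <- (out$position %/% window) * window
  out$window_end <- pmin(out$window_start + window, nchar(seq))
  rownames(out) <- NULL
  out[order(out$position), , drop = FALSE]
}

## Try to kill one predicted site by a single synonymous swap inside its
## motif span; returns the edited sequence or NULL.
purge_one_site <- function(seq, site, predictor, table, constraints,
                           threshold = NULL) {
  motif_len <- ncol(predictor[[site$kind]])
  span <- c(site$motif_start, site$motif_start + motif_len - 1L)
  syn_by_codon <- split(table$codon, table$aa)[codon_aa(table)]
  names(syn_by_codon) <- table$codon
  cand <- enumerate_swaps(seq, codon_range(span[1], span[2], nchar(seq)),
                          syn_by_codon)
  if (!length(cand)) return(NULL)
  base_n <- nrow(predict_splice_sites(seq, predictor, threshold = threshold))
  best <- NULL
  best_key <- c(Inf, Inf)
  for (x in cand) {
    preds <- predict_splice_sites(x, predictor, threshold = threshold)
    still <- any(preds$kind == site$kind &
                   preds$motif_start == site$motif_start)
    if (still) next
    nv <- nrow(find_violations(x, constraints, include_gc = FALSE))
    key <- c(nrow(preds), nv)
    if (key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2])) {
      best <- x
      best_key <- key
    }
  }
  if (!is.null(best) && best_key[1] <= base_n) best else NULL
}

#' Purge predicted splice sites by iterative synonymous mutation
#'
#' Up to `max_iterations` rounds of scan -> synonymous purge ->
#' re-domestication. If residual predictions remain, the whole procedure is
#' retried under additional seeds and the best run (fewest residual sites,
#' then fewest edits) is returned. Residual sites are reported, never fatal.
#'
#' @param cds CDS string.
#' @param constraints A `design_constraints`.
#' @param table A `codon_table`.
#' @param predictor A `splice_predictor`.
#' @param max_iterations Purge rounds per run (default 4).
#' @param seed Integer seed.
#' @param n_seeds Number of independent runs to try while residuals remain
#'   (default 3).
#' @return List: `seq`, `residual` (prediction data frame), `iterations`,
#'   `edits`, `seed_used`.
#' @export
deintronize <- function(cds, constraints = design_constraints(),
                        table = flat_codon_table(),
                        predictor = pwm_splice_predictor(),
                        max_iterations = 4L, seed = 1, n_seeds = 3L) {
  cds <- validate_cds(cds)
  best <- NULL
  for (k in seq_len(n_seeds)) {
    run_seed <- derive_seed(seed, k)
    res <- deintronize_once(cds, constraints, table, predictor,
                            max_iterations, run_seed)
    res$seed_used <- run_seed
    if (is.null(best) ||
        nrow(res$residual) < nrow(best$residual) ||
        (nrow(res$residual) == nrow(best$residual) &&
           res$edits < best$edits)) {
      best <- res
    }
    if (nrow(best$residual) == 0L) break
  }
  best
}

deintronize_once <- function(cds, constraints, table, predictor,
                             max_iterations, seed) {
  seq <- cds
  edits <- 0L
  iterations <- 0L
  for (iter in seq_len(max_iterations)) {
    preds <- predict_splice_sites(seq, predictor)
    if (!nrow(preds)) break
    iterations <- iter
    changed <- FALSE
    for (i in seq_len(nrow(preds))) {
      site <- preds[i, ]
      ## site may have moved/vanished after earlier purges this round
      cur <- predict_splice_sites(seq, predictor)
      if (!any(cur$kind == site$kind & cur$motif_start == site$motif_start)) {
        next
      }
      new_seq <- purge_one_site(seq, site, predictor, table, constraints)
      if (!is.null(new_seq)) {
        seq <- new_seq
        edits <- edits + 1L
        changed <- TRUE
      } else {
        ## seeded kick inside the motif to reshuffle the local neighborhood
        seq <- splice_kick(seq, site, predictor, table, seed + iter + i)
        edits <- edits + 1L
        changed <- TRUE
      }
    }
    seq <- as.character(domesticate(seq, constraints, table, seed))
    if (!changed) break
  }
  list(seq = seq, residual = predict_splice_sites(seq, predictor),
       iterations = iterations, edits = edits)
}

splice_kick <- function(seq, site, predictor, table, seed) {
  motif_len <- ncol(predictor[[site$kind]])
  syn_by_codon <- split(table$codon, table$aa)[codon_aa(table)]
  names(syn_by_codon) <- table$codon
  cand <- enumerate_swaps(
    seq, codon_range(site$motif_start, site$motif_start + motif_len - 1L,
                     nchar(seq)), syn_by_codon)
  if (!length(cand)) return(seq)
  with_seed(seed, cand[[sample.int(length(cand), 1L)]])
}
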