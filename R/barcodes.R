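## Edit-distance-separated amplicon barcodes.
##
## Colony amplicons from many clones are pooled on one long-read flow cell;
## 18-mer primer barcodes with a guaranteed minimum pairwise Levenshtein
## distance keep demultiplexing unambiguous under indel-prone reads.

#' Levenshtein edit distance
#'
#' Unit-cost substitutions, insertions and deletions.
#' @param a,b DNA (or any) strings; `b` may be a vector.
#' @return Integer distance(s).
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

#' Select a maximally separated barcode set
#'
#' Greedy max-min selection: seed with the globally farthest candidate
#' pair, then repeatedly add the candidate whose minimum Levenshtein
#' distance to the chosen set is largest (ties: larger mean distance, then
#' input order). Fails loudly if the distance floor cannot be held at the
#' requested size.
#'
#' @param candidates Character vector of barcode candidates (or the data
#'   frame from [generate_primer_candidates()]).
#' @param size Barcodes to select (default 96).
#' @param min_distance Required minimum pairwise distance (default 8).
#' @return A `barcode_set`: list with `members`, `min_pairwise_distance`,
#'   `mean_pairwise_distance`.
#' @export
select_barcode_set <- function(candidates, size = 96L, min_distance = 8L) {
  seqs <- if (is.data.frame(candidates)) candidates$sequence else candidates
  seqs <- unique(seqs)
  n <- length(seqs)
  if (n < size) stop("fewer unique candidates than requested size",
                     call. = FALSE)
  ## full matrix only for the seed pair; afterwards one column per addition
  D <- utils::adist(seqs)
  seed_pair <- which(D == max(D), arr.ind = TRUE)[1, ]
  chosen <- as.integer(seed_pair)
  min_d <- pmin(D[, chosen[1]], D[, chosen[2]])
  sum_d <- D[, chosen[1]] + D[, chosen[2]]
  while (length(chosen) < size) {
    min_d[chosen] <- -1L
    best <- max(min_d)
    if (best < min_distance) {
      stop(sprintf(
        "distance floor %d unreachable: best achievable (size=%d, floor=%d)",
        min_distance, length(chosen), best), call. = FALSE)
    }
    tie <- which(min_d == best)
    pick <- tie[which.max(sum_d[tie])]
    chosen <- c(chosen, pick)
    min_d <- pmin(min_d, D[, pick])
    sum_d <- sum_d + D[, pick]
  }
  members <- seqs[chosen]
  sub <- D[chosen, chosen]
  pair <- sub[upper.tri(sub)]
  if (min(pair) < min_distance) {
    stop(sprintf("selected set violates the distance floor (%d < %d)",
                 min(pair), min_distance), call. = FALSE)
  }
  structure(list(members = members,
                 min_pairwise_distance = as.integer(min(pair)),
                 mean_pairwise_distance = mean(pair)),
            class = "barcode_set")
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf(
    "barcode_set: %d barcodes, min pairwise distance %d, mean %.2f\n",
    length(x$members), x$min_pairwise_distance, x$mean_pairwise_distance))
  invisible(x)
}

#' Pair barcodes into a 96-position plate layout
#' @param set A `barcode_set` (>= 2 * n_positions members not required;
#'   pairs are drawn with wraparound across the member list).
#' @param n_positions Plate positions (default 96).
#' @return Data frame: `position`, `well`, `fwd_barcode`, `rev_barcode`.
#' @export
barcode_plate_layout <- function(set, n_positions = 96L) {
  m <- set$members
  idx <- seq_len(n_positions)
  rows <- LETTERS[((idx - 1L) %/% 12L) + 1L]
  cols <- ((idx - 1L) %% 12L) + 1L
  data.frame(position = idx,
             well = sprintf("%s%02d", rows, cols),
             fwd_barcode = m[((idx - 1L) %% length(m)) + 1L],
             rev_barcode = m[((idx) %% length(m)) + 1L],
             stringsAsFactors = FALSE)
}
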