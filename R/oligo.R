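## Oligo layout: expand fragment plans into indexed, type-IIS-flanked
## synthesis oligos under the 250-nt budget, and pool tables.
##
## Layout per oligo:
##   fwd_index(18) + recognition + spacer + payload +
##   rc(spacer + recognition) + rc(rev_index)(18)
## so digestion with the layout enzyme releases exactly the fragment
## payload with its designed 4-nt 5' overhangs. With 18-mer indexes and
## BbsI (6-bp site, 2-bp spacer) the overhead is 2 x (18 + 6 + 2) = 52 nt.

#' Maximum synthesis oligo length (nt)
#' @export
OLIGO_BUDGET <- 250L

default_spacer <- function(enzyme) {
  e <- get_enzyme(enzyme)
  substr("TT", 1, e$spacer)
}

spacer_alternatives <- function(n) {
  if (n == 1L) c("T", "A", "C", "G") else c("TT", "AA", "CA", "GT", "AC")
}

#' Lay out the synthesis oligos for a fragment plan
#'
#' @param plan A `fragment_plan`.
#' @param enzyme Layout enzyme (default `"BbsI"`, the oligos-to-blocks step).
#' @param index_pair Character vector of two 18-mer index primers
#'   `c(fwd, rev)`; all fragments of one target share the pair.
#' @param oligo_budget Maximum oligo length (default 250 nt).
#' @return Data frame of `oligo_record`s: `target_id`, `fragment_index`,
#'   `full_sequence`, `payload`, `payload_start`, `payload_end`,
#'   `fwd_index`, `rev_index`, `enzyme`, `left_ov`, `right_ov`, `length`.
#' @export
layout_oligos <- function(plan, enzyme = "BbsI", index_pair,
                          oligo_budget = OLIGO_BUDGET) {
  e <- get_enzyme(enzyme)
  stopifnot(length(index_pair) == 2L, all(nchar(index_pair) == 18L))
  recs <- lapply(seq_along(plan$fragments), function(i) {
    payload <- plan$fragments[i]
    if (has_recognition_site(payload, enzyme)) {
      stop(sprintf(
        "fragment %d of %s contains a %s site inside its payload",
        i, plan$target_id, e$name), call. = FALSE)
    }
    full <- NULL
    for (sp_l in spacer_alternatives(e$spacer)) {
      for (sp_r in spacer_alternatives(e$spacer)) {
        cand <- paste0(index_pair[1], e$site, sp_l, payload,
                       revcomp(paste0(e$site, sp_r)), revcomp(index_pair[2]))
        ## spacers must not create extra sites with adjacent bases
        d <- digest(cand, enzyme)
        if (nrow(d) == 3L && d$seq[2] == payload) {
          full <- cand
          break
        }
      }
      if (!is.null(full)) break
    }
    if (is.null(full)) {
      stop(sprintf("no spacer choice yields a clean digest for fragment %d",
                   i), call. = FALSE)
    }
    if (nchar(full) > oligo_budget) {
      stop(sprintf(
        "fragment %d of %s overflows the oligo budget: %d nt > %d",
        i, plan$target_id, nchar(full), oligo_budget), call. = FALSE)
    }
    pay_start <- 18L + nchar(e$site) + e$spacer + 1L
    data.frame(target_id = plan$target_id, fragment_index = i,
               full_sequence = full, payload = payload,
               payload_start = pay_start,
               payload_end = pay_start + nchar(payload) - 1L,
               fwd_index = index_pair[1], rev_index = index_pair[2],
               enzyme = e$name,
               left_ov = substr(payload, 1, 4),
               right_ov = substr(payload, nchar(payload) - 3L,
                                 nchar(payload)),
               length = nchar(full), stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Build a pool table for a set of fragment plans
#'
#' Assigns one index primer pair per target (all fragments of a target
#' amplify together in one reaction) and emits one row per oligo.
#'
#' @param plans List of `fragment_plan`s.
#' @param indexset Character vector of index primers (consumed in pairs),
#'   or a two-column matrix/data.frame of pairs.
#' @param enzyme Layout enzyme (default `"BbsI"`).
#' @param pool_id Pool identifier.
#' @return A `pool_table` data frame (one row per oligo) with attribute
#'   `index_assignment` (target -> pair).
#' @export
build_pool_table <- function(plans, indexset, enzyme = "BbsI",
                             pool_id = "pool1") {
  if (!length(plans)) {
    out <- data.frame(target_id = character(0), fragment_index = integer(0),
                      full_sequence = character(0), fwd_index = character(0),
                      rev_index = character(0), stringsAsFactors = FALSE)
    attr(out, "pool_id") <- pool_id
    return(out)
  }
  pairs <- if (is.matrix(indexset) || is.data.frame(indexset)) {
    as.matrix(indexset)
  } else {
    n <- length(indexset) %/% 2L
    cbind(indexset[seq_len(n) * 2L - 1L], indexset[seq_len(n) * 2L])
  }
  if (nrow(pairs) < length(plans)) {
    stop(sprintf("index exhaustion: %d pairs available for %d targets",
                 nrow(pairs), length(plans)), call. = FALSE)
  }
  rows <- lapply(seq_along(plans), function(i) {
    layout_oligos(plans[[i]], enzyme = enzyme, index_pair = pairs[i, ])
  })
  out <- do.call(rbind, rows)
  attr(out, "pool_id") <- pool_id
  attr(out, "index_assignment") <- data.frame(
    target_id = vapply(plans, `[[`, "", "target_id"),
    fwd_index = pairs[seq_along(plans), 1],
    rev_index = pairs[seq_along(plans), 2], stringsAsFactors = FALSE)
  class(out) <- c("pool_table", "data.frame")
  out
}

#' Write a pool table as TSV plus oligo/primer FASTA
#' @param pool A `pool_table`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_pool_table <- function(pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "pool_table.tsv")
  utils::write.table(as.data.frame(pool), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  oligos <- stats::setNames(
    pool$full_sequence,
    sprintf("%s_frag%02d", pool$target_id, pool$fragment_index))
  fa <- file.path(dir, "oligos.fasta")
  write_fasta(oligos, fa)
  idx <- attr(pool, "index_assignment")
  primers <- stats::setNames(
    c(idx$fwd_index, idx$rev_index),
    c(paste0(idx$target_id, "_F"), paste0(idx$target_id, "_R")))
  pf <- file.path(dir, "index_primers.fasta")
  write_fasta(primers, pf)
  invisible(c(tsv, fa, pf))
}
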