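## Type IIS enzymes and the digital digest-ligate simulator.
##
## The assembly hierarchy is BbsI (oligos -> ~1 kb blocks), BsmBI (blocks ->
## full-length part / cloning) and BsaI (downstream part reuse). All three
## cut outside a 6-bp recognition site and expose 4-nt 5' overhangs.

#' Type IIS enzymes used by the pipeline
#'
#' Recognition sequence, spacer length between recognition site and the
#' 4-nt overhang, for BsaI, BsmBI and BbsI.
#' @export
TYPE_IIS_ENZYMES <- list(
  BsaI  = list(site = "GGTCTC", spacer = 1L),
  BsmBI = list(site = "CGTCTC", spacer = 1L),
  BbsI  = list(site = "GAAGAC", spacer = 2L)
)

get_enzyme <- function(enzyme) {
  if (is.list(enzyme)) return(enzyme)
  e <- TYPE_IIS_ENZYMES[[enzyme]]
  if (is.null(e)) stop(sprintf("unknown enzyme %s", enzyme), call. = FALSE)
  c(e, list(name = enzyme))
}

## Does `seq` contain the enzyme's recognition site on either strand?
has_recognition_site <- function(seq, enzyme) {
  e <- get_enzyme(enzyme)
  grepl(e$site, seq, fixed = TRUE) || grepl(revcomp(e$site), seq, fixed = TRUE)
}

#' Digest a double-stranded (top-strand-represented) sequence in silico
#'
#' Finds all recognition sites on both strands and cuts at the enzyme's
#' offset, exposing 4-nt 5' overhangs. Each resulting fragment is reported by
#' its top strand *including* both terminal overhang 4-mers; `left_ov` /
#' `right_ov` are the first and last 4 nt (two fragments ligate when one's
#' `right_ov` equals the next one's `left_ov`).
#'
#' @param seq Top-strand DNA string (linear molecule).
#' @param enzyme Enzyme name (`"BsaI"`, `"BsmBI"`, `"BbsI"`).
#' @return Data frame with columns `seq`, `left_ov`, `right_ov`, `terminal`
#'   (whether the fragment includes an original molecule end).
#' @export
digest <- function(seq, enzyme) {
  e <- get_enzyme(enzyme)
  seq <- toupper(seq)
  n <- nchar(seq)
  site_len <- nchar(e$site)
  ## top-strand sites: cut pair (a, a+4), a = site_end + spacer
  top <- find_fixed(seq, e$site)
  cuts_top <- top + site_len - 1L + e$spacer
  ## bottom-strand sites (rc(site) on top at q): cut pair a = q - spacer - 5
  bot <- find_fixed(seq, revcomp(e$site))
  cuts_bot <- bot - e$spacer - 5L
  cuts <- sort(unique(c(cuts_top, cuts_bot)))
  cuts <- cuts[cuts >= 0L & cuts + 4L <= n]
  if (!length(cuts)) {
    return(data.frame(seq = seq, left_ov = NA_character_,
                      right_ov = NA_character_, terminal = TRUE,
                      stringsAsFactors = FALSE))
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts + 4L, n)
  frags <- substring(seq, starts, ends)
  data.frame(
    seq = frags,
    left_ov = c(NA_character_, substring(seq, cuts + 1L, cuts + 4L)),
    right_ov = c(substring(seq, cuts + 1L, cuts + 4L), NA_character_),
    terminal = c(TRUE, rep(FALSE, length(cuts) - 1L), TRUE)[
      seq_len(length(cuts) + 1L)],
    stringsAsFactors = FALSE
  )
}

find_fixed <- function(seq, pattern) {
  hits <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  hits[hits > 0L]
}

#' Simulate a one-pot Golden Gate digest-ligate reaction
#'
#' Digests every input molecule, discards pieces still carrying a
#' recognition site (they are re-cut in the real one-pot reaction), and
#' ligates the remaining sticky-ended fragments wherever overhangs are
#' complementary. Reports the assembled product(s) plus diagnostics:
#' ambiguous overhangs (an overhang usable by more than one fragment end),
#' dead ends, and circularity.
#'
#' @param sequences Character vector of top-strand molecules.
#' @param enzyme Enzyme name.
#' @return List with `products` (character vector of assembled top strands),
#'   `circular` (logical per product), `ambiguous` (logical), and
#'   `diagnostics` (character messages).
#' @export
digest_ligate <- function(sequences, enzyme) {
  e <- get_enzyme(enzyme)
  pieces <- do.call(rbind, lapply(sequences, digest, enzyme = enzyme))
  keep <- !vapply(pieces$seq, has_recognition_site, logical(1), enzyme = enzyme)
  pieces <- pieces[keep & !is.na(pieces$left_ov) & !is.na(pieces$right_ov), ,
                   drop = FALSE]
  diagnostics <- character(0)
  if (!nrow(pieces)) {
    return(list(products = character(0), circular = logical(0),
                ambiguous = FALSE,
                diagnostics = "no ligatable site-free fragments released"))
  }
  ambiguous <- FALSE
  left_tab <- table(pieces$left_ov)
  right_tab <- table(pieces$right_ov)
  dup_left <- names(left_tab)[left_tab > 1L]
  dup_right <- names(right_tab)[right_tab > 1L]
  if (length(dup_left) || length(dup_right)) {
    ambiguous <- TRUE
    diagnostics <- c(diagnostics, sprintf(
      "ambiguous overhang(s): %s",
      paste(unique(c(dup_left, dup_right)), collapse = ", ")))
  }
  pal <- unique(c(pieces$left_ov, pieces$right_ov))
  pal <- pal[is_palindromic(pal)]
  if (length(pal)) {
    ambiguous <- TRUE
    diagnostics <- c(diagnostics, sprintf(
      "palindromic overhang(s) can self-ligate: %s",
      paste(pal, collapse = ", ")))
  }

  ## chain fragments: next fragment's left_ov == current right_ov
  products <- character(0)
  circular <- logical(0)
  used <- rep(FALSE, nrow(pieces))
  next_by_left <- split(seq_len(nrow(pieces)), pieces$left_ov)
  starts <- which(!pieces$left_ov %in% pieces$right_ov)
  walk <- function(i) {
    chain <- i
    used[i] <<- TRUE
    repeat {
      cand <- next_by_left[[pieces$right_ov[chain[length(chain)]]]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      used[cand[1]] <<- TRUE
      chain <- c(chain, cand[1])
    }
    chain
  }
  assemble <- function(chain) {
    seqs <- pieces$seq[chain]
    paste0(seqs[1], paste(substring(seqs[-1], 5L), collapse = ""))
  }
  for (i in starts) {
    if (used[i]) next
    chain <- walk(i)
    products <- c(products, assemble(chain))
    circular <- c(circular, FALSE)
    last <- chain[length(chain)]
    if (!pieces$right_ov[last] %in% pieces$left_ov) {
      diagnostics <- c(diagnostics, sprintf(
        "chain ends with unligated overhangs %s / %s",
        pieces$left_ov[chain[1]], pieces$right_ov[last]))
    }
  }
  ## remaining unused fragments form circles
  while (any(!used)) {
    i <- which(!used)[1]
    chain <- walk(i)
    if (pieces$right_ov[chain[length(chain)]] == pieces$left_ov[chain[1]]) {
      products <- c(products, assemble(chain))
      circular <- c(circular, TRUE)
    } else {
      products <- c(products, assemble(chain))
      circular <- c(circular, FALSE)
      diagnostics <- c(diagnostics, sprintf(
        "dead-end junction at overhang %s",
        pieces$right_ov[chain[length(chain)]]))
    }
  }
  list(products = products, circular = circular, ambiguous = ambiguous,
       diagnostics = diagnostics)
}
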