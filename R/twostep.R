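## Hierarchical two-step assembly planning.
##
## Large targets (multi-kb) are split into ~1 kb "step-one" blocks at
## hingeset junctions; each block is synthesized from BbsI-flanked oligos
## and, once sequence-verified, the BsmBI-flanked blocks reassemble into
## the final part. The enzyme hierarchy is fixed: BbsI (oligos -> blocks),
## BsmBI (blocks -> part / cloning), BsaI (downstream part reuse, recorded
## as flank metadata on the final construct).

## Pads around BsmBI flanks chosen so each flanked block's termini are
## admissible overhangs (non-palindromic, not rc of each other).
BLOCK_PAD_LEFT <- "AA"
BLOCK_PAD_RIGHT <- "AG"

block_flank <- function(payload) {
  e <- get_enzyme("BsmBI")
  paste0(BLOCK_PAD_LEFT, e$site, "A", payload,
         "T", revcomp(e$site), BLOCK_PAD_RIGHT)
}

#' Plan a two-step assembly
#'
#' Splits the prepared part (`A + cds + GCTT`, terminal AATG/GCTT
#' overhangs) into `round(length / target_block_length)` blocks (minimum 1)
#' at hingeset junctions using the fragmenter at block scale, then computes
#' a BbsI oligo-level [fragment_sequence()] plan for each BsmBI-flanked
#' block. BsaI adapter flanks for downstream part reuse are recorded as
#' metadata (`bsai_flanks`), outside the tiled region.
#'
#' @param cds Domesticated CDS string.
#' @param hingeset A `hingeset` constraining junctions at both levels.
#' @param m A symmetrized `overhang_matrix`.
#' @param target_block_length Target block payload length (default 1050).
#' @param oligo_budget Maximum oligo length (default 250).
#' @param radius Junction search radius at both levels (default 30).
#' @param target_id Identifier.
#' @return A `two_step_plan`: `target_id`, `prepared_sequence`, `blocks`
#'   (data frame: span, junction overhangs, flanked sequence),
#'   `per_block_fragment_plans`, `predicted_block_fidelity`, `bsai_flanks`.
#' @export
plan_two_step <- function(cds, hingeset, m, target_block_length = 1050L,
                          oligo_budget = OLIGO_BUDGET, radius = 30L,
                          target_id = "target") {
  if (!is_symmetrized(m)) m <- symmetrize_matrix(m)
  prepared <- prepare_cds_part(validate_cds(cds))
  L <- nchar(prepared)
  n_blocks <- max(1L, as.integer(round(L / target_block_length)))
  max_payload <- oligo_budget - 52L

  ## block-level fragmentation (payload budget inactive at this scale)
  block_plan <- fragment_sequence(
    prepared, hingeset, m, max_payload = L + 4L, radius = radius,
    n_fragments = n_blocks, target_id = paste0(target_id, "_blocks"))

  blocks <- data.frame(
    block = seq_along(block_plan$fragments),
    start = c(0L, block_plan$cut_positions),
    end = c(block_plan$cut_positions + 4L, L),
    left_ov = block_plan$overhangs[-length(block_plan$overhangs)],
    right_ov = block_plan$overhangs[-1],
    payload = block_plan$fragments,
    stringsAsFactors = FALSE)
  blocks$flanked <- vapply(blocks$payload, block_flank, character(1),
                           USE.NAMES = FALSE)

  per_block <- lapply(seq_len(nrow(blocks)), function(i) {
    fl <- blocks$flanked[i]
    terms <- c(substr(fl, 1, 4), substr(fl, nchar(fl) - 3L, nchar(fl)))
    fragment_sequence(fl, hingeset, m, max_payload = max_payload,
                      radius = radius, terminal_overhangs = terms,
                      target_id = sprintf("%s_block%02d", target_id, i))
  })

  structure(list(
    target_id = target_id,
    prepared_sequence = prepared,
    blocks = blocks,
    per_block_fragment_plans = per_block,
    predicted_block_fidelity = block_plan$predicted_fidelity,
    bsai_flanks = c(
      upstream = paste0("AA", TYPE_IIS_ENZYMES$BsaI$site, "T"),
      downstream = paste0("A", revcomp(TYPE_IIS_ENZYMES$BsaI$site), "AA")),
    constraining_set = block_plan$constraining_set
  ), class = "two_step_plan")
}

#' @export
print.two_step_plan <- function(x, ...) {
  cat(sprintf(
    "two_step_plan %s: %d blocks (%d-%d nt payloads), block fidelity %.4f\n",
    x$target_id, nrow(x$blocks), min(nchar(x$blocks$payload)),
    max(nchar(x$blocks$payload)), x$predicted_block_fidelity))
  cat(sprintf("  oligos per block: %s\n",
              paste(vapply(x$per_block_fragment_plans,
                           function(p) length(p$fragments), 1L),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate a two-step assembly end to end
#'
#' Step one: per block, lay out BbsI oligos and digest-ligate them; the
#' product must equal the BsmBI-flanked block. Step two: digest-ligate the
#' flanked blocks with BsmBI; the product must equal the prepared part.
#'
#' @param plan A `two_step_plan`.
#' @param index_pairs Optional matrix of index pairs, one row per block
#'   (defaults to generated primers, seeded).
#' @param seed Seed for default index-primer generation.
#' @return List: `final_sequence`, `ok` (logical), `diagnostics`
#'   (per-step character messages).
#' @export
simulate_two_step <- function(plan, index_pairs = NULL, seed = 1) {
  n <- nrow(plan$blocks)
  if (is.null(index_pairs)) {
    cand <- generate_primer_candidates(2L * n, seed = derive_seed(seed, 11L))
    index_pairs <- matrix(cand$sequence, ncol = 2L, byrow = TRUE)
  }
  diagnostics <- character(0)
  step_one <- character(n)
  ok <- TRUE
  for (i in seq_len(n)) {
    oligos <- layout_oligos(plan$per_block_fragment_plans[[i]],
                            enzyme = "BbsI", index_pair = index_pairs[i, ])
    res <- digest_ligate(oligos$full_sequence, "BbsI")
    if (length(res$products) != 1L ||
        res$products[1] != plan$blocks$flanked[i]) {
      ok <- FALSE
      diagnostics <- c(diagnostics, sprintf(
        "step one failed for block %d: %s", i,
        paste(res$diagnostics, collapse = "; ")))
    }
    step_one[i] <- if (length(res$products)) res$products[1] else ""
  }
  res2 <- digest_ligate(step_one[nzchar(step_one)], "BsmBI")
  final <- if (length(res2$products) == 1L) res2$products[1] else NA_character_
  if (is.na(final) || final != plan$prepared_sequence) {
    ok <- FALSE
    ## locate the first junction where the assembled product diverges
    msg <- if (res2$ambiguous) "ambiguous step-two assembly" else {
      bad <- which(vapply(seq_len(n - 1L), function(j) {
        expected <- plan$blocks$right_ov[j]
        !grepl(expected, if (is.na(final)) "" else final, fixed = TRUE)
      }, logical(1)))
      sprintf("misassembly at block junction(s): %s",
              paste(if (length(bad)) bad else "?", collapse = ", "))
    }
    diagnostics <- c(diagnostics,
                     paste("step two:", msg,
                           paste(res2$diagnostics, collapse = "; ")))
  }
  list(final_sequence = final, ok = ok, diagnostics = diagnostics)
}
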