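## Desk-scale amplicon validation: simulate barcoded noisy reads,
## demultiplex, align, call a consensus, and classify clones.
##
## The contract is verdict-level correctness on simulations with known
## ground truth, not numerical parity with any production long-read stack.
## Consensus is reference-anchored plurality: amplicons have a known
## expected sequence, so de novo assembly is unnecessary.

#' Per-base sequencing error model
#'
#' Independent per-base substitution, insertion and deletion rates
#' (nanopore-like when a few percent).
#'
#' @param substitution_rate,insertion_rate,deletion_rate Fractions in
#'   `[0, 0.2]`.
#' @return An `error_model` list.
#' @export
error_model <- function(substitution_rate = 0.02, insertion_rate = 0.005,
                        deletion_rate = 0.005) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  stopifnot(all(rates >= 0), all(rates <= 0.2))
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate),
            class = "error_model")
}

apply_errors <- function(seq, model) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  sub <- stats::runif(n) < model$substitution_rate
  if (any(sub)) {
    bases[sub] <- vapply(bases[sub], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  del <- stats::runif(n) < model$deletion_rate
  ins <- stats::runif(n) < model$insertion_rate
  out <- bases
  out[del] <- ""
  if (any(ins)) {
    out[ins] <- paste0(out[ins],
                       sample(DNA_BASES, sum(ins), replace = TRUE))
  }
  paste(out, collapse = "")
}

#' Simulate barcoded amplicon reads
#'
#' Each read is `fwd_barcode + template + rc(rev_barcode)` with i.i.d.
#' per-base errors at the model rates, on a random strand.
#'
#' @param template Amplicon (insert) sequence.
#' @param barcode_pair Character vector `c(fwd, rev)`.
#' @param model An [error_model()].
#' @param n_reads Number of reads (>= 1).
#' @param seed Integer seed.
#' @param clone_id Read name prefix.
#' @return Data frame: `id`, `seq`, `strand`.
#' @export
simulate_reads <- function(template, barcode_pair, model = error_model(),
                           n_reads, seed = 1, clone_id = "clone") {
  stopifnot(n_reads >= 1L)
  amplicon <- paste0(barcode_pair[1], template, revcomp(barcode_pair[2]))
  with_seed(seed, {
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- vapply(seq_len(n_reads), function(i) {
      r <- apply_errors(amplicon, model)
      if (strands[i] == "-") revcomp(r) else r
    }, character(1))
    data.frame(id = sprintf("%s_read%04d", clone_id, seq_len(n_reads)),
               seq = seqs, strand = strands, stringsAsFactors = FALSE)
  })
}

#' Write reads as FASTQ (flat quality)
#' @param reads Data frame from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+",
                           vapply(nchar(reads$seq),
                                  function(n) strrep("I", n), "")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a reads data frame
#' @param path FASTQ path.
#' @return Data frame: `id`, `seq`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  ids <- sub("^@", "", lines[seq(1, length(lines), 4L)])
  data.frame(id = sub("\\s.*", "", ids),
             seq = toupper(lines[seq(2, length(lines), 4L)]),
             stringsAsFactors = FALSE)
}

#' Demultiplex reads by terminal barcodes
#'
#' A read is assigned to pair `(i, j)` iff its leading 18 nt match forward
#' barcode `i` and its trailing 18 nt match `rc(rev barcode j)` within
#' `max_distance` edits, in either read orientation; anything else (or any
#' second barcode also within threshold) is unassigned. Requires the
#' barcode set's minimum pairwise distance to exceed `2 * max_distance`,
#' which makes within-threshold matches unique.
#'
#' @param reads Data frame with `id`, `seq`.
#' @param barcode_pairs Data frame or matrix with columns
#'   `fwd_barcode`, `rev_barcode` (one row per clone), or a list of pairs.
#' @param max_distance Maximum edit distance per barcode (default 3).
#' @return `reads` with added columns `pair` (row index into
#'   `barcode_pairs`, NA when unassigned) and `orientation`.
#' @export
demultiplex <- function(reads, barcode_pairs, max_distance = 3L) {
  bp <- as.data.frame(barcode_pairs, stringsAsFactors = FALSE)
  if (!all(c("fwd_barcode", "rev_barcode") %in% names(bp))) {
    names(bp)[1:2] <- c("fwd_barcode", "rev_barcode")
  }
  all_bc <- unique(c(bp$fwd_barcode, bp$rev_barcode))
  if (length(all_bc) > 1L) {
    dmin <- min(utils::adist(all_bc)[upper.tri(diag(length(all_bc)))])
    if (dmin <= 2L * max_distance) {
      stop(sprintf(
        "barcode set min pairwise distance %d must exceed 2 x max_distance = %d",
        dmin, 2L * max_distance), call. = FALSE)
    }
  }
  bl <- nchar(bp$fwd_barcode[1])
  match_end <- function(window, barcodes) {
    d <- as.integer(utils::adist(window, barcodes))
    hits <- which(d <= max_distance)
    if (length(hits) == 1L) hits else NA_integer_
  }
  pair <- integer(nrow(reads))
  orient <- character(nrow(reads))
  for (r in seq_len(nrow(reads))) {
    assigned <- NA_integer_
    ori <- NA_character_
    for (o in c("+", "-")) {
      s <- if (o == "+") reads$seq[r] else revcomp(reads$seq[r])
      if (nchar(s) < 2L * bl) next
      f <- match_end(substr(s, 1, bl), bp$fwd_barcode)
      b <- match_end(substr(s, nchar(s) - bl + 1L, nchar(s)),
                     revcomp(bp$rev_barcode))
      if (!is.na(f) && !is.na(b) && f == b) {
        if (!is.na(assigned) && assigned != f) {
          assigned <- NA_integer_  # ambiguous across orientations
          break
        }
        assigned <- f
        ori <- o
      }
    }
    pair[r] <- assigned
    orient[r] <- ori
  }
  reads$pair <- pair
  reads$orientation <- orient
  reads
}

#' Globally align a read or consensus to its reference
#'
#' Optimal global edit-distance alignment (match 0, mismatch/indel -1, no
#' gap-opening surcharge), reporting edits and reference coverage.
#'
#' @param query Query sequence.
#' @param reference Reference sequence.
#' @return List: `edit_distance`, `coverage` (fraction of reference bases
#'   not deleted), `aligned_query`, `aligned_reference`.
#' @export
align_to_reference <- function(query, reference) {
  stopifnot(nchar(query) > 0L, nchar(reference) > 0L)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(reference),
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 1,
    type = "global")
  ap <- as.character(Biostrings::alignedPattern(al))
  as <- as.character(Biostrings::alignedSubject(al))
  pa <- strsplit(ap, "", fixed = TRUE)[[1]]
  sa <- strsplit(as, "", fixed = TRUE)[[1]]
  deleted <- sum(pa == "-" & sa != "-")
  list(edit_distance = as.integer(-Biostrings::score(al)),
       coverage = 1 - deleted / nchar(reference),
       aligned_query = ap, aligned_reference = as)
}

## Per-reference-position calls from one alignment: list(calls = character
## vector length nchar(ref) ("-" = deleted), inserts = named list of
## insertion strings keyed by reference position they follow).
alignment_calls <- function(aligned_query, aligned_reference) {
  pa <- strsplit(aligned_query, "", fixed = TRUE)[[1]]
  sa <- strsplit(aligned_reference, "", fixed = TRUE)[[1]]
  ref_len <- sum(sa != "-")
  calls <- character(ref_len)
  inserts <- list()
  pos <- 0L
  pending_ins <- ""
  for (k in seq_along(sa)) {
    if (sa[k] == "-") {
      if (pa[k] != "-") pending_ins <- paste0(pending_ins, pa[k])
    } else {
      if (nzchar(pending_ins)) {
        inserts[[as.character(pos)]] <- pending_ins
        pending_ins <- ""
      }
      pos <- pos + 1L
      calls[pos] <- pa[k]
    }
  }
  if (nzchar(pending_ins)) inserts[[as.character(pos)]] <- pending_ins
  list(calls = calls, inserts = inserts)
}

#' Build a consensus from assigned reads and classify the clone
#'
#' Reads are oriented, barcode-trimmed, length-filtered (within 20% of the
#' expected amplicon length), and globally aligned to the reference; the
#' consensus is the per-position plurality call (deletions and majority
#' insertions included). Categories: `unassigned` (< `min_reads` usable
#' reads), `misassembled` (reference coverage below `coverage_floor` or
#' plan junction flanks absent/out of order), `error_free` (consensus
#' equals reference), else `correct_with_errors` with the variant list.
#'
#' @param reads Demultiplexed reads of one clone (data frame with `seq`,
#'   `orientation`; unoriented reads are re-oriented against the
#'   reference).
#' @param reference Expected amplicon (insert) sequence.
#' @param plan Optional `fragment_plan` for junction-order checking.
#' @param barcode_pair `c(fwd, rev)` used to trim terminal barcodes.
#' @param min_reads Minimum usable reads (default 5).
#' @param coverage_floor Minimum reference coverage (default 0.98).
#' @param clone_id Identifier for the verdict.
#' @return A `clone_verdict`: `clone_id`, `category`, `variants` (data
#'   frame: position, ref, alt), `coverage_fraction`, `supporting_reads`,
#'   `consensus`.
#' @export
consensus_and_classify <- function(reads, reference, plan = NULL,
                                   barcode_pair = NULL, min_reads = 5L,
                                   coverage_floor = 0.98,
                                   clone_id = "clone") {
  bl <- if (is.null(barcode_pair)) 0L else nchar(barcode_pair[1])
  expected_len <- nchar(reference) + 2L * bl
  usable <- list()
  for (r in seq_len(nrow(reads))) {
    s <- reads$seq[r]
    ori <- if ("orientation" %in% names(reads)) reads$orientation[r] else NA
    if (!is.na(ori) && ori == "-") s <- revcomp(s)
    if (abs(nchar(s) - expected_len) > 0.2 * expected_len) next
    if (bl > 0L) s <- substr(s, bl + 1L, nchar(s) - bl)
    usable[[length(usable) + 1L]] <- s
  }
  if (length(usable) < min_reads) {
    return(new_clone_verdict(clone_id, "unassigned", empty_variants(),
                             0, length(usable), NA_character_))
  }
  aligns <- lapply(usable, align_to_reference, reference = reference)
  call_list <- lapply(aligns, function(a) {
    alignment_calls(a$aligned_query, a$aligned_reference)
  })
  ref_len <- nchar(reference)
  call_mat <- do.call(rbind, lapply(call_list, `[[`, "calls"))
  consensus_calls <- apply(call_mat, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  })
  ## majority insertions
  ins_all <- unlist(lapply(call_list, function(cl) names(cl$inserts)))
  ins_cons <- list()
  if (length(ins_all)) {
    for (p in unique(ins_all)) {
      strs <- vapply(call_list, function(cl) {
        x <- cl$inserts[[p]]
        if (is.null(x)) "" else x
      }, character(1))
      tab <- sort(table(strs), decreasing = TRUE)
      top <- names(tab)[1]
      if (nzchar(top) && tab[1] > length(call_list) / 2) {
        ins_cons[[p]] <- top
      }
    }
  }
  pieces <- consensus_calls
  pieces[pieces == "-"] <- ""
  for (p in names(ins_cons)) {
    i <- as.integer(p)
    if (i == 0L) pieces[1] <- paste0(ins_cons[[p]], pieces[1])
    else pieces[i] <- paste0(pieces[i], ins_cons[[p]])
  }
  consensus <- paste(pieces, collapse = "")
  covered <- mean(consensus_calls != "-")

  ## variants vs reference
  ref_bases <- strsplit(reference, "", fixed = TRUE)[[1]]
  variants <- empty_variants()
  subs <- which(consensus_calls != "-" & consensus_calls != ref_bases)
  for (i in subs) {
    variants <- rbind(variants, data.frame(
      position = i, ref = ref_bases[i], alt = consensus_calls[i],
      stringsAsFactors = FALSE))
  }
  dels <- which(consensus_calls == "-")
  for (i in dels) {
    variants <- rbind(variants, data.frame(
      position = i, ref = ref_bases[i], alt = "-", stringsAsFactors = FALSE))
  }
  for (p in names(ins_cons)) {
    variants <- rbind(variants, data.frame(
      position = as.integer(p), ref = "-", alt = ins_cons[[p]],
      stringsAsFactors = FALSE))
  }
  variants <- variants[order(variants$position), , drop = FALSE]

  structural_ok <- covered >= coverage_floor
  if (structural_ok && !is.null(plan) && length(plan$cut_positions)) {
    ## every junction's flanking 20-mer must occur, in order, in the
    ## consensus; fuzzy matching tolerates residual point errors without
    ## masking a dropped or reordered fragment
    flank <- 20L
    last_hit <- 0L
    for (cp in plan$cut_positions) {
      lo <- max(1L, cp + 2L - flank %/% 2L)
      probe <- substr(plan$sequence, lo, lo + flank - 1L)
      hit <- utils::aregexec(probe, consensus, max.distance = 4L,
                             fixed = TRUE)[[1]][1]
      if (hit < 0L || hit < last_hit) {
        structural_ok <- FALSE
        break
      }
      last_hit <- hit
    }
  }
  category <- if (!structural_ok) "misassembled"
  else if (consensus == reference) "error_free"
  else "correct_with_errors"
  new_clone_verdict(clone_id, category, variants, covered,
                    length(usable), consensus)
}

empty_variants <- function() {
  data.frame(position = integer(0), ref = character(0), alt = character(0),
             stringsAsFactors = FALSE)
}

new_clone_verdict <- function(clone_id, category, variants, coverage,
                              supporting_reads, consensus) {
  structure(list(clone_id = clone_id, category = category,
                 variants = variants, coverage_fraction = coverage,
                 supporting_reads = supporting_reads, consensus = consensus),
            class = "clone_verdict")
}

#' @export
print.clone_verdict <- function(x, ...) {
  cat(sprintf("clone_verdict %s: %s (%d reads, coverage %.3f, %d variants)\n",
              x$clone_id, x$category, x$supporting_reads,
              x$coverage_fraction, nrow(x$variants)))
  invisible(x)
}

#' Summarize a validation run
#'
#' @param verdicts List of `clone_verdict`s.
#' @param targets Optional character vector mapping each verdict to its
#'   target (defaults to the clone id prefix before the last `_`).
#' @return List: `counts` (per category), `fractions`, `per_target` (data
#'   frame with per-target fractions and an `any_error_free` flag),
#'   `n_clones`.
#' @export
summarize_run <- function(verdicts, targets = NULL) {
  cats <- c("error_free", "correct_with_errors", "misassembled", "unassigned")
  if (!length(verdicts)) {
    counts <- stats::setNames(rep(0L, length(cats)), cats)
    return(list(counts = counts, fractions = counts, n_clones = 0L,
                per_target = data.frame()))
  }
  got <- vapply(verdicts, `[[`, "", "category")
  ids <- vapply(verdicts, `[[`, "", "clone_id")
  if (is.null(targets)) targets <- sub("_[^_]*$", "", ids)
  counts <- stats::setNames(vapply(cats, function(k) sum(got == k), 0L), cats)
  fractions <- counts / length(verdicts)
  per_target <- do.call(rbind, lapply(unique(targets), function(tg) {
    g <- got[targets == tg]
    data.frame(target = tg, n = length(g),
               error_free = mean(g == "error_free"),
               correct = mean(g %in% c("error_free", "correct_with_errors")),
               any_error_free = any(g == "error_free"),
               stringsAsFactors = FALSE)
  }))
  list(counts = counts, fractions = fractions, per_target = per_target,
       n_clones = length(verdicts))
}

#' Write a run summary as TSV + JSON
#' @param summary Output of [summarize_run()].
#' @param dir Output directory.
#' @return Paths, invisibly.
#' @export
write_run_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "per_target.tsv")
  utils::write.table(summary$per_target, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, "run_summary.json")
  jsonlite::write_json(
    list(counts = as.list(summary$counts),
         fractions = as.list(summary$fractions),
         n_clones = summary$n_clones),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
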