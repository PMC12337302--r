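## Constrained fragmentation of a target at hingeset junctions.
##
## A target (already domesticated, with terminal part overhangs as its
## first and last 4 nt) is cut into n fragments overlapping by exactly 4 nt
## at junctions whose 4-mers are drawn from a constraining hingeset, each
## junction within `radius` of the ideal equidistant position. Junction
## assignment is a depth-first branch-and-bound: because adding overhangs
## can only lower set fidelity, the fidelity of a partial assignment is an
## upper bound on any completion, so the search maximizes predicted plan
## fidelity exactly (ties broken by total offset from ideal positions, then
## lexicographic overhang order).

#' Add standard part termini to a CDS
#'
#' Prepends `A` (completing the AATG start-codon overhang) and appends
#' `GCTT` after the stop, yielding the standard coding-sequence part layout
#' whose first and last 4 nt are the fixed terminal overhangs.
#'
#' @param cds CDS string beginning with ATG.
#' @return DNA string `A + cds + GCTT`.
#' @export
prepare_cds_part <- function(cds) {
  cds <- toupper(cds)
  if (substr(cds, 1, 3) != "ATG") {
    stop("CDS must begin with ATG to form the AATG terminal overhang",
         call. = FALSE)
  }
  paste0("A", cds, "GCTT")
}

#' Candidate junction positions near an ideal cut site
#'
#' All 0-based positions `p` with `|p - ideal_pos| <= radius` whose 4-mer
#' `seq[p, p+4)` is usable: a member of `allowed` (either orientation),
#' non-palindromic, and neither a member nor a reverse complement of
#' `taken`.
#'
#' @param seq DNA string.
#' @param ideal_pos 0-based target position.
#' @param radius Search radius in bp (>= 0).
#' @param allowed An `overhang_set` or character vector of allowed 4-mers.
#' @param taken Overhangs already used (character vector or `overhang_set`).
#' @return Data frame (`position`, `overhang`, `offset`) sorted by
#'   `|offset|` ascending, then position. May be empty.
#' @export
candidate_junctions <- function(seq, ideal_pos, radius, allowed,
                                taken = character(0)) {
  stopifnot(ideal_pos >= 0, ideal_pos < nchar(seq), radius >= 0)
  allowed <- if (inherits(allowed, "overhang_set")) allowed$members
             else toupper(allowed)
  taken <- if (inherits(taken, "overhang_set")) taken$members
           else toupper(taken)
  usable <- unique(c(allowed, revcomp(allowed)))
  blocked <- unique(c(taken, revcomp(taken)))
  lo <- max(0L, ideal_pos - as.integer(radius))
  hi <- min(nchar(seq) - 4L, ideal_pos + as.integer(radius))
  if (lo > hi) {
    return(data.frame(position = integer(0), overhang = character(0),
                      offset = integer(0), stringsAsFactors = FALSE))
  }
  p <- lo:hi
  ov <- substring(seq, p + 1L, p + 4L)
  keep <- ov %in% usable & !ov %in% blocked & !is_palindromic(ov)
  out <- data.frame(position = p[keep], overhang = ov[keep],
                    offset = p[keep] - as.integer(ideal_pos),
                    stringsAsFactors = FALSE)
  out[order(abs(out$offset), out$position), , drop = FALSE]
}

#' Fragment a target under a constraining hingeset
#'
#' @param seq DNA string whose first and last 4 nt equal
#'   `terminal_overhangs` (see [prepare_cds_part()]); must be free of the
#'   assembly enzymes' recognition sites.
#' @param hingeset A `hingeset` (or `overhang_set`) constraining internal
#'   junction overhangs.
#' @param m A symmetrized `overhang_matrix`.
#' @param max_payload Maximum fragment span including both flanking
#'   overhangs (default 198 nt = 250-nt oligo budget minus 52 nt of index
#'   and cut sequence).
#' @param radius Junction search radius around the ideal equidistant
#'   positions (default 30 bp).
#' @param terminal_overhangs Length-2 character vector of the 5' and 3'
#'   terminal overhangs (default AATG/GCTT).
#' @param n_fragments Force a fragment count (default: minimal count
#'   satisfying the payload budget, incremented if the search fails).
#' @param target_id Identifier recorded in the plan.
#' @return A `fragment_plan`: list with `target_id`, `cut_positions`
#'   (0-based overhang starts), `overhangs` (terminal + internal, in
#'   order), `fragments` (payloads overlapping neighbors by 4 nt),
#'   `predicted_fidelity`, `constraining_set`, `max_payload`.
#' @export
fragment_sequence <- function(seq, hingeset, m, max_payload = 198L,
                              radius = 30L,
                              terminal_overhangs = FIXED_OVERHANGS,
                              n_fragments = NULL, target_id = "target") {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (!is_symmetrized(m)) m <- symmetrize_matrix(m)
  hset <- if (inherits(hingeset, "hingeset")) hingeset$set else hingeset
  if (substr(seq, 1, 4) != terminal_overhangs[1] ||
      substr(seq, L - 3L, L) != terminal_overhangs[2]) {
    stop(sprintf(
      "sequence termini (%s...%s) do not match the terminal overhangs %s/%s; see prepare_cds_part()",
      substr(seq, 1, 4), substr(seq, L - 3L, L),
      terminal_overhangs[1], terminal_overhangs[2]), call. = FALSE)
  }
  n_min <- if (is.null(n_fragments)) {
    max(1L, as.integer(ceiling((L - 4L) / (max_payload - 4L))))
  } else as.integer(n_fragments)
  n_max <- if (is.null(n_fragments)) n_min + 3L else n_min
  last_err <- NULL
  for (n in n_min:n_max) {
    sol <- try(solve_junctions(seq, n, hset, m, max_payload, radius,
                               terminal_overhangs), silent = TRUE)
    if (!inherits(sol, "try-error")) {
      return(build_plan(seq, sol, m, hset, max_payload, target_id))
    }
    last_err <- attr(sol, "condition")$message
  }
  stop(last_err, call. = FALSE)
}

## Branch-and-bound junction assignment. Returns list(positions, overhangs)
## for the n-1 internal junctions (possibly empty for n = 1).
##
## Two admissible prunes keep the search exact and fast: (1) adding
## overhangs can only lower set fidelity, so a partial assignment's
## fidelity bounds any completion; (2) on fidelity ties, a lower bound on
## the remaining offset sum bounds the offset tie-break key. Junction
## fidelities are maintained incrementally over integer-indexed counts.
solve_junctions <- function(seq, n, hset, m, max_payload, radius,
                            terminal_overhangs) {
  L <- nchar(seq)
  if (n == 1L) {
    if (L > max_payload) stop("single fragment exceeds the payload budget",
                              call. = FALSE)
    return(list(positions = integer(0), overhangs = character(0)))
  }
  ideal <- round((1:(n - 1L)) * L / n)
  cand <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    cand[[i]] <- candidate_junctions(seq, ideal[i], radius, hset$members,
                                     taken = terminal_overhangs)
    if (!nrow(cand[[i]])) {
      stop(sprintf(
        "no admissible junction in window [%d, %d] around position %d; increase the radius or use a larger hingeset",
        max(0, ideal[i] - radius), ideal[i] + radius, ideal[i]),
        call. = FALSE)
    }
  }
  kmers <- all_overhangs()
  mm <- unclass(m)
  dimnames(mm) <- NULL
  rc_of <- match(revcomp(kmers), kmers)
  to_int <- function(x) match(x, kmers)
  ## lower bound on the offset-sum contribution of junctions i..n-1
  min_rem <- rev(cumsum(rev(vapply(cand, function(d) min(abs(d$offset)),
                                   numeric(1)))))
  min_rem <- c(min_rem, 0)

  ## state: member ints (terminals first), per-member on-target and
  ## denominator tallies over the current pool
  init_members <- to_int(terminal_overhangs)
  add_member <- function(members, on, denom, x) {
    rx <- rc_of[x]
    rc_mem <- rc_of[members]
    denom <- denom + mm[cbind(members, x)] + mm[cbind(members, rx)] +
      mm[cbind(rc_mem, x)] + mm[cbind(rc_mem, rx)]
    pool <- unique(c(members, rc_mem, x, rx))
    on_x <- mm[x, rx] + mm[rx, x]
    denom_x <- sum(mm[x, pool]) + sum(mm[rx, pool])
    list(members = c(members, x), on = c(on, on_x),
         denom = c(denom, denom_x))
  }
  state0 <- list(members = init_members[1], on = numeric(0),
                 denom = numeric(0))
  state0 <- {
    x <- init_members[1]
    rx <- rc_of[x]
    list(members = x, on = mm[x, rx] + mm[rx, x],
         denom = sum(mm[x, c(x, rx)]) + sum(mm[rx, c(x, rx)]))
  }
  state0 <- add_member(state0$members, state0$on, state0$denom,
                       init_members[2])
  if (any(state0$denom == 0)) {
    stop("terminal overhang has no ligation signal", call. = FALSE)
  }

  best <- new.env(parent = emptyenv())
  best$fid <- -1
  best$off <- Inf
  best$sol <- NULL
  nodes <- 0L
  node_cap <- 2000000L
  eps <- 1e-12

  recurse <- function(i, positions, state, off_so_far) {
    if (i > n - 1L) {
      prev <- positions[length(positions)]
      if ((L - prev) > max_payload) return(invisible(NULL))
      fid <- prod(state$on / state$denom)
      if (fid > best$fid + eps ||
          (fid >= best$fid - eps && off_so_far < best$off)) {
        best$fid <- fid
        best$off <- off_so_far
        best$sol <- list(positions = positions,
                         overhangs = kmers[state$members[-(1:2)]])
      }
      return(invisible(NULL))
    }
    prev <- if (length(positions)) positions[length(positions)] else 0L
    ci <- cand[[i]]
    min_next <- L - max_payload - (n - 1L - i) * (max_payload - 4L)
    ok <- ci$position >= prev + 4L &
      (ci$position + 4L - prev) <= max_payload &
      ci$position >= min_next
    ci <- ci[ok, , drop = FALSE]
    for (r in seq_len(nrow(ci))) {
      nodes <<- nodes + 1L
      if (nodes > node_cap) return(invisible(NULL))
      x <- match(ci$overhang[r], kmers)
      if (x %in% state$members || rc_of[x] %in% state$members) next
      st <- add_member(state$members, state$on, state$denom, x)
      if (any(st$denom == 0)) next
      fid <- prod(st$on / st$denom)
      off <- off_so_far + abs(ci$offset[r])
      if (fid < best$fid - eps) next
      if (fid <= best$fid + eps && off + min_rem[i + 1L] >= best$off) next
      recurse(i + 1L, c(positions, ci$position[r]), st, off)
    }
    invisible(NULL)
  }
  recurse(1L, integer(0), state0, 0)
  if (is.null(best$sol)) {
    stop(sprintf(
      "no junction assignment satisfies the payload budget at n = %d; increase the radius or use a larger hingeset", n),
      call. = FALSE)
  }
  best$sol
}

build_plan <- function(seq, sol, m, hset, max_payload, target_id) {
  L <- nchar(seq)
  cuts <- sol$positions
  starts <- c(0L, cuts)
  ends <- c(cuts + 4L, L)
  fragments <- substring(seq, starts + 1L, ends)
  overhangs <- c(substr(seq, 1, 4), sol$overhangs,
                 substr(seq, L - 3L, L))
  plan <- structure(list(
    target_id = target_id,
    cut_positions = cuts,
    overhangs = overhangs,
    fragments = fragments,
    predicted_fidelity = set_fidelity(unique(overhangs), m),
    constraining_set = hset,
    max_payload = as.integer(max_payload),
    sequence = seq
  ), class = "fragment_plan")
  stopifnot(reassemble_plan(plan) == seq)
  plan
}

#' Collapse a plan's fragments back into the target sequence
#' @param plan A `fragment_plan`.
#' @return DNA string (4-nt overlaps collapsed).
#' @export
reassemble_plan <- function(plan) {
  f <- plan$fragments
  paste0(f[1], paste(substring(f[-1], 5L), collapse = ""))
}

#' @export
print.fragment_plan <- function(x, ...) {
  cat(sprintf(
    "fragment_plan %s: %d fragments (%s nt), predicted fidelity %.4f\n",
    x$target_id, length(x$fragments),
    paste(range(nchar(x$fragments)), collapse = "-"),
    x$predicted_fidelity))
  cat("  overhangs:", paste(x$overhangs, collapse = " "), "\n")
  invisible(x)
}

#' Serialize a fragment plan to JSON
#' @param plan A `fragment_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  x <- plan[c("target_id", "cut_positions", "overhangs", "fragments",
              "predicted_fidelity", "max_payload")]
  x$constraining_set <- plan$constraining_set$members
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
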