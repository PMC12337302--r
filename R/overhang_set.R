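## Overhang sets and ligation-fidelity scoring.
##
## An overhang set is the collection of 4-nt junction overhangs used in one
## Golden Gate reaction. A junction whose top-strand overhang is `o`
## contributes both `o` and `rc(o)` to the ligation pool, so admissible
## members are non-palindromic and pairwise reverse-complement-distinct.

#' Default fixed overhangs (standard coding-sequence part termini)
#' @export
FIXED_OVERHANGS <- c("AATG", "GCTT")

#' Construct and validate an overhang set
#'
#' @param members Character vector of 4-mers.
#' @param fixed_members 4-mers that must be present (default `AATG`/`GCTT`,
#'   the coding-sequence part termini).
#' @return An `overhang_set` (list with `members`, `fixed_members`).
#' @export
overhang_set <- function(members, fixed_members = FIXED_OVERHANGS) {
  members <- toupper(members)
  fixed_members <- toupper(fixed_members)
  s <- structure(list(members = members, fixed_members = fixed_members),
                 class = "overhang_set")
  problems <- overhang_set_violations(s)
  if (length(problems)) {
    stop("invalid overhang set: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  s
}

## All invariant violations of an overhang set, as character messages
## (empty = valid). Used by both the constructor and validate_hingeset().
overhang_set_violations <- function(s) {
  problems <- character(0)
  mem <- s$members
  if (any(nchar(mem) != 4L) || any(grepl("[^ACGT]", mem))) {
    problems <- c(problems, "members must be 4-mers over A/C/G/T")
    return(problems)
  }
  if (anyDuplicated(mem)) {
    problems <- c(problems, sprintf("duplicate member %s",
                                    mem[duplicated(mem)][1]))
  }
  pal <- mem[is_palindromic(mem)]
  if (length(pal)) {
    problems <- c(problems, sprintf("palindromic member %s", pal[1]))
  }
  rc_hit <- intersect(mem, revcomp(mem))
  rc_hit <- setdiff(rc_hit, pal)
  if (length(rc_hit)) {
    problems <- c(problems,
                  sprintf("members %s and %s are reverse complements",
                          rc_hit[1], revcomp(rc_hit[1])))
  }
  missing_fixed <- setdiff(s$fixed_members, mem)
  if (length(missing_fixed)) {
    problems <- c(problems, sprintf("missing fixed member %s",
                                    missing_fixed[1]))
  }
  problems
}

#' @export
print.overhang_set <- function(x, ...) {
  cat(sprintf("overhang_set: %d members (%s)\n", length(x$members),
              paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Predicted ligation fidelity of one junction within a set
#'
#' The fraction of ligation events involving overhang `o` (either strand
#' orientation) that join its true Watson-Crick partner, given that all
#' members of `s` (and their reverse complements) are present in the
#' reaction pool:
#' `(counts[o, rc(o)] + counts[rc(o), o]) / sum_p (counts[o, p] + counts[rc(o), p])`
#' over the pool `P = members(s) U rc(members(s))`.
#'
#' @param o A member 4-mer of `s`.
#' @param s An `overhang_set`.
#' @param m A symmetrized `overhang_matrix`.
#' @return Fraction in `[0, 1]`.
#' @export
junction_fidelity <- function(o, s, m) {
  o <- toupper(o)
  if (!o %in% s$members) {
    stop(sprintf("overhang %s is not a member of the set", o), call. = FALSE)
  }
  if (!is_symmetrized(m)) {
    stop("matrix must be symmetrized before fidelity scoring", call. = FALSE)
  }
  pool <- unique(c(s$members, revcomp(s$members)))
  mm <- unclass(m)
  on_target <- mm[o, revcomp(o)] + mm[revcomp(o), o]
  denom <- sum(mm[o, pool]) + sum(mm[revcomp(o), pool])
  if (denom == 0) {
    stop(sprintf("overhang %s has no ligation signal", o), call. = FALSE)
  }
  on_target / denom
}

#' Predicted ligation fidelity of a whole overhang set
#'
#' Product of [junction_fidelity()] over all members: the probability that
#' every junction in an assembly using this set ligates to its intended
#' partner. Empty sets score 1 by convention. Adding members can only add
#' mismatch mass, so set fidelity is non-increasing in set size.
#'
#' @param s An `overhang_set` (or character vector of members).
#' @param m A symmetrized `overhang_matrix`.
#' @return Fraction in `[0, 1]`.
#' @export
set_fidelity <- function(s, m) {
  if (is.character(s)) s <- overhang_set(s, fixed_members = character(0))
  if (!is_symmetrized(m)) {
    stop("matrix must be symmetrized before fidelity scoring", call. = FALSE)
  }
  mem <- s$members
  if (!length(mem)) return(1.0)
  pool <- unique(c(mem, revcomp(mem)))
  mm <- unclass(m)
  rcm <- revcomp(mem)
  on_target <- mm[cbind(mem, rcm)] + mm[cbind(rcm, mem)]
  denom <- rowSums(mm[mem, pool, drop = FALSE]) +
    rowSums(mm[rcm, pool, drop = FALSE])
  if (any(denom == 0)) {
    stop(sprintf("overhang %s has no ligation signal", mem[denom == 0][1]),
         call. = FALSE)
  }
  prod(on_target / denom)
}
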