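## Genetic-algorithm optimization of high-fidelity overhang sets
## ("hingesets").
##
## Search space: sets of admissible 4-mers (no palindromes, no two members
## reverse complements of each other) always containing the fixed part
## termini AATG and GCTT. Genome = the member set; tournament selection;
## uniform set crossover (child sampled from the union of both parents,
## fixed members forced); mutation replaces one non-fixed member with a
## random admissible 4-mer; elitism preserves the best individuals. The
## whole run is deterministic given the seed.

#' Genetic-algorithm configuration
#'
#' @param population_size Individuals per generation (>= 2, default 50).
#' @param generations_max Maximum generations (default 500).
#' @param mutation_rate Per-child probability of a mutation (default 0.3).
#' @param elitism Individuals copied unchanged each generation (default 2).
#' @param tournament_size Tournament size for parent selection (default 3).
#' @param stagnation_stop Stop after this many generations without
#'   improvement (default 50).
#' @param seed Integer seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 50L, generations_max = 500L,
                      mutation_rate = 0.3, elitism = 2L,
                      tournament_size = 3L, stagnation_stop = 50L,
                      seed = 1L) {
  stopifnot(population_size >= 2L, mutation_rate > 0, mutation_rate < 1,
            elitism < population_size)
  structure(list(population_size = as.integer(population_size),
                 generations_max = as.integer(generations_max),
                 mutation_rate = mutation_rate, elitism = as.integer(elitism),
                 tournament_size = as.integer(tournament_size),
                 stagnation_stop = as.integer(stagnation_stop),
                 seed = as.integer(seed)),
            class = "ga_config")
}

## Admissible 4-mers: non-palindromic, optionally restricted to an alphabet.
admissible_overhangs <- function(alphabet = all_overhangs()) {
  alphabet[!is_palindromic(alphabet)]
}

## Can `x` join `members` (no duplicate, no rc collision, not palindromic)?
admissible_addition <- function(x, members) {
  !is_palindromic(x) && !x %in% members && !revcomp(x) %in% members
}

#' Optimize a high-fidelity overhang set of a given size
#'
#' @param size Number of members (2..120; 120 is the count of
#'   reverse-complement pairs of non-palindromic 4-mers).
#' @param m A symmetrized `overhang_matrix`.
#' @param cfg A [ga_config()].
#' @param fixed_members Overhangs forced into every set (default
#'   AATG/GCTT).
#' @param alphabet Candidate 4-mers (default all 256; restrict for toy
#'   problems).
#' @return A `hingeset`: list with `set` (an `overhang_set`), `size`,
#'   `fidelity`, `generations_run`, `seed`.
#' @export
optimize_hingeset <- function(size, m, cfg = ga_config(),
                              fixed_members = FIXED_OVERHANGS,
                              alphabet = all_overhangs()) {
  size <- as.integer(size)
  pool <- admissible_overhangs(alphabet)
  if (size < length(fixed_members)) {
    stop("size smaller than the number of fixed members", call. = FALSE)
  }
  if (size > length(pool) / 2) {
    stop(sprintf("size %d infeasible: only %d reverse-complement pairs",
                 size, length(pool) %/% 2L), call. = FALSE)
  }
  if (!is_symmetrized(m)) m <- symmetrize_matrix(m)
  if (size == length(fixed_members)) {
    s <- overhang_set(fixed_members, fixed_members)
    return(new_hingeset(s, set_fidelity(s, m), 0L, cfg$seed))
  }

  fit_cache <- new.env(parent = emptyenv())
  fitness <- function(members) {
    key <- paste(sort(members), collapse = "")
    got <- fit_cache[[key]]
    if (!is.null(got)) return(got)
    f <- set_fidelity(overhang_set(members, fixed_members), m)
    fit_cache[[key]] <- f
    f
  }
  random_set <- function() {
    members <- fixed_members
    while (length(members) < size) {
      x <- sample(pool, 1L)
      if (admissible_addition(x, members)) members <- c(members, x)
    }
    members
  }
  mutate <- function(members) {
    idx <- seq_along(members)[!members %in% fixed_members]
    i <- if (length(idx) == 1L) idx else sample(idx, 1L)
    repeat {
      x <- sample(pool, 1L)
      if (admissible_addition(x, members[-i])) {
        members[i] <- x
        return(members)
      }
    }
  }
  crossover <- function(a, b) {
    u <- unique(c(a, b))
    members <- fixed_members
    for (x in sample(u)) {
      if (length(members) >= size) break
      if (admissible_addition(x, members)) members <- c(members, x)
    }
    while (length(members) < size) {
      x <- sample(pool, 1L)
      if (admissible_addition(x, members)) members <- c(members, x)
    }
    members
  }

  with_seed(cfg$seed, {
    popn <- replicate(cfg$population_size, random_set(), simplify = FALSE)
    fit <- vapply(popn, fitness, numeric(1))
    best_fit <- max(fit)
    stagnant <- 0L
    gens <- 0L
    for (gen in seq_len(cfg$generations_max)) {
      gens <- gen
      ord <- order(fit, decreasing = TRUE)
      new_pop <- popn[ord[seq_len(cfg$elitism)]]
      while (length(new_pop) < cfg$population_size) {
        pa <- tournament(popn, fit, cfg$tournament_size)
        pb <- tournament(popn, fit, cfg$tournament_size)
        child <- crossover(pa, pb)
        if (stats::runif(1) < cfg$mutation_rate) child <- mutate(child)
        new_pop[[length(new_pop) + 1L]] <- child
      }
      popn <- new_pop
      fit <- vapply(popn, fitness, numeric(1))
      if (max(fit) > best_fit + 1e-15) {
        best_fit <- max(fit)
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        if (stagnant >= cfg$stagnation_stop) break
      }
    }
    best <- popn[[which.max(fit)]]
    s <- overhang_set(sort(best), fixed_members)
    new_hingeset(s, set_fidelity(s, m), gens, cfg$seed)
  })
}

tournament <- function(popn, fit, k) {
  i <- sample.int(length(popn), k, replace = TRUE)
  popn[[i[which.max(fit[i])]]]
}

new_hingeset <- function(set, fidelity, generations_run, seed) {
  structure(list(set = set, size = length(set$members),
                 fidelity = fidelity, generations_run = generations_run,
                 seed = seed),
            class = "hingeset")
}

#' @export
print.hingeset <- function(x, ...) {
  cat(sprintf("hingeset: %d overhangs, predicted fidelity %.4f (seed %d)\n",
              x$size, x$fidelity, x$seed))
  cat("  ", paste(x$set$members, collapse = " "), "\n")
  invisible(x)
}

#' Re-validate a hingeset against a matrix
#'
#' Re-checks every overhang-set invariant and recomputes the fidelity.
#' Violations are returned as data, not raised.
#'
#' @param h A `hingeset`.
#' @param m An `overhang_matrix`.
#' @return List: `violations` (character vector, empty when valid) and
#'   `recomputed_fidelity`.
#' @export
validate_hingeset <- function(h, m) {
  if (!is_symmetrized(m)) m <- symmetrize_matrix(m)
  violations <- overhang_set_violations(h$set)
  if (h$size != length(h$set$members)) {
    violations <- c(violations, sprintf("size field %d != %d members",
                                        h$size, length(h$set$members)))
  }
  fid <- tryCatch(set_fidelity(h$set, m), error = function(e) NA_real_)
  if (is.na(fid)) {
    violations <- c(violations, "fidelity not computable under this matrix")
  } else if (abs(fid - h$fidelity) > 1e-9) {
    violations <- c(violations,
                    sprintf("fidelity mismatch: stored %.6f, recomputed %.6f",
                            h$fidelity, fid))
  }
  list(violations = violations, recomputed_fidelity = fid)
}

#' Write hingesets as TSV (size, fidelity, members, seed)
#' @param hingesets List of `hingeset` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hingesets <- function(hingesets, path) {
  df <- do.call(rbind, lapply(hingesets, function(h) {
    data.frame(size = h$size, fidelity = h$fidelity,
               members = paste(h$set$members, collapse = ","),
               seed = h$seed, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read hingesets from TSV
#' @param path TSV written by [write_hingesets()].
#' @return List of `hingeset` objects.
#' @export
read_hingesets <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    members <- strsplit(df$members[i], ",", fixed = TRUE)[[1]]
    new_hingeset(overhang_set(members), df$fidelity[i], NA_integer_,
                 df$seed[i])
  })
}

#' Bundled precomputed hingesets
#'
#' Hingesets of sizes 10-60 optimized against the package's synthetic
#' Watson-Crick-dominant ligation matrix (labelled synthetic; regenerate
#' against a measured matrix for production designs).
#'
#' @return List of `hingeset` objects.
#' @export
bundled_hingesets <- function() {
  path <- system.file("extdata", "hingesets_synthetic.tsv",
                      package = "goldenpool")
  read_hingesets(path)
}
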