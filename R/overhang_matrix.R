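## Ligation-count matrices between all 4-nt overhangs.
##
## The substrate of the fidelity model: a 256 x 256 matrix of observed
## ligation events between every pair of 4-mers (rows and columns are the
## overhang read 5'->3' on each strand). Real data of this shape come from
## multiplexed ligation profiling experiments; `synthetic_ligation_matrix()`
## generates Watson-Crick-dominant stand-ins so every test is self-contained.

#' All 256 overhang 4-mers in lexicographic order
#' @return Character vector of length 256.
#' @export
all_overhangs <- function() {
  g <- expand.grid(b4 = DNA_BASES, b3 = DNA_BASES, b2 = DNA_BASES,
                   b1 = DNA_BASES, stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3, g$b4))
}

#' Is a 4-mer palindromic (its own reverse complement)?
#' @param x Character vector of 4-mers.
#' @return Logical vector.
#' @export
is_palindromic <- function(x) x == revcomp(x)

new_overhang_matrix <- function(counts, symmetrized = FALSE,
                                source_label = "unknown") {
  structure(counts,
            symmetrized = symmetrized,
            source_label = source_label,
            class = c("overhang_matrix", "matrix", "array"))
}

#' Load an all-by-all overhang ligation count matrix
#'
#' Reads a comma- or tab-delimited file whose first column and header row are
#' the 256 overhang 4-mers; cells are non-negative ligation counts. Rows and
#' columns are reordered lexicographically.
#'
#' @param path Path to the CSV/TSV file.
#' @param source_label Free-text provenance recorded on the matrix (e.g. the
#'   ligation condition the counts were collected under).
#' @return An `overhang_matrix`: a 256 x 256 numeric matrix with
#'   `symmetrized` and `source_label` attributes.
#' @export
load_ligation_matrix <- function(path, source_label = basename(path)) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  validate_ligation_counts(m)
  kmers <- all_overhangs()
  m <- m[kmers, kmers]
  storage.mode(m) <- "double"
  new_overhang_matrix(m, symmetrized = FALSE, source_label = source_label)
}

validate_ligation_counts <- function(m) {
  kmers <- all_overhangs()
  for (dim_name in c("row", "column")) {
    labs <- if (dim_name == "row") rownames(m) else colnames(m)
    if (anyDuplicated(labs)) {
      stop(sprintf("duplicate %s label %s", dim_name,
                   labs[duplicated(labs)][1]), call. = FALSE)
    }
    missing <- setdiff(kmers, labs)
    if (length(missing)) {
      stop(sprintf("missing overhang %s (%s)", missing[1], dim_name),
           call. = FALSE)
    }
    extra <- setdiff(labs, kmers)
    if (length(extra)) {
      stop(sprintf("unexpected %s label %s", dim_name, extra[1]),
           call. = FALSE)
    }
  }
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count at [%s, %s]",
                 rownames(m)[idx[1]], colnames(m)[idx[2]]), call. = FALSE)
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at [%s, %s]",
                 rownames(m)[idx[1]], colnames(m)[idx[2]]), call. = FALSE)
  }
  invisible(m)
}

#' Write an overhang matrix as CSV
#' @param m An `overhang_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ligation_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}

#' Symmetrize a ligation matrix across strand orientation
#'
#' Raw all-by-all counts are strand-asymmetric (the two orientations of one
#' physical junction are tallied in different cells). Averaging each cell
#' with its reverse-complement-transposed partner,
#' `counts'[a,b] = (counts[a,b] + counts[rc(b),rc(a)]) / 2`, makes the matrix
#' orientation-consistent before fidelity scoring. Idempotent.
#'
#' @param m An `overhang_matrix`.
#' @return The symmetrized `overhang_matrix` (flag set).
#' @export
symmetrize_matrix <- function(m) {
  stopifnot(inherits(m, "overhang_matrix"))
  kmers <- all_overhangs()
  rc_perm <- match(revcomp(kmers), kmers)
  mm <- unclass(m)
  sym <- (mm + t(mm)[rc_perm, rc_perm]) / 2
  dimnames(sym) <- dimnames(mm)
  new_overhang_matrix(sym, symmetrized = TRUE,
                      source_label = attr(m, "source_label"))
}

is_symmetrized <- function(m) isTRUE(attr(m, "symmetrized"))

#' @export
print.overhang_matrix <- function(x, ...) {
  cat(sprintf("overhang_matrix: 256 x 256 ligation counts (%s)\n",
              attr(x, "source_label")))
  cat(sprintf("  symmetrized: %s | total counts: %.0f | WC fraction: %.4f\n",
              is_symmetrized(x), sum(x), wc_fraction(x)))
  invisible(x)
}

## Fraction of total ligation mass on Watson-Crick cells [o, rc(o)].
wc_fraction <- function(m) {
  kmers <- all_overhangs()
  sum(unclass(m)[cbind(kmers, revcomp(kmers))]) / sum(m)
}
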