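test_that("best_codon mode uses each amino acid's top codon (CAI = 1)", {
  tab <- wobble_codon_table()
  cds <- random_cds(300, 0.5, seed = 8)
  out <- codon_optimize(cds, tab, "best_codon")
  expect_identical(translate_cds(out), translate_cds(cds))
  met <- sequence_metrics(out, tab)
  expect_equal(met$cai, 1.0, tolerance = 1e-12)
  best <- vapply(split(tab, tab$aa),
                 function(d) d$codon[which.max(d$freq)], character(1))
  codons <- goldenpool:::split_codons(out)
  expect_true(all(codons == best[goldenpool:::codon_aa(tab)[codons]]))
})

test_that("match_usage tracks table frequencies closely per amino acid", {
  tab <- random_codon_table(seed = 21)
  set.seed(9)
  protein <- paste(c("M", sample(c("L", "S", "R", "A", "G", "V"), 599,
                                 replace = TRUE)), collapse = "")
  out <- codon_optimize(protein, tab, "match_usage", seed = 3)
  expect_identical(translate_cds(out), protein)
  codons <- goldenpool:::split_codons(out)
  aa_of <- goldenpool:::codon_aa(tab)
  for (a in c("L", "S", "R", "A", "G", "V")) {
    obs <- table(factor(codons[aa_of[codons] == a],
                        levels = tab$codon[tab$aa == a]))
    obs <- as.numeric(obs) / sum(obs)
    l1 <- sum(abs(obs - tab$freq[tab$aa == a]))
    expect_lte(l1, 0.15)
  }
})

test_that("domesticate purges a planted type IIS site with one codon change", {
  tab <- flat_codon_table()
  ## embed GGTCTC on a codon-degenerate frame (GGT CTC = Gly Leu) inside an
  ## otherwise clean random CDS
  base <- random_cds(300, 0.5, seed = 30)
  cds <- goldenpool:::validate_cds(
    paste0(substr(base, 1, 90), "GGTCTC", substr(base, 97, nchar(base))))
  expect_gt(nrow(goldenpool:::find_pattern_hits(cds, "GGTCTC")), 0L)
  out <- domesticate(cds, design_constraints(), tab, seed = 1)
  hits <- goldenpool:::find_pattern_hits(as.character(out),
                                         c("GGTCTC", "CGTCTC", "GAAGAC"))
  expect_equal(nrow(hits), 0L)
  expect_identical(translate_cds(as.character(out)), translate_cds(cds))
  expect_equal(attr(out, "edits"), 1L)
})

test_that("domesticate removes long repeats and inverted repeats", {
  tab <- flat_codon_table()
  base <- random_cds(402, 0.5, seed = 31)
  ## exact internal 30 bp duplication (codon-aligned)
  dup <- paste0(substr(base, 1, 150), substr(base, 61, 90),
                substr(base, 181, nchar(base)))
  dup <- goldenpool:::validate_cds(dup)
  out <- domesticate(dup, design_constraints(), tab, seed = 2)
  expect_equal(nrow(goldenpool:::find_duplicate_kmers(as.character(out), 12)),
               0L)
  expect_identical(translate_cds(as.character(out)), translate_cds(dup))

  ## designed 24 bp inverted repeat ~100 bp apart
  arm <- substr(base, 31, 54)
  hp <- paste0(substr(base, 1, 120), revcomp(arm),
               substr(base, 145, nchar(base)))
  hp <- goldenpool:::validate_cds(hp)
  expect_gt(nrow(goldenpool:::find_hairpins(hp, 20, 250)), 0L)
  out2 <- domesticate(hp, design_constraints(), tab, seed = 3)
  expect_equal(nrow(goldenpool:::find_hairpins(as.character(out2), 20, 250)),
               0L)
  expect_identical(translate_cds(as.character(out2)), translate_cds(hp))
})

test_that("gc_tune lifts every window to the floor and keeps the protein", {
  tab <- wobble_codon_table()
  cds <- random_cds(600, 0.45, seed = 11)
  out <- gc_tune(cds, 0.53, design_constraints(), tab, seed = 2)
  prof <- goldenpool:::window_gc(as.character(out), 60)
  expect_gte(min(prof), 0.53 - 0.02)
  expect_gte(gc_content(as.character(out)), 0.53)
  expect_identical(translate_cds(as.character(out)), translate_cds(cds))
  expect_equal(nrow(goldenpool:::find_violations(as.character(out),
                                                 design_constraints())), 0L)
})

test_that("global GC is non-decreasing in the requested floor", {
  tab <- wobble_codon_table()
  cds <- random_cds(450, 0.5, seed = 14)
  gcs <- vapply(c(0.45, 0.53, 0.60), function(g) {
    gc_content(as.character(gc_tune(cds, g, design_constraints(), tab,
                                    seed = 2)))
  }, numeric(1))
  expect_true(all(diff(gcs) >= -1e-9))
})

test_that("gc_min of zero reduces to usage-only optimization", {
  tab <- wobble_codon_table()
  cds <- random_cds(300, 0.5, seed = 15)
  a <- gc_tune(cds, 0, design_constraints(), tab, seed = 4)
  b <- domesticate(codon_optimize(cds, tab, "match_usage", 4),
                   design_constraints(), tab, 4)
  expect_identical(as.character(a), as.character(b))
})

test_that("unreachable GC floors error naming the window", {
  tab <- flat_codon_table()
  cds <- random_cds(300, 0.5, seed = 34)
  expect_error(gc_tune(cds, 0.78, design_constraints(), tab, seed = 1),
               "window starting at")
})

test_that("designer operations preserve translation and are deterministic", {
  tab <- wobble_codon_table()
  for (seed in 1:6) {
    cds <- random_cds(300 + 60 * seed, 0.5, seed = 100 + seed)
    d1 <- domesticate(cds, design_constraints(), tab, seed = seed)
    d2 <- domesticate(cds, design_constraints(), tab, seed = seed)
    expect_identical(as.character(d1), as.character(d2))
    expect_identical(translate_cds(as.character(d1)), translate_cds(cds))
    o <- codon_optimize(cds, tab, "match_usage", seed = seed)
    expect_identical(translate_cds(o), translate_cds(cds))
    expect_identical(o, codon_optimize(cds, tab, "match_usage", seed = seed))
  }
})

test_that("invalid coding sequences are rejected", {
  expect_error(goldenpool:::validate_cds("ATGTAATTTTAA"), "internal stop")
  expect_error(goldenpool:::validate_cds("ATGAANTAA"), "non-ACGT")
  expect_error(goldenpool:::validate_cds("ATGAATA"), "divisible by 3")
  expect_error(sequence_metrics(""), "empty")
})

test_that("sequence metrics match a direct per-codon oracle", {
  expect_equal(sequence_metrics("ATGC")$gc, 0.5)
  tab <- random_codon_table(seed = 33)
  cds <- random_cds(900, 0.5, seed = 44)
  met <- sequence_metrics(cds, tab)
  ## independent CAI: product over degenerate non-stop codons of
  ## f(codon)/f(best synonym), geometric mean
  codons <- goldenpool:::split_codons(cds)
  code <- Biostrings::GENETIC_CODE
  logs <- c()
  gc3_hits <- c()
  for (co in codons) {
    aa <- code[co]
    syn <- names(code)[code == aa]
    if (aa == "*" || length(syn) == 1L) next
    f <- tab$freq[match(syn, tab$codon)]
    logs <- c(logs, log(f[syn == co] / max(f)))
    gc3_hits <- c(gc3_hits, substr(co, 3, 3) %in% c("G", "C"))
  }
  expect_equal(met$cai, exp(mean(logs)), tolerance = 1e-9)
  expect_equal(met$gc3s, mean(gc3_hits), tolerance = 1e-12)
})

test_that("splice predictor finds consensus motifs and nothing in poly-A", {
  don <- "CAGGTAAGT"
  s <- paste0(strrep("CAT", 30), don, strrep("GAA", 30))
  p <- predict_splice_sites(s)
  expect_true(any(p$kind == "donor" &
                    p$motif_start == 91))
  expect_equal(nrow(predict_splice_sites(strrep("A", 500))), 0L)
})

test_that("PWM scan equals a brute-force per-position rescan", {
  seq <- random_cds(9999, 0.45, seed = 55)
  pred <- pwm_splice_predictor()
  got <- predict_splice_sites(seq, pred)
  ## brute force: score every window explicitly
  for (kind in c("donor", "acceptor")) {
    lom <- pred[[kind]]
    L <- ncol(lom)
    thr <- pred$threshold_frac * sum(apply(lom, 2, max))
    hits <- integer(0)
    chars <- strsplit(seq, "")[[1]]
    for (i in 1:(nchar(seq) - L + 1L)) {
      sc <- 0
      for (j in 1:L) sc <- sc + lom[chars[i + j - 1L], j]
      if (sc >= thr) hits <- c(hits, i)
    }
    expect_identical(sort(got$motif_start[got$kind == kind]), sort(hits))
  }
})

test_that("deintronize purges a planted donor and is idempotent when clean", {
  tab <- wobble_codon_table()
  s <- random_cds(600, 0.5, seed = 13)
  s2 <- goldenpool:::validate_cds(
    paste0(substr(s, 1, 300), "CAGGTAAGT", substr(s, 310, nchar(s))))
  expect_gt(nrow(predict_splice_sites(s2)), 0L)
  res <- deintronize(s2, design_constraints(), tab, seed = 4)
  expect_equal(nrow(res$residual), 0L)
  expect_lte(res$iterations, 4L)
  expect_identical(translate_cds(res$seq), translate_cds(s2))

  clean <- res$seq
  res2 <- deintronize(clean, design_constraints(), tab, seed = 5)
  expect_identical(res2$seq, clean)
  expect_equal(res2$iterations, 0L)
  expect_equal(res2$edits, 0L)
})

test_that("multi-seed retry returns the best run on a hard multi-site case", {
  tab <- wobble_codon_table()
  s <- random_cds(1200, 0.5, seed = 66)
  motifs <- c("CAGGTAAGT", "AAGGTAAGA", "CAGGTATGT")
  pos <- c(150, 450, 900)
  for (i in seq_along(pos)) {
    s <- paste0(substr(s, 1, pos[i]), motifs[i],
                substr(s, pos[i] + 10, nchar(s)))
  }
  s <- goldenpool:::validate_cds(s)
  n0 <- nrow(predict_splice_sites(s))
  expect_gte(n0, 3L)
  res <- deintronize(s, design_constraints(), tab, seed = 7, n_seeds = 3)
  expect_lte(nrow(res$residual), n0 - 3L)
  expect_identical(translate_cds(res$seq), translate_cds(s))
})
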