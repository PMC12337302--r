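# Nearest-neighbor Tm oracle values computed independently with a published
# NN implementation (unified parameters; 500 nM strands, 200 mM monovalent
# salt) and frozen here.
NN_ORACLE <- list(
  c("ATATATATATATATATAT", 31.972354),
  c("GCGCGCGCGCGCGCGCGC", 84.558704),
  c("ACGTTGCAACGTTGCAAC", 63.430311),
  c("GATCGGAATCCTTGACGA", 59.405511),
  c("TTGACCATGGATCCAAGT", 58.705120),
  c("CAGTCAGTCAGTCAGTCA", 58.757497),
  c("AAACCCGGGTTTAAACCC", 60.777011),
  c("TGCATGCATGCATGCATG", 63.201558)
)

test_that("nearest-neighbor Tm matches an independent implementation", {
  for (case in NN_ORACLE) {
    expect_equal(melting_temperature(case[1]), as.numeric(case[2]),
                 tolerance = 0.5 / as.numeric(case[2]))
  }
  expect_lt(melting_temperature("ATATATATATATATATAT"),
            melting_temperature("GCGCGCGCGCGCGCGCGC"))
  expect_error(melting_temperature("ACGT"), "too short")
  expect_error(melting_temperature("ACGTNACGTNACGTNACG"), "non-ACGT")
})

test_that("primer candidates satisfy every generation constraint", {
  cand <- generate_primer_candidates(200, seed = 10)
  expect_equal(nrow(cand), 200L)
  expect_true(all(nchar(cand$sequence) == 18L))
  expect_true(all(round(cand$gc * 18) == 9L))
  pats <- c("GGTCTC", "CGTCTC", "GAAGAC")
  hits <- vapply(cand$sequence, function(s) {
    nrow(goldenpool:::find_pattern_hits(s, pats))
  }, integer(1))
  expect_true(all(hits == 0L))
  expect_true(all(abs(cand$tm - 60) <= 1.5))
  expect_true(all(vapply(cand$sequence, goldenpool:::max_homopolymer,
                         integer(1)) <= 4L))
  expect_identical(cand, generate_primer_candidates(200, seed = 10))
})

test_that("cross-hybridization scoring behaves like a duplex model", {
  a <- "ACGTTGCAACGTTGCAAC"
  expect_equal(cross_hybridization_score(a, revcomp(a)), 18 + 18 + 18)
  set.seed(31)
  ## symmetric
  for (i in 1:10) {
    x <- paste(sample(c("A", "C", "G", "T"), 18, TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), 18, TRUE), collapse = "")
    expect_equal(cross_hybridization_score(x, y),
                 cross_hybridization_score(y, x))
  }
  ## random unrelated pairs score under the dimer threshold >= 95% of time
  set.seed(32)
  scores <- replicate(400, {
    x <- paste(sample(c("A", "C", "G", "T"), 18, TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), 18, TRUE), collapse = "")
    cross_hybridization_score(x, y)
  })
  expect_gte(mean(scores < 24), 0.95)
  ## appending a complementary 3' base never lowers the score
  base <- "ACGTTGCAACGTT"
  partner <- revcomp("ACGTTGCAACGTTGCAAC")
  sc <- vapply(13:18, function(k) {
    cross_hybridization_score(substr("ACGTTGCAACGTTGCAAC", 1, k), partner)
  }, numeric(1))
  expect_true(all(diff(sc) >= 0))
})

test_that("index-set selection removes dimer-prone primers first", {
  cand <- generate_primer_candidates(40, seed = 12)$sequence
  keep <- select_index_set(cand, 40)
  expect_setequal(keep, cand)

  planted <- c(cand[1:20], revcomp(cand[1]))
  keep2 <- select_index_set(planted, 20)
  expect_false(all(c(cand[1], revcomp(cand[1])) %in% keep2))

  ## greedy result at least matches random subsets on the worst pair
  set.seed(13)
  pool <- generate_primer_candidates(60, seed = 14)$sequence
  sel <- select_index_set(pool, 20)
  worst <- function(ss) {
    mx <- 0
    for (i in 1:(length(ss) - 1)) for (j in (i + 1):length(ss)) {
      mx <- max(mx, cross_hybridization_score(ss[i], ss[j]))
    }
    mx
  }
  w_sel <- worst(sel)
  w_rand <- replicate(200, worst(sample(pool, 20)))
  expect_lte(w_sel, min(w_rand))
})

test_that("edit distance equals the DP oracle", {
  expect_equal(edit_distance("AATG", "AATG"), 0L)
  expect_equal(edit_distance("AATG", "AACG"), 1L)
  expect_equal(edit_distance("AATG", "ATG"), 1L)
  set.seed(41)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), 18, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(12:22, 1), TRUE),
               collapse = "")
    expect_equal(edit_distance(a, b), oracle_levenshtein(a, b))
  }
})

test_that("barcode selection enforces the distance floor", {
  expect_identical(
    select_barcode_set(c(strrep("A", 18), strrep("T", 18)), size = 2,
                       min_distance = 8)$members |> sort(),
    sort(c(strrep("A", 18), strrep("T", 18))))

  cand <- generate_primer_candidates(600, seed = 15)
  bs <- select_barcode_set(cand, size = 24, min_distance = 8)
  expect_length(bs$members, 24L)
  D <- utils::adist(bs$members)
  expect_equal(bs$min_pairwise_distance, min(D[upper.tri(D)]))
  expect_gte(bs$min_pairwise_distance, 8L)
  expect_equal(bs$mean_pairwise_distance, mean(D[upper.tri(D)]))

  ## greedy max-min beats random subsets of the same size nearly always
  set.seed(16)
  rand_min <- replicate(100, {
    ss <- sample(cand$sequence, 24)
    d <- utils::adist(ss)
    min(d[upper.tri(d)])
  })
  expect_gte(mean(bs$min_pairwise_distance >= rand_min), 0.99)

  expect_error(select_barcode_set(cand, size = 24, min_distance = 17),
               "floor")
})

test_that("barcode plate layout pairs 96 positions", {
  cand <- generate_primer_candidates(600, seed = 17)
  bs <- select_barcode_set(cand, size = 24, min_distance = 8)
  plate <- barcode_plate_layout(bs, 96)
  expect_equal(nrow(plate), 96L)
  expect_equal(plate$well[1], "A01")
  expect_equal(plate$well[96], "H12")
  expect_true(all(plate$fwd_barcode %in% bs$members))
})
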