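barcode_fixture <- function() {
  if (is.null(.fixture_env$bc12)) {
    cand <- generate_primer_candidates(300, seed = 20)
    .fixture_env$bc12 <- select_barcode_set(cand, size = 12,
                                            min_distance = 8)$members
  }
  .fixture_env$bc12
}

test_that("read simulation is exact at zero error and seeded", {
  bc <- barcode_fixture()
  tmpl <- random_cds(300, 0.5, seed = 90)
  pair <- c(bc[1], bc[2])
  r0 <- simulate_reads(tmpl, pair, error_model(0, 0, 0), n_reads = 10,
                       seed = 1)
  expected <- paste0(pair[1], tmpl, revcomp(pair[2]))
  plus <- r0$strand == "+"
  expect_true(all(r0$seq[plus] == expected))
  expect_true(all(r0$seq[!plus] == revcomp(expected)))
  expect_true(all(c("+", "-") %in% r0$strand))
  expect_identical(r0, simulate_reads(tmpl, pair, error_model(0, 0, 0),
                                      n_reads = 10, seed = 1))
})

test_that("observed substitution rate is within binomial bounds", {
  bc <- barcode_fixture()
  tmpl <- random_cds(999, 0.5, seed = 91)
  rate <- 0.02
  r <- simulate_reads(tmpl, c(bc[1], bc[2]),
                      error_model(rate, 0, 0), n_reads = 12, seed = 2)
  total <- 0L
  bases <- 0L
  expected <- paste0(bc[1], tmpl, revcomp(bc[2]))
  for (i in seq_len(nrow(r))) {
    s <- if (r$strand[i] == "-") revcomp(r$seq[i]) else r$seq[i]
    total <- total + sum(strsplit(s, "")[[1]] != strsplit(expected, "")[[1]])
    bases <- bases + nchar(s)
  }
  sigma <- sqrt(rate * (1 - rate) / bases)
  expect_lte(abs(total / bases - rate), 3 * sigma)
})

test_that("FASTQ round-trips through disk", {
  bc <- barcode_fixture()
  r <- simulate_reads(random_cds(150, 0.5, seed = 92), c(bc[1], bc[2]),
                      error_model(), n_reads = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r, path)
  back <- read_fastq(path)
  expect_identical(back$seq, r$seq)
  expect_identical(back$id, r$id)
})

test_that("demultiplexing assigns within the edit budget and refuses junk", {
  bc <- barcode_fixture()
  pairs <- data.frame(fwd_barcode = bc[1:4], rev_barcode = bc[5:8])
  tmpl <- random_cds(300, 0.5, seed = 93)

  exact <- simulate_reads(tmpl, c(bc[2], bc[6]), error_model(0, 0, 0),
                          n_reads = 4, seed = 4)
  dm <- demultiplex(exact, pairs)
  expect_true(all(dm$pair == 2L))

  ## two edits inside the forward barcode: still assigned
  mut <- exact
  s <- mut$seq[mut$strand == "+"][1]
  substr(s, 3, 3) <- if (substr(s, 3, 3) == "A") "C" else "A"
  substr(s, 7, 7) <- if (substr(s, 7, 7) == "G") "T" else "G"
  dm2 <- demultiplex(data.frame(id = "x", seq = s,
                                stringsAsFactors = FALSE), pairs)
  expect_equal(dm2$pair, 2L)

  ## scrambled terminal windows: unassigned
  scr <- paste0(strrep("ACGT", 5), tmpl, strrep("TGCA", 5))
  dm3 <- demultiplex(data.frame(id = "y", seq = scr,
                                stringsAsFactors = FALSE), pairs)
  expect_true(is.na(dm3$pair))

  ## barcode sets too close together violate the precondition
  close_pairs <- data.frame(fwd_barcode = c(bc[1], bc[1]),
                            rev_barcode = c(bc[2], sub("A", "T", bc[2])))
  expect_error(demultiplex(exact, close_pairs), "max_distance")
})

test_that("alignment reports edits and coverage like the DP oracle", {
  al <- align_to_reference("ACGTACGT", "ACGTACGT")
  expect_equal(al$edit_distance, 0L)
  expect_equal(al$coverage, 1.0)

  ref <- random_cds(600, 0.5, seed = 94)
  del <- paste0(substr(ref, 1, 200), substr(ref, 401, 600))
  al2 <- align_to_reference(del, ref)
  expect_lt(al2$coverage, 1.0)
  expect_equal(al2$edit_distance, 200L)

  set.seed(95)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 290, TRUE), collapse = "")
    expect_equal(align_to_reference(a, b)$edit_distance,
                 oracle_levenshtein(a, b))
  }
})

test_that("consensus classification recovers ground truth", {
  bc <- barcode_fixture()
  tmpl <- random_cds(450, 0.5, seed = 96)
  pair <- c(bc[1], bc[5])
  em <- error_model(0.02, 0.005, 0.005)

  clean <- simulate_reads(tmpl, pair, em, n_reads = 20, seed = 5)
  clean$orientation <- clean$strand
  v1 <- consensus_and_classify(clean, tmpl, barcode_pair = pair,
                               clone_id = "ok")
  expect_equal(v1$category, "error_free")
  expect_equal(nrow(v1$variants), 0L)

  ## one true substitution in the clone
  mut <- tmpl
  substr(mut, 222, 222) <- if (substr(tmpl, 222, 222) == "A") "G" else "A"
  r2 <- simulate_reads(mut, pair, em, n_reads = 20, seed = 6)
  r2$orientation <- r2$strand
  v2 <- consensus_and_classify(r2, tmpl, barcode_pair = pair,
                               clone_id = "snp")
  expect_equal(v2$category, "correct_with_errors")
  expect_equal(v2$variants$position, 222L)
  expect_equal(v2$variants$alt, substr(mut, 222, 222))

  ## dropped internal fragment (well under the 20% length filter):
  ## misassembled via the coverage / junction-order check
  m <- fixture_matrix()
  h <- fixture_hingeset(20)
  part <- prepare_cds_part(random_cds(1200, 0.5, seed = 97))
  plan <- fragment_sequence(part, h, m)
  dropped <- paste0(plan$fragments[1],
                    paste(substring(plan$fragments[-c(1, 4)], 5),
                          collapse = ""))
  r3 <- simulate_reads(dropped, pair, em, n_reads = 20, seed = 7)
  r3$orientation <- r3$strand
  v3 <- consensus_and_classify(r3, part, plan = plan, barcode_pair = pair,
                               clone_id = "drop")
  expect_equal(v3$category, "misassembled")

  ## too few reads
  v4 <- consensus_and_classify(clean[1:3, ], tmpl, barcode_pair = pair,
                               clone_id = "thin")
  expect_equal(v4$category, "unassigned")
  v5 <- consensus_and_classify(clean[0, ], tmpl, barcode_pair = pair,
                               clone_id = "empty")
  expect_equal(v5$category, "unassigned")
})

test_that("run summaries report headline fractions exactly", {
  mk <- function(cat, id) {
    goldenpool:::new_clone_verdict(id, cat, goldenpool:::empty_variants(),
                                   1, 20, "X")
  }
  cats <- c(rep("error_free", 69), rep("correct_with_errors", 24),
            rep("misassembled", 7))
  verdicts <- Map(mk, cats, sprintf("t%02d_c%d", rep(1:25, 4), 1:100))
  rep <- summarize_run(verdicts)
  expect_equal(unname(rep$fractions["error_free"]), 0.69)
  expect_equal(unname(rep$fractions["error_free"] +
                        rep$fractions["correct_with_errors"]), 0.93)
  empty <- summarize_run(list())
  expect_equal(empty$n_clones, 0L)
  expect_true(all(empty$counts == 0))
})
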