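test_that("candidate junctions match a brute-force window scan", {
  h <- fixture_hingeset(20)
  seq <- random_cds(999, 0.5, seed = 71)
  allowed <- h$set$members
  got <- candidate_junctions(seq, 500, 30, allowed, taken = c("AATG", "GCTT"))
  ## brute force
  usable <- c(allowed, revcomp(allowed))
  blocked <- c("AATG", "GCTT", revcomp(c("AATG", "GCTT")))
  exp_pos <- integer(0)
  for (p in 470:530) {
    ov <- substr(seq, p + 1, p + 4)
    if (ov %in% usable && !ov %in% blocked && ov != revcomp(ov)) {
      exp_pos <- c(exp_pos, p)
    }
  }
  expect_setequal(got$position, exp_pos)
  expect_true(all(diff(abs(got$offset)) >= 0))
})

test_that("radius-0 candidates and palindrome exclusion behave", {
  seq <- paste0(strrep("G", 10), "ACGG", strrep("G", 10))
  got <- candidate_junctions(seq, 10, 0, c("ACGG"), character(0))
  expect_equal(nrow(got), 1L)
  expect_equal(got$position, 10L)
  seq2 <- paste0(strrep("G", 10), "GATC", strrep("G", 10))
  expect_equal(nrow(candidate_junctions(seq2, 10, 0, c("GATC"),
                                        character(0))), 0L)
})

test_that("short targets yield a single fragment with only the termini", {
  m <- fixture_matrix()
  h <- fixture_hingeset(20)
  part <- prepare_cds_part(random_cds(150, 0.5, seed = 72))
  plan <- fragment_sequence(part, h, m)
  expect_length(plan$fragments, 1L)
  expect_identical(plan$overhangs, c("AATG", "GCTT"))
  expect_identical(reassemble_plan(plan), part)
})

test_that("fragment count follows the payload budget arithmetic", {
  m <- fixture_matrix()
  h <- fixture_hingeset(20)
  ## 923 nt part: smallest n with (923 + 4(n-1))/n <= 198 is 5
  part <- prepare_cds_part(random_cds(918, 0.5, seed = 73))
  expect_equal(nchar(part), 923L)
  plan <- fragment_sequence(part, h, m)
  expect_equal(length(plan$fragments), 5L)
  expect_true(all(nchar(plan$fragments) <= 198L))
  expect_identical(reassemble_plan(plan), part)
})

test_that("plans are deterministic, valid, and at least as good as the set", {
  m <- fixture_matrix(rate = 0.08, seed = 6)
  h <- optimize_hingeset(16, m, ga_config(seed = 9, generations_max = 100))
  for (s in 1:5) {
    part <- prepare_cds_part(random_cds(600 + 90 * s, 0.5, seed = 200 + s))
    p1 <- fragment_sequence(part, h, m)
    p2 <- fragment_sequence(part, h, m)
    expect_identical(p1$cut_positions, p2$cut_positions)
    expect_identical(reassemble_plan(p1), part)
    expect_gte(p1$predicted_fidelity, h$fidelity - 1e-12)
    ov <- p1$overhangs
    expect_false(any(duplicated(ov)))
    expect_length(intersect(ov, revcomp(ov)), 0L)
    expect_true(all(ov[-c(1, length(ov))] %in%
                      c(h$set$members, revcomp(h$set$members))))
    expect_equal(p1$predicted_fidelity, oracle_set_fidelity(ov, m),
                 tolerance = 1e-12)
  }
})

test_that("search equals exhaustive enumeration on small instances", {
  m <- fixture_matrix(rate = 0.08, seed = 6)
  toy_members <- c("AATG", "GCTT", "ACGG", "ATCC", "CTTG", "GACA",
                   "TCAG", "AGGC")
  hs <- overhang_set(toy_members)
  for (s in 1:3) {
    part <- prepare_cds_part(random_cds(450, 0.5, seed = 300 + s))
    plan <- try(fragment_sequence(part, hs, m, max_payload = 180,
                                  radius = 40), silent = TRUE)
    ## exhaustive: every admissible pair of junction assignments
    L <- nchar(part)
    n <- ceiling((L - 4) / (180 - 4))
    ideal <- round((1:(n - 1)) * L / n)
    cands <- lapply(ideal, function(ip) {
      candidate_junctions(part, ip, 40, toy_members,
                          taken = c("AATG", "GCTT"))
    })
    best <- -1
    enum <- function(i, pos, ovs) {
      if (i > n - 1) {
        prev <- if (length(pos)) pos[length(pos)] else 0
        spans <- diff(c(0, pos + 4, L + 4))
        starts <- c(0, pos)
        ends <- c(pos + 4, L)
        if (any(ends - starts > 180)) return()
        f <- oracle_set_fidelity(unique(c("AATG", "GCTT", ovs)), m)
        if (f > best) best <<- f
        return()
      }
      ci <- cands[[i]]
      for (r in seq_len(nrow(ci))) {
        p <- ci$position[r]; o <- ci$overhang[r]
        prev <- if (length(pos)) pos[length(pos)] else 0
        if (p < prev + 4) next
        if (o %in% ovs || revcomp(o) %in% ovs) next
        enum(i + 1, c(pos, p), c(ovs, o))
      }
    }
    enum(1, integer(0), character(0))
    if (inherits(plan, "try-error")) {
      expect_equal(best, -1)
    } else {
      expect_equal(plan$predicted_fidelity, best, tolerance = 1e-12)
    }
  }
})

test_that("larger radius never lowers achievable fidelity", {
  m <- fixture_matrix(rate = 0.08, seed = 6)
  h <- optimize_hingeset(12, m, ga_config(seed = 10, generations_max = 80))
  part <- prepare_cds_part(random_cds(900, 0.5, seed = 77))
  fids <- vapply(c(10, 20, 40), function(r) {
    p <- try(fragment_sequence(part, h, m, radius = r), silent = TRUE)
    if (inherits(p, "try-error")) -1 else p$predicted_fidelity
  }, numeric(1))
  expect_true(all(diff(fids) >= -1e-12))
})

test_that("mismatched termini and impossible windows raise useful errors", {
  m <- fixture_matrix()
  h <- fixture_hingeset(20)
  expect_error(fragment_sequence(random_cds(300, 0.5, seed = 1), h, m),
               "prepare_cds_part")
  ## a homopolymer interior offers no admissible junction 4-mers
  bad <- paste0("AATG", strrep("A", 400), "GCTT")
  expect_error(fragment_sequence(bad, h, m, max_payload = 150),
               "radius|hingeset")
})

test_that("plans serialize to JSON with their fidelity and junctions", {
  m <- fixture_matrix()
  h <- fixture_hingeset(20)
  plan <- fragment_sequence(prepare_cds_part(random_cds(600, 0.5, seed = 78)),
                            h, m)
  path <- withr::local_tempfile(fileext = ".json")
  write_plan_json(plan, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$overhangs, plan$overhangs)
  expect_equal(back$predicted_fidelity, plan$predicted_fidelity)
})
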