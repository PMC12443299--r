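stats_row <- function(a = 10, ror = 5, ror_lo = 2, prr = 4, prr_lo = 2,
                      ic025 = 1, ebgm05 = 3) {
  data.frame(a = a, ror = ror, ror_lo = ror_lo, prr = prr, prr_lo = prr_lo,
             ic025 = ic025, ebgm05 = ebgm05)
}

test_that("the combined criterion is the conjunction of all four algorithms", {
  ev <- evaluate_signals(stats_row())
  expect_true(ev$combined)
  # support rule: a = 2 kills the verdict no matter how large the ROR
  ev <- evaluate_signals(stats_row(a = 2, ror = 1e6, ror_lo = 1e5))
  expect_false(ev$ror_pos)
  expect_false(ev$combined)
  # one failing algorithm (PRR) fails the whole row
  ev <- evaluate_signals(stats_row(ror = 4, ror_lo = 1.2, prr = 1.5))
  expect_true(ev$ror_pos)
  expect_false(ev$prr_pos)
  expect_false(ev$combined)
  # undefined statistics are FALSE flags, not NA
  ev <- evaluate_signals(stats_row(ror = NA, ror_lo = NA))
  expect_false(ev$ror_pos)
  expect_false(ev$combined)
})

test_that("combined implies every component flag over random rows", {
  set.seed(55)
  rows <- data.frame(a = sample(0:20, 400, TRUE),
                     ror = runif(400, 0, 10), ror_lo = runif(400, 0, 3),
                     prr = runif(400, 0, 10), prr_lo = runif(400, 0, 3),
                     ic025 = runif(400, -2, 2), ebgm05 = runif(400, 0, 5))
  ev <- evaluate_signals(rows)
  expect_true(all(!ev$combined |
                    (ev$ror_pos & ev$prr_pos & ev$ic_pos & ev$ebgm_pos &
                       ev$support)))
})

test_that("growing a (holding b, c, d) never demotes a combined signal", {
  b <- 200; c <- 50; d <- 5000
  prev <- FALSE
  for (a in 1:40) {
    st <- signal_stats(a, b, c, d)
    comb <- evaluate_signals(st)$combined
    expect_false(prev && !comb)
    prev <- comb
  }
  expect_true(prev)  # by a = 40 the pair is an unambiguous signal
})

test_that("ranking sorts descending with documented tie-breaks", {
  rows <- data.frame(term = c("r1", "r2", "r3"), a = c(5, 5, 5),
                     ror = c(5, 9, 7))
  expect_equal(rank_signals(rows, by = "ror")$ror, c(9, 7, 5))
  ties <- data.frame(term = c("b_small", "a_big", "c_small"),
                     a = c(2, 9, 2), ror = c(4, 4, 4))
  expect_equal(rank_signals(ties, by = "ror")$term,
               c("a_big", "b_small", "c_small"))
  expect_equal(nrow(rank_signals(rows, by = "ror", top = 2)), 2L)
  expect_error(rank_signals(rows, by = "nope"), "unknown ranking statistic")
})

test_that("cohort summary computes percentages and outcome precedence", {
  cases <- data.table::data.table(
    primaryid = sprintf("p%d", 1:4), case_id = sprintf("c%d", 1:4),
    sex = c("female", "female", "male", "unknown"),
    age_years = c(50, 75, NA, 65), reporter = "physician",
    country = c("US", "US", "FR", "JP"))
  outcomes <- data.table::data.table(
    primaryid = c("p1", "p1", "p2"), case_id = c("c1", "c1", "c2"),
    outcome = c("HO", "DE", "HO"))
  sm <- describe_cohort(cases, outcomes)
  expect_equal(sm$pct[sm$block == "sex" & sm$category == "female"], 50)
  # boundary 75 falls in the >=75 band; 65 in the 65-75 band
  expect_equal(sm$n[sm$block == "age" & sm$category == ">=75"], 1L)
  expect_equal(sm$n[sm$block == "age" & sm$category == "65-75"], 1L)
  expect_equal(sm$n[sm$block == "age" & sm$category == "unknown"], 1L)
  # case p1 has HO and DE: counted once as death under precedence
  expect_equal(sm$n[sm$block == "outcome" & sm$category == "DE"], 1L)
  expect_equal(sm$n[sm$block == "outcome" & sm$category == "HO"], 1L)
  multi <- describe_cohort(cases, outcomes, outcome_mode = "multi")
  expect_equal(multi$n[multi$block == "outcome" & multi$category == "HO"], 2L)
  # percentages within each block cover the cohort
  for (blk in c("sex", "age")) {
    expect_equal(sum(sm$pct[sm$block == blk]), 100, tolerance = 0.05)
  }
})

test_that("synthetic cohort reproduces the generator demographics", {
  cfg <- synthetic_config(n_cases = 4000, n_drugs = 4, seed = 19)
  out <- file.path(tempdir(), "cohort")
  gt <- generate_faers(cfg, out)
  q <- deduplicate_cases(read_faers_quarter(out, "24Q3"))
  sm <- describe_cohort(q$cases, q$outcomes)
  dem <- default_demographics()
  for (blk in c("sex", "age", "outcome")) {
    probs <- dem[[blk]]
    for (cat in names(probs)) {
      catname <- if (blk == "sex") cat else cat
      n <- sm$n[sm$block == blk & sm$category == catname]
      if (length(n) == 0) n <- 0L
      p <- probs[[cat]]
      # 4 binomial SDs around the generator probability
      expect_lt(abs(n - 4000 * p), 4 * sqrt(4000 * p * (1 - p)) + 1)
    }
  }
  # outcome counts match ground truth exactly: precedence recovers the
  # primary outcome the generator drew for every case
  truth <- table(gt$cases$outcome)
  for (code in names(truth)) {
    expect_equal(sm$n[sm$block == "outcome" & sm$category == code],
                 as.integer(truth[[code]]))
  }
})

test_that("the end-to-end run flags the planted pair and honours thresholds", {
  cfg <- synthetic_config(n_cases = 20000, n_drugs = 100, n_events = 500,
                          background_rate = 2,
                          planted_signals = data.frame(drug = 1, event = 1,
                                                       lambda = 100),
                          duplicate_fraction = 0.1, variant_fraction = 0.2,
                          seed = 23)
  out <- file.path(tempdir(), "endtoend")
  generate_faers(cfg, out)
  run <- detect_signals(out, "24Q3", "DRUG_0001")
  expect_identical(run$pt$pt[1], "PT_0001")
  expect_true(run$pt$combined[1])
  expect_equal(run$log$cases_after, 20000L)
  expect_lte(run$log$cases_after, run$log$cases_before)
  # absurd thresholds switch every verdict off
  run2 <- detect_signals(out, "24Q3", "DRUG_0001",
                         thresholds = signal_thresholds(ror = 1e6))
  expect_false(any(run2$pt$combined))
  # empty REAC is an explicit stage error
  empty <- file.path(tempdir(), "empty_reac")
  generate_faers(synthetic_config(n_cases = 10, seed = 4), empty)
  writeLines("primaryid$caseid$pt", file.path(empty, "REAC24Q3.txt"))
  expect_error(detect_signals(empty, "24Q3", "DRUG_0001"), "no REAC rows")
})

test_that("exports write the documented files deterministically", {
  cfg <- synthetic_config(n_cases = 500, seed = 33)
  out <- file.path(tempdir(), "exports")
  generate_faers(cfg, out)
  run <- detect_signals(out, "24Q3", "DRUG_0001")
  rep1 <- file.path(tempdir(), "rep1"); rep2 <- file.path(tempdir(), "rep2")
  p1 <- write_signal_tables(run, rep1)
  run_again <- detect_signals(out, "24Q3", "DRUG_0001")
  p2 <- write_signal_tables(run_again, rep2)
  expect_true(all(file.exists(p1)))
  expect_identical(unname(tools::md5sum(p1[1:3])),
                   unname(tools::md5sum(p2[1:3])))
})
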