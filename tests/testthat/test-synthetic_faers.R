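test_that("config validation names the offending field", {
  expect_error(synthetic_config(n_cases = 0), "n_cases")
  expect_error(synthetic_config(background_rate = -1), "background_rate")
  expect_error(synthetic_config(duplicate_fraction = 1), "duplicate_fraction")
  expect_error(synthetic_config(
    planted_signals = data.frame(drug = 99, event = 1, lambda = 2),
    n_drugs = 10), "drug index")
  expect_error(synthetic_config(
    planted_signals = data.frame(drug = 1, event = 1, lambda = 0)), "lambda")
  bad_dem <- default_demographics()
  bad_dem$sex <- c(female = 0.6, male = 0.6)
  expect_error(synthetic_config(demographics = bad_dem), "sex")
})

test_that("no duplication requested gives one row and one version per case", {
  cfg <- synthetic_config(n_cases = 100, n_drugs = 5, n_events = 10,
                          duplicate_fraction = 0, variant_fraction = 0,
                          seed = 3)
  gt <- generate_faers(cfg, file.path(tempdir(), "nodup"))
  demo <- data.table::fread(file.path(tempdir(), "nodup", "DEMO24Q3.txt"),
                            sep = "$")
  expect_equal(nrow(demo), 100L)
  expect_equal(length(unique(demo$caseid)), 100L)
  expect_true(all(demo$caseversion == 1L))
  expect_true(all(gt$cases$n_versions == 1L))
})

test_that("identical config and seed give byte-identical files", {
  cfg <- synthetic_config(n_cases = 150, duplicate_fraction = 0.2, seed = 17)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  g1 <- generate_faers(cfg, d1)
  g2 <- generate_faers(cfg, d2)
  sums1 <- unname(tools::md5sum(g1$files))
  sums2 <- unname(tools::md5sum(g2$files))
  expect_identical(sums1, sums2)
  # a different seed changes the content
  g3 <- generate_faers(synthetic_config(n_cases = 150,
                                        duplicate_fraction = 0.2, seed = 18),
                       file.path(tempdir(), "det3"))
  expect_false(all(unname(tools::md5sum(g3$files)) == sums1))
})

test_that("duplicated cases keep distinct ids but inflate DEMO rows", {
  cfg <- synthetic_config(n_cases = 200, duplicate_fraction = 0.4, seed = 5)
  gt <- generate_faers(cfg, file.path(tempdir(), "dupfrac"))
  demo <- data.table::fread(file.path(tempdir(), "dupfrac", "DEMO24Q3.txt"),
                            sep = "$")
  expect_equal(length(unique(demo$caseid)), 200L)
  expect_gt(nrow(demo), 200L)
  expect_equal(nrow(demo), 200L + sum(gt$cases$n_versions == 2L))
})

test_that("expected cell counts are independent under lambda = 1 and linear in n_cases", {
  cfg <- synthetic_config(n_cases = 1000, n_drugs = 8, n_events = 20)
  e <- expected_cell_counts(cfg, 3, 7)
  # no association: target and comparator report the event at the same rate
  expect_equal(e[["a"]] / (e[["a"]] + e[["b"]]),
               e[["c"]] / (e[["c"]] + e[["d"]]), tolerance = 1e-12)
  cfg2 <- synthetic_config(n_cases = 2000, n_drugs = 8, n_events = 20)
  expect_equal(unname(expected_cell_counts(cfg2, 3, 7)), unname(2 * e),
               tolerance = 1e-12)
  expect_error(expected_cell_counts(cfg, 99, 1), "drug index")
})

test_that("a planted lambda tilts E[a] by the documented rate equations", {
  base <- synthetic_config(n_cases = 10000, n_drugs = 20, n_events = 500,
                           background_rate = 2)
  tilted <- synthetic_config(n_cases = 10000, n_drugs = 20, n_events = 500,
                             background_rate = 2,
                             planted_signals = data.frame(drug = 1, event = 1,
                                                          lambda = 10))
  e0 <- expected_cell_counts(base, 1, 1)
  e1 <- expected_cell_counts(tilted, 1, 1)
  # closed form: per-slot probability lambda/denom vs 1/n_events, through
  # the truncated-Poisson inclusion probability
  mu <- 2
  inc <- function(q) 1 - (exp(-mu * q) - exp(-mu)) / (1 - exp(-mu))
  expect_equal(e1[["a"]] / e0[["a"]],
               inc(10 / (500 + 9)) / inc(1 / 500), tolerance = 1e-12)
  # in the small-q regime this is close to (but slightly below) lambda
  expect_gt(e1[["a"]] / e0[["a"]], 9.5)
  expect_lt(e1[["a"]] / e0[["a"]], 10)
  # comparator cells are untouched by the plant
  expect_equal(e1[["c"]], e0[["c"]], tolerance = 1e-12)
})

test_that("closed-form expectations match a direct Monte Carlo of the model", {
  cfg <- synthetic_config(n_cases = 4000, n_drugs = 6, n_events = 12,
                          background_rate = 1.5, duplicate_fraction = 0,
                          variant_fraction = 0,
                          planted_signals = data.frame(drug = 2, event = 3,
                                                       lambda = 5),
                          seed = 31)
  # independent mini-simulation of the documented model (drug uniform,
  # zero-truncated Poisson slots, tilted categorical, within-case dedup)
  set.seed(1234)
  reps <- 60
  acc <- matrix(0, reps, 4)
  for (r in seq_len(reps)) {
    drug <- sample.int(6, 4000, TRUE)
    k <- qpois(runif(4000, ppois(0, 1.5), 1), 1.5)
    cs <- rep(seq_len(4000), k)
    w <- rep(1, 12); w[3] <- 5
    pt <- ifelse(drug[cs] == 2,
                 sample.int(12, length(cs), TRUE, prob = w / sum(w)),
                 sample.int(12, length(cs), TRUE))
    pairs <- unique(data.frame(cs, pt))
    tgt <- pairs$cs %in% which(drug == 2)
    ev <- pairs$pt == 3
    acc[r, ] <- c(sum(tgt & ev), sum(tgt & !ev), sum(!tgt & ev),
                  sum(!tgt & !ev))
  }
  mc <- colMeans(acc)
  e <- expected_cell_counts(cfg, 2, 3)
  mc_se <- apply(acc, 2, sd) / sqrt(reps)
  expect_true(all(abs(mc - e) < 4 * mc_se + 1e-9))
})

test_that("a planted pair's observed count falls within 4 Poisson SD of expectation", {
  cfg <- synthetic_config(n_cases = 200000, n_drugs = 100, n_events = 2000,
                          background_rate = 2, duplicate_fraction = 0.1,
                          variant_fraction = 0.2,
                          planted_signals = data.frame(drug = 1, event = 1,
                                                       lambda = 50),
                          seed = 97)
  e <- expected_cell_counts(cfg, 1, 1)
  expect_gt(e[["a"]], 90)  # design point: expected a of about 100
  out <- file.path(tempdir(), "big")
  gt <- generate_faers(cfg, out)
  run <- detect_signals(out, "24Q3", "DRUG_0001")
  row <- run$pt[run$pt$pt == "PT_0001", ]
  expect_true(abs(row$a - e[["a"]]) < 4 * sqrt(e[["a"]]))
  # and the planted pair tops the ROR ranking as a combined-positive signal
  expect_identical(run$pt$pt[1], "PT_0001")
  expect_true(row$combined)
})

test_that("table-level Monte Carlo reproduces the closed-form expectations", {
  cfg <- synthetic_config(n_cases = 50000, n_drugs = 40, n_events = 80,
                          planted_signals = data.frame(drug = 2, event = 5,
                                                       lambda = 8))
  tabs <- simulate_pair_tables(cfg, 2, 5, 400, seed = 61)
  e <- expected_cell_counts(cfg, 2, 5)
  z <- (colMeans(tabs) - e) / (apply(tabs, 2, sd) / sqrt(400))
  expect_true(all(abs(z) < 4))
})
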