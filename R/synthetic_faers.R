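#' Default demographic category probabilities for the synthetic cohort
#'
#' Category probabilities used by [generate_faers()] for sex, age band,
#' reporter occupation, reporting country and the primary outcome of each
#' case. The defaults mirror the demographic mix typical of a spironolactone
#' cohort in a spontaneous-reporting database: slight female preponderance,
#' an elderly skew, mostly health-professional reporters, US as the leading
#' single country, and hospitalization as the most common serious outcome.
#'
#' @return A named list of probability vectors (`sex`, `age`, `reporter`,
#'   `country`, `outcome`), each summing to 1.
#' @export
default_demographics <- function() {
  list(
    sex = c(female = 0.5011, male = 0.4135, unknown = 0.0854),
    age = c("<65" = 0.2886, "65-75" = 0.1945, ">=75" = 0.3097,
            unknown = 0.2072),
    reporter = c(physician = 0.3012, pharmacist = 0.2623, consumer = 0.2485,
                 `other health-professional` = 0.1565, unknown = 0.0315),
    country = c(US = 0.2850, FR = 0.1610, GB = 0.0836, DE = 0.0411,
                other = 0.4293),
    outcome = c(HO = 0.4439, OT = 0.3841, LT = 0.0741, DE = 0.0559,
                DS = 0.0227, RI = 0.0144, CA = 0.0049)
  )
}

#' Configuration for the synthetic spontaneous-report generator
#'
#' Defines a FAERS-like reporting database with known ground truth. Each
#' case receives one primary-suspect (PS) drug drawn uniformly from
#' `n_drugs` synthetic ingredients, a number of reaction preferred terms
#' (PTs) drawn from a zero-truncated Poisson with mean `background_rate`,
#' and each PT slot drawn from a categorical distribution over `n_events`
#' terms that is uniform except where a planted signal tilts it: for a case
#' whose PS drug is `g`, event `e` has weight `lambda(g, e)` (1 unless
#' planted), normalized over events. `lambda` therefore plays the role of
#' the true reporting-rate ratio that the disproportionality statistics
#' estimate (up to the normalization and margin terms given in
#' [expected_cell_counts()]).
#'
#' @param n_cases Number of distinct safety reports (cases).
#' @param n_drugs Number of synthetic ingredients (`DRUG_0001`, ...).
#' @param n_events Number of synthetic preferred terms (`PT_0001`, ...).
#' @param n_socs Number of synthetic system organ classes; PT `j` belongs to
#'   SOC `((j - 1) mod n_socs) + 1`.
#' @param background_rate Mean of the zero-truncated Poisson count of PTs
#'   per case.
#' @param planted_signals `NULL` or a `data.frame` with columns `drug`,
#'   `event` (1-based indices) and `lambda` (> 0 rate ratio).
#' @param duplicate_fraction Share of cases emitted with two versions (the
#'   later version is the authoritative one; the earlier one lacks one PT
#'   when the case has several).
#' @param variant_fraction Share of drug mentions written as a brand-name or
#'   misspelled synonym instead of the canonical ingredient string.
#' @param concomitant_rate Mean Poisson count of concomitant (role `C`)
#'   drug mentions per case.
#' @param demographics Category probabilities, see [default_demographics()].
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output files.
#' @return An object of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(n_cases = 100, seed = 1)
#' @export
synthetic_config <- function(n_cases = 5000, n_drugs = 50, n_events = 100,
                             n_socs = 10, background_rate = 2,
                             planted_signals = NULL,
                             duplicate_fraction = 0.1,
                             variant_fraction = 0.15,
                             concomitant_rate = 0.7,
                             demographics = default_demographics(),
                             seed = 1L) {
  chk_pos_int <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x)) {
      stop("synthetic_config: '", nm, "' must be a positive integer",
           call. = FALSE)
    }
    as.integer(x)
  }
  n_cases <- chk_pos_int(n_cases, "n_cases")
  n_drugs <- chk_pos_int(n_drugs, "n_drugs")
  n_events <- chk_pos_int(n_events, "n_events")
  n_socs <- chk_pos_int(n_socs, "n_socs")
  if (!is.finite(background_rate) || background_rate <= 0) {
    stop("synthetic_config: 'background_rate' must be positive",
         call. = FALSE)
  }
  for (nm in c("duplicate_fraction", "variant_fraction")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v >= 1) {
      stop("synthetic_config: '", nm, "' must lie in [0, 1)", call. = FALSE)
    }
  }
  if (!is.finite(concomitant_rate) || concomitant_rate < 0) {
    stop("synthetic_config: 'concomitant_rate' must be non-negative",
         call. = FALSE)
  }
  if (is.null(planted_signals)) {
    planted_signals <- data.frame(drug = integer(), event = integer(),
                                  lambda = numeric())
  }
  planted_signals <- as.data.frame(planted_signals)
  if (!all(c("drug", "event", "lambda") %in% names(planted_signals))) {
    stop("synthetic_config: 'planted_signals' needs columns drug, event, lambda",
         call. = FALSE)
  }
  if (nrow(planted_signals)) {
    if (any(planted_signals$drug < 1 | planted_signals$drug > n_drugs)) {
      stop("synthetic_config: 'planted_signals' drug index out of range",
           call. = FALSE)
    }
    if (any(planted_signals$event < 1 | planted_signals$event > n_events)) {
      stop("synthetic_config: 'planted_signals' event index out of range",
           call. = FALSE)
    }
    if (any(!is.finite(planted_signals$lambda) | planted_signals$lambda <= 0)) {
      stop("synthetic_config: 'planted_signals' lambda must be > 0",
           call. = FALSE)
    }
    if (anyDuplicated(planted_signals[, c("drug", "event")])) {
      stop("synthetic_config: 'planted_signals' has duplicate (drug, event)",
           call. = FALSE)
    }
  }
  needed <- c("sex", "age", "reporter", "country", "outcome")
  if (!is.list(demographics) || !all(needed %in% names(demographics))) {
    stop("synthetic_config: 'demographics' must list probabilities for ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  for (nm in needed) {
    p <- demographics[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9 || is.null(names(p))) {
      stop("synthetic_config: 'demographics$", nm,
           "' must be a named probability vector summing to 1", call. = FALSE)
    }
  }
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
    stop("synthetic_config: 'seed' must be an integer", call. = FALSE)
  }
  structure(list(n_cases = n_cases, n_drugs = n_drugs, n_events = n_events,
                 n_socs = n_socs, background_rate = background_rate,
                 planted_signals = planted_signals,
                 duplicate_fraction = duplicate_fraction,
                 variant_fraction = variant_fraction,
                 concomitant_rate = concomitant_rate,
                 demographics = demographics, seed = as.integer(seed)),
            class = "synthetic_config")
}

drug_name <- function(i) sprintf("DRUG_%04d", i)
pt_name <- function(i) sprintf("PT_%04d", i)
soc_name <- function(i) sprintf("SOC_%02d", i)

# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# zero-truncated Poisson sampler
rtpois <- function(n, mu) {
  stats::qpois(stats::runif(n, stats::ppois(0, mu), 1), mu)
}

# per-slot event probabilities for one drug: uniform tilted by planted lambda
event_weights <- function(config, drug) {
  lam <- rep(1, config$n_events)
  ps <- config$planted_signals
  if (nrow(ps)) {
    sel <- ps$drug == drug
    lam[ps$event[sel]] <- ps$lambda[sel]
  }
  lam / sum(lam)
}

#' Write a synthetic FAERS-style quarter with known ground truth
#'
#' Emits dollar-delimited `DEMO`, `DRUG`, `REAC` and `OUTC` files in the
#' quarterly-file dialect read by [read_faers_quarter()], together with the
#' matching drug-synonym dictionary (`drug_dictionary.tsv`), PT/SOC map
#' (`pt_soc_map.tsv`) and ground-truth sidecars (`truth_cases.tsv`,
#' `truth_signals.tsv`). A `duplicate_fraction` share of cases is written
#' twice (case versions 1 and 2, version 2 carrying the authoritative
#' content and a later receipt date); a `variant_fraction` share of drug
#' mentions uses a brand or misspelled synonym covered by the emitted
#' dictionary.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @param quarter Quarter label used in file names, e.g. `"24Q3"`.
#' @return Invisibly, a `faers_ground_truth` list: `config`, `quarter`,
#'   `cases` (one row per ground-truth case with its canonical content),
#'   `signals` (planted drug/event names and lambda), and `files`.
#' @export
generate_faers <- function(config, out_dir, quarter = "24Q3") {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("out_dir is not writable: ", out_dir, call. = FALSE)
  }
  gt <- with_seed(config$seed, generate_faers_impl(config, out_dir, quarter))
  invisible(gt)
}

generate_faers_impl <- function(config, out_dir, quarter) {
  n <- config$n_cases
  dem <- config$demographics
  caseid <- sprintf("%08d", seq_len(n) + 10000000L)

  ps_drug <- sample.int(config$n_drugs, n, replace = TRUE)
  k_pts <- rtpois(n, config$background_rate)

  # draw PT slots per case, tilted for drugs carrying planted signals
  slot_case <- rep(seq_len(n), k_pts)
  slot_drug <- ps_drug[slot_case]
  m <- length(slot_case)
  slot_pt <- integer(m)
  planted_drugs <- unique(config$planted_signals$drug)
  plain <- !(slot_drug %in% planted_drugs)
  slot_pt[plain] <- sample.int(config$n_events, sum(plain), replace = TRUE)
  for (g in planted_drugs) {
    sel <- slot_drug == g
    slot_pt[sel] <- sample.int(config$n_events, sum(sel), replace = TRUE,
                               prob = event_weights(config, g))
  }

  # demographics
  draw <- function(p, nn = n) {
    names(p)[sample.int(length(p), nn, replace = TRUE, prob = p)]
  }
  sex_cat <- draw(dem$sex)
  age_band <- draw(dem$age)
  age <- rep(NA_integer_, n)
  age[age_band == "<65"] <- sample(18:64, sum(age_band == "<65"), TRUE)
  age[age_band == "65-75"] <- sample(65:74, sum(age_band == "65-75"), TRUE)
  age[age_band == ">=75"] <- sample(75:99, sum(age_band == ">=75"), TRUE)
  reporter <- draw(dem$reporter)
  country_cat <- draw(dem$country)
  country <- country_cat
  other_pool <- c("JP", "CA", "IT", "ES", "CN", "BR", "AU", "NL")
  country[country_cat == "other"] <-
    sample(other_pool, sum(country_cat == "other"), TRUE)
  outcome <- draw(dem$outcome)

  # a tenth of cases get one extra outcome code of strictly lower severity
  # precedence, so precedence-based summarization is observable
  prec <- c("DE", "LT", "DS", "CA", "RI", "HO", "OT")
  extra_outc <- rep(NA_character_, n)
  has_extra <- stats::runif(n) < 0.1 & outcome != "OT"
  if (any(has_extra)) {
    lower <- lapply(match(outcome[has_extra], prec),
                    function(i) prec[(i + 1):length(prec)])
    extra_outc[has_extra] <- vapply(lower, function(v) {
      v[sample.int(length(v), 1L)]
    }, character(1))
  }

  # case versions: duplicated cases carry versions 1 and 2; the later
  # version holds the canonical content, the earlier one misses one PT
  is_dup <- stats::runif(n) < config$duplicate_fraction
  latest_version <- ifelse(is_dup, 2L, 1L)
  base_date <- as.Date("2024-07-01") + sample(0:80, n, TRUE)
  date_latest <- format(base_date + ifelse(is_dup, sample(5:45, n, TRUE), 0L),
                        "%Y%m%d")
  date_first <- format(base_date, "%Y%m%d")

  # some known ages are reported in months to exercise unit conversion
  age_cod <- ifelse(is.na(age), "",
                    ifelse(stats::runif(n) < 0.05, "MON", "YR"))
  age_val <- ifelse(is.na(age), "",
                    ifelse(age_cod == "MON", as.character(age * 12L),
                           as.character(age)))
  sex_code <- c(female = "F", male = "M", unknown = "UNK")[sex_cat]
  occp <- c(physician = "MD", pharmacist = "PH", consumer = "CN",
            `other health-professional` = "OT", unknown = "")[reporter]

  # concomitant drug mentions
  k_con <- stats::rpois(n, config$concomitant_rate)
  con_case <- rep(seq_len(n), k_con)
  con_drug <- sample.int(config$n_drugs, length(con_case), replace = TRUE)

  # verbatim drug strings: canonical or one of three synonym variants
  variant_of <- function(idx) {
    v <- stats::runif(length(idx))
    f <- findInterval(stats::runif(length(idx)), c(1 / 3, 2 / 3)) + 1L
    out <- drug_name(idx)
    use <- v < config$variant_fraction
    out[use & f == 1L] <- sprintf("BR_DRUG_%04d", idx[use & f == 1L])
    out[use & f == 2L] <- sprintf("DRUG %04d", idx[use & f == 2L])
    out[use & f == 3L] <- sprintf(" drug_%04d. ", idx[use & f == 3L])
    out
  }
  ps_verbatim <- variant_of(ps_drug)
  con_verbatim <- variant_of(con_drug)

  # PT dropped from the earlier version of duplicated cases (when >= 2)
  pt_by_case <- split(slot_pt, factor(slot_case, levels = seq_len(n)))
  drop_pt <- rep(NA_integer_, n)
  cand <- which(is_dup)
  for (i in cand) {
    u <- unique(pt_by_case[[i]])
    if (length(u) >= 2L) drop_pt[i] <- u[sample.int(length(u), 1L)]
  }

  # assemble per-version row sets (versions = latest for every case, plus
  # an earlier version 1 for duplicated cases)
  dup_idx <- which(is_dup)
  ver_case <- c(seq_len(n), dup_idx)
  ver_no <- c(latest_version, rep(1L, length(dup_idx)))
  ver_date <- c(date_latest, date_first[dup_idx])
  primaryid <- paste0(caseid[ver_case], ver_no)

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid[ver_case], caseversion = ver_no,
    fda_dt = ver_date, age = age_val[ver_case], age_cod = age_cod[ver_case],
    sex = sex_code[ver_case], occp_cod = occp[ver_case],
    occr_country = country[ver_case])

  # DRUG: the PS mention plus concomitants, repeated in every version
  pid_of <- function(case, version) {
    if (!length(case)) return(character(0))  # paste0 would recycle to "1"
    paste0(caseid[case], version)
  }
  con_dup <- is_dup[con_case]
  drug <- data.table::data.table(
    primaryid = c(pid_of(seq_len(n), latest_version),
                  pid_of(dup_idx, 1L),
                  pid_of(con_case, latest_version[con_case]),
                  pid_of(con_case[con_dup], 1L)),
    caseid = caseid[c(seq_len(n), dup_idx, con_case, con_case[con_dup])],
    role_cod = c(rep("PS", n + length(dup_idx)),
                 rep("C", length(con_case) + sum(con_dup))),
    drugname = c(ps_verbatim, ps_verbatim[dup_idx],
                 con_verbatim, con_verbatim[con_dup]))

  # REAC: latest version carries all drawn slots; the earlier version of a
  # duplicated case omits the dropped PT
  first_sel <- is_dup[slot_case] &
    (is.na(drop_pt[slot_case]) | slot_pt != drop_pt[slot_case])
  reac <- data.table::data.table(
    primaryid = c(pid_of(slot_case, latest_version[slot_case]),
                  pid_of(slot_case[first_sel], 1L)),
    caseid = caseid[c(slot_case, slot_case[first_sel])],
    pt = pt_name(c(slot_pt, slot_pt[first_sel])))

  # OUTC: outcome codes repeated in every version
  oc_case <- c(seq_len(n), which(has_extra))
  oc_code <- c(outcome, extra_outc[has_extra])
  oc_dup <- is_dup[oc_case]
  outc <- data.table::data.table(
    primaryid = c(pid_of(oc_case, latest_version[oc_case]),
                  pid_of(oc_case[oc_dup], 1L)),
    caseid = caseid[c(oc_case, oc_case[oc_dup])],
    outc_cod = c(oc_code, oc_code[oc_dup]))

  fw <- function(x, f) {
    data.table::fwrite(x, file.path(out_dir, f), sep = "$", quote = FALSE)
  }
  fw(demo, sprintf("DEMO%s.txt", quarter))
  fw(drug, sprintf("DRUG%s.txt", quarter))
  fw(reac, sprintf("REAC%s.txt", quarter))
  fw(outc, sprintf("OUTC%s.txt", quarter))

  # vocabulary fixtures: dictionary covers every variant the generator emits
  di <- seq_len(config$n_drugs)
  dict <- data.table::data.table(
    synonym = c(drug_name(di), sprintf("BR_DRUG_%04d", di),
                sprintf("DRUG %04d", di)),
    ingredient = rep(drug_name(di), 3L))
  pe <- seq_len(config$n_events)
  ptsoc <- data.table::data.table(
    pt = pt_name(pe), soc = soc_name((pe - 1L) %% config$n_socs + 1L))
  data.table::fwrite(dict, file.path(out_dir, "drug_dictionary.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(ptsoc, file.path(out_dir, "pt_soc_map.tsv"),
                     sep = "\t", quote = FALSE)

  truth_cases <- data.table::data.table(
    caseid = caseid, max_version = latest_version,
    n_versions = ifelse(is_dup, 2L, 1L),
    ps_drug = drug_name(ps_drug),
    n_pts = vapply(pt_by_case, function(v) length(unique(v)), integer(1)),
    sex = sex_cat, age_band = age_band, age = age, reporter = reporter,
    country = country, outcome = outcome)
  signals <- data.table::data.table(
    drug = drug_name(config$planted_signals$drug),
    event = pt_name(config$planted_signals$event),
    lambda = config$planted_signals$lambda)
  data.table::fwrite(truth_cases, file.path(out_dir, "truth_cases.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(signals, file.path(out_dir, "truth_signals.tsv"),
                     sep = "\t", quote = FALSE)

  files <- file.path(out_dir, c(sprintf(c("DEMO%s.txt", "DRUG%s.txt",
                                          "REAC%s.txt", "OUTC%s.txt"),
                                        quarter),
                                "drug_dictionary.tsv", "pt_soc_map.tsv",
                                "truth_cases.tsv", "truth_signals.tsv"))
  structure(list(config = config, quarter = quarter, cases = truth_cases,
                 case_pts = pt_by_case, signals = signals, files = files),
            class = "faers_ground_truth")
}

#' Expected contingency-table cells under the generator's rate model
#'
#' Closed-form expectations of the `(a, b, c, d)` cells of the 2x2 table for
#' one (drug, event) pair, where the counting unit is the (case, PT) pair
#' with PTs de-duplicated within a case (the convention used by
#' [build_pt_tables()]). With `K ~` zero-truncated Poisson(`mu`) PT slots
#' per case and per-slot probability `q` of the event given the case's PS
#' drug, the probability that the event appears in a case is
#' `1 - (exp(-mu q) - exp(-mu)) / (1 - exp(-mu))`, and every cell is a sum
#' of such inclusion probabilities over drugs and events. Duplicate case
#' versions and name variants do not alter the expectations because
#' deduplication retains the canonical content and the dictionary resolves
#' every variant.
#'
#' @param config A [synthetic_config()].
#' @param drug,event 1-based target indices.
#' @return Named numeric vector `c(a, b, c, d)`.
#' @export
expected_cell_counts <- function(config, drug, event) {
  stopifnot(inherits(config, "synthetic_config"))
  if (drug < 1 || drug > config$n_drugs) {
    stop("drug index out of range", call. = FALSE)
  }
  if (event < 1 || event > config$n_events) {
    stop("event index out of range", call. = FALSE)
  }
  mu <- config$background_rate
  inc <- function(q) 1 - (exp(-mu * q) - exp(-mu)) / (1 - exp(-mu))
  p_g <- 1 / config$n_drugs
  ps <- config$planted_signals
  ne <- config$n_events

  # per-drug: normalization and planted rows
  drug_rows <- function(g) ps[ps$drug == g, , drop = FALSE]
  denom <- function(g) ne + sum(drug_rows(g)$lambda - 1)
  q_ge <- function(g, e) {
    r <- drug_rows(g)
    lam <- if (e %in% r$event) r$lambda[r$event == e] else 1
    lam / denom(g)
  }
  # expected distinct PTs per case for drug g
  pairs_per_case <- function(g) {
    r <- drug_rows(g)
    (ne - nrow(r)) * inc(1 / denom(g)) + sum(inc(r$lambda / denom(g)))
  }

  n <- config$n_cases
  e_a <- n * p_g * inc(q_ge(drug, event))
  e_target <- n * p_g * pairs_per_case(drug)

  planted_drugs <- unique(ps$drug)
  bg_drugs <- config$n_drugs - length(planted_drugs)
  e_event <- n * p_g * (bg_drugs * inc(1 / ne) +
                          sum(vapply(planted_drugs, function(g) {
                            inc(q_ge(g, event))
                          }, numeric(1))))
  e_total <- n * p_g * (bg_drugs * ne * inc(1 / ne) +
                          sum(vapply(planted_drugs, pairs_per_case,
                                     numeric(1))))
  c(a = e_a, b = e_target - e_a, c = e_event - e_a,
    d = e_total - e_target - e_event + e_a)
}

#' Monte Carlo contingency tables for one drug-event pair
#'
#' Table-level simulation of the generator model: draws `n_rep` 2x2 tables
#' from a multinomial over the four cells with probabilities proportional to
#' [expected_cell_counts()] and total size equal to the expected number of
#' (case, PT) pairs. This reproduces the sampling distribution of the
#' pipeline's per-pair table (with the total pair count held at its
#' expectation) at a tiny fraction of the cost of writing and re-reading
#' quarterly files, and is the path used for operating-characteristic
#' studies (null calibration, parameter recovery).
#'
#' @param config A [synthetic_config()].
#' @param drug,event 1-based target indices.
#' @param n_rep Number of replicate tables.
#' @param seed Optional seed (the caller's RNG state is restored).
#' @return A `data.frame` with `n_rep` rows and columns `a`, `b`, `c`, `d`.
#' @export
simulate_pair_tables <- function(config, drug, event, n_rep, seed = NULL) {
  e <- expected_cell_counts(config, drug, event)
  size <- round(sum(e))
  draw <- function() {
    m <- stats::rmultinom(n_rep, size, e / sum(e))
    data.frame(a = m[1, ], b = m[2, ], c = m[3, ], d = m[4, ])
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
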