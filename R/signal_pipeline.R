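#' Signal thresholds of the combined four-algorithm criterion
#'
#' Defaults: a drug--event pair is a signal only if, simultaneously,
#' `a >= 3`, `ROR >= 3` with 95% CI lower limit > 1, `PRR >= 2` with 95% CI
#' lower limit > 1, `IC025 > 0`, and `EBGM05 > 2`.
#'
#' @param min_a Minimum report (pair) count supporting the cell.
#' @param ror,ror_lo ROR point and CI-lower thresholds.
#' @param prr,prr_lo PRR point and CI-lower thresholds.
#' @param ic025 IC lower-bound threshold (exclusive).
#' @param ebgm05 EBGM lower-bound threshold (exclusive).
#' @return A named list of thresholds.
#' @export
signal_thresholds <- function(min_a = 3, ror = 3, ror_lo = 1, prr = 2,
                              prr_lo = 1, ic025 = 0, ebgm05 = 2) {
  th <- list(min_a = min_a, ror = ror, ror_lo = ror_lo, prr = prr,
             prr_lo = prr_lo, ic025 = ic025, ebgm05 = ebgm05)
  if (any(!vapply(th, is.finite, logical(1))) ||
      any(unlist(th[c("min_a", "ror", "prr")]) <= 0)) {
    stop("signal thresholds must be finite (point thresholds positive)",
         call. = FALSE)
  }
  th
}

#' Apply the per-algorithm thresholds and the combined signal criterion
#'
#' Each algorithm gets a boolean flag; the combined verdict is their
#' conjunction. Undefined statistics (`NA`) make the corresponding flag
#' `FALSE`, never `NA`, so rows with zero cells are auditable but cannot be
#' signals.
#'
#' @param stats A `data.frame` from [signal_stats()] (must include column
#'   `a`).
#' @param thresholds A list from [signal_thresholds()].
#' @return `stats` with added logical columns `ror_pos`, `prr_pos`,
#'   `ic_pos`, `ebgm_pos`, `support` (`a >= min_a`) and `combined`.
#' @export
evaluate_signals <- function(stats, thresholds = signal_thresholds()) {
  th <- thresholds
  yes <- function(x) !is.na(x) & x
  support <- yes(stats$a >= th$min_a)
  out <- cbind(stats, data.frame(
    ror_pos = support & yes(stats$ror >= th$ror) &
      yes(stats$ror_lo > th$ror_lo),
    prr_pos = support & yes(stats$prr >= th$prr) &
      yes(stats$prr_lo > th$prr_lo),
    ic_pos = yes(stats$ic025 > th$ic025),
    ebgm_pos = yes(stats$ebgm05 > th$ebgm05),
    support = support))
  out$combined <- out$ror_pos & out$prr_pos & out$ic_pos & out$ebgm_pos &
    out$support
  out
}

#' Rank signal rows by a statistic
#'
#' Stable descending sort by the chosen statistic; ties are broken by `a`
#' (descending), then by term lexicographically.
#'
#' @param rows A `data.frame` of evaluated signal rows containing the
#'   statistic column, `a`, and a term column (`pt`, `soc`, or `term`).
#' @param by Statistic column name (e.g. `"ror"`, `"ebgm"`).
#' @param top Keep at most this many rows (default all).
#' @return The reordered (and truncated) `data.frame`.
#' @export
rank_signals <- function(rows, by = "ror", top = Inf) {
  if (!by %in% names(rows) || !is.numeric(rows[[by]])) {
    stop("unknown ranking statistic: ", by, call. = FALSE)
  }
  term_col <- intersect(c("term", "pt", "soc"), names(rows))[1]
  if (is.na(term_col)) stop("rows carry no term column", call. = FALSE)
  ord <- order(-xtfrm(rows[[by]]), -rows$a, rows[[term_col]],
               method = "radix")
  out <- rows[ord, , drop = FALSE]
  utils::head(out, n = if (is.finite(top)) top else nrow(out))
}

#' Descriptive summary of a report cohort
#'
#' Counts and percentages per category block: sex, age band (`<65`,
#' `65-75` lower-inclusive, `>=75`, unknown), reporter occupation, country
#' (the four most frequent plus `other`), and outcome. When a case carries
#' several outcome codes it is counted once under the most severe one
#' (default precedence `DE > LT > DS > CA > RI > HO > OT`); set
#' `outcome_mode = "multi"` to count every code.
#'
#' @param cases Deduplicated `cases` table (typically restricted to
#'   target-drug reports).
#' @param outcomes Matching `outcomes` mention table.
#' @param outcome_mode `"precedence"` (default) or `"multi"`.
#' @param precedence Severity order, most severe first.
#' @return A `data.table` with columns `block`, `category`, `n`, `pct`.
#' @export
describe_cohort <- function(cases, outcomes,
                            outcome_mode = c("precedence", "multi"),
                            precedence = c("DE", "LT", "DS", "CA", "RI",
                                           "HO", "OT")) {
  outcome_mode <- match.arg(outcome_mode)
  cases <- data.table::as.data.table(cases)
  n_cases <- nrow(cases)
  block <- function(name, x, levels = NULL) {
    x <- as.character(x)
    tab <- table(if (is.null(levels)) x else factor(x, levels = levels))
    data.table::data.table(block = name, category = names(tab),
                           n = as.integer(tab),
                           pct = round(100 * as.integer(tab) / n_cases, 2))
  }
  age_band <- ifelse(is.na(cases$age_years), "unknown",
                     ifelse(cases$age_years < 65, "<65",
                            ifelse(cases$age_years < 75, "65-75", ">=75")))
  cn <- cases$country
  top4 <- names(sort(table(cn[cn != "unknown"]), decreasing = TRUE))
  top4 <- utils::head(top4, 4L)
  country_cat <- ifelse(cn %in% top4, cn, "other")

  oc <- data.table::as.data.table(outcomes)
  oc <- oc[oc$primaryid %in% cases$primaryid & oc$outcome %in% precedence]
  if (outcome_mode == "precedence") {
    oc[, rank := match(outcome, precedence)]
    oc <- oc[order(oc$primaryid, oc$rank)]
    oc <- oc[!duplicated(oc$primaryid)]
  }
  out <- data.table::rbindlist(list(
    data.table::data.table(block = "total", category = "cases",
                           n = n_cases, pct = 100),
    block("sex", cases$sex, c("female", "male", "unknown")),
    block("age", age_band, c("<65", "65-75", ">=75", "unknown")),
    block("reporter", cases$reporter),
    block("country", country_cat, c(top4, "other")),
    block("outcome", factor(oc$outcome, levels = precedence))))
  out[]
}

#' Run the full signal-detection workflow on one or more quarters
#'
#' Ingest, deduplicate, normalize drug names, build PT- and SOC-level 2x2
#' tables for the target ingredient, compute all five disproportionality
#' statistics, apply the combined four-algorithm criterion, and summarize
#' the target cohort. Stage counts (rows read, cases after deduplication,
#' unresolved drug names, unmapped PTs) are collected in `log`.
#'
#' @param dir Directory with the quarterly files.
#' @param quarters Character vector of quarter labels, e.g. `"24Q3"`.
#' @param target Canonical ingredient of interest.
#' @param vocab A `vocabulary_map`, or `NULL` to load from `drug_file` /
#'   `meddra_file`.
#' @param drug_file,meddra_file Vocabulary paths used when `vocab` is
#'   `NULL`.
#' @param thresholds [signal_thresholds()].
#' @param priors [bcpnn_priors()] for the IC bound.
#' @param ebgm_z EBGM lower-bound multiplier (default 1.645).
#' @param ps_only,dedup_within_case Passed to [build_pt_tables()].
#' @param haldane Passed to [signal_stats()].
#' @return A list of class `signal_run`: `pt` and `soc` signal tables
#'   (statistics + decision flags), `cohort` summary, and `log`.
#' @export
detect_signals <- function(dir, quarters, target, vocab = NULL,
                           drug_file = file.path(dir, "drug_dictionary.tsv"),
                           meddra_file = file.path(dir, "pt_soc_map.tsv"),
                           thresholds = signal_thresholds(),
                           priors = bcpnn_priors(), ebgm_z = 1.645,
                           ps_only = TRUE, dedup_within_case = TRUE,
                           haldane = FALSE) {
  if (is.null(vocab)) vocab <- load_vocabulary(drug_file, meddra_file)
  qs <- lapply(quarters, function(q) read_faers_quarter(dir, q))
  merged <- list(
    cases = data.table::rbindlist(lapply(qs, `[[`, "cases")),
    drugs = data.table::rbindlist(lapply(qs, `[[`, "drugs")),
    events = data.table::rbindlist(lapply(qs, `[[`, "events")),
    outcomes = data.table::rbindlist(lapply(qs, `[[`, "outcomes")),
    log = list())
  if (nrow(merged$cases) == 0L) {
    stop("ingest stage: no DEMO rows in quarters ",
         paste(quarters, collapse = ", "), call. = FALSE)
  }
  if (nrow(merged$events) == 0L) {
    stop("ingest stage: no REAC rows in quarters ",
         paste(quarters, collapse = ", "), call. = FALSE)
  }
  deduped <- deduplicate_cases(merged)
  deduped$drugs <- normalize_drug_names(deduped$drugs, vocab)

  pt_tab <- build_pt_tables(deduped, target, ps_only = ps_only,
                            dedup_within_case = dedup_within_case)
  soc_tab <- build_soc_tables(pt_tab, vocab)
  decorate <- function(tab) {
    st <- signal_stats(tab$a, tab$b, tab$c, tab$d, priors = priors,
                       ebgm_z = ebgm_z, haldane = haldane)
    cbind(tab[, !c("a", "b", "c", "d", "n"), with = FALSE],
          evaluate_signals(st, thresholds))
  }
  pt_rows <- decorate(pt_tab)
  pt_rows$soc <- soc_of(pt_rows$pt, vocab)
  soc_rows <- decorate(soc_tab)

  sel <- deduped$drugs$resolved & deduped$drugs$ingredient == target
  if (ps_only) sel <- sel & deduped$drugs$role == "PS"
  target_cases <- deduped$cases[
    deduped$cases$case_id %in% unique(deduped$drugs$case_id[sel])]
  cohort <- describe_cohort(target_cases, deduped$outcomes)

  structure(list(
    pt = rank_signals(pt_rows, by = "ror"),
    soc = rank_signals(soc_rows, by = "ror"),
    cohort = cohort,
    log = c(deduped$log, list(
      quarters = quarters,
      unresolved_drug_names = attr(deduped$drugs, "unresolved"),
      target_cases = nrow(target_cases),
      pts_observed = nrow(pt_tab),
      unmapped_pts = sum(soc_of(pt_tab$pt, vocab) == "unmapped")))),
    class = "signal_run")
}

#' Export a signal run as delimited text and JSON
#'
#' Writes `pt_signals.tsv`, `soc_signals.tsv`, `cohort_summary.tsv` and a
#' `run_log.json` with the stage counts, mirroring the usual published
#' table layouts (term, count, statistic columns with interval bounds,
#' per-algorithm flags, combined verdict).
#'
#' @param run A `signal_run` from [detect_signals()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_signal_tables <- function(run, out_dir) {
  stopifnot(inherits(run, "signal_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("pt_signals.tsv", "soc_signals.tsv",
                                "cohort_summary.tsv", "run_log.json"))
  data.table::fwrite(run$pt, paths[1], sep = "\t")
  data.table::fwrite(run$soc, paths[2], sep = "\t")
  data.table::fwrite(run$cohort, paths[3], sep = "\t")
  jsonlite::write_json(run$log, paths[4], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
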