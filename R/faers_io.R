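#' Read one FAERS-style quarter
#'
#' Loads the dollar-delimited `DEMO`, `DRUG`, `REAC` and (if present)
#' `OUTC` tables for a quarter, e.g. `DEMO24Q3.txt`. The post-2012 dialect
#' is expected: `primaryid` is the case id concatenated with the case
#' version, alongside explicit `caseid`/`caseversion` columns. Legacy files
#' that carry an `isr` column instead are handled by treating ISR as the
#' version id under the shared `caseid`. Ages are converted to years from
#' the FAERS unit codes (`YR`, `DEC`, `MON`, `WK`, `DY`, `HR`; `DEC` is
#' deliberately read as years, see Details), reporter and sex codes are
#' mapped to readable categories, and unparseable rows are counted in the
#' returned log rather than dropped silently.
#'
#' @details `DEC` ("decade") is ambiguous in legacy FAERS documentation;
#' it is treated as years and counted in `log$age_dec_rows` so the choice
#' is auditable. Converted ages of 150 years or more are set to missing.
#'
#' @param dir Directory holding the quarter's files.
#' @param quarter Quarter label, e.g. `"24Q3"`.
#' @return A list of class `faers_quarter`: `cases` (one row per DEMO row,
#'   pre-deduplication), `drugs`, `events`, `outcomes` (all
#'   `data.table`s keyed by `primaryid`), and `log` (row counts and
#'   skip/flag counters).
#' @export
read_faers_quarter <- function(dir, quarter) {
  paths <- file.path(dir, sprintf(c("DEMO%s.txt", "DRUG%s.txt",
                                    "REAC%s.txt", "OUTC%s.txt"), quarter))
  names(paths) <- c("demo", "drug", "reac", "outc")
  for (nm in c("demo", "drug", "reac")) {
    if (!file.exists(paths[[nm]])) {
      stop("missing FAERS file: ", paths[[nm]], call. = FALSE)
    }
  }
  rd <- function(path) {
    data.table::fread(path, sep = "$", colClasses = "character",
                      header = TRUE, na.strings = NULL)
  }
  demo <- rd(paths[["demo"]])
  need_demo <- c("caseid", "sex")
  if (!all(need_demo %in% names(demo)) ||
      !any(c("primaryid", "isr") %in% names(demo))) {
    stop("DEMO header mismatch; expected columns: primaryid (or isr), ",
         "caseid, caseversion, fda_dt (or event_dt), age, age_cod, sex, ",
         "occp_cod, occr_country", call. = FALSE)
  }
  if (!"primaryid" %in% names(demo)) demo$primaryid <- demo$isr
  version <- if ("caseversion" %in% names(demo)) {
    suppressWarnings(as.numeric(demo$caseversion))
  } else {
    suppressWarnings(as.numeric(demo$primaryid))
  }
  date_col <- if ("fda_dt" %in% names(demo)) demo$fda_dt
              else if ("event_dt" %in% names(demo)) demo$event_dt
              else rep(NA_character_, nrow(demo))

  age_num <- suppressWarnings(as.numeric(demo$age))
  cod <- toupper(if ("age_cod" %in% names(demo)) demo$age_cod
                 else rep("YR", nrow(demo)))
  div <- c(YR = 1, DEC = 1, MON = 12, WK = 52.1775, DY = 365.25,
           HR = 8765.82)
  fac <- div[cod]
  fac[is.na(fac)] <- 1
  age_years <- age_num / fac
  bad_age <- !is.na(age_years) & (age_years < 0 | age_years >= 150)
  age_years[bad_age] <- NA_real_

  sex_map <- c(F = "female", M = "male")
  occp_map <- c(MD = "physician", PH = "pharmacist", CN = "consumer",
                OT = "other health-professional",
                HP = "other health-professional", LW = "other")
  cases <- data.table::data.table(
    primaryid = demo$primaryid,
    case_id = demo$caseid,
    version_id = version,
    receipt_date = date_col,
    sex = unname(ifelse(demo$sex %in% names(sex_map),
                        sex_map[demo$sex], "unknown")),
    age_years = age_years,
    reporter = if ("occp_cod" %in% names(demo)) {
      unname(ifelse(demo$occp_cod %in% names(occp_map),
                    occp_map[demo$occp_cod], "unknown"))
    } else rep("unknown", nrow(demo)),
    country = if ("occr_country" %in% names(demo)) {
      ifelse(demo$occr_country == "", "unknown", demo$occr_country)
    } else rep("unknown", nrow(demo)))

  drug_raw <- rd(paths[["drug"]])
  if (!all(c("role_cod", "drugname") %in% names(drug_raw)) ||
      !any(c("primaryid", "isr") %in% names(drug_raw))) {
    stop("DRUG header mismatch; expected columns: primaryid (or isr), ",
         "caseid, role_cod, drugname", call. = FALSE)
  }
  if (!"primaryid" %in% names(drug_raw)) drug_raw$primaryid <- drug_raw$isr
  drug_bad <- !(toupper(drug_raw$role_cod) %in% c("PS", "SS", "C", "I"))
  drugs <- data.table::data.table(
    primaryid = drug_raw$primaryid[!drug_bad],
    case_id = if ("caseid" %in% names(drug_raw)) {
      drug_raw$caseid[!drug_bad]
    } else rep(NA_character_, sum(!drug_bad)),
    role = toupper(drug_raw$role_cod[!drug_bad]),
    verbatim_name = drug_raw$drugname[!drug_bad],
    ingredient = NA_character_,
    resolved = NA)

  reac_raw <- rd(paths[["reac"]])
  if (!"pt" %in% names(reac_raw) ||
      !any(c("primaryid", "isr") %in% names(reac_raw))) {
    stop("REAC header mismatch; expected columns: primaryid (or isr), ",
         "caseid, pt", call. = FALSE)
  }
  if (!"primaryid" %in% names(reac_raw)) reac_raw$primaryid <- reac_raw$isr
  reac_bad <- is.na(reac_raw$pt) | reac_raw$pt == ""
  events <- data.table::data.table(
    primaryid = reac_raw$primaryid[!reac_bad],
    case_id = if ("caseid" %in% names(reac_raw)) {
      reac_raw$caseid[!reac_bad]
    } else rep(NA_character_, sum(!reac_bad)),
    pt = reac_raw$pt[!reac_bad])

  outcomes <- if (file.exists(paths[["outc"]])) {
    oc <- rd(paths[["outc"]])
    if (!"primaryid" %in% names(oc) && "isr" %in% names(oc)) {
      oc$primaryid <- oc$isr
    }
    data.table::data.table(primaryid = oc$primaryid,
                           case_id = if ("caseid" %in% names(oc)) oc$caseid
                                     else NA_character_,
                           outcome = toupper(oc$outc_cod))
  } else {
    data.table::data.table(primaryid = character(), case_id = character(),
                           outcome = character())
  }

  structure(list(
    cases = cases, drugs = drugs, events = events, outcomes = outcomes,
    log = list(demo_rows = nrow(demo), drug_rows = nrow(drug_raw),
               reac_rows = nrow(reac_raw), outc_rows = nrow(outcomes),
               skipped_drug_rows = sum(drug_bad),
               skipped_reac_rows = sum(reac_bad),
               invalid_age_rows = sum(bad_age),
               age_dec_rows = sum(cod == "DEC", na.rm = TRUE))),
    class = "faers_quarter")
}

#' Deduplicate case versions, keeping the latest report
#'
#' A spontaneous-report case may be submitted several times as updated
#' versions. For each `case_id` exactly one version is retained: the one
#' with the maximal `version_id`; ties are broken by the latest
#' `receipt_date`, then by the lexicographically largest `primaryid`. All
#' drug, event and outcome mentions of dropped versions are removed. The
#' operation is idempotent and never invents records.
#'
#' @param quarter A `faers_quarter` list from [read_faers_quarter()] (or
#'   several quarters row-bound into one).
#' @return A `faers_quarter` with one row per `case_id` in `cases` and
#'   mentions restricted to the retained versions; `log` gains
#'   `cases_before`/`cases_after`.
#' @export
deduplicate_cases <- function(quarter) {
  cases <- data.table::as.data.table(quarter$cases)
  if (nrow(cases) == 0L) return(quarter)
  ord <- order(cases$case_id,
               -data.table::frank(cases$version_id, ties.method = "dense",
                                  na.last = FALSE),
               -data.table::frank(cases$receipt_date, ties.method = "dense",
                                  na.last = FALSE),
               -data.table::frank(cases$primaryid, ties.method = "dense"))
  sorted <- cases[ord]
  keep <- sorted[!duplicated(sorted$case_id)]
  keep_ids <- keep$primaryid
  res <- quarter
  res$cases <- keep
  res$drugs <- quarter$drugs[quarter$drugs$primaryid %in% keep_ids]
  res$events <- quarter$events[quarter$events$primaryid %in% keep_ids]
  res$outcomes <- quarter$outcomes[quarter$outcomes$primaryid %in% keep_ids]
  res$log$cases_before <- nrow(cases)
  res$log$cases_after <- nrow(keep)
  res
}

#' Normalize verbatim drug names against the synonym dictionary
#'
#' FAERS drug names are free text (generic names, brands, study codes,
#' misspellings). Matching is case-insensitive after trimming surrounding
#' whitespace and punctuation ([normalize_name_key()]). Matched mentions
#' get the canonical `ingredient`; unmatched mentions are flagged
#' `resolved = FALSE` and counted, never dropped.
#'
#' @param drugs A `data.table` of drug mentions with `verbatim_name`.
#' @param vocab A `vocabulary_map` from [load_vocabulary()].
#' @return The mentions table with `ingredient` and `resolved` filled in;
#'   attribute `unresolved` holds the unmatched count.
#' @export
normalize_drug_names <- function(drugs, vocab) {
  stopifnot(inherits(vocab, "vocabulary_map"))
  if (length(vocab$drug_synonyms) == 0L) {
    stop("drug-synonym dictionary is empty", call. = FALSE)
  }
  out <- data.table::as.data.table(drugs)
  key <- normalize_name_key(out$verbatim_name)
  ing <- unname(vocab$drug_synonyms[key])
  out[, `:=`(ingredient = ing, resolved = !is.na(ing))]
  data.table::setattr(out, "unresolved", sum(is.na(ing)))
  out
}
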