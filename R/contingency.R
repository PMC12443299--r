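#' Build 2x2 contingency tables for the target drug against every PT
#'
#' The counting unit is the (case, PT) pair, with repeated identical PTs
#' within one case counted once (switchable). For each preferred term the
#' four-grid is: `a` = pairs from cases whose primary-suspect ingredient is
#' the target and whose PT is the event, `b` = remaining pairs from target
#' cases, `c` = pairs from comparator cases with the event, `d` = the rest.
#' The four cells partition the full set of (case, PT) pairs, so margins
#' are consistent by construction: `a + b` is the target side's pair total
#' for every PT, and `a + c` is the event's pair total.
#'
#' A case is on the target side when the target ingredient appears with the
#' primary-suspect role (`ps_only = TRUE`, the default); cases mentioning
#' the target only as secondary suspect, concomitant or interacting
#' contribute to the comparator side.
#'
#' @param quarter A deduplicated, name-normalized `faers_quarter`.
#' @param target Canonical ingredient string of the drug of interest.
#' @param ps_only If `TRUE`, only primary-suspect mentions define the
#'   target side.
#' @param dedup_within_case If `TRUE` (default), a PT appearing several
#'   times in one case counts once.
#' @return A `data.table` with columns `pt`, `a`, `b`, `c`, `d`, `n`
#'   (one row per PT present in the data). Empty, with a warning, when the
#'   target does not occur.
#' @export
build_pt_tables <- function(quarter, target, ps_only = TRUE,
                            dedup_within_case = TRUE) {
  drugs <- data.table::as.data.table(quarter$drugs)
  events <- data.table::as.data.table(quarter$events)
  sel <- !is.na(drugs$ingredient) & drugs$ingredient == target
  if (ps_only) sel <- sel & drugs$role == "PS"
  target_cases <- unique(drugs$case_id[sel])
  if (length(target_cases) == 0L) {
    warning("target ingredient '", target, "' not found in the data")
    return(data.table::data.table(pt = character(), a = integer(),
                                  b = integer(), c = integer(),
                                  d = integer(), n = integer()))
  }
  pairs <- events[, c("case_id", "pt")]
  if (dedup_within_case) pairs <- unique(pairs)
  pairs[, is_target := case_id %in% target_cases]
  n_total <- nrow(pairs)
  n_target <- sum(pairs$is_target)
  tab <- pairs[, .(a = sum(is_target), ac = .N), by = pt]
  tab[, `:=`(b = n_target - a,
             c = ac - a)]
  tab[, d := n_total - n_target - c]
  tab[, `:=`(n = n_total, ac = NULL)]
  data.table::setorder(tab, pt)
  tab[]
}

#' Aggregate PT-level tables to the system organ class level
#'
#' SOC cell `a` is the sum of member-PT `a` values (distinct (case, PT)
#' pairs, not distinct cases), and the margins are recomputed consistently:
#' the target-side total `a + b` is unchanged and `d` completes the table.
#' PTs absent from the vocabulary are accumulated into an `"unmapped"` SOC
#' bucket so nothing is lost silently.
#'
#' @param pt_tables Output of [build_pt_tables()].
#' @param vocab A `vocabulary_map` from [load_vocabulary()].
#' @return A `data.table` with columns `soc`, `a`, `b`, `c`, `d`, `n`.
#' @export
build_soc_tables <- function(pt_tables, vocab) {
  tab <- data.table::as.data.table(pt_tables)
  if (nrow(tab) == 0L) {
    return(data.table::data.table(soc = character(), a = integer(),
                                  b = integer(), c = integer(),
                                  d = integer(), n = integer()))
  }
  n_total <- tab$n[1L]
  n_target <- tab$a[1L] + tab$b[1L]
  tab[, soc := soc_of(pt, vocab)]
  out <- tab[, .(a = sum(a), c = sum(c)), by = soc]
  out[, `:=`(b = n_target - a,
             d = n_total - n_target - c,
             n = n_total)]
  data.table::setcolorder(out, c("soc", "a", "b", "c", "d", "n"))
  data.table::setorder(out, soc)
  out[]
}
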