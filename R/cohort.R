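#' First qualifying hospitalization per enrollee
#'
#' An admission qualifies when at least one of its first ten diagnosis
#' codes belongs to the ADRD code set; the earliest such admission defines
#' cohort entry. Enrollees with no qualifying admission are excluded.
#' Records whose diagnosis string cannot be parsed are skipped with a
#' warning.
#'
#' @param admissions data.frame with columns `enrollee_id`, `admit_date`,
#'   `discharge_date`, `dx_codes` (semicolon-delimited), `source_code`,
#'   `snf_flag`, `zip`.
#' @param adrd_codes character vector of cohort-defining diagnosis codes.
#' @return data.frame, one row per qualifying enrollee: `enrollee_id`,
#'   `qualifying_date`, `qualifying_discharge`, `zip`.
#' @export
identify_qualifying <- function(admissions, adrd_codes) {
  stopifnot(all(c("enrollee_id", "admit_date", "dx_codes") %in% names(admissions)))
  dx <- strsplit(as.character(admissions$dx_codes), ";", fixed = TRUE)
  bad <- vapply(dx, function(d) length(d) == 0L || all(!nzchar(d)), logical(1))
  bad <- bad | is.na(admissions$dx_codes)
  if (any(bad)) {
    warning(sum(bad), " admission(s) with malformed diagnosis codes skipped")
    dx[bad] <- list(character(0))
  }
  hit <- vapply(dx, function(d) any(d[seq_len(min(10L, length(d)))] %in% adrd_codes),
                logical(1))
  q <- admissions[hit, , drop = FALSE]
  q <- q[order(q$enrollee_id, q$admit_date), , drop = FALSE]
  q <- q[!duplicated(q$enrollee_id), , drop = FALSE]
  data.frame(enrollee_id = q$enrollee_id, qualifying_date = q$admit_date,
             qualifying_discharge = q$discharge_date, zip = q$zip,
             stringsAsFactors = FALSE)
}

#' Eligibility rules for outcome selection
#'
#' @param washout_days minimum gap between the qualifying hospitalization
#'   and the outcome admission (default 30).
#' @param washout_anchor date the washout counts from: the qualifying
#'   `"admission"` (default) or `"discharge"`.
#' @param readmit_days no further admission may occur within this many days
#'   after the outcome discharge (default 30).
#' @param season_months calendar months of the warm season (default 5:9).
#' @param allowed_sources admission-source codes kept (non-healthcare
#'   facility, clinic referral, emergency room).
#' @param exclude_snf drop skilled-nursing-facility-origin admissions?
#' @return list of class `eligibility_rules`.
#' @export
eligibility_rules <- function(washout_days = 30L,
                              washout_anchor = c("admission", "discharge"),
                              readmit_days = 30L, season_months = 5:9,
                              allowed_sources = c("non-healthcare", "clinic", "er"),
                              exclude_snf = TRUE) {
  structure(list(washout_days = as.integer(washout_days),
                 washout_anchor = match.arg(washout_anchor),
                 readmit_days = as.integer(readmit_days),
                 season_months = as.integer(season_months),
                 allowed_sources = allowed_sources,
                 exclude_snf = isTRUE(exclude_snf)),
            class = "eligibility_rules")
}

#' Select the outcome hospitalization for one enrollee
#'
#' Scans the enrollee's admissions in date order for the first warm-season
#' admission that (i) starts at least `washout_days` after the qualifying
#' anchor, (ii) is not followed by another admission within `readmit_days`
#' of its discharge, (iii) is not of skilled-nursing-facility origin, and
#' (iv) has an allowed admission-source code. Candidates overlapping a
#' later admission interval are flagged and rejected, and the search
#' continues. Returns `NULL` when no admission passes.
#'
#' @param admissions this enrollee's admissions (any order).
#' @param qualifying one row of [identify_qualifying()] output.
#' @param rules an [eligibility_rules()] object.
#' @return data.frame row (`enrollee_id`, `case_date`, `zip`) or `NULL`.
#' @export
select_outcome <- function(admissions, qualifying, rules = eligibility_rules()) {
  a <- admissions[admissions$enrollee_id == qualifying$enrollee_id, , drop = FALSE]
  a <- a[order(a$admit_date), , drop = FALSE]
  anchor <- if (rules$washout_anchor == "admission") qualifying$qualifying_date
            else qualifying$qualifying_discharge
  for (i in seq_len(nrow(a))) {
    d <- a$admit_date[i]
    if (as.integer(d - anchor) < rules$washout_days) next
    if (!(as.integer(format(d, "%m")) %in% rules$season_months)) next
    if (rules$exclude_snf && isTRUE(a$snf_flag[i])) next
    if (!a$source_code[i] %in% rules$allowed_sources) next
    later <- a$admit_date[-seq_len(i)]
    if (length(later)) {
      overlap <- later <= a$discharge_date[i]
      if (any(overlap)) {
        warning("admission intervals overlap for ", qualifying$enrollee_id,
                "; candidate rejected")
        next
      }
      gap <- as.integer(later - a$discharge_date[i])
      if (any(gap <= rules$readmit_days)) next
    }
    return(data.frame(enrollee_id = qualifying$enrollee_id, case_date = d,
                      zip = a$zip[i], stringsAsFactors = FALSE))
  }
  NULL
}

#' Build the outcome-event table for a cohort
#'
#' Applies [identify_qualifying()] then [select_outcome()] across all
#' enrollees, logging the count surviving each filter.
#'
#' @inheritParams identify_qualifying
#' @inheritParams select_outcome
#' @param verbose print the filter ledger?
#' @return data.frame of outcome events (`enrollee_id`, `case_date`, `zip`)
#'   with attribute `filter_counts`.
#' @export
build_cohort <- function(admissions, adrd_codes, rules = eligibility_rules(),
                         verbose = FALSE) {
  qual <- identify_qualifying(admissions, adrd_codes)
  events <- vector("list", nrow(qual))
  for (i in seq_len(nrow(qual)))
    events[[i]] <- select_outcome(admissions, qual[i, , drop = FALSE], rules)
  out <- do.call(rbind, events)
  if (is.null(out))
    out <- data.frame(enrollee_id = character(0), case_date = as.Date(character(0)),
                      zip = character(0), stringsAsFactors = FALSE)
  counts <- c(enrollees = length(unique(admissions$enrollee_id)),
              qualifying = nrow(qual), with_outcome = nrow(out))
  if (verbose) {
    message(sprintf("cohort flow: %d enrollees -> %d with qualifying admission -> %d with eligible outcome",
                    counts[1], counts[2], counts[3]))
  }
  attr(out, "filter_counts") <- counts
  out
}

#' Time-stratified referent days
#'
#' All dates sharing the case day's weekday, calendar month and year,
#' excluding the case day itself — the bidirectional time-stratified
#' control set (a Monday case in July 2014 is matched to the other Mondays
#' of July 2014). Every calendar date yields 3 or 4 controls.
#'
#' @param case_date a `Date` (vector allowed).
#' @return for a single date, a `Date` vector of controls; for a vector, a
#'   list of such vectors.
#' @examples
#' make_referents(as.Date("2014-07-14"))  # the other Mondays of July 2014
#' @export
make_referents <- function(case_date) {
  one <- function(d) {
    first <- as.Date(format(d, "%Y-%m-01"))
    last <- seq(first, by = "month", length.out = 2)[2] - 1
    days <- seq(first, last, by = "day")
    days[format(days, "%u") == format(d, "%u") & days != d]
  }
  if (length(case_date) == 1L) one(case_date) else lapply(case_date, one)
}

#' Assemble case-crossover strata with exposures attached
#'
#' One stratum per outcome event: the case day plus its [make_referents()]
#' controls, each joined to that ZIP's exposure row. Days missing any
#' required exposure are dropped; strata reduced below two days (or whose
#' ZIP is absent from the panel) are excluded, with counts reported in the
#' `dropped` attribute.
#'
#' @param events outcome-event table (`enrollee_id`, `case_date`, `zip`).
#' @param exposures ZIP-day exposure panel containing `zip`, `date` and the
#'   columns in `required`.
#' @param required exposure columns each stratum day must have.
#' @return long data.frame (`stratum_id`, `enrollee_id`, `zip`, `date`,
#'   `case`, exposure columns) with attribute `dropped` (named counts).
#' @export
build_strata <- function(events, exposures,
                         required = c("heat_pctl", "pm25_ugm3")) {
  stopifnot(all(c("zip", "date") %in% names(exposures)),
            all(required %in% names(exposures)))
  key <- paste(exposures$zip, exposures$date)
  dropped <- c(zip_missing = 0L, day_missing = 0L, stratum_too_small = 0L)
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (!ev$zip %in% exposures$zip) {
      dropped["zip_missing"] <- dropped["zip_missing"] + 1L
      next
    }
    dates <- c(ev$case_date, make_referents(ev$case_date))
    idx <- match(paste(ev$zip, dates), key)
    rows <- exposures[idx, required, drop = FALSE]
    ok <- !is.na(idx) & Reduce(`&`, lapply(rows, is.finite))
    dropped["day_missing"] <- dropped["day_missing"] + sum(!ok)
    if (sum(ok) < 2L || !ok[1]) {       # need the case day and >= 1 control
      dropped["stratum_too_small"] <- dropped["stratum_too_small"] + 1L
      next
    }
    st <- data.frame(stratum_id = i, enrollee_id = ev$enrollee_id,
                     zip = ev$zip, date = dates[ok],
                     case = as.integer(dates[ok] == ev$case_date),
                     stringsAsFactors = FALSE)
    st <- cbind(st, rows[ok, , drop = FALSE])
    out[[i]] <- st
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(stratum_id = integer(0), enrollee_id = character(0),
                      zip = character(0), date = as.Date(character(0)),
                      case = integer(0))
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}
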