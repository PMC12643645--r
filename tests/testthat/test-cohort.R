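test_that("qualifying admission needs an ADRD code in the first ten positions", {
  codes <- paste(sprintf("DX%03d", 1:12), collapse = ";")
  at_pos <- function(pos) {
    dx <- sprintf("DX%03d", 1:12); dx[pos] <- "ADRD1"
    paste(dx, collapse = ";")
  }
  adm <- rbind(adm_row("E1", "2005-02-01", dx = at_pos(1)),
               adm_row("E2", "2005-02-01", dx = at_pos(10)),
               adm_row("E3", "2005-02-01", dx = at_pos(11)),
               adm_row("E4", "2005-02-01", dx = codes))
  q <- identify_qualifying(adm, "ADRD1")
  expect_setequal(q$enrollee_id, c("E1", "E2"))
  # earliest of several qualifying admissions wins
  adm2 <- rbind(adm_row("E5", "2006-03-01", dx = at_pos(2)),
                adm_row("E5", "2005-03-01", dx = at_pos(3)))
  expect_equal(identify_qualifying(adm2, "ADRD1")$qualifying_date,
               as.Date("2005-03-01"))
  # malformed code strings are skipped with a warning
  adm3 <- rbind(adm_row("E6", "2005-02-01", dx = NA),
                adm_row("E6", "2005-06-01", dx = at_pos(1)))
  expect_warning(q3 <- identify_qualifying(adm3, "ADRD1"), "malformed")
  expect_equal(q3$qualifying_date, as.Date("2005-06-01"))
})

test_that("outcome selection honors washout, season, SNF and source filters", {
  qual <- data.frame(enrollee_id = "E1", qualifying_date = as.Date("2010-03-01"),
                     qualifying_discharge = as.Date("2010-03-05"), zip = "Z00001")
  # day-19 admission fails the 30-day washout; the June one is selected
  adm <- rbind(adm_row("E1", "2010-03-20"), adm_row("E1", "2010-06-15"))
  expect_equal(select_outcome(adm, qual)$case_date, as.Date("2010-06-15"))
  # outside May-September there is no outcome
  adm <- adm_row("E1", "2010-12-10")
  expect_null(select_outcome(adm, qual))
  # a readmission within 30 days of discharge rejects the candidate and the
  # search continues
  adm <- rbind(adm_row("E1", "2010-06-28", discharge = "2010-07-01"),
               adm_row("E1", "2010-07-20", snf = TRUE),
               adm_row("E1", "2010-08-25"))
  expect_equal(select_outcome(adm, qual)$case_date, as.Date("2010-08-25"))
  # SNF-origin and non-qualifying sources are excluded, and the two filters
  # commute (order-independent outcomes)
  adm <- rbind(adm_row("E1", "2010-06-10", snf = TRUE),
               adm_row("E1", "2010-07-15", source = "transfer"),
               adm_row("E1", "2010-08-20"))
  expect_equal(select_outcome(adm, qual)$case_date, as.Date("2010-08-20"))
  rules2 <- eligibility_rules(exclude_snf = FALSE)
  expect_equal(select_outcome(adm, qual, rules2)$case_date, as.Date("2010-06-10"))
  # washout may anchor at discharge instead of admission
  adm <- adm_row("E1", "2010-06-02")  # 93 days after admission, 89 after discharge
  r30 <- eligibility_rules(washout_days = 92, washout_anchor = "admission")
  expect_not_null <- function(x) expect_false(is.null(x))
  expect_not_null(select_outcome(adm, qual, r30))
  r30d <- eligibility_rules(washout_days = 92, washout_anchor = "discharge")
  expect_null(select_outcome(adm, qual, r30d))
})

test_that("overlapping admission intervals are flagged and rejected", {
  qual <- data.frame(enrollee_id = "E1", qualifying_date = as.Date("2010-01-01"),
                     qualifying_discharge = as.Date("2010-01-04"), zip = "Z00001")
  adm <- rbind(adm_row("E1", "2010-06-10", discharge = "2010-06-25"),
               adm_row("E1", "2010-06-20"))
  expect_warning(out <- select_outcome(adm, qual), "overlap")
  expect_false(isTRUE(out$case_date == as.Date("2010-06-10")))
})

test_that("referent days are the other same-weekday days of the month", {
  expect_equal(make_referents(as.Date("2014-07-14")),
               as.Date(c("2014-07-07", "2014-07-21", "2014-07-28")))
  # bidirectional: a first-Monday case gets later Mondays
  expect_equal(make_referents(as.Date("2014-07-07")),
               as.Date(c("2014-07-14", "2014-07-21", "2014-07-28")))
  # sampled dates across years: always 3 or 4 controls, same weekday/month/year
  set.seed(4)
  for (d in sample(seq(as.Date("2000-01-01"), as.Date("2016-12-31"), 1), 200)) {
    d <- as.Date(d, origin = "1970-01-01")
    ctl <- make_referents(d)
    expect_true(length(ctl) %in% 3:4)
    expect_true(all(format(ctl, "%u") == format(d, "%u")))
    expect_true(all(format(ctl, "%Y-%m") == format(d, "%Y-%m")))
    expect_false(d %in% ctl)
  }
})

test_that("strata attach exposures and drop incomplete days", {
  ev <- data.frame(enrollee_id = "E1", case_date = as.Date("2014-07-14"),
                   zip = "A", stringsAsFactors = FALSE)
  days <- seq(as.Date("2014-07-01"), as.Date("2014-07-31"), 1)
  panel <- data.frame(zip = "A", date = days, heat_pctl = seq_along(days),
                      pm25_ugm3 = 10)
  st <- build_strata(ev, panel)
  expect_equal(nrow(st), 4)              # case + 3 referents
  expect_equal(sum(st$case), 1)
  expect_equal(st$date[st$case == 1], as.Date("2014-07-14"))
  # one control day missing PM2.5 shrinks the stratum by one
  panel2 <- panel
  panel2$pm25_ugm3[panel2$date == as.Date("2014-07-21")] <- NA
  st2 <- build_strata(ev, panel2)
  expect_equal(nrow(st2), 3)
  expect_equal(attr(st2, "dropped")[["day_missing"]], 1)
  # all controls missing: stratum excluded
  panel3 <- panel[panel$date == as.Date("2014-07-14"), ]
  st3 <- build_strata(ev, panel3)
  expect_equal(nrow(st3), 0)
  expect_equal(attr(st3, "dropped")[["stratum_too_small"]], 1)
  # unknown ZIP: excluded and counted
  ev2 <- ev; ev2$zip <- "B"
  st4 <- build_strata(ev2, panel)
  expect_equal(attr(st4, "dropped")[["zip_missing"]], 1)
})

test_that("cohort counting matches hand-injected violations", {
  # 3 enrollees: one clean, one with no ADRD code, one whose only
  # post-washout admission is SNF-origin
  adm <- rbind(
    adm_row("E1", "2004-01-10", dx = "ADRD1;DX001"),
    adm_row("E1", "2004-06-20"),
    adm_row("E2", "2004-01-10", dx = "DX001"),
    adm_row("E2", "2004-06-20"),
    adm_row("E3", "2004-01-10", dx = "ADRD1;DX001"),
    adm_row("E3", "2004-06-20", snf = TRUE))
  ev <- build_cohort(adm, "ADRD1")
  expect_equal(attr(ev, "filter_counts"),
               c(enrollees = 3L, qualifying = 2L, with_outcome = 1L))
  expect_equal(ev$enrollee_id, "E1")
  # every stratum day shares weekday, month and year by construction
  panel <- data.frame(zip = "Z00001",
                      date = seq(as.Date("2004-06-01"), as.Date("2004-06-30"), 1),
                      heat_pctl = 50, pm25_ugm3 = 10)
  st <- build_strata(ev, panel)
  expect_true(all(format(st$date, "%u") == format(st$date[1], "%u")))
  expect_true(all(format(st$date, "%Y-%m") == format(st$date[1], "%Y-%m")))
})
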