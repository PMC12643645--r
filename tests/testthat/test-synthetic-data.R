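test_that("climate map covers every subtype and is deterministic", {
  m <- gen_climate_map(18, 18, seed = 1)
  expect_equal(sort(unique(m$subtype)), sort(m$subtype))  # one per ZIP
  expect_equal(length(unique(m$subtype)), 18)
  expect_true(all(m$type %in% c("Tropical", "Arid", "Temperate", "Continental")))
  # subtype determines type via the leading Koppen letter
  expect_true(all((substr(m$subtype, 1, 1) == "B") == (m$type == "Arid")))
  expect_identical(gen_climate_map(100, 4, seed = 7), gen_climate_map(100, 4, seed = 7))
  m2 <- gen_climate_map(100, 4, seed = 7)
  expect_equal(length(unique(m2$subtype)), 4)
  expect_error(gen_climate_map(2, 5, seed = 3), "n_zips >= n_subtypes")
  expect_error(gen_climate_map(30, 19), "between 1 and 18")
})

test_that("exposure panel has the advertised structure", {
  cfg <- sim_config(n_zips = 4, n_enrollees = 10, date_start = "2003-01-01",
                    date_end = "2003-12-31", rng_seed = 5)
  cm <- gen_climate_map(4, 2, seed = 5)
  p <- gen_exposure_panel(cm, cfg)
  expect_equal(nrow(p), 4 * 365)
  expect_true(all(p$pm25_ugm3 > 0))
  expect_true(all(p$rhmin_pct >= 5 & p$rhmin_pct <= 100))
  expect_true(all(p$heat_pctl >= 0 & p$heat_pctl <= 100, na.rm = TRUE))
  # byte-identical rerun under the same config
  expect_identical(p, gen_exposure_panel(cm, cfg))
  expect_error(gen_exposure_panel(cm[0, ], cfg), "empty climate")
})

test_that("noiseless config collapses tmax to the deterministic seasonal curve", {
  cfg <- sim_config(n_zips = 2, n_enrollees = 5, date_start = "2003-01-01",
                    date_end = "2003-12-31", heat_noise_sd = 0, ar1_rho = 0,
                    rng_seed = 2)
  cm <- gen_climate_map(2, 2, seed = 2)
  p <- gen_exposure_panel(cm, cfg, percentiles = FALSE)
  doy <- as.integer(format(p$date, "%j"))
  season <- cfg$seasonal_amplitude * cos(2 * pi * (doy - 208) / 365.25)
  resid <- p$tmax_c - season
  # per ZIP the residual is the constant subtype baseline
  for (z in unique(p$zip))
    expect_lt(diff(range(resid[p$zip == z])), 1e-10)
})

test_that("PM2.5 is positively coupled to heat and right-skewed", {
  cfg <- sim_config(n_zips = 10, n_enrollees = 10, date_start = "2003-01-01",
                    date_end = "2005-12-31", rng_seed = 3)
  cm <- gen_climate_map(10, 3, seed = 3)
  p <- gen_exposure_panel(cm, cfg, percentiles = FALSE)
  expect_gt(nrow(p), 10000)
  expect_gt(cor(p$tmax_c, log(p$pm25_ugm3)), 0)
  # negative link slope flips the sign
  cfg2 <- sim_config(n_zips = 10, n_enrollees = 10, date_start = "2003-01-01",
                     date_end = "2005-12-31", pm_link_coefs = c(20, -0.25),
                     rng_seed = 3)
  p2 <- gen_exposure_panel(cm, cfg2, percentiles = FALSE)
  expect_lt(cor(p2$tmax_c, log(p2$pm25_ugm3)), 0)
  # warm-season skewness is positive
  warm <- p[as.integer(format(p$date, "%m")) %in% 5:9, ]
  sk <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  expect_gt(sk(warm$pm25_ugm3), 0)
})

test_that("with constant heat the PM2.5 skewness matches the lognormal closed form", {
  # amplitude 0 and no noise make mu(tmax) constant, so pm25 is exactly
  # lognormal and skewness has the closed form (e^{s2}+2) sqrt(e^{s2}-1)
  sd_log <- 0.45
  cfg <- sim_config(n_zips = 6, n_enrollees = 5, date_start = "2003-01-01",
                    date_end = "2007-12-31", seasonal_amplitude = 0,
                    heat_noise_sd = 0, pm_lognoise_sd = sd_log, rng_seed = 4)
  cm <- gen_climate_map(6, 1, seed = 4)
  p <- gen_exposure_panel(cm, cfg, percentiles = FALSE)
  s2 <- sd_log^2
  closed <- (exp(s2) + 2) * sqrt(exp(s2) - 1)
  sk <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  # sample skewness of a lognormal converges slowly; wide band around the
  # closed form, n ~ 11,000
  expect_gt(sk(p$pm25_ugm3), 0.6 * closed)
  expect_lt(sk(p$pm25_ugm3), 1.6 * closed)
})

test_that("admission generator exercises every eligibility filter", {
  cfg <- sim_config(n_zips = 5, n_enrollees = 150, date_start = "2002-01-01",
                    date_end = "2006-12-31", rng_seed = 6)
  cm <- gen_climate_map(5, 2, seed = 6)
  adm <- gen_admissions(cfg, cm, adrd_fraction = 1)
  expect_equal(nrow(identify_qualifying(adm, "ADRD1")), 150)
  # every record carries parseable fields
  expect_true(all(!is.na(adm$admit_date)))
  expect_true(all(adm$discharge_date > adm$admit_date))
  # with all outcome admissions SNF-origin the cohort empties
  adm_snf <- gen_admissions(cfg, cm, adrd_fraction = 1, snf_fraction = 1)
  ev <- build_cohort(adm_snf, "ADRD1")
  expect_equal(nrow(ev), 0)
  # ADRD code at position 11 does not qualify
  adm_late <- gen_admissions(cfg, cm, adrd_fraction = 1, late_code_fraction = 1)
  expect_equal(nrow(identify_qualifying(adm_late, "ADRD1")), 0)
  expect_identical(gen_admissions(cfg, cm), gen_admissions(cfg, cm))
})

test_that("case-day sampling is uniform under a null coefficient", {
  sp <- list(heat_pctl = basis_spec("linear", boundary = c(0, 100), reference = 50))
  n <- 20000
  tmpl <- data.frame(stratum_id = rep(seq_len(n), each = 4),
                     date = as.Date("2010-07-05") + rep(c(0, 7, 14, 21), n),
                     heat_pctl = runif(4 * n, 0, 100))
  st <- sample_case_days(tmpl, 0, sp, seed = 9)
  expect_true(all(tapply(st$case, st$stratum_id, sum) == 1))
  pos <- tapply(seq_len(nrow(st)), st$stratum_id, function(i) which(st$case[i] == 1))
  tab <- tabulate(unlist(pos), 4)
  expect_gt(stats::chisq.test(tab, p = rep(0.25, 4))$p.value, 0.001)
})

test_that("case-day sampling follows the softmax of the true coefficients", {
  # stratum days with x in {0,1,1,1} and beta = log 2: P(case has x = 1)
  # equals 3*2 / (1 + 3*2) = 6/7 by direct softmax evaluation
  n <- 20000
  sp <- list(x = basis_spec("linear", boundary = c(0, 1), reference = 0))
  tmpl <- data.frame(stratum_id = rep(seq_len(n), each = 4),
                     date = as.Date("2010-07-05") + rep(c(0, 7, 14, 21), n),
                     x = rep(c(0, 1, 1, 1), n))
  st <- sample_case_days(tmpl, log(2), sp, seed = 11)
  p_hat <- mean(st$x[st$case == 1])
  expect_equal(p_hat, 6 / 7, tolerance = 0.012)
  # determinism under the same seed
  st2 <- sample_case_days(tmpl, log(2), sp, seed = 11)
  expect_identical(st, st2)
  # strata with missing exposures are rejected
  tmpl$x[1:4] <- NA
  st3 <- sample_case_days(tmpl, log(2), sp, seed = 11)
  expect_false(1 %in% st3$stratum_id)
})

test_that("sim_config validates its invariants and round-trips via YAML", {
  expect_error(sim_config(ar1_rho = 1), "ar1_rho")
  expect_error(sim_config(pm_lognoise_sd = -1), "pm_lognoise_sd")
  expect_error(sim_config(date_start = "2000-06-01", date_end = "2000-08-31"),
               "warm season")
  cfg <- sim_config(n_zips = 7, rng_seed = 42, beta_true = c(0.1, 0.2))
  cfg2 <- sim_config_from_yaml(sim_config_to_yaml(cfg))
  expect_equal(cfg, cfg2)
})
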