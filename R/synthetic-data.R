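#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic study generator. The
#' defaults describe a deliberately plain but recognizable warm-season
#' climate-health world: a May-September analysis window inside a multi-year
#' study period, sinusoidal seasonal heat peaking in late July with
#' first-order autocorrelated day-to-day noise, and right-skewed PM2.5
#' positively coupled to temperature (photochemistry and stagnation both
#' push fine particulate matter up on hot days).
#'
#' `pm_link_coefs` gives the median PM2.5 in ug/m3 as a polynomial in tmax
#' (intercept, slope per degree C, optional curvature); day-level PM2.5 is
#' that median times a lognormal multiplicative error with log-sd
#' `pm_lognoise_sd`, hence strictly positive and right-skewed.
#'
#' @param n_zips,n_enrollees cohort dimensions.
#' @param date_start,date_end study window (must span at least one full
#'   May-September warm season).
#' @param seasonal_amplitude half-range of the seasonal tmax sinusoid, deg C.
#' @param ar1_rho AR(1) coefficient of daily tmax noise, in (-1, 1).
#' @param heat_noise_sd marginal sd of the AR(1) tmax noise, deg C.
#' @param pm_link_coefs numeric length 2 or 3: median PM2.5 as intercept +
#'   slope * tmax (+ curv * tmax^2), ug/m3.
#' @param pm_lognoise_sd lognormal log-scale sd of PM2.5 noise (>= 0).
#' @param beta_true true log-odds coefficients on the model basis scale,
#'   used by [sample_case_days()].
#' @param rng_seed root seed; per-operation child seeds are derived as
#'   documented in the generator functions.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_zips = 50L, n_enrollees = 2000L,
                       date_start = as.Date("2000-01-01"),
                       date_end = as.Date("2004-12-31"),
                       seasonal_amplitude = 12, ar1_rho = 0.6,
                       heat_noise_sd = 3, pm_link_coefs = c(6, 0.25),
                       pm_lognoise_sd = 0.45, beta_true = numeric(0),
                       rng_seed = 1L) {
  date_start <- as.Date(date_start); date_end <- as.Date(date_end)
  if (is.na(date_start) || is.na(date_end) || date_end <= date_start)
    stop("invalid date range")
  # require at least one complete May-September window
  yrs <- seq(as.integer(format(date_start, "%Y")), as.integer(format(date_end, "%Y")))
  full_season <- any(date_start <= as.Date(paste0(yrs, "-05-01")) &
                     date_end >= as.Date(paste0(yrs, "-09-30")))
  if (!full_season) stop("date range must span at least one full warm season")
  if (abs(ar1_rho) >= 1) stop("ar1_rho must lie in (-1, 1)")
  if (pm_lognoise_sd < 0) stop("pm_lognoise_sd must be >= 0")
  if (heat_noise_sd < 0) stop("heat_noise_sd must be >= 0")
  if (!length(pm_link_coefs) %in% 2:3) stop("pm_link_coefs must have length 2 or 3")
  structure(list(n_zips = as.integer(n_zips), n_enrollees = as.integer(n_enrollees),
                 date_start = date_start, date_end = date_end,
                 seasonal_amplitude = seasonal_amplitude, ar1_rho = ar1_rho,
                 heat_noise_sd = heat_noise_sd, pm_link_coefs = pm_link_coefs,
                 pm_lognoise_sd = pm_lognoise_sd, beta_true = beta_true,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @param file YAML file to write to / read from.
#' @export
sim_config_to_yaml <- function(cfg, file = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  obj <- unclass(cfg)
  obj$date_start <- format(obj$date_start)
  obj$date_end <- format(obj$date_end)
  txt <- yaml::as.yaml(obj, precision = 17L)
  if (is.null(file)) txt else { writeLines(txt, file); invisible(file) }
}

#' @rdname sim_config
#' @export
sim_config_from_yaml <- function(file) {
  obj <- if (file.exists(file[1])) yaml::read_yaml(file)
         else yaml::yaml.load(paste(file, collapse = "\n"))
  obj$beta_true <- as.numeric(obj$beta_true)
  do.call(sim_config, obj)
}

#' @rdname sim_config
#' @param cfg a `sim_config`.
#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d ZIPs, %d enrollees, %s to %s, seed %d\n",
              x$n_zips, x$n_enrollees, format(x$date_start), format(x$date_end),
              x$rng_seed))
  invisible(x)
}

# The 18 Koppen-Geiger subtypes present in the contiguous US; the leading
# letter determines the climate type.
.koppen_subtypes <- c("Af", "Am", "Aw",                         # Tropical
                      "BWh", "BWk", "BSh", "BSk",               # Arid
                      "Csa", "Csb", "Cfa", "Cfb",               # Temperate
                      "Dsa", "Dsb", "Dfa", "Dfb", "Dfc", "Dwa", "Dwb") # Continental

.koppen_type <- function(subtype) {
  c(A = "Tropical", B = "Arid", C = "Temperate", D = "Continental")[
    substr(subtype, 1, 1)]
}

#' Synthetic ZIP to climate-subtype map
#'
#' Assigns each ZIP one of up to 18 Koppen-Geiger subtype codes. When
#' `n_zips >= n_subtypes` every subtype is guaranteed at least one ZIP (the
#' first `n_subtypes` ZIPs get one subtype each, the rest are drawn
#' uniformly); fewer ZIPs than requested subtypes is an error because the
#' per-subtype percentile tables downstream would be undefined.
#'
#' @param n_zips number of ZIPs (>= 1).
#' @param n_subtypes number of distinct subtypes to use, 1..18.
#' @param seed RNG seed.
#' @return data.frame with columns `zip`, `subtype`, `type`.
#' @export
gen_climate_map <- function(n_zips, n_subtypes = 4L, seed = 1L) {
  n_zips <- as.integer(n_zips); n_subtypes <- as.integer(n_subtypes)
  if (n_zips < 1L) stop("n_zips must be >= 1")
  if (n_subtypes < 1L || n_subtypes > 18L)
    stop("n_subtypes must be between 1 and 18")
  if (n_zips < n_subtypes)
    stop("need n_zips >= n_subtypes so every subtype has at least one ZIP")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  subs <- .koppen_subtypes[sample.int(18L, n_subtypes)]
  assigned <- c(subs, sample(subs, n_zips - n_subtypes, replace = TRUE))
  zips <- sprintf("Z%05d", seq_len(n_zips))
  data.frame(zip = zips, subtype = assigned,
             type = unname(.koppen_type(assigned)),
             stringsAsFactors = FALSE)
}

#' Synthetic ZIP-day exposure panel
#'
#' Daily maximum temperature per ZIP is a subtype-specific mean plus a
#' seasonal sinusoid peaking July 26 (day 208) plus AR(1) Gaussian noise of
#' marginal sd `heat_noise_sd`; minimum relative humidity is Gaussian
#' truncated to \[5, 100\]%; PM2.5 is `mu(tmax) * exp(N(0, pm_lognoise_sd))`
#' with `mu` from `pm_link_coefs` (floored at 0.1 ug/m3), so it is strictly
#' positive, right-skewed and positively coupled to heat whenever the link
#' slope is positive. The heat index and, when `percentiles = TRUE`, the
#' subtype heat-index percentile are attached. Child seed:
#' `cfg$rng_seed + 1`.
#'
#' @param climate a [gen_climate_map()] table.
#' @param cfg a [sim_config()].
#' @param percentiles attach `heat_pctl` via [compute_percentiles()]?
#' @return data.frame with one row per ZIP-day: `zip`, `date`, `tmax_c`,
#'   `rhmin_pct`, `pm25_ugm3`, `heat_index_c` and optionally `heat_pctl`.
#' @export
gen_exposure_panel <- function(climate, cfg, percentiles = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(climate) == 0L) stop("empty climate table")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$rng_seed + 1L)
  dates <- seq(cfg$date_start, cfg$date_end, by = "day")
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  season <- cfg$seasonal_amplitude * cos(2 * pi * (doy - 208) / 365.25)
  # subtype mean tmax: Tropical/Arid hot, Continental cool
  base_by_type <- c(Tropical = 27, Arid = 24, Temperate = 20, Continental = 15)
  sub_idx <- match(climate$subtype, .koppen_subtypes)
  base <- base_by_type[climate$type] + (sub_idx %% 3)  # small within-type spread
  innov_sd <- cfg$heat_noise_sd * sqrt(1 - cfg$ar1_rho^2)
  panels <- vector("list", nrow(climate))
  for (z in seq_len(nrow(climate))) {
    eps <- if (cfg$heat_noise_sd == 0) numeric(nd)
           else if (cfg$ar1_rho == 0) stats::rnorm(nd, 0, cfg$heat_noise_sd)
           else as.numeric(stats::arima.sim(list(ar = cfg$ar1_rho), n = nd,
                                            sd = innov_sd))
    tmax <- base[z] + season + eps
    rh <- pmin(pmax(stats::rnorm(nd, mean = 55, sd = 18), 5), 100)
    mu <- cfg$pm_link_coefs[1] + cfg$pm_link_coefs[2] * tmax +
      if (length(cfg$pm_link_coefs) == 3L) cfg$pm_link_coefs[3] * tmax^2 else 0
    mu <- pmax(mu, 0.1)
    pm <- mu * exp(stats::rnorm(nd, 0, cfg$pm_lognoise_sd))
    panels[[z]] <- data.frame(zip = climate$zip[z], date = dates,
                              tmax_c = tmax, rhmin_pct = rh, pm25_ugm3 = pm,
                              stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, panels)
  panel$heat_index_c <- heat_index(panel$tmax_c, panel$rhmin_pct)
  if (percentiles) {
    tabs <- compute_percentiles(
      data.frame(zip = panel$zip, date = panel$date, heat_index = panel$heat_index_c),
      climate)
    sub_of <- climate$subtype[match(panel$zip, climate$zip)]
    panel$heat_pctl <- NA_real_
    for (s in names(tabs)) {
      i <- which(sub_of == s)
      panel$heat_pctl[i] <- to_percentile(panel$heat_index_c[i], s, tabs)
    }
  }
  rownames(panel) <- NULL
  panel
}

#' Synthetic admission histories
#'
#' Per-enrollee hospitalization records engineered to exercise every
#' eligibility filter downstream: a qualifying admission carrying an
#' ADRD-type code within the first ten diagnosis positions for a
#' configurable fraction of enrollees, later admissions spread over the
#' study window (some in and some out of the warm season), skilled-nursing
#' origin flags and non-qualifying admission-source codes injected at
#' configurable rates, and a configurable fraction of enrollees whose ADRD
#' code sits at position 11 (and therefore must not qualify). Child seed:
#' `cfg$rng_seed + 2`.
#'
#' @param cfg a [sim_config()].
#' @param climate a [gen_climate_map()] table (fixed ZIP per enrollee).
#' @param adrd_fraction fraction of enrollees with a qualifying admission.
#' @param snf_fraction fraction of outcome-candidate admissions flagged as
#'   skilled-nursing-facility origin.
#' @param bad_source_fraction fraction of outcome-candidate admissions with
#'   a non-qualifying admission-source code.
#' @param late_code_fraction fraction of would-be qualifying admissions
#'   whose ADRD code is pushed to diagnosis position 11.
#' @param mean_admissions mean number of post-qualifying admissions per
#'   enrollee (Poisson, min 1).
#' @return data.frame with columns `enrollee_id`, `admit_date`,
#'   `discharge_date`, `dx_codes` (semicolon-delimited), `source_code`,
#'   `snf_flag`, `zip`.
#' @export
gen_admissions <- function(cfg, climate, adrd_fraction = 0.9,
                           snf_fraction = 0.1, bad_source_fraction = 0.08,
                           late_code_fraction = 0, mean_admissions = 2) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$rng_seed + 2L)
  n <- cfg$n_enrollees
  ids <- sprintf("E%06d", seq_len(n))
  zips <- sample(climate$zip, n, replace = TRUE)
  days <- as.integer(cfg$date_end - cfg$date_start)
  qualifying_sources <- c("non-healthcare", "clinic", "er")
  other_codes <- sprintf("DX%03d", 1:200)
  recs <- vector("list", n)
  has_adrd <- stats::runif(n) < adrd_fraction
  late_code <- stats::runif(n) < late_code_fraction
  for (i in seq_len(n)) {
    q_date <- cfg$date_start + sample.int(max(1L, days %/% 3L), 1L)
    dx <- sample(other_codes, 12L, replace = FALSE)
    if (has_adrd[i]) {
      pos <- if (late_code[i]) 11L else sample.int(10L, 1L)
      dx[pos] <- "ADRD1"
    }
    q <- data.frame(enrollee_id = ids[i], admit_date = q_date,
                    discharge_date = q_date + sample.int(10L, 1L),
                    dx_codes = paste(dx, collapse = ";"),
                    source_code = "er", snf_flag = FALSE, zip = zips[i],
                    stringsAsFactors = FALSE)
    n_out <- max(1L, stats::rpois(1L, mean_admissions))
    gap <- sample(20:500, n_out, replace = TRUE)
    a_date <- q_date + cumsum(gap)
    a_date <- a_date[a_date <= cfg$date_end]
    if (length(a_date)) {
      outc <- data.frame(
        enrollee_id = ids[i], admit_date = a_date,
        discharge_date = a_date + sample.int(10L, length(a_date), replace = TRUE),
        dx_codes = vapply(seq_along(a_date), function(j)
          paste(sample(other_codes, 10L), collapse = ";"), ""),
        source_code = ifelse(stats::runif(length(a_date)) < bad_source_fraction,
                             "transfer", sample(qualifying_sources,
                                                length(a_date), replace = TRUE)),
        snf_flag = stats::runif(length(a_date)) < snf_fraction,
        zip = zips[i], stringsAsFactors = FALSE)
      recs[[i]] <- rbind(q, outc)
    } else recs[[i]] <- q
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Sample case days inside strata under a known log-odds surface
#'
#' Inverts the conditional logistic model: within each stratum the case day
#' is drawn with probability proportional to `exp(x_d . beta_true)`, where
#' `x_d` is the basis row of day `d`. This makes downstream
#' parameter-recovery exact-model by construction.
#'
#' @param strata_template long data.frame with columns `stratum_id`, `date`
#'   and the exposure columns required by `basis`; any existing `case`
#'   column is ignored. Strata with fewer than 2 complete days are dropped.
#' @param beta_true coefficient vector on the basis scale.
#' @param basis a named list of [basis_spec()]s or a [crossbasis_spec()]
#'   (then supply `cols`), as in [build_design()].
#' @param cols crossbasis exposure column names.
#' @param seed RNG seed.
#' @return `strata_template` with a 0/1 `case` column, one case per stratum.
#' @export
sample_case_days <- function(strata_template, beta_true, basis, cols = NULL,
                             seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  st <- strata_template
  if (inherits(basis, "crossbasis_spec")) {
    stopifnot(length(cols) == 2L)
    need <- cols
  } else need <- names(basis)
  complete <- Reduce(`&`, lapply(need, function(cl) is.finite(st[[cl]])))
  st <- st[complete, , drop = FALSE]
  sizes <- table(st$stratum_id)
  st <- st[st$stratum_id %in% names(sizes)[sizes >= 2], , drop = FALSE]
  if (nrow(st) == 0L) stop("no stratum has >= 2 complete days")
  X <- if (inherits(basis, "crossbasis_spec"))
    crossbasis_matrix(st[[cols[1]]], st[[cols[2]]], basis)
  else do.call(cbind, lapply(names(basis), function(cl)
    basis_matrix(st[[cl]], basis[[cl]])))
  stopifnot(length(beta_true) == ncol(X))
  eta <- drop(X %*% beta_true)
  sid <- as.integer(factor(st$stratum_id))
  mx <- as.numeric(tapply(eta, sid, max))
  w <- as.numeric(exp(eta - mx[sid]))
  cum <- stats::ave(w, sid, FUN = cumsum)
  tot <- drop(rowsum(w, sid))
  u <- stats::runif(length(tot)) * tot          # one draw per stratum
  st$case <- as.integer(cum - w < u[sid] & u[sid] <= cum)
  # guard against ties from floating point: force exactly one case
  ncase <- tapply(st$case, sid, sum)
  if (any(ncase != 1)) {
    for (s in which(ncase != 1)) {
      i <- which(sid == s)
      st$case[i] <- 0L
      st$case[i[which.max(cum[i] >= u[s])]] <- 1L
    }
  }
  rownames(st) <- NULL
  st
}

#' Simulate ready-made case-crossover strata
#'
#' Convenience generator for parameter-recovery studies: draws `n_strata`
#' strata of `days_per_stratum` days with day-level exposures sampled from
#' simple marginals mimicking pooled warm-season data (heat percentile
#' uniform on \[0, 100\]; PM2.5 lognormal around a heat-linked median), then
#' assigns the case day with [sample_case_days()] under `beta_true`.
#'
#' @param n_strata number of strata.
#' @param beta_true coefficients on the basis scale.
#' @param basis named list of [basis_spec()]s or a [crossbasis_spec()].
#' @param cols crossbasis column names, default `c("heat_pctl", "pm25")`.
#' @param days_per_stratum days per stratum (4 = typical referent set).
#' @param seed RNG seed (exposure draw uses `seed`, case draw `seed + 1`).
#' @param pm_coupling slope tying median log-PM2.5 to the heat percentile.
#' @return long stratum table with `stratum_id`, `date`, `case`,
#'   `heat_pctl`, `pm25`.
#' @export
simulate_strata <- function(n_strata, beta_true, basis,
                            cols = c("heat_pctl", "pm25"),
                            days_per_stratum = 4L, seed = 1L,
                            pm_coupling = 0.006) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- n_strata * days_per_stratum
  heat <- stats::runif(n, 0, 100)
  pm <- exp(log(9) + pm_coupling * heat + stats::rnorm(n, 0, 0.45))
  tmpl <- data.frame(stratum_id = rep(seq_len(n_strata), each = days_per_stratum),
                     date = as.Date("2010-07-01") + seq_len(n) %% 28,
                     heat_pctl = heat, pm25 = pm)
  sample_case_days(tmpl, beta_true, basis, cols = cols, seed = seed + 1L)
}

#' CSV writers/readers for the synthetic study inputs
#'
#' Plain-CSV serialization of the three generator outputs with the fixed
#' column layouts used throughout the package.
#'
#' @param x table to write.
#' @param file path.
#' @name synthetic_csv
#' @export
write_panel_csv <- function(x, file) {
  utils::write.csv(x, file, row.names = FALSE)
  invisible(file)
}

#' @rdname synthetic_csv
#' @export
read_panel_csv <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  if ("date" %in% names(x)) x$date <- as.Date(x$date)
  if ("admit_date" %in% names(x)) x$admit_date <- as.Date(x$admit_date)
  if ("discharge_date" %in% names(x)) x$discharge_date <- as.Date(x$discharge_date)
  x
}
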