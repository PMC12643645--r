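#' Run configuration for the full analysis
#'
#' Declarative description of one end-to-end run: which models to fit,
#' reference levels, basis dimensions, sensitivity switches, seeds. Models
#' available: `"single-linear"` and `"single-nonlinear"` (each exposure on
#' its own), `"joint"` (both exposures, no interaction) and
#' `"joint-interaction"` (the 3+3+9 crossbasis).
#'
#' @param models character subset of the model menu.
#' @param nonlinear_df df of the single/joint nonlinear bases (default 4).
#' @param crossbasis_df df of each crossbasis margin (default 3).
#' @param pm_reference reference PM2.5, ug/m3 (default 5).
#' @param heat_reference_pctl reference heat percentile (default 50, the
#'   median).
#' @param heat_target_pctl target heat percentile for the extreme-heat
#'   contrast (default 99).
#' @param pm_target target PM2.5 for the reported PM contrast (default 10).
#' @param season_months warm season (default 5:9).
#' @param moving_average_window if > 1, pre-average exposures over this
#'   trailing window before building strata (sensitivity analysis).
#' @param subcohort_split_year if not `NULL`, additionally refit the linear
#'   interaction model on case-years `< split` and `>= split`.
#' @param reporting_cap_pctl clamp reported exposure axes at this observed
#'   percentile (default 99; inference beyond it is unreliable because the
#'   PM2.5 distribution is heavily right-skewed).
#' @param seed analysis seed (Monte Carlo etc.).
#' @return list of class `run_config`.
#' @export
run_config <- function(models = c("single-linear", "single-nonlinear",
                                  "joint", "joint-interaction"),
                       nonlinear_df = 4L, crossbasis_df = 3L,
                       pm_reference = 5, heat_reference_pctl = 50,
                       heat_target_pctl = 99, pm_target = 10,
                       season_months = 5:9, moving_average_window = 1L,
                       subcohort_split_year = NULL,
                       reporting_cap_pctl = 99, seed = 1L) {
  menu <- c("single-linear", "single-nonlinear", "joint", "joint-interaction")
  stopifnot(all(models %in% menu))
  if (pm_reference <= 0) stop("reference PM2.5 must be positive")
  structure(list(models = models, nonlinear_df = as.integer(nonlinear_df),
                 crossbasis_df = as.integer(crossbasis_df),
                 pm_reference = pm_reference,
                 heat_reference_pctl = heat_reference_pctl,
                 heat_target_pctl = heat_target_pctl, pm_target = pm_target,
                 season_months = as.integer(season_months),
                 moving_average_window = as.integer(moving_average_window),
                 subcohort_split_year = subcohort_split_year,
                 reporting_cap_pctl = reporting_cap_pctl,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full case-crossover analysis
#'
#' Orchestrates exposure preparation, cohort construction, all requested
#' conditional-logit fits, the odds-ratio contrasts/curves/surface, the
#' two-stage PM2.5-heat dependence contrast, and the sensitivity refits.
#' Inputs can come from the synthetic generator ([gen_exposure_panel()],
#' [gen_admissions()]) or from CSVs with the same layouts.
#'
#' @param panel ZIP-day exposure panel (needs `zip`, `date`, `tmax_c`,
#'   `rhmin_pct`, `pm25_ugm3`; `heat_index_c`/`heat_pctl` are computed if
#'   absent, which requires `climate`).
#' @param admissions admission records (see [gen_admissions()]).
#' @param climate ZIP-to-subtype lookup.
#' @param adrd_codes cohort-defining diagnosis codes.
#' @param config a [run_config()].
#' @param rules an [eligibility_rules()].
#' @param out_dir optional directory; when given, all artifacts are written
#'   as CSV/YAML under it.
#' @param verbose log filter counts and stage progress?
#' @return a results bundle (list of class `hpcc_bundle`): `config`,
#'   `counts`, `strata`, `specs`, `fits`, `contrasts`, `curves`, `surface`,
#'   `dependence`, `two_stage`, `sensitivity`.
#' @export
run_pipeline <- function(panel, admissions, climate, adrd_codes = "ADRD1",
                         config = run_config(), rules = eligibility_rules(),
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stopifnot(inherits(config, "run_config"))

  ## ---- exposure preparation ----
  if (!"heat_index_c" %in% names(panel))
    panel$heat_index_c <- heat_index(panel$tmax_c, panel$rhmin_pct)
  if (config$moving_average_window > 1L) {
    say("applying %d-day moving average", config$moving_average_window)
    panel <- moving_average(panel, c("heat_index_c", "pm25_ugm3"),
                            config$moving_average_window)
  }
  pct_tabs <- compute_percentiles(
    data.frame(zip = panel$zip, date = panel$date,
               heat_index = panel$heat_index_c),
    climate, season_months = config$season_months)
  sub_of <- climate$subtype[match(panel$zip, climate$zip)]
  panel$heat_pctl <- NA_real_
  for (s in names(pct_tabs)) {
    i <- which(sub_of == s)
    panel$heat_pctl[i] <- to_percentile(panel$heat_index_c[i], s, pct_tabs)
  }

  ## ---- cohort and strata ----
  events <- build_cohort(admissions, adrd_codes, rules, verbose = verbose)
  say("eligible outcome events: %d", nrow(events))
  strata <- build_strata(events, panel)
  names(strata)[names(strata) == "pm25_ugm3"] <- "pm25"
  n_strata <- length(unique(strata$stratum_id))
  say("strata built: %d (dropped: %s)", n_strata,
      paste(names(attr(strata, "dropped")), attr(strata, "dropped"),
            sep = "=", collapse = ", "))
  counts <- c(attr(events, "filter_counts"), strata = n_strata)

  heat_obs <- strata$heat_pctl[is.finite(strata$heat_pctl)]
  pm_obs <- strata$pm25[is.finite(strata$pm25)]
  pm_cap <- stats::quantile(pm_obs, config$reporting_cap_pctl / 100, names = FALSE)

  ## ---- basis specs ----
  # boundaries extended to cover the configured reference level, which can
  # sit below the observed minimum (e.g. a 5 ug/m3 PM2.5 reference after
  # moving-average smoothing)
  mk <- function(kind, df, x, ref)
    basis_spec(kind, df = df, x = x, boundary = range(c(x, ref)),
               reference = ref)
  specs <- list(
    heat_lin = mk("linear", 1L, heat_obs, config$heat_reference_pctl),
    pm_lin = mk("linear", 1L, pm_obs, config$pm_reference),
    heat_nl = mk("bspline", config$nonlinear_df, heat_obs,
                 config$heat_reference_pctl),
    pm_nl = mk("bspline", config$nonlinear_df, pm_obs, config$pm_reference))
  specs$cb <- crossbasis_spec(
    mk("bspline", config$crossbasis_df, heat_obs, config$heat_reference_pctl),
    mk("bspline", config$crossbasis_df, pm_obs, config$pm_reference))

  ## ---- fits ----
  fits <- list()
  if ("single-linear" %in% config$models) {
    fits$heat_linear <- clogit_fit(build_design(strata, list(heat_pctl = specs$heat_lin)))
    fits$pm_linear <- clogit_fit(build_design(strata, list(pm25 = specs$pm_lin)))
  }
  if ("single-nonlinear" %in% config$models) {
    fits$heat_nonlinear <- clogit_fit(build_design(strata, list(heat_pctl = specs$heat_nl)))
    fits$pm_nonlinear <- clogit_fit(build_design(strata, list(pm25 = specs$pm_nl)))
  }
  if ("joint" %in% config$models) {
    fits$joint_linear <- clogit_fit(build_design(
      strata, list(heat_pctl = specs$heat_lin, pm25 = specs$pm_lin)))
    fits$joint_nonlinear <- clogit_fit(build_design(
      strata, list(heat_pctl = specs$heat_nl, pm25 = specs$pm_nl)))
  }
  if ("joint-interaction" %in% config$models) {
    fits$interaction <- clogit_fit(build_design(strata, specs$cb,
                                                cols = c("heat_pctl", "pm25")))
    # linear-interaction companion for marginal ORs and subcohort refits
    li <- strata
    li$hx <- li$heat_pctl; li$px <- li$pm25; li$hp <- li$heat_pctl * li$pm25
    lin_specs <- list(hx = basis_spec("linear", boundary = range(heat_obs)),
                      px = basis_spec("linear", boundary = range(pm_obs)),
                      hp = basis_spec("linear",
                                      boundary = range(li$hp, na.rm = TRUE)))
    fits$interaction_linear <- clogit_fit(build_design(li, lin_specs))
  }
  say("fitted %d model(s)", length(fits))

  ## ---- contrasts, curves, surface ----
  h_ref <- config$heat_reference_pctl; h_tgt <- config$heat_target_pctl
  p_ref <- config$pm_reference; p_tgt <- config$pm_target
  contrasts <- list()
  add_con <- function(name, fit, cvec)
    contrasts[[name]] <<- or_contrast(fit, cvec)
  if (!is.null(fits$heat_linear)) {
    add_con("heat_linear_99v50", fits$heat_linear,
            contrast_vector(h_tgt, h_ref, specs$heat_lin))
    add_con("pm_linear_10v5", fits$pm_linear,
            contrast_vector(p_tgt, p_ref, specs$pm_lin))
  }
  if (!is.null(fits$heat_nonlinear)) {
    add_con("heat_nonlinear_99v50", fits$heat_nonlinear,
            contrast_vector(h_tgt, h_ref, specs$heat_nl))
    add_con("pm_nonlinear_10v5", fits$pm_nonlinear,
            contrast_vector(p_tgt, p_ref, specs$pm_nl))
  }
  if (!is.null(fits$joint_linear)) {
    add_con("joint_heat_99v50", fits$joint_linear,
            c(contrast_vector(h_tgt, h_ref, specs$heat_lin), 0))
    add_con("joint_pm_10v5", fits$joint_linear,
            c(0, contrast_vector(p_tgt, p_ref, specs$pm_lin)))
    dfnl <- specs$heat_nl$df
    add_con("joint_nl_heat_99v50", fits$joint_nonlinear,
            c(contrast_vector(h_tgt, h_ref, specs$heat_nl), numeric(dfnl)))
    add_con("joint_nl_pm_10v5", fits$joint_nonlinear,
            c(numeric(dfnl), contrast_vector(p_tgt, p_ref, specs$pm_nl)))
  }
  curves <- list()
  surface <- NULL
  if (!is.null(fits$interaction)) {
    add_con("interaction_heat_99v50_at_pmref", fits$interaction,
            contrast_vector(c(h_tgt, p_ref), c(h_ref, p_ref), specs$cb))
    add_con("interaction_pm_10v5_at_heatref", fits$interaction,
            contrast_vector(c(h_ref, p_tgt), c(h_ref, p_ref), specs$cb))
    add_con("interaction_joint_both_high", fits$interaction,
            contrast_vector(c(h_tgt, p_tgt), c(h_ref, p_ref), specs$cb))
    hg <- seq(specs$cb$spec1$boundary[1],
              min(specs$cb$spec1$boundary[2],
                  stats::quantile(heat_obs, config$reporting_cap_pctl / 100,
                                  names = FALSE)), length.out = 40)
    pg <- seq(specs$cb$spec2$boundary[1], pm_cap, length.out = 25)
    surface <- or_surface(fits$interaction, specs$cb, hg, pg,
                          observed = data.frame(strata$heat_pctl, strata$pm25))
    # marginal ORs at the co-exposure median
    contrasts$marginal_heat <- marginal_linear_or(
      fits$interaction_linear, delta = h_tgt - h_ref,
      at = stats::median(pm_obs), which = 1L)
    contrasts$marginal_pm <- marginal_linear_or(
      fits$interaction_linear, delta = 5, at = stats::median(heat_obs),
      which = 2L)
  }
  if (!is.null(fits$heat_nonlinear)) {
    curves$heat <- or_curve(fits$heat_nonlinear, specs$heat_nl,
                            seq(specs$heat_nl$boundary[1],
                                specs$heat_nl$boundary[2], length.out = 80))
    curves$pm <- or_curve(fits$pm_nonlinear, specs$pm_nl,
                          seq(specs$pm_nl$boundary[1], pm_cap,
                              length.out = 50))
  }

  ## ---- two-stage dependence analysis ----
  dependence <- NULL; two_stage <- NULL
  if (!is.null(fits$interaction)) {
    dep_rec <- data.frame(heat_pctl = strata$heat_pctl, pm25_ugm3 = strata$pm25)
    dependence <- fit_dependence(dep_rec, df = 4L)
    two_stage <- combined_contrast_mc(dependence, fits$interaction, specs$cb,
                                      h_target = h_tgt, h_ref = h_ref,
                                      n_iter = 5000L, seed = config$seed)
  }

  ## ---- sensitivity: temporal subcohorts ----
  sensitivity <- list()
  if (!is.null(config$subcohort_split_year) && !is.null(fits$interaction_linear)) {
    yr <- as.integer(format(strata$date, "%Y"))
    case_yr <- stats::ave(yr * strata$case, strata$stratum_id, FUN = max)
    for (half in c("early", "late")) {
      keep <- if (half == "early") case_yr < config$subcohort_split_year
              else case_yr >= config$subcohort_split_year
      sub <- strata[keep, , drop = FALSE]
      if (length(unique(sub$stratum_id)) < 50L) next
      sub$hx <- sub$heat_pctl; sub$px <- sub$pm25; sub$hp <- sub$heat_pctl * sub$pm25
      lin_specs <- list(hx = basis_spec("linear", boundary = range(heat_obs)),
                        px = basis_spec("linear", boundary = range(pm_obs)),
                        hp = basis_spec("linear",
                                        boundary = range(sub$hp, na.rm = TRUE)))
      sensitivity[[paste0("subcohort_", half)]] <-
        clogit_fit(build_design(sub, lin_specs))
    }
  }

  bundle <- structure(list(config = config, counts = counts, strata = strata,
                           pct_tables = pct_tabs, specs = specs, fits = fits,
                           contrasts = contrasts, curves = curves,
                           surface = surface, dependence = dependence,
                           two_stage = two_stage, sensitivity = sensitivity),
                      class = "hpcc_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Summary table of a results bundle
#'
#' The reporting grid of the analysis: one row per model and exposure
#' contrast (extreme heat vs median; 10 vs 5 ug/m3 PM2.5; the joint and
#' marginal contrasts where the interaction model was fitted), with OR and
#' 95% CI. Regenerating the report from the same bundle is exact.
#'
#' @param bundle a [run_pipeline()] result.
#' @return data.frame: `model`, `contrast`, `or`, `lo`, `hi`, `method`.
#' @export
report_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "hpcc_bundle"))
  rows <- lapply(names(bundle$contrasts), function(nm) {
    cc <- bundle$contrasts[[nm]]
    data.frame(model = sub("_[^_]*$", "", nm), contrast = nm, or = cc$or,
               lo = cc$lo, hi = cc$hi, method = cc$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(bundle$two_stage)) {
    ts <- bundle$two_stage
    out <- rbind(out, data.frame(model = "two-stage", contrast = "heat_99v50_with_pm_shift",
                                 or = ts$or, lo = ts$lo, hi = ts$hi,
                                 method = ts$method, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' @rdname report_bundle
#' @param out_dir directory for the CSV/YAML artifacts.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report_bundle(bundle),
                   file.path(out_dir, "report.csv"), row.names = FALSE)
  if (!is.null(bundle$surface))
    utils::write.csv(bundle$surface, file.path(out_dir, "surface.csv"),
                     row.names = FALSE)
  for (nm in names(bundle$curves))
    utils::write.csv(bundle$curves[[nm]],
                     file.path(out_dir, paste0("curve_", nm, ".csv")),
                     row.names = FALSE)
  for (nm in names(bundle$fits)) {
    f <- bundle$fits[[nm]]
    utils::write.csv(data.frame(beta = f$beta, se = sqrt(diag(f$vcov))),
                     file.path(out_dir, paste0("fit_", nm, ".csv")),
                     row.names = FALSE)
  }
  basis_to_yaml(bundle$specs$cb, file.path(out_dir, "crossbasis.yaml"))
  writeLines(yaml::as.yaml(list(counts = as.list(bundle$counts),
                                seed = bundle$config$seed,
                                models = bundle$config$models)),
             file.path(out_dir, "run_meta.yaml"))
  invisible(out_dir)
}

#' @export
print.hpcc_bundle <- function(x, ...) {
  cat("Case-crossover results bundle\n")
  cat("  strata:", x$counts[["strata"]], " models:",
      paste(names(x$fits), collapse = ", "), "\n")
  print(report_bundle(x))
  invisible(x)
}
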