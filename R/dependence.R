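#' Stage-1 model: PM2.5 as a spline function of heat index
#'
#' Ordinary least squares of PM2.5 on a B-spline of the heat exposure
#' (df = 4 by default) plus intercept, fitted on the pooled ZIP-day records
#' independently of the hospitalization outcomes. The coefficient
#' covariance comes from standard linear-model theory and feeds the Monte
#' Carlo propagation in [combined_contrast_mc()].
#'
#' @param records data.frame of stratum-day or panel records.
#' @param heat_col,pm_col column names of the heat exposure and PM2.5.
#' @param df spline degrees of freedom (default 4).
#' @return object of class `dependence_model`: `gamma` (intercept first),
#'   `vcov_gamma`, `basis` (a [basis_spec()]), `sigma2`, `n`.
#' @export
fit_dependence <- function(records, heat_col = "heat_pctl",
                           pm_col = "pm25_ugm3", df = 4L) {
  h <- records[[heat_col]]; p <- records[[pm_col]]
  ok <- is.finite(h) & is.finite(p)
  h <- h[ok]; p <- p[ok]
  if (length(h) < df + 2L) stop("need at least df + 2 records")
  spec <- basis_spec("bspline", df = df, x = h)
  X <- cbind(1, basis_matrix(h, spec))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("rank-deficient stage-1 design (rank ", qr_x$rank, " < ", ncol(X), ")")
  gamma <- qr.coef(qr_x, p)
  res <- p - drop(X %*% gamma)
  sigma2 <- sum(res^2) / (length(p) - ncol(X))
  XtXinv <- chol2inv(qr.R(qr_x))
  structure(list(gamma = gamma, vcov_gamma = sigma2 * XtXinv, basis = spec,
                 sigma2 = sigma2, n = length(p)),
            class = "dependence_model")
}

#' @export
print.dependence_model <- function(x, ...) {
  cat(sprintf("PM2.5 ~ bs(heat, df=%d) on %d records; residual sd %.3f\n",
              x$basis$df, x$n, sqrt(x$sigma2)))
  invisible(x)
}

#' Predicted PM2.5 at given heat levels
#'
#' Mean prediction `c(1, b(h)) . gamma` with a delta-method 95% interval
#' for the conditional mean (not a prediction interval for a new day).
#' Heat values outside the stage-1 boundary are clamped and flagged.
#'
#' @param model a [fit_dependence()] result.
#' @param heat_values numeric heat exposures.
#' @param conf_mult normal quantile, default 1.96.
#' @return data.frame: `heat`, `pm25_hat`, `lo`, `hi`, `se`, `clamped`.
#' @export
predict_pm25 <- function(model, heat_values, conf_mult = 1.96) {
  stopifnot(inherits(model, "dependence_model"))
  clamped <- heat_values < model$basis$boundary[1] |
             heat_values > model$basis$boundary[2]
  if (any(clamped))
    warning(sum(clamped), " heat value(s) outside the fitted range; clamped")
  B <- cbind(1, basis_matrix(heat_values, model$basis))
  mu <- drop(B %*% model$gamma)
  se <- sqrt(pmax(0, rowSums((B %*% model$vcov_gamma) * B)))
  data.frame(heat = heat_values, pm25_hat = mu,
             lo = mu - conf_mult * se, hi = mu + conf_mult * se,
             se = se, clamped = clamped)
}

#' Two-stage heat contrast with Monte Carlo uncertainty
#'
#' The combined contrast asks: what is the odds ratio of moving the heat
#' exposure from `h_ref` to `h_target` when PM2.5 moves along with it
#' according to the stage-1 dependence model? The point estimate is the
#' plug-in contrast
#' `[cb(h_t, p(h_t)) - cb(h_r, p(h_r))] . beta` with `p(h) = c(1, b(h)) . gamma`.
#' Uncertainty from both fitted models is propagated by Monte Carlo: each
#' iteration draws `gamma* ~ N(gamma, V_gamma)` and `beta* ~ N(beta, V_beta)`
#' independently, recomputes the predicted PM2.5 pair and the contrast, and
#' the 2.5/97.5 empirical percentiles of the simulated log odds ratios form
#' the interval. Independence of the two draws is an approximation (the
#' models share exposure data but the outcome model conditions on
#' exposure).
#'
#' @param dep a [fit_dependence()] model.
#' @param fit the crossbasis [clogit_fit()] (design = `cb_spec` columns).
#' @param cb_spec the [crossbasis_spec()] (exposure 1 = heat, 2 = PM2.5).
#' @param h_target,h_ref heat levels contrasted (e.g. 99th vs median
#'   percentile).
#' @param n_iter Monte Carlo iterations, default 5000.
#' @param seed RNG seed.
#' @param center `"plugin"` (default) reports the deterministic plug-in
#'   contrast; `"mean"`/`"median"` report the MC mean/median.
#' @return one-row data.frame of class `or_contrast` with `method = "mc"`
#'   and attributes `pm25_target`, `pm25_ref`, `draws_summary`.
#' @export
combined_contrast_mc <- function(dep, fit, cb_spec, h_target, h_ref,
                                 n_iter = 5000L, seed = 1L,
                                 center = c("plugin", "mean", "median")) {
  stopifnot(inherits(dep, "dependence_model"),
            inherits(cb_spec, "crossbasis_spec"))
  center <- match.arg(center)
  if (any(!is.finite(dep$vcov_gamma)) || any(!is.finite(fit$vcov)))
    stop("non-finite covariance")
  ev1 <- eigen(dep$vcov_gamma, symmetric = TRUE, only.values = TRUE)$values
  ev2 <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev1) < -1e-8 * max(abs(ev1), 1) || min(ev2) < -1e-8 * max(abs(ev2), 1))
    stop("covariance matrix is not positive semidefinite")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  b_t <- c(1, basis_row(h_target, dep$basis))
  b_r <- c(1, basis_row(h_ref, dep$basis))
  p_t <- sum(b_t * dep$gamma); p_r <- sum(b_r * dep$gamma)
  plug <- sum((crossbasis_row(h_target, p_t, cb_spec) -
               crossbasis_row(h_ref, p_r, cb_spec)) * fit$beta)
  g_draw <- MASS::mvrnorm(n_iter, dep$gamma, dep$vcov_gamma)
  b_draw <- MASS::mvrnorm(n_iter, fit$beta, fit$vcov)
  pt_star <- drop(g_draw %*% b_t)
  pr_star <- drop(g_draw %*% b_r)
  cb_t <- crossbasis_matrix(rep(h_target, n_iter), pt_star, cb_spec)
  cb_r <- crossbasis_matrix(rep(h_ref, n_iter), pr_star, cb_spec)
  draws <- rowSums((cb_t - cb_r) * b_draw)
  qs <- unname(stats::quantile(draws, c(0.025, 0.975), type = 7))
  log_or <- switch(center, plugin = plug, mean = mean(draws),
                   median = stats::median(draws))
  out <- data.frame(log_or = log_or, se = stats::sd(draws), or = exp(log_or),
                    lo = exp(qs[1]), hi = exp(qs[2]), method = "mc",
                    stringsAsFactors = FALSE)
  attr(out, "pm25_target") <- p_t
  attr(out, "pm25_ref") <- p_r
  attr(out, "n_iter") <- n_iter
  class(out) <- c("or_contrast", "data.frame")
  out
}
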