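#' Odds-ratio contrast from a fitted model
#'
#' Log odds ratio `c . beta` for a contrast vector `c` with delta-method
#' standard error `sqrt(c' V c)` and normal 95% interval
#' `exp(logOR +/- 1.96 se)`.
#'
#' @param fit a [clogit_fit()] result (or any list with `beta`, `vcov`).
#' @param cvec contrast vector, same length as `fit$beta` (see
#'   [contrast_vector()]).
#' @param conf_mult normal quantile for the interval, default 1.96 (95%).
#' @return one-row data.frame of class `or_contrast`: `log_or`, `se`, `or`,
#'   `lo`, `hi`, `method`.
#' @export
or_contrast <- function(fit, cvec, conf_mult = 1.96) {
  if (length(cvec) != length(fit$beta))
    stop("contrast length ", length(cvec), " does not match ",
         length(fit$beta), " coefficients")
  log_or <- sum(cvec * fit$beta)
  se <- sqrt(max(0, drop(t(cvec) %*% fit$vcov %*% cvec)))
  structure(data.frame(log_or = log_or, se = se, or = exp(log_or),
                       lo = exp(log_or - conf_mult * se),
                       hi = exp(log_or + conf_mult * se),
                       method = "delta", stringsAsFactors = FALSE),
            class = c("or_contrast", "data.frame"))
}

#' Exposure-response curve of odds ratios
#'
#' One [or_contrast()] per grid point against a common reference level, the
#' standard way a spline exposure term is displayed. Grid values outside
#' the basis boundary are clamped and flagged.
#'
#' @param fit a [clogit_fit()] on a design whose columns are exactly
#'   `basis_matrix(., spec)`.
#' @param spec the [basis_spec()] that built the design.
#' @param grid exposure values to evaluate.
#' @param reference reference exposure (default `spec$reference`).
#' @inheritParams or_contrast
#' @return data.frame: `exposure`, `or`, `lo`, `hi`, `log_or`, `se`,
#'   `clamped`.
#' @export
or_curve <- function(fit, spec, grid, reference = NULL, conf_mult = 1.96) {
  if (length(grid) == 0L) stop("empty exposure grid")
  if (is.null(reference)) reference <- spec$reference
  clamped <- grid < spec$boundary[1] | grid > spec$boundary[2]
  if (any(clamped))
    warning(sum(clamped), " grid value(s) outside the basis boundary; clamped")
  rows <- lapply(grid, function(g)
    or_contrast(fit, contrast_vector(g, reference, spec), conf_mult))
  out <- do.call(rbind, rows)
  data.frame(exposure = grid, or = out$or, lo = out$lo, hi = out$hi,
             log_or = out$log_or, se = out$se, clamped = clamped)
}

#' Joint odds-ratio surface for two interacting exposures
#'
#' Evaluates the crossbasis fit on the grid `grid1 x grid2`, every cell
#' contrasted against the fixed reference pair, so the surface equals 1 at
#' the reference. Cells supported by fewer than `min_support` observed
#' exposure pairs (within the cell's grid rectangle) can be flagged as
#' data-sparse, mirroring the artifact corners a real exposure surface
#' shows where hot days with extreme PM2.5 never occur.
#'
#' @param fit [clogit_fit()] on a design built from `cb_spec` alone.
#' @param cb_spec the [crossbasis_spec()].
#' @param grid1,grid2 grids for the first (heat) and second (PM2.5)
#'   exposure.
#' @param reference length-2 reference pair (default: spec references).
#' @param observed optional two-column matrix/data.frame of observed
#'   exposure pairs used for sparsity flagging.
#' @param min_support minimum observed pairs per cell (only used with
#'   `observed`).
#' @inheritParams or_contrast
#' @return data.frame in long form: `x1`, `x2`, `or`, `lo`, `hi`, `log_or`,
#'   `se`, `sparse`.
#' @export
or_surface <- function(fit, cb_spec, grid1, grid2, reference = NULL,
                       observed = NULL, min_support = 5L, conf_mult = 1.96) {
  if (length(grid1) == 0L || length(grid2) == 0L) stop("empty exposure grid")
  if (is.null(reference))
    reference <- c(cb_spec$spec1$reference, cb_spec$spec2$reference)
  g <- expand.grid(x1 = grid1, x2 = grid2, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(g)), function(i)
    or_contrast(fit, contrast_vector(c(g$x1[i], g$x2[i]), reference, cb_spec),
                conf_mult))
  out <- do.call(rbind, rows)
  sparse <- rep(NA, nrow(g))
  if (!is.null(observed)) {
    b1 <- sort(unique(c(-Inf, filled_midpoints(grid1), Inf)))
    b2 <- sort(unique(c(-Inf, filled_midpoints(grid2), Inf)))
    c1 <- cut(observed[[1]], b1); c2 <- cut(observed[[2]], b2)
    tab <- table(c1, c2)
    i1 <- cut(g$x1, b1); i2 <- cut(g$x2, b2)
    sparse <- tab[cbind(as.integer(i1), as.integer(i2))] < min_support
  }
  data.frame(x1 = g$x1, x2 = g$x2, or = out$or, lo = out$lo, hi = out$hi,
             log_or = out$log_or, se = out$se, sparse = sparse)
}

filled_midpoints <- function(grid) {
  grid <- sort(grid)
  if (length(grid) < 2L) return(grid)
  (grid[-1] + grid[-length(grid)]) / 2
}

#' Marginal odds ratio from the linear interaction model
#'
#' For the three-coefficient model `b1*H + b2*P + b3*H*P`, the log odds
#' ratio of a change `delta` in one exposure depends on where the other is
#' held: holding PM2.5 at `at`, a heat change `delta` has contrast
#' `(delta, 0, delta * at)`; symmetrically for PM2.5. The co-exposure
#' evaluation level is an explicit argument because a "marginal" effect in
#' an interaction model is undefined without it; the observed median is a
#' natural default.
#'
#' @param fit a [clogit_fit()] with exactly 3 coefficients ordered
#'   (exposure 1, exposure 2, interaction).
#' @param delta change in the exposure of interest.
#' @param at level the co-exposure is held at.
#' @param which which exposure changes: 1 (heat) or 2 (PM2.5).
#' @inheritParams or_contrast
#' @return an [or_contrast()] row.
#' @export
marginal_linear_or <- function(fit, delta, at, which = 1L, conf_mult = 1.96) {
  if (length(fit$beta) != 3L)
    stop("marginal_linear_or needs the 3-coefficient linear interaction model")
  cvec <- if (which == 1L) c(delta, 0, delta * at) else c(0, delta, delta * at)
  or_contrast(fit, cvec, conf_mult)
}
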