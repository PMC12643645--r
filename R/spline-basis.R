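#' Exposure basis specification
#'
#' Declarative description of a one-dimensional exposure transform: either
#' the identity (`kind = "linear"`, one column) or a degree-3 B-spline
#' without intercept (`kind = "bspline"`, `df` columns). For B-splines the
#' internal knots default to equally spaced quantiles of `x` (so `df - degree`
#' of them) and the boundary knots to the observed range; both can be given
#' explicitly, which together with [basis_to_yaml()] makes fits exactly
#' reproducible. Evaluation outside the boundary is clamped to the nearest
#' boundary value, and `reference` records the exposure level contrasts are
#' taken against.
#'
#' @param kind `"linear"` or `"bspline"`.
#' @param df number of basis columns (for `"linear"` forced to 1).
#' @param x optional data used to place knots and boundary.
#' @param degree spline degree, default 3 (cubic).
#' @param internal_knots,boundary explicit knot placement, overriding `x`.
#' @param reference reference exposure level; defaults to the median of `x`
#'   or the boundary midpoint.
#' @return an object of class `basis_spec`.
#' @examples
#' sp <- basis_spec("bspline", df = 4, x = runif(500, 0, 100))
#' basis_row(50, sp)
#' @export
basis_spec <- function(kind = c("bspline", "linear"), df = 3L, x = NULL,
                       degree = 3L, internal_knots = NULL, boundary = NULL,
                       reference = NULL) {
  kind <- match.arg(kind)
  if (kind == "linear") {
    df <- 1L
    if (is.null(boundary)) boundary <- if (!is.null(x)) range(x) else c(-Inf, Inf)
    internal_knots <- numeric(0)
  } else {
    df <- as.integer(df)
    degree <- as.integer(degree)
    if (df < degree) stop("bspline df must be >= degree")
    n_int <- df - degree
    if (is.null(boundary)) {
      if (is.null(x)) stop("supply `x` or an explicit `boundary`")
      boundary <- range(x, na.rm = TRUE)
    }
    if (is.null(internal_knots)) {
      internal_knots <- if (n_int > 0) {
        if (is.null(x)) stop("supply `x` or explicit `internal_knots`")
        unname(stats::quantile(x, probs = seq_len(n_int) / (n_int + 1),
                               na.rm = TRUE))
      } else numeric(0)
    }
    if (length(internal_knots) != n_int)
      stop("need exactly df - degree internal knots")
    if (length(internal_knots) && (any(internal_knots <= boundary[1]) ||
                                   any(internal_knots >= boundary[2])))
      stop("internal knots must lie strictly inside the boundary")
  }
  if (is.null(reference))
    reference <- if (!is.null(x)) stats::median(x, na.rm = TRUE) else mean(boundary)
  if (all(is.finite(boundary)) &&
      (reference < boundary[1] || reference > boundary[2]))
    stop("reference must lie within the boundary")
  structure(list(kind = kind, df = df, degree = if (kind == "bspline") degree else NA_integer_,
                 internal_knots = as.numeric(internal_knots),
                 boundary = as.numeric(boundary),
                 reference = as.numeric(reference)),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("basis_spec: %s, df=%d, boundary [%g, %g], reference %g\n",
              x$kind, x$df, x$boundary[1], x$boundary[2], x$reference))
  if (length(x$internal_knots))
    cat("  internal knots:", paste(signif(x$internal_knots, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a basis specification
#'
#' `basis_matrix()` returns one row per value of `x`; `basis_row()` is the
#' single-value convenience. Values outside the boundary are clamped to the
#' boundary before evaluation.
#'
#' @param x numeric exposure values.
#' @param spec a [basis_spec()].
#' @return numeric matrix, `length(x)` rows by `spec$df` columns.
#' @export
basis_matrix <- function(x, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  if (any(!is.finite(x))) stop("non-finite exposure value")
  if (spec$kind == "linear") return(matrix(x, ncol = 1L))
  xc <- pmin(pmax(x, spec$boundary[1]), spec$boundary[2])
  m <- splines::bs(xc, knots = spec$internal_knots,
                   Boundary.knots = spec$boundary,
                   degree = spec$degree, intercept = FALSE)
  matrix(as.numeric(m), nrow = length(x), ncol = spec$df)
}

#' @rdname basis_matrix
#' @export
basis_row <- function(x, spec) {
  stopifnot(length(x) == 1L)
  drop(basis_matrix(x, spec))
}

#' Crossbasis specification for two interacting exposures
#'
#' Tensor-product design for a pair of exposures (heat-index percentile and
#' PM2.5 in the motivating analysis): the two marginal bases followed by
#' their tensor interaction, giving `df1 + df2 + df1*df2` columns. The
#' interaction block is the flattened outer product in row-major order:
#' column `(i-1)*df2 + j` of the block is `b1_i(x1) * b2_j(x2)`. The
#' reference pair (median heat percentile and 5 ug/m3 PM2.5 in the
#' motivating analysis) anchors all odds-ratio contrasts.
#'
#' @param spec1,spec2 [basis_spec()] objects for the two exposures.
#' @return an object of class `crossbasis_spec`.
#' @export
crossbasis_spec <- function(spec1, spec2) {
  stopifnot(inherits(spec1, "basis_spec"), inherits(spec2, "basis_spec"))
  structure(list(spec1 = spec1, spec2 = spec2,
                 df = spec1$df + spec2$df + spec1$df * spec2$df),
            class = "crossbasis_spec")
}

#' @export
print.crossbasis_spec <- function(x, ...) {
  cat(sprintf("crossbasis_spec: %d + %d + %d columns, reference (%g, %g)\n",
              x$spec1$df, x$spec2$df, x$spec1$df * x$spec2$df,
              x$spec1$reference, x$spec2$reference))
  invisible(x)
}

#' Evaluate a crossbasis
#'
#' @param x1,x2 numeric exposure vectors of equal length.
#' @param spec a [crossbasis_spec()].
#' @return matrix with `spec$df` columns: `b1`, then `b2`, then the tensor
#'   interaction flattened as documented in [crossbasis_spec()].
#' @export
crossbasis_matrix <- function(x1, x2, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"), length(x1) == length(x2))
  b1 <- basis_matrix(x1, spec$spec1)
  b2 <- basis_matrix(x2, spec$spec2)
  d1 <- ncol(b1); d2 <- ncol(b2)
  inter <- matrix(0, nrow = length(x1), ncol = d1 * d2)
  for (i in seq_len(d1))
    inter[, (i - 1L) * d2 + seq_len(d2)] <- b1[, i] * b2
  cbind(b1, b2, inter, deparse.level = 0)
}

#' @rdname crossbasis_matrix
#' @export
crossbasis_row <- function(x1, x2, spec) {
  stopifnot(length(x1) == 1L, length(x2) == 1L)
  drop(crossbasis_matrix(x1, x2, spec))
}

#' Contrast vector between two exposure configurations
#'
#' Difference of design rows, so that `sum(contrast * beta)` is the log odds
#' ratio of `target` versus `reference`. Works for both one-dimensional
#' [basis_spec()] (scalar `target`/`reference`) and [crossbasis_spec()]
#' (length-2 `target`/`reference`, ordered as (x1, x2)).
#'
#' @param target,reference exposure value(s); default reference is the
#'   spec's stored reference point.
#' @param spec a `basis_spec` or `crossbasis_spec`.
#' @return numeric contrast vector of length `spec$df`.
#' @examples
#' sp <- basis_spec("linear", x = c(0, 100))
#' contrast_vector(99, 50, sp)   # 49, the extreme-heat-vs-median contrast
#' @export
contrast_vector <- function(target, reference = NULL, spec) {
  if (inherits(spec, "crossbasis_spec")) {
    if (is.null(reference))
      reference <- c(spec$spec1$reference, spec$spec2$reference)
    stopifnot(length(target) == 2L, length(reference) == 2L)
    crossbasis_row(target[1], target[2], spec) -
      crossbasis_row(reference[1], reference[2], spec)
  } else {
    stopifnot(inherits(spec, "basis_spec"))
    if (is.null(reference)) reference <- spec$reference
    basis_row(target, spec) - basis_row(reference, spec)
  }
}

#' Serialize basis specifications to YAML
#'
#' Round-trips knots, boundary and reference so a fitted model's design can
#' be reconstructed bit-exactly in a later session.
#'
#' @param spec a `basis_spec` or `crossbasis_spec`.
#' @param file optional path; if `NULL` the YAML string is returned.
#' @export
basis_to_yaml <- function(spec, file = NULL) {
  to_list <- function(s) list(kind = s$kind, df = s$df, degree = s$degree,
                              internal_knots = s$internal_knots,
                              boundary = s$boundary, reference = s$reference)
  obj <- if (inherits(spec, "crossbasis_spec"))
    list(crossbasis = list(spec1 = to_list(spec$spec1),
                           spec2 = to_list(spec$spec2)))
  else list(basis = to_list(spec))
  txt <- yaml::as.yaml(obj, precision = 17L)
  if (is.null(file)) txt else { writeLines(txt, file); invisible(file) }
}

#' @rdname basis_to_yaml
#' @param yaml_txt YAML string or path produced by [basis_to_yaml()].
#' @export
basis_from_yaml <- function(yaml_txt) {
  obj <- if (file.exists(yaml_txt[1])) yaml::read_yaml(yaml_txt)
         else yaml::yaml.load(paste(yaml_txt, collapse = "\n"))
  from_list <- function(l)
    basis_spec(kind = l$kind, df = l$df,
               degree = if (is.null(l$degree) || is.na(l$degree)) 3L else l$degree,
               internal_knots = as.numeric(l$internal_knots),
               boundary = as.numeric(l$boundary), reference = l$reference)
  if (!is.null(obj$crossbasis))
    crossbasis_spec(from_list(obj$crossbasis$spec1), from_list(obj$crossbasis$spec2))
  else from_list(obj$basis)
}
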