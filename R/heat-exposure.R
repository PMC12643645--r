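#' NWS heat index
#'
#' Computes the US National Weather Service heat index from air temperature
#' and relative humidity, following the source of the NWS online heat index
#' calculator: below an apparent temperature of about 80 F the simple
#' Steadman average is used; above it, the Rothfusz nine-coefficient
#' regression with the low-humidity (RH <= 13%, 80-112 F) and high-humidity
#' (RH > 85%, 80-87 F) adjustments. Temperatures at or below 40 F are
#' returned unchanged. All arithmetic is done in Fahrenheit (the scale the
#' regression is defined on); conversion is exact, not rounded.
#'
#' The hand-off between the Steadman average and the Rothfusz regression is
#' discontinuous by construction; the jump is below 1.5 F at moderate
#' humidities, which is well under the regression's own error of +/- 1.3 F.
#'
#' @param temp numeric vector of daily maximum temperature.
#' @param rh numeric vector of relative humidity in percent, in \[0, 100\].
#' @param unit unit of `temp` and of the returned heat index: `"celsius"`
#'   (default) or `"fahrenheit"`.
#' @return numeric vector of heat index values in `unit`.
#' @examples
#' heat_index(35, 60)                       # hot humid day, Celsius
#' heat_index(96, 65, unit = "fahrenheit")  # Rothfusz branch
#' @export
heat_index <- function(temp, rh, unit = c("celsius", "fahrenheit")) {
  unit <- match.arg(unit)
  if (length(rh) == 1L && length(temp) > 1L) rh <- rep(rh, length(temp))
  if (length(temp) == 1L && length(rh) > 1L) temp <- rep(temp, length(rh))
  if (length(temp) != length(rh))
    stop("`temp` and `rh` must have the same length")
  if (any(!is.finite(temp)) || any(!is.finite(rh)))
    stop("non-finite temperature or humidity")
  if (any(rh < 0 | rh > 100))
    stop("`rh` must lie in [0, 100]")
  t_f <- if (unit == "celsius") celsius_to_fahrenheit(temp) else temp
  hi_f <- heat_index_f(t_f, rh)
  if (unit == "celsius") fahrenheit_to_celsius(hi_f) else hi_f
}

# Rothfusz regression core on the Fahrenheit scale, vectorized.
heat_index_f <- function(t, rh) {
  alpha <- 61 + (t - 68) * 1.2 + rh * 0.094
  hi <- 0.5 * (alpha + t)
  full <- hi > 79
  if (any(full)) {
    tf <- t[full]; rf <- rh[full]
    h <- -42.379 + 2.04901523 * tf + 10.14333127 * rf -
      0.22475541 * tf * rf - 6.83783e-3 * tf^2 - 5.481717e-2 * rf^2 +
      1.22874e-3 * tf^2 * rf + 8.5282e-4 * tf * rf^2 - 1.99e-6 * tf^2 * rf^2
    lo <- rf <= 13 & tf >= 80 & tf <= 112
    h[lo] <- h[lo] - (13 - rf[lo]) / 4 * sqrt((17 - abs(tf[lo] - 95)) / 17)
    hh <- rf > 85 & tf >= 80 & tf <= 87
    h[hh] <- h[hh] + (rf[hh] - 85) / 10 * (87 - tf[hh]) / 5
    hi[full] <- h
  }
  hi[t <= 40] <- t[t <= 40]
  hi
}

#' @rdname heat_index
#' @export
celsius_to_fahrenheit <- function(temp) temp * 9 / 5 + 32

#' @rdname heat_index
#' @export
fahrenheit_to_celsius <- function(temp) (temp - 32) * 5 / 9

#' Aggregate grid-cell values to ZIP codes
#'
#' Unweighted mean of all grid-cell values mapped to each ZIP, the standard
#' way gridded exposure surfaces (PM2.5 predictions, gridMET temperature) are
#' attached to ZIP-level health records. ZIPs with no mapped cell are absent
#' from the output.
#'
#' @param grid_values data.frame with columns `cell_id`, `value`.
#' @param mapping data.frame with columns `cell_id`, `zip`.
#' @return data.frame with columns `zip`, `value` (per-ZIP mean), sorted by
#'   `zip`.
#' @export
aggregate_grid_to_zip <- function(grid_values, mapping) {
  stopifnot(all(c("cell_id", "value") %in% names(grid_values)),
            all(c("cell_id", "zip") %in% names(mapping)))
  if (nrow(mapping) == 0L) {
    warning("empty cell-to-ZIP mapping; returning empty aggregate")
    return(data.frame(zip = character(0), value = numeric(0)))
  }
  if (anyDuplicated(mapping$cell_id))
    stop("each cell_id may be mapped at most once")
  m <- merge(mapping, grid_values, by = "cell_id")
  agg <- stats::aggregate(value ~ zip, data = m, FUN = mean)
  agg[order(agg$zip), , drop = FALSE]
}

#' Climate-subtype heat-index percentile tables
#'
#' Pools all warm-season ZIP-day heat-index values of each climate subtype --
#' across every ZIP and every study year, case and control days alike -- and
#' stores the sorted sample. Percentiles are then defined by the
#' right-continuous empirical CDF, `100 * mean(sample <= x)`, so the subtype
#' minimum maps to its positive ECDF mass and the maximum to exactly 100.
#' Localizing the percentile scale to the climate subtype is what lets the
#' same absolute temperature count as "extreme" in one climate and routine in
#' another (acclimatization).
#'
#' @param records data.frame of ZIP-day exposures with columns `zip`, `date`
#'   (Date), `heat_index`.
#' @param climate data.frame with columns `zip`, `subtype`.
#' @param season_months integer months defining the warm season pool
#'   (default May-September).
#' @return an object of class `heat_pctl_table`: a named list of sorted
#'   numeric vectors, one per subtype.
#' @seealso [to_percentile()], [pctl_quantile()]
#' @export
compute_percentiles <- function(records, climate, season_months = 5:9) {
  stopifnot(all(c("zip", "date", "heat_index") %in% names(records)),
            all(c("zip", "subtype") %in% names(climate)))
  rec <- merge(records, climate[, c("zip", "subtype")], by = "zip")
  rec <- rec[as.integer(format(as.Date(rec$date), "%m")) %in% season_months, ]
  rec <- rec[is.finite(rec$heat_index), ]
  tabs <- lapply(split(rec$heat_index, rec$subtype), sort)
  empty <- setdiff(unique(climate$subtype), names(tabs))
  if (length(empty))
    warning("subtypes with no warm-season data excluded: ",
            paste(empty, collapse = ", "))
  structure(tabs, class = "heat_pctl_table")
}

#' @export
print.heat_pctl_table <- function(x, ...) {
  cat("Heat-index percentile tables for", length(x), "climate subtype(s)\n")
  for (s in names(x))
    cat(sprintf("  %-4s n=%d  range [%.2f, %.2f]\n",
                s, length(x[[s]]), min(x[[s]]), max(x[[s]])))
  invisible(x)
}

#' Map heat-index values to subtype percentiles
#'
#' Right-continuous ECDF percentile of `x` within the pooled warm-season
#' sample of `subtype`: `100 * (number of pooled values <= x) / n`. Values
#' below the subtype minimum map to 0 and the maximum maps to 100.
#'
#' @param x numeric heat-index values (same unit as the pooled table).
#' @param subtype single subtype code present in `table`.
#' @param table a [compute_percentiles()] result.
#' @return numeric percentiles in \[0, 100\].
#' @export
to_percentile <- function(x, subtype, table) {
  stopifnot(inherits(table, "heat_pctl_table"))
  if (!subtype %in% names(table))
    stop("unknown climate subtype: ", subtype)
  s <- table[[subtype]]
  100 * findInterval(x, s) / length(s)
}

#' @rdname to_percentile
#' @param p percentiles in \[0, 100\] to invert by nearest rank, so
#'   `pctl_quantile(0, ...)` is the subtype minimum and
#'   `pctl_quantile(100, ...)` the maximum.
#' @export
pctl_quantile <- function(p, subtype, table) {
  stopifnot(inherits(table, "heat_pctl_table"))
  if (!subtype %in% names(table))
    stop("unknown climate subtype: ", subtype)
  if (any(p < 0 | p > 100)) stop("percentiles must lie in [0, 100]")
  s <- table[[subtype]]
  s[pmax(1L, ceiling(p / 100 * length(s)))]
}

#' Trailing moving average per ZIP
#'
#' Mean of days `t, t-1, ..., t-window+1` (exposure precedes admission, so
#' the window trails). Days whose window reaches before the start of the
#' supplied series are `NA`; supplying late-April rows therefore yields
#' defined averages on the first warm-season days.
#'
#' @param x data.frame with columns `zip`, `date` (Date) plus the value
#'   columns named in `cols`, one row per ZIP-day; dates need not be sorted
#'   but must be gapless per ZIP for the lag to be meaningful (gaps produce
#'   `NA`).
#' @param cols character vector of value columns to average.
#' @param window integer window length, default 3.
#' @return `x` with `cols` replaced by their trailing moving averages.
#' @export
moving_average <- function(x, cols, window = 3L) {
  stopifnot(all(c("zip", "date") %in% names(x)), all(cols %in% names(x)))
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1")
  x <- x[order(x$zip, x$date), , drop = FALSE]
  for (cl in cols) {
    x[[cl]] <- unlist(lapply(split(seq_len(nrow(x)), x$zip), function(i) {
      d <- as.integer(x$date[i]); v <- x[[cl]][i]
      # align on calendar days so date gaps yield NA rather than a shifted lag
      full <- seq(min(d), max(d))
      fv <- rep(NA_real_, length(full))
      fv[match(d, full)] <- v
      ma <- stats::filter(fv, rep(1 / window, window), sides = 1)
      as.numeric(ma)[match(d, full)]
    }), use.names = FALSE)
  }
  rownames(x) <- NULL
  x
}
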