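# Correlation of ASR with plane-averaged hemodynamic summaries.
#
# Hemodynamic fields (velocity, WSS) are external inputs produced by a flow
# solver; this module only averages supplied point samples over the three
# measurement planes and correlates the summaries with ASR.

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance
#' @return correlation coefficient in `[-1, 1]`
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort_validation("x and y must have equal length")
  if (length(x) < 3L) abort_validation("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) abort_validation("missing values in correlation input")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx * dx)
  syy <- sum(dy * dy)
  if (sxx == 0 || syy == 0) abort_validation("zero variance in correlation input")
  sum(dx * dy) / sqrt(sxx * syy)
}

#' Average field samples over the measurement planes
#'
#' Each sample (a point in neck-frame coordinates with a scalar value) is
#' assigned to the nearest measurement plane if it lies within the
#' half-spacing band `h/6` of it; samples outside every band are ignored
#' (their count is reported).  Returns per-plane arithmetic means and the
#' grand mean, taken as the mean of the plane means.
#'
#' @param samples data.frame with columns `x`, `y`, `z`, `value` (frame
#'   coordinates, mm)
#' @param planes a [measurement_planes()] result
#' @return list with `per_plane` (named numeric, P1/P2/P3; `NA` where a
#'   plane received no samples), `grand_mean`, `n_per_plane`, `n_unassigned`
#' @export
plane_average <- function(samples, planes) {
  stopifnot(inherits(planes, "measurement_planes"))
  need <- c("x", "y", "z", "value")
  if (!all(need %in% names(samples))) {
    abort_validation("samples must have columns x, y, z, value")
  }
  zs <- c(P1 = planes$P1$z, P2 = planes$P2$z, P3 = planes$P3$z)
  band <- planes$h / 6
  dz <- abs(outer(samples$z, zs, "-"))
  nearest <- max.col(-dz, ties.method = "first")
  in_band <- dz[cbind(seq_len(nrow(dz)), nearest)] <= band + 1e-12
  assigned <- factor(names(zs)[nearest[in_band]], levels = names(zs))
  vals <- samples$value[in_band]
  per <- tapply(vals, assigned, mean)
  per <- as.numeric(per); names(per) <- names(zs)
  n_per <- as.integer(table(assigned))
  list(per_plane = per,
       grand_mean = mean(per, na.rm = TRUE),
       n_per_plane = {names(n_per) <- names(zs); n_per},
       n_unassigned = sum(!in_band))
}

#' Correlate ASR against a summary column of a model table
#'
#' @param table data.frame with one row per model; must contain an `ASR`
#'   column without missing values
#' @param column name of the summary column (e.g. a plane-averaged velocity
#'   or WSS)
#' @return list with `r` (Pearson correlation), `n` (rows used)
#' @export
correlate_asr <- function(table, column) {
  if (!"ASR" %in% names(table)) abort_validation("table has no ASR column")
  if (!column %in% names(table)) {
    abort_validation("table has no column '%s'", column)
  }
  if (anyNA(table$ASR)) abort_validation("missing ASR values in table")
  keep <- !is.na(table[[column]])
  list(r = pearson_r(table$ASR[keep], table[[column]][keep]),
       n = sum(keep))
}
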