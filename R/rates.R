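# Specific-rate estimators and internal-standard normalization:
#   A_r = A_i / (DCW * A_s)      relative abundance
#   q   = dc / (DCW * dt)        specific butanol production rate, 1/h
#   mu  = d ln(OD) / dt          specific growth rate, 1/h

#' Internal-standard / biomass normalization of a peak-area table
#'
#' Converts raw GC-MS peak areas to relative abundances
#' `A_r[s, j] = A_i[s, j] / (DCW_s * A_s[s])`, where `A_s` is the spiked
#' deuterated internal-standard channel and `DCW_s` the dry cell weight of
#' the sample. The internal-standard column is removed from the output.
#' Rows with non-positive internal standard or DCW are rejected (dropped
#' with a named warning), never silently normalized.
#'
#' @param table Data frame with annotation columns `time_h`, `replicate`,
#'   metabolite peak-area columns, and the internal-standard column.
#' @param dcw_per_sample Dry cell weight (g/L), one value per row.
#' @param is_col Name of the internal-standard column.
#' @return Data frame with `time_h`, `replicate` and one relative-abundance
#'   column per metabolite (units 1/(g/L)).
#' @export
relative_abundance <- function(table, dcw_per_sample,
                               is_col = "IS_succinate_d4") {
  ferm_assert(is_col %in% names(table),
              sprintf("internal-standard column '%s' not found", is_col))
  ferm_assert(all(c("time_h", "replicate") %in% names(table)),
              "table needs time_h and replicate annotation columns")
  ferm_assert(length(dcw_per_sample) == nrow(table),
              "dcw_per_sample must have one value per row")
  key <- paste(table$time_h, table$replicate)
  ferm_assert(!anyDuplicated(key), "duplicate (time, replicate) keys")

  a_s <- table[[is_col]]
  bad <- which(!(a_s > 0) | !(dcw_per_sample > 0))
  if (length(bad)) {
    warning(sprintf(
      "rejecting %d row(s) with non-positive internal standard or DCW: %s",
      length(bad), paste(key[bad], collapse = ", ")))
    table <- table[-bad, , drop = FALSE]
    a_s <- a_s[-bad]
    dcw_per_sample <- dcw_per_sample[-bad]
  }
  met_cols <- setdiff(names(table), c("time_h", "replicate", is_col))
  out <- table[c("time_h", "replicate")]
  denom <- dcw_per_sample * a_s
  for (j in met_cols) out[[j]] <- table[[j]] / denom
  out
}

# Shared derivative engine: central differences on the sampled grid
# (one-sided at the ends), or the analytic derivative of an interpolating
# natural cubic spline for noisy series.
series_derivative <- function(t, v, method = c("fd", "spline"), at = NULL) {
  method <- match.arg(method)
  ferm_assert(length(t) >= 2 && all(diff(t) > 0),
              "need >= 2 strictly increasing time points")
  if (method == "fd") {
    n <- length(t)
    d <- numeric(n)
    if (n == 2) {
      d[] <- (v[2] - v[1]) / (t[2] - t[1])
    } else {
      i <- 2:(n - 1)
      d[i] <- (v[i + 1] - v[i - 1]) / (t[i + 1] - t[i - 1])
      d[1] <- (v[2] - v[1]) / (t[2] - t[1])
      d[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
    }
    if (is.null(at)) return(data.frame(time_h = t, deriv = d))
    data.frame(time_h = at,
               deriv = stats::approx(t, d, xout = at, rule = 2)$y)
  } else {
    f <- stats::splinefun(t, v, method = "natural")
    tt <- if (is.null(at)) t else at
    data.frame(time_h = tt, deriv = f(tt, deriv = 1))
  }
}

#' Specific growth rate from an OD time course
#'
#' Estimates `mu(t) = d ln(OD600) / dt` (natural log, 1/h) by central
#' finite differences on the sampled grid (one-sided at the ends), or by the
#' analytic first derivative of an interpolating natural cubic spline
#' (`method = "spline"`). Since ln OD is differenced, the estimate is
#' invariant to rescaling OD by any positive constant; negative rates in the
#' decline phase are retained, not clipped.
#'
#' @param tc A `fermentation_timecourse` (or data.frame with `time_h`,
#'   `od600`).
#' @param method `"fd"` (default) or `"spline"`.
#' @param at Optional evaluation times; `fd` estimates are linearly
#'   interpolated from the grid, spline derivatives evaluated directly.
#' @return Data frame with `time_h`, `mu`.
#' @export
compute_mu <- function(tc, method = c("fd", "spline"), at = NULL) {
  ferm_assert(all(c("time_h", "od600") %in% names(tc)),
              "time course needs time_h and od600")
  ferm_assert(all(tc$od600 > 0), "OD must be positive wherever mu is computed")
  d <- series_derivative(tc$time_h, log(tc$od600), method, at)
  data.frame(time_h = d$time_h, mu = d$deriv)
}

#' Specific butanol production rate from a titer time course
#'
#' Estimates `q(t) = (dc/dt) / DCW(t)` in 1/h (g butanol per g dry cell
#' weight per hour) with the same differencing scheme as [compute_mu()].
#'
#' @inheritParams compute_mu
#' @return Data frame with `time_h`, `q`.
#' @export
compute_q <- function(tc, method = c("fd", "spline"), at = NULL) {
  ferm_assert(all(c("time_h", "butanol", "dcw") %in% names(tc)),
              "time course needs time_h, butanol and dcw")
  ferm_assert(all(tc$dcw > 0), "DCW must be positive wherever q is computed")
  d <- series_derivative(tc$time_h, tc$butanol, method, at)
  dcw_at <- if (is.null(at)) tc$dcw else {
    stats::approx(tc$time_h, tc$dcw, xout = at, rule = 2)$y
  }
  data.frame(time_h = d$time_h, q = d$deriv / dcw_at)
}

#' Phenotype vector at the metabolome sampling times
#'
#' Convenience wrapper evaluating [compute_mu()] and [compute_q()] at the
#' metabolome sampling times and carrying the interpolated dry cell weight,
#' i.e. everything downstream modeling and normalization need.
#'
#' @inheritParams compute_mu
#' @param sample_times_h Metabolome sampling times (hours).
#' @return Data frame with `time_h`, `mu`, `q`, `dcw`.
#' @export
phenotype_rates <- function(tc, sample_times_h, method = c("fd", "spline")) {
  mu <- compute_mu(tc, method, at = sample_times_h)
  q <- compute_q(tc, method, at = sample_times_h)
  data.frame(time_h = sample_times_h, mu = mu$mu, q = q$q,
             dcw = stats::approx(tc$time_h, tc$dcw, xout = sample_times_h,
                                 rule = 2)$y)
}

#' Display transform for relative abundances
#'
#' `log10(10000 * A_r)`, the scale conventionally used to plot relative
#' abundances spanning several decades.
#'
#' @param a_r Numeric vector/matrix of relative abundances (> 0).
#' @return Transformed values, same shape.
#' @export
display_transform <- function(a_r) {
  ferm_assert(all(a_r > 0), "display transform requires positive abundances")
  log10(10000 * a_r)
}
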