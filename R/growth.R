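#' Area under a growth curve
#'
#' Trapezoidal integral of background-corrected optical density over time,
#' the standard plate-reader summary of total growth. Background correction
#' subtracts the first (pre-growth) OD reading of the well; negative
#' corrected values are permitted (heavily inhibited wells can dip below
#' their blank) but flagged with an attribute.
#'
#' @param time_h numeric vector of time points, hours, strictly increasing.
#' @param od optical density readings.
#' @param background `"t0"` (subtract the first reading, default),
#'   `"none"`, or a numeric blank value.
#' @return AUC in od-hours; attribute `negative_od` is TRUE if any
#'   corrected reading was negative.
#' @export
growth_auc <- function(time_h, od, background = "t0") {
  stopifnot(length(time_h) == length(od), length(time_h) >= 2L)
  if (is.unsorted(time_h, strictly = TRUE)) stop("time points must be strictly increasing")
  corr <- if (identical(background, "t0")) od - od[1L]
  else if (identical(background, "none")) od
  else od - as.numeric(background)
  out <- pracma::trapz(time_h, corr)
  attr(out, "negative_od") <- any(corr < 0)
  out
}

#' Treated growth as percent of control
#'
#' `100 * mean(treated AUC) / mean(control AUC)`, with a delta-method
#' standard error propagated from the replicate spreads.
#'
#' @param treated,control numeric vectors of replicate AUCs.
#' @return list: `percent`, `se` (NA with a single replicate pair).
#' @export
percent_of_control <- function(treated, control) {
  stopifnot(length(treated) >= 1L, length(control) >= 1L)
  mt <- mean(treated)
  mc <- mean(control)
  if (mc == 0) stop("control mean AUC is zero")
  pct <- 100 * mt / mc
  vt <- if (length(treated) > 1L) stats::var(treated) / length(treated) else NA_real_
  vc <- if (length(control) > 1L) stats::var(control) / length(control) else NA_real_
  se <- abs(pct) * sqrt(vt / mt^2 + vc / mc^2)
  list(percent = pct, se = se)
}

#' Interpolated ICx from a dose-response ladder
#'
#' Finds the dose producing x percent growth inhibition, i.e. where the
#' percent-of-control response first crosses `100 - x`, by linear
#' interpolation between the flanking grid doses. Returns `NA` with a
#' diagnostic message when the response never crosses.
#'
#' @param dose numeric dose grid (ascending, first entry usually 0).
#' @param percent percent-of-control response at each dose.
#' @param x inhibition percentage (default 20 for the IC20).
#' @return interpolated dose, or `NA` if no crossing.
#' @export
icx <- function(dose, percent, x = 20) {
  stopifnot(length(dose) == length(percent), length(dose) >= 2L)
  o <- order(dose)
  dose <- dose[o]; percent <- percent[o]
  target <- 100 - x
  below <- percent <= target
  if (!any(below)) {
    message("response never reaches ", target, "% of control; ICx undefined")
    return(NA_real_)
  }
  i <- which(below)[1L]
  if (i == 1L) return(dose[1L])
  d0 <- dose[i - 1L]; d1 <- dose[i]
  r0 <- percent[i - 1L]; r1 <- percent[i]
  d0 + (r0 - target) / (r0 - r1) * (d1 - d0)
}

#' Dose ladder derived from an IC20
#'
#' Exposure screens treat pools at the IC20 and at 50% and 25% of it; this
#' helper expands an IC20 estimate into that ladder (e.g. an IC20 of 4 mM
#' gives 1, 2 and 4 mM).
#'
#' @param ic20 the IC20 dose.
#' @return named numeric vector with elements `"25"`, `"50"`, `"100"`.
#' @export
dose_ladder <- function(ic20) {
  stopifnot(is.numeric(ic20), ic20 > 0)
  c("25" = 0.25 * ic20, "50" = 0.5 * ic20, "100" = ic20)
}

#' Dose-response summary of a growth-curve collection
#'
#' Computes per-well AUCs, averages replicates within each dose, expresses
#' doses as percent of the zero-dose control, and interpolates the
#' requested ICx.
#'
#' @param curves long data.frame (well, dose, time_h, od) as produced by
#'   [generate_growth_curves()] or [read_growth_csv()].
#' @param x inhibition percentage for the ICx (default 20).
#' @param background passed to [growth_auc()].
#' @return list: `auc` (per-well data.frame), `response` (per-dose percent
#'   of control with SE), `icx` (dose), `x`.
#' @export
dose_response <- function(curves, x = 20, background = "t0") {
  stopifnot(all(c("well", "dose", "time_h", "od") %in% names(curves)))
  wells <- split(curves, curves$well)
  auc_tab <- do.call(rbind, lapply(wells, function(w) {
    w <- w[order(w$time_h), ]
    data.frame(well = w$well[1L], dose = w$dose[1L],
               auc = as.numeric(growth_auc(w$time_h, w$od, background)),
               stringsAsFactors = FALSE)
  }))
  rownames(auc_tab) <- NULL
  if (!any(auc_tab$dose == 0)) stop("need zero-dose control wells")
  ctrl <- auc_tab$auc[auc_tab$dose == 0]
  doses <- sort(unique(auc_tab$dose))
  resp <- do.call(rbind, lapply(doses, function(dd) {
    poc <- percent_of_control(auc_tab$auc[auc_tab$dose == dd], ctrl)
    data.frame(dose = dd, percent = poc$percent, se = poc$se)
  }))
  resp$percent[resp$dose == 0] <- 100  # by construction
  list(auc = auc_tab, response = resp,
       icx = icx(resp$dose, resp$percent, x = x), x = x)
}
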