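#' Exponential growth rate between two biomass measurements
#'
#' `r = (x_t2 / x_t1)^(1 / (t2 - t1)) - 1`, the per-day relative growth
#' rate under geometric growth; for the standard 2-day sampling interval
#' this is `sqrt(CDW_t2 / CDW_t1) - 1`. Vectorised over all arguments.
#'
#' @param x_t1,x_t2 biomass (g CDW / L) at the two time points (> 0)
#' @param t1,t2 times in days, `t2 > t1`
#' @return growth rate per day
#' @export
growth_rate <- function(x_t1, x_t2, t1, t2) {
  if (any(x_t1 <= 0) || any(x_t2 <= 0))
    stop("biomass must be positive", call. = FALSE)
  if (any(t2 <= t1)) stop("t2 must exceed t1", call. = FALSE)
  (x_t2 / x_t1)^(1 / (t2 - t1)) - 1
}

#' Construct a growth series
#'
#' @param days strictly increasing sampling times (days)
#' @param cdw matrix of cell dry weight (g/L), one row per time point,
#'   one column per replicate; all values positive
#' @return list of class `growth_series`
#' @export
growth_series <- function(days, cdw) {
  cdw <- as.matrix(cdw)
  stopifnot(length(days) == nrow(cdw))
  if (is.unsorted(days, strictly = TRUE))
    stop("days must be strictly increasing", call. = FALSE)
  if (any(cdw <= 0)) stop("CDW values must be positive", call. = FALSE)
  if (is.null(colnames(cdw)))
    colnames(cdw) <- paste0("rep", seq_len(ncol(cdw)))
  structure(list(days = days, cdw = cdw), class = "growth_series")
}

#' Read a growth series from TSV
#'
#' Expected columns: `day` plus one column per replicate (any names).
#'
#' @param path TSV path (`#` comment lines skipped)
#' @export
read_growth_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (!"day" %in% names(raw))
    stop("mandatory column `day` missing from ", path, call. = FALSE)
  growth_series(raw$day, as.matrix(raw[setdiff(names(raw), "day")]))
}

#' Period growth rates and their summary
#'
#' Computes each replicate's growth rate over consecutive periods of
#' `interval_days` (default the 2-day sampling scheme) from `from_day` to
#' `to_day`, then the replicate mean and sample SD per period. The
#' average growth rate is the unweighted mean of the period means; the
#' maximum growth rate is the largest period mean.
#'
#' @param series a [growth_series()]
#' @param interval_days period length in days
#' @param from_day,to_day period range (default days 0 to 8)
#' @return list of class `growth_summary`: `periods` (data.frame with
#'   per-replicate rates, `mean`, `sd`), `average_rate`, `maximum_rate`
#' @export
summarize_growth <- function(series, interval_days = 2, from_day = 0,
                             to_day = 8) {
  stopifnot(inherits(series, "growth_series"))
  starts <- seq(from_day, to_day - interval_days, by = interval_days)
  idx <- function(d) {
    i <- match(d, series$days)
    if (is.na(i)) stop("no measurement at day ", d, call. = FALSE)
    i
  }
  rows <- lapply(starts, function(t1) {
    t2 <- t1 + interval_days
    r <- growth_rate(series$cdw[idx(t1), ], series$cdw[idx(t2), ], t1, t2)
    c(r, mean = mean(r), sd = stats::sd(r))
  })
  periods <- as.data.frame(do.call(rbind, rows))
  periods <- cbind(period = sprintf("%g-%g", starts, starts + interval_days),
                   periods)
  structure(list(periods = periods,
                 average_rate = mean(periods$mean),
                 maximum_rate = max(periods$mean)),
            class = "growth_summary")
}

#' @export
print.growth_summary <- function(x, ...) {
  df <- x$periods
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 3)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("average growth rate: %.3f per day\n", x$average_rate))
  cat(sprintf("maximum growth rate: %.3f per day\n", x$maximum_rate))
  invisible(x)
}

#' Total chlorophyll from two-wavelength absorbance
#'
#' Chlorophyll a+b in 96 % ethanol extract:
#' `C (mg/L) = 20.2 * OD645 + 8.05 * OD663`. When the culture's cell dry
#' weight is supplied the content is also expressed as percent of CDW.
#'
#' @param od645,od663 absorbances against an ethanol blank (>= 0)
#' @param cdw_g_per_l optional cell dry weight (g/L)
#' @return list `mg_per_l` and, when CDW is given, `pct_cdw`
#' @export
chlorophyll_content <- function(od645, od663, cdw_g_per_l = NULL) {
  if (any(od645 < 0) || any(od663 < 0))
    stop("absorbances must be non-negative", call. = FALSE)
  c_mg_l <- 20.2 * od645 + 8.05 * od663
  out <- list(mg_per_l = c_mg_l)
  if (!is.null(cdw_g_per_l))
    out$pct_cdw <- c_mg_l / (1000 * cdw_g_per_l) * 100
  out
}

#' Effective quantum yield of photosystem II
#'
#' `Y(II) = (Fm' - F) / Fm'` from pulse-amplitude-modulated fluorometry
#' under actinic light; always in \[0, 1\] for a valid measurement.
#'
#' @param fm_prime maximal fluorescence in the light-adapted state (> 0)
#' @param f steady-state fluorescence (`0 <= f <= fm_prime`)
#' @export
quantum_yield <- function(fm_prime, f) {
  if (any(fm_prime <= 0)) stop("fm_prime must be positive", call. = FALSE)
  if (any(f < 0)) stop("fluorescence must be non-negative", call. = FALSE)
  if (any(f > fm_prime))
    stop("invalid measurement: F exceeds Fm'", call. = FALSE)
  (fm_prime - f) / fm_prime
}

#' Component mass as percent of cell dry weight
#' @param component_g_per_l component (e.g. total lipid) in g/L
#' @param cdw_g_per_l cell dry weight in g/L (> 0)
#' @return `100 * component / cdw`; unit changes applied to both
#'   arguments cancel
#' @export
percent_cdw <- function(component_g_per_l, cdw_g_per_l) {
  if (any(cdw_g_per_l <= 0)) stop("CDW must be positive", call. = FALSE)
  100 * component_g_per_l / cdw_g_per_l
}

#' Fold change between two measurements
#' @param before reference value (> 0)
#' @param after comparison value
#' @return `after / before`
#' @export
fold_change <- function(before, after) {
  if (any(before <= 0)) stop("reference value must be positive",
                             call. = FALSE)
  after / before
}
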