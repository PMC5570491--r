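#' Convert a doubling time to an exponential growth rate
#'
#' Uses mu = ln(2) / T, so `mu * T == log(2)` exactly before rounding. An
#' 88-hour doubling time — a slow-growing cancer cell line — corresponds to
#' the 0.008 per hr minimal-growth bound used throughout the model-building
#' pipeline.
#'
#' @param doubling_time doubling time in hours; must be > 0.
#' @return Growth rate per hour.
#' @seealso [doubling_time_from_growth_rate()]
#' @examples
#' round(growth_rate_from_doubling_time(88), 3) # 0.008
#' @export
growth_rate_from_doubling_time <- function(doubling_time) {
  if (any(!is.finite(doubling_time) | doubling_time <= 0))
    stop("doubling time must be positive and finite")
  log(2) / doubling_time
}

#' Convert an exponential growth rate to a doubling time
#'
#' Inverse of [growth_rate_from_doubling_time()]: T = ln(2) / mu.
#'
#' @param rate growth rate per hour; must be > 0.
#' @return Doubling time in hours.
#' @examples
#' round(doubling_time_from_growth_rate(0.038), 1) # 18.2
#' @export
doubling_time_from_growth_rate <- function(rate) {
  if (any(!is.finite(rate) | rate <= 0))
    stop("growth rate must be positive and finite")
  log(2) / rate
}

#' Scale a reference dry mass by cell volume
#'
#' Infers the dry weight of a target cell type from a reference cell's dry
#' mass by assuming dry mass proportional to cell volume:
#' `dry_mass * target_volume / reference_volume`. Scaling the 60 pg dry mass
#' of U2OS cells (4000 um^3) to lymphocyte volume (243 um^3) gives 3.645 pg.
#'
#' @param dry_mass reference dry mass in pg.
#' @param reference_volume reference cell volume in um^3.
#' @param target_volume target cell volume in um^3.
#' @return Inferred dry mass in pg.
#' @examples
#' infer_dry_weight(60, 4000, 243) # 3.645
#' @export
infer_dry_weight <- function(dry_mass, reference_volume, target_volume) {
  vals <- c(dry_mass, reference_volume, target_volume)
  if (any(!is.finite(vals) | vals <= 0))
    stop("all inputs must be positive and finite")
  dry_mass * target_volume / reference_volume
}
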