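.env_columns <- c("timepoint", "chl_a", "secchi_depth", "wind_speed_max",
                  "water_level", "detritus_score", "tide_direction")

#' Construct an environmental covariate table
#'
#' Per-timepoint environmental measurements accompanying the amplicon time
#' series: chlorophyll a (ug/L), Secchi depth (m, water clarity), daily
#' maximum wind speed (km/h), water level (m relative to reference zero), an
#' ordinal microscopy detritus score (0 = none .. 6 = massive) and tidal
#' direction at sampling. Missing measurements are `NA`.
#'
#' @param timepoint Integer Julian days, strictly increasing.
#' @param chl_a,secchi_depth,wind_speed_max,water_level Numeric vectors
#'   (may contain `NA`).
#' @param detritus_score Integer in 0..6 or `NA`.
#' @param tide_direction `"rising"`, `"falling"` or `"unknown"`.
#' @return A data frame of class `env_table`.
#' @export
env_table <- function(timepoint, chl_a = NA_real_, secchi_depth = NA_real_,
                      wind_speed_max = NA_real_, water_level = NA_real_,
                      detritus_score = NA_integer_,
                      tide_direction = "unknown") {
  x <- data.frame(
    timepoint = as.integer(timepoint),
    chl_a = as.numeric(chl_a),
    secchi_depth = as.numeric(secchi_depth),
    wind_speed_max = as.numeric(wind_speed_max),
    water_level = as.numeric(water_level),
    detritus_score = as.integer(detritus_score),
    tide_direction = as.character(tide_direction),
    stringsAsFactors = FALSE
  )
  class(x) <- c("env_table", "data.frame")
  validate_env_table(x)
}

#' Validate an environmental table
#'
#' @param x An `env_table`.
#' @return `x` if valid, else an error locating the violation.
#' @export
validate_env_table <- function(x) {
  stopifnot(inherits(x, "env_table"))
  if (!all(.env_columns %in% names(x))) {
    stop("env table must contain columns: ",
         paste(.env_columns, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) > 1L && any(diff(x$timepoint) <= 0L)) {
    stop("env timepoints must be strictly increasing", call. = FALSE)
  }
  ds <- x$detritus_score
  if (any(!is.na(ds) & (ds < 0L | ds > 6L))) {
    stop("detritus_score must lie in 0..6", call. = FALSE)
  }
  sd_ <- x$secchi_depth
  if (any(!is.na(sd_) & sd_ <= 0)) {
    stop("secchi_depth must be positive where present", call. = FALSE)
  }
  td <- x$tide_direction
  if (any(!td %in% c("rising", "falling", "unknown"))) {
    stop("tide_direction must be rising/falling/unknown", call. = FALSE)
  }
  x
}
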