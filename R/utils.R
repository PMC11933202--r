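#' Haversine distance in meters
#'
#' Great-circle distance on a sphere of radius 6,371,000 m, the convention used
#' throughout the pipeline (no projection step is needed at stop-detection
#' scales).
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in WGS84 decimal degrees; vectors are
#'   recycled to a common length.
#' @return Numeric vector of distances in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  haversine_m_cpp(rep_len(as.numeric(lat1), n), rep_len(as.numeric(lon1), n),
                  rep_len(as.numeric(lat2), n), rep_len(as.numeric(lon2), n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# meters -> degrees at a given latitude
m_per_deg_lat <- function() 110574
m_per_deg_lon <- function(lat) 111320 * cos(lat * pi / 180)

as_date <- function(x) {
  if (inherits(x, "Date")) x else as.Date(x)
}

# 1-based day index relative to an origin date
day_index <- function(date, origin) as.integer(date - as_date(origin)) + 1L

# Monday=1 .. Sunday=7 for a day index given the origin date
weekday_of <- function(day_idx, origin) {
  w0 <- as.integer(format(as_date(origin), "%u"))
  ((w0 - 1L + day_idx - 1L) %% 7L) + 1L
}

is_weekday_idx <- function(day_idx, origin) weekday_of(day_idx, origin) <= 5L

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1 || is.na(x)) stop(sprintf("'%s' must be a non-NA scalar", name))
  invisible(x)
}

# Exponential recovery shape, mean-normalised to 1 over the post-declaration
# window so that planted period-averaged effects equal their nominal values
# irrespective of the relaxation halflife.
recovery_shape <- function(day_idx, pandemic_day, post_days, halflife) {
  if (!is.finite(halflife)) {
    s <- rep(1, length(post_days))
  } else {
    s <- 2^(-(post_days - pandemic_day - 1L) / halflife)
  }
  h <- s / mean(s)
  out <- numeric(length(day_idx))
  m <- match(day_idx, post_days)
  out[!is.na(m)] <- h[m[!is.na(m)]]
  out
}
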