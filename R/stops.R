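#' Detect stop events from raw pings
#'
#' Greedy sequential spatiotemporal clustering (the stay-point convention):
#' a candidate cluster grows while each new ping lies within `d_max_m` of the
#' cluster's running centroid (Haversine, Earth radius 6,371 km); a ping
#' breaking the radius closes the candidate, which becomes a stop event iff
#' the time spanned between its earliest and latest ping is at least `t_min`.
#' The breaking ping seeds the next candidate; transit pings that never form a
#' qualifying cluster are discarded. The event centroid is the unweighted mean
#' of member coordinates.
#'
#' @param pings data.table/data.frame with `user_id`, `t` (POSIXct or numeric
#'   seconds), `lat`, `lon`, `accuracy_m`; rows must be time-sorted within
#'   each user (an error is raised otherwise).
#' @param d_max_m Maximum distance from the running centroid, meters.
#' @param t_min_s Minimum stop duration, seconds (default 5 minutes).
#' @param predicate "centroid" (default): each ping must lie within `d_max_m`
#'   of the running centroid; "diameter": within `d_max_m` of every member
#'   ping (a stricter reading of the maximum spatial distance).
#' @return data.table of stop events: `user_id`, `t_start`, `t_end` (same
#'   class as `t`), `lat`, `lon`, `n_pings`, `mean_accuracy_m`, `event_id`.
#' @export
detect_stop_events <- function(pings, d_max_m = 25, t_min_s = 300,
                               predicate = c("centroid", "diameter")) {
  predicate <- match.arg(predicate)
  pings <- as.data.table(pings)
  if (nrow(pings) == 0)
    return(data.table(user_id = integer(), t_start = numeric(),
                      t_end = numeric(), lat = numeric(), lon = numeric(),
                      n_pings = integer(), mean_accuracy_m = numeric(),
                      event_id = integer()))
  tnum <- as.numeric(pings$t)
  res <- detect_stops_cpp(as.integer(pings$user_id), tnum,
                          pings$lat, pings$lon, pings$accuracy_m,
                          d_max_m, t_min_s, predicate == "diameter")
  ev <- data.table(user_id = res$user, t_start = res$t_start,
                   t_end = res$t_end, lat = res$lat, lon = res$lon,
                   n_pings = res$n_pings, mean_accuracy_m = res$mean_accuracy_m)
  if (inherits(pings$t, "POSIXct")) {
    ev[, `:=`(t_start = as.POSIXct(t_start, origin = "1970-01-01", tz = "UTC"),
              t_end = as.POSIXct(t_end, origin = "1970-01-01", tz = "UTC"))]
  }
  ev[, event_id := .I]
  ev[]
}

#' Filter stop events by mean positional accuracy
#'
#' Keeps events whose mean ping accuracy is strictly below
#' `max_mean_accuracy_m` (an event at exactly the cutoff is dropped). The
#' number of removed events is reported via message.
#'
#' @param events Output of [detect_stop_events()].
#' @param max_mean_accuracy_m Accuracy cutoff in meters (default 100).
#' @return Filtered events table.
#' @export
filter_by_accuracy <- function(events, max_mean_accuracy_m = 100) {
  events <- as.data.table(events)
  keep <- events$mean_accuracy_m < max_mean_accuracy_m
  if (any(!keep))
    message(sprintf("filter_by_accuracy: dropped %d of %d stop events",
                    sum(!keep), length(keep)))
  events[keep]
}

#' Per-user daily presence from raw pings
#'
#' A user is active on a calendar day (local time) if at least one raw ping
#' was recorded that day. Used by the activity filters and as the denominator
#' of daily indicators.
#'
#' @param pings Ping table (`user_id`, `t` in UTC).
#' @param users User table with `user_id` and `country`.
#' @param countries Country table with `country` and `tz_offset_hours`.
#' @param origin Observation start date.
#' @return data.table (`user_id`, `day`) of active user-days, keyed.
#' @export
daily_presence <- function(pings, users, countries, origin) {
  p <- as.data.table(pings)[, .(user_id, t)]
  p[as.data.table(users), country := i.country, on = "user_id"]
  p[as.data.table(countries), tz := i.tz_offset_hours, on = "country"]
  origin_utc <- as.POSIXct(paste(as_date(origin), "00:00:00"), tz = "UTC")
  p[, day := as.integer(floor((as.numeric(t) - as.numeric(origin_utc) +
                                 tz * 3600) / 86400)) + 1L]
  out <- unique(p[, .(user_id, day)])
  setkey(out, user_id, day)
  out
}

#' Activity filter: retain longitudinally observable users
#'
#' A user is retained iff the share of days with at least one ping is at
#' least `threshold` in the full observation window AND in the pre-pandemic
#' window.
#'
#' @param presence Active user-days from [daily_presence()].
#' @param obs_days Integer vector of day indices of the observation window.
#' @param pre_days Integer vector of day indices of the pre-pandemic window.
#' @param threshold Minimum share of active days in both windows (default 0.20).
#' @return Integer vector of retained user ids.
#' @export
filter_active_users <- function(presence, obs_days, pre_days, threshold = 0.20) {
  presence <- as.data.table(presence)
  if (!any(presence$day %in% obs_days) || !any(presence$day %in% pre_days))
    warning("activity windows do not overlap the observed data range")
  act <- presence[, .(obs = sum(day %in% obs_days) / length(obs_days),
                      pre = sum(day %in% pre_days) / length(pre_days)),
                  by = user_id]
  act[obs >= threshold & pre >= threshold, user_id]
}
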