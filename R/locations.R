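#' Cluster stop events into stop locations
#'
#' DBSCAN over stop-event centroids with the Haversine metric, run per user.
#' With the default `min_samples = 1` every event is a core point and clusters
#' are the connected components of the eps-graph (density-reachability at
#' `eps_m`), so no event is lost as noise; rare but long stays (a home visited
#' once per window) still form locations.
#'
#' @param events Accuracy-filtered stop events ([detect_stop_events()]).
#' @param eps_m Neighbourhood radius in meters (default 25).
#' @param min_samples Minimum neighbourhood size for a core point (default 1).
#' @return A list with `events` (the input plus a `location_id` column;
#'   `location_id` 0 marks noise events when `min_samples > 1`) and
#'   `locations` (`user_id`, `location_id`, centroid `lat`/`lon`, `n_events`),
#'   where a location centroid is the mean of its member event centroids.
#' @export
cluster_stop_locations <- function(events, eps_m = 25, min_samples = 1L) {
  events <- as.data.table(events)
  setorder(events, user_id, t_start)
  cl <- dbscan_eps_cpp(as.integer(events$user_id), events$lat, events$lon,
                       eps_m, as.integer(min_samples))
  events[, location_id := cl]
  locations <- events[location_id > 0,
                      .(lat = mean(lat), lon = mean(lon), n_events = .N),
                      by = .(user_id, location_id)]
  list(events = events[], locations = locations)
}

#' Expand stop events into per-day visit records (local time)
#'
#' Splits each stop event over the calendar days it overlaps in the user's
#' local time and computes, per (user, location, day): total overlap minutes,
#' whether the day counts as a nighttime visit (any overlap with Mon-Fri
#' 23:00-05:00(+1), attributed to the starting day, or any time on Sat/Sun),
#' and workday-daytime overlap minutes (Mon-Fri 05:00-23:00).
#'
#' @param events Stop events with `location_id`.
#' @param users User table (`user_id`, `country`).
#' @param countries Country table (`country`, `tz_offset_hours`).
#' @param origin Observation start date.
#' @return data.table (`user_id`, `location_id`, `day`, `minutes`,
#'   `night`, `day_min`, `fd`).
#' @export
stop_event_days <- function(events, users, countries, origin) {
  ev <- as.data.table(events)[, .(user_id, location_id, t_start, t_end)]
  ev[as.data.table(users), country := i.country, on = "user_id"]
  ev[as.data.table(countries), tz := i.tz_offset_hours, on = "country"]
  origin_utc <- as.POSIXct(paste(as_date(origin), "00:00:00"), tz = "UTC")
  ev[, `:=`(l0 = (as.numeric(t_start) - as.numeric(origin_utc)) / 60 + tz * 60,
            l1 = (as.numeric(t_end) - as.numeric(origin_utc)) / 60 + tz * 60)]
  ev[, `:=`(d0 = pmax(1L, as.integer(l0 %/% 1440) + 1L),
            d1 = as.integer(l1 %/% 1440) + 1L)]
  # expand to day range d0-1 .. d1 (the preceding day can earn night credit
  # from an after-midnight overlap)
  nrep <- ev$d1 - ev$d0 + 2L
  x <- ev[rep.int(seq_len(nrow(ev)), nrep)]
  x[, day := ev$d0[rep.int(seq_len(nrow(ev)), nrep)] - 2L + sequence(nrep)]
  x <- x[day >= 1L]
  w0 <- as.integer(format(as_date(origin), "%u"))
  x[, wd := ((w0 - 1L + day - 1L) %% 7L) + 1L]
  T0 <- (x$day - 1) * 1440
  ovl <- function(a0, a1) pmax(0, pmin(x$l1, a1) - pmax(x$l0, a0))
  x[, minutes := ovl(T0, T0 + 1440)]
  x[, night := fifelse(wd <= 5L, ovl(T0 + 1380, T0 + 1740) > 0, minutes > 0)]
  x[, day_min := fifelse(wd <= 5L, ovl(T0 + 300, T0 + 1380), 0)]
  x <- x[minutes > 0 | night == TRUE]
  out <- x[, .(minutes = sum(minutes), night = any(night),
               day_min = sum(day_min)),
           by = .(user_id, location_id, day)]
  out[, fd := min(day), by = .(user_id, location_id)]
  setkey(out, user_id, location_id, day)
  out
}

#' Label stop locations as home/workplace per 49-day window
#'
#' Trailing windows of `window_days` advanced in `step_days` steps. For each
#' window, HOME is the location with the most nighttime-visit days among
#' locations visited on at least `min_visit_share` of the user's active days
#' in the window (nighttime: Mon-Fri 23:00-05:00(+1), or any time Sat/Sun).
#' WORK is, among the remaining locations, the one with the most
#' workday-daytime visit days (Mon-Fri 05:00-23:00), subject to the same
#' active-day coverage and an average dwell of at least `work_min_dwell_min`
#' per visited day. Ties break by total dwell time, then earliest first
#' visit. A location can be home in one window and work in another, never
#' both in the same window.
#'
#' @param event_days Output of [stop_event_days()].
#' @param presence Output of [daily_presence()].
#' @param n_days Number of days in the observation period.
#' @param window_days,step_days Window length and step (defaults 49 and 7;
#'   `window_days` must be a multiple of `step_days`).
#' @param min_visit_share Minimum share of active days on which a candidate
#'   must be visited (default 0.20).
#' @param work_min_dwell_min Minimum average daytime dwell per visited day for
#'   a work label, minutes (default 60).
#' @return data.table (`user_id`, `window`, `window_end`, `active_days`,
#'   `home_location`, `work_location`); one row per user per completed window
#'   with at least one active day.
#' @export
label_windows <- function(event_days, presence, n_days,
                          window_days = 49L, step_days = 7L,
                          min_visit_share = 0.20, work_min_dwell_min = 60) {
  if (window_days %% step_days != 0)
    stop("window_days must be a multiple of step_days")
  k <- window_days %/% step_days
  w_max <- n_days %/% step_days
  if (w_max < k) stop("observation period shorter than one window")

  wk_of <- function(day) (day - 1L) %/% as.integer(step_days) + 1L
  vw <- as.data.table(event_days)
  vw[, week := wk_of(day)]
  wkl <- vw[, .(nights = sum(night), dayvs = sum(day_min > 0),
                daymin = sum(day_min), vis = sum(minutes > 0),
                totmin = sum(minutes), fd = min(day)),
            by = .(user_id, location_id, week)]
  # replicate each week row into the k trailing windows it belongs to
  expand_windows <- function(dt) {
    x <- dt[rep.int(seq_len(nrow(dt)), k)]
    x[, window := week + rep(seq_len(k) - 1L, each = nrow(dt))]
    x[window >= k & window <= w_max]
  }
  ww <- expand_windows(wkl)[, .(nights = sum(nights), dayvs = sum(dayvs),
                                daymin = sum(daymin), vis = sum(vis),
                                totmin = sum(totmin), fd = min(fd)),
                            by = .(user_id, location_id, window)]
  pr <- as.data.table(presence)[day <= w_max * step_days]
  pr[, week := wk_of(day)]
  aw <- pr[, .(n = .N), by = .(user_id, week)]
  act <- expand_windows(aw)[, .(active_days = sum(n)),
                            by = .(user_id, window)]
  ww[act, active_days := i.active_days, on = c("user_id", "window")]
  ww <- ww[!is.na(active_days) & active_days > 0]

  home <- ww[vis >= min_visit_share * active_days & nights > 0]
  setorder(home, user_id, window, -nights, -totmin, fd)
  home <- home[, .SD[1], by = .(user_id, window)]
  home <- home[, .(user_id, window, active_days,
                   home_location = location_id)]
  work <- ww[home, on = c("user_id", "window"), nomatch = NULL]
  work <- work[location_id != home_location &
                 dayvs >= min_visit_share * active_days &
                 dayvs > 0 & daymin / dayvs >= work_min_dwell_min]
  setorder(work, user_id, window, -dayvs, -totmin, fd)
  work <- work[, .SD[1], by = .(user_id, window)]
  out <- merge(home,
               work[, .(user_id, window, work_location = location_id)],
               by = c("user_id", "window"), all.x = TRUE)
  out[, window_end := window * as.integer(step_days)]
  setkey(out, user_id, window)
  out[]
}

# map points to administrative units (rectangle containment when bounds
# columns are present, polygon test otherwise)
locate_units <- function(points, units) {
  pts <- as.data.table(points)
  units <- as.data.table(units)
  res <- rep(NA_character_, nrow(pts))
  if (all(c("lat0", "lat1", "lon0", "lon1") %in% names(units))) {
    for (i in seq_len(nrow(units))) {
      hit <- is.na(res) & pts$lat >= units$lat0[i] & pts$lat < units$lat1[i] &
        pts$lon >= units$lon0[i] & pts$lon < units$lon1[i]
      res[hit] <- units$unit_id[i]
    }
  } else {
    for (i in seq_len(nrow(units))) {
      poly <- rect_polygon(units$lat0[i], units$lat1[i],
                           units$lon0[i], units$lon1[i])
      hit <- is.na(res) & mgcv::in.out(poly, cbind(pts$lon, pts$lat))
      res[hit] <- units$unit_id[i]
    }
  }
  res
}

#' Build user profiles and dynamic home histories
#'
#' Maps each window's home location to an administrative unit
#' (point-in-polygon on the location centroid), records a relocation event
#' whenever consecutive windows' home units differ (flagging urban-rural
#' transitions), and fixes each user's *primary home* — the modal home unit
#' over pre-pandemic windows — from which the wealth label is inherited.
#' Users whose primary home centroid falls outside every unit polygon are
#' excluded from group aggregates (wealth label NA) and counted in a message.
#'
#' @param labelings Output of [label_windows()].
#' @param locations Stop locations (from [cluster_stop_locations()]).
#' @param units Admin units with `urban` and `wealth_group` columns (from
#'   [classify_urban()] + [assign_wealth_groups()]).
#' @param users User table (`user_id`, `country`).
#' @param pandemic_day Day index of the pandemic declaration.
#' @return A list: `profiles` (one row per user: primary home unit, wealth
#'   group, commuter flag, work unit and workplace wealth), `home_history`
#'   (per user-window home unit and urban flag) and `relocations` (one row
#'   per home-unit change, with `from_urban`/`to_urban`).
#' @export
build_home_history <- function(labelings, locations, units, users,
                               pandemic_day) {
  lab <- as.data.table(labelings)
  locs <- as.data.table(locations)
  units <- as.data.table(units)
  locs[, unit_id := locate_units(.SD, units), .SDcols = c("lat", "lon")]
  lab[locs, home_unit := i.unit_id,
      on = c("user_id", home_location = "location_id")]
  lab[units, `:=`(home_urban = i.urban), on = c(home_unit = "unit_id")]

  hist <- lab[, .(user_id, window, window_end, home_location, home_unit,
                  home_urban)]
  setkey(hist, user_id, window)
  hist[, prev_unit := shift(home_unit), by = user_id]
  hist[, prev_urban := shift(home_urban), by = user_id]
  rel <- hist[!is.na(prev_unit) & !is.na(home_unit) & prev_unit != home_unit,
              .(user_id, window, window_end, from_unit = prev_unit,
                to_unit = home_unit, from_urban = prev_urban,
                to_urban = home_urban)]

  pre <- lab[window_end <= pandemic_day]
  if (nrow(pre) == 0) pre <- lab[window == min(window)]
  modal <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_character_)
    names(sort(table(x), decreasing = TRUE))[1]
  }
  prof <- pre[, .(home_unit_primary = modal(home_unit),
                  home_location_primary = {
                    hl <- home_location[!is.na(home_location)]
                    if (length(hl)) as.integer(modal(as.character(hl))) else NA_integer_
                  },
                  work_location = {
                    wl <- work_location[!is.na(work_location)]
                    if (length(wl)) as.integer(modal(as.character(wl))) else NA_integer_
                  }),
              by = user_id]
  prof[, commuter := !is.na(work_location)]
  wl <- prof[commuter == TRUE, .(user_id, location_id = work_location)]
  wl[locs, `:=`(lat = i.lat, lon = i.lon), on = c("user_id", "location_id")]
  wl[, work_unit := locate_units(.SD, units), .SDcols = c("lat", "lon")]
  prof[wl, `:=`(work_unit = i.work_unit, work_lat = i.lat, work_lon = i.lon),
       on = "user_id"]
  prof[units, `:=`(wealth_group = as.character(i.wealth_group),
                   urban_primary = i.urban),
       on = c(home_unit_primary = "unit_id")]
  prof[units, work_wealth := as.character(i.wealth_group),
       on = c(work_unit = "unit_id")]
  prof[as.data.table(users), country := i.country, on = "user_id"]
  prof[locs, `:=`(home_lat = i.lat, home_lon = i.lon),
       on = c("user_id", home_location_primary = "location_id")]
  n_lost <- prof[is.na(home_unit_primary), .N]
  if (n_lost > 0)
    message(sprintf("build_home_history: %d users outside all unit polygons",
                    n_lost))
  list(profiles = prof[], home_history = hist[],
       relocations = rel[])
}
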