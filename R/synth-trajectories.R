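# Behaviour solver: converts planted period-averaged relative changes into
# daily probabilities/durations, and relocation targets into weekly hazards.
#
# Planted indicators are defined as period-averaged relative changes over the
# post-declaration window. The solver inverts the measurement equations:
#
# * self-isolation: p_si(d,g) = p0 * (1 + rel_g/100 * h(d)), where h is the
#   mean-normalised recovery shape (so the period average equals rel_g).
# * non-commuting share among commuters (q0 = 1: commuters commute every
#   weekday unless self-isolating or stopped): the unconditional weekday
#   commute propensity C(d) = C0 * (1 - beta * h(d)) with beta solved so the
#   period-averaged relative change of the non-commuting share equals the
#   planted value given the actual weekday composition of the baseline and
#   post windows. The daily stop-commuting probability follows as
#   s(d) = 1 - C(d) / (1 - p_si(d)).
# * minutes at home: the duration of the daily "other" outing D(d,g) is
#   solved so the group's expected minutes at home follow
#   M0 * (1 + rel_g/100 * h(d)).
behavior_schedule <- function(world, behavior, users = NULL) {
  cfg <- world$config
  origin <- cfg$observation_start
  n_days <- as.integer(cfg$observation_end - origin) + 1L
  pandemic_day <- day_index(cfg$pandemic_date, origin)
  cal <- data.table(day = seq_len(n_days))
  cal[, date := origin + day - 1L]
  cal[, wd := weekday_of(day, origin)]
  cal[, is_weekday := wd <= 5L]
  cal[, post := day > pandemic_day]
  post_days <- cal[post == TRUE, day]
  cal[, h := recovery_shape(day, pandemic_day, post_days,
                            behavior$recovery_halflife_days)]
  base_days <- cal[date >= cfg$baseline_start & date <= cfg$pandemic_date, day]

  p0 <- behavior$p_selfisolate_pre
  groups <- c("high", "medium", "low", "rural")
  rel_si <- c(behavior$rel_selfisolate,
              rural = unname(behavior$rel_selfisolate["low"]))
  si <- CJ(group = groups, day = cal$day)
  si <- si[cal, on = "day"]
  si[, p_si := pmin(1, pmax(0, p0 * (1 + rel_si[group] / 100 * h)))]

  # stop-commuting probabilities per (home group, workplace wealth) stratum
  C0 <- 1 - p0
  wd_b <- mean(cal[day %in% base_days, is_weekday])
  L0_b <- 1 - wd_b * C0
  wd_post <- mean(cal[post == TRUE, is_weekday])
  m_h <- mean(cal[post == TRUE & is_weekday == TRUE, h])
  strata <- rbindlist(list(
    data.table(group = "high", work_wealth = c("high", "medium", "low"),
               rel = unname(behavior$rel_noncommute["high"])),
    data.table(group = "medium", work_wealth = c("high", "medium", "low"),
               rel = unname(behavior$rel_noncommute["medium"])),
    data.table(group = "low", work_wealth = c("high", "medium", "low"),
               rel = unname(c(behavior$rel_noncommute_low_by_work["high"],
                              mean(behavior$rel_noncommute_low_by_work),
                              behavior$rel_noncommute_low_by_work["low"])))))
  strata[, beta := (L0_b * (1 + rel / 100) - 1 + wd_post * C0) /
           (C0 * wd_post * m_h)]
  sc <- strata[, cal[, .(day, h, is_weekday)], by = .(group, work_wealth, beta)]
  sc <- sc[si, on = c("group", "day"), p_si := i.p_si]
  sc[, C := pmax(0, C0 * (1 - beta * h))]
  sc[, p_stop := fifelse(p_si >= 1, 1, pmin(1, pmax(0, 1 - C / (1 - p_si))))]
  clamped <- sc[is_weekday == TRUE & h > 0 &
                  abs(C0 * (1 - beta * h) - C) > 1e-9, .N]
  if (clamped > 0)
    warning(sprintf("commute propensity clamped on %d stratum-days; planted %s",
                    clamped, "non-commuting targets are not exactly attainable"))

  # "other" outing duration per (group, day)
  s_bar <- sc[, .(s = sum(p_stop *
                            c(high = behavior$frac_low_home_high_work,
                              medium = 0,
                              low = 1 - behavior$frac_low_home_high_work)[work_wealth] *
                            (group == "low") +
                            p_stop * (group != "low") / 3)),
              by = .(group, day)]
  OC <- behavior$commute_return_min - behavior$commute_leave_min
  TR <- 2 * behavior$transit_min
  D0 <- behavior$other_duration_pre_min
  fc <- behavior$commuter_fraction
  rel_mh <- c(behavior$rel_minutes_home,
              rural = unname(behavior$rel_minutes_home["low"]))
  dh <- CJ(group = groups, day = cal$day)
  dh <- dh[cal, on = "day"]
  dh <- dh[si, on = c("group", "day"), p_si := i.p_si]
  dh[s_bar, s := i.s, on = c("group", "day")]
  dh[is.na(s), s := 0]
  dh[group == "rural", s := 0]
  M0_b <- dh[group == "high" & day %in% base_days,
             mean(p0 * 1440 + (1 - p0) *
                    (fc * is_weekday * (1440 - OC) +
                       (1 - fc * is_weekday) * (1440 - TR - D0)))]
  dh[, Pc := fc * is_weekday * (1 - s)]
  dh[group == "rural", Pc := 0]
  dh[, M_t := M0_b * (1 + rel_mh[group] / 100 * h)]
  dh[, d_other := {
    inner <- (M_t - p_si * 1440) / pmax(1 - p_si, 1e-9)
    X <- (inner - Pc * (1440 - OC)) / pmax(1 - Pc, 1e-9)
    fifelse(p_si >= 0.999, D0, pmin(780, pmax(30, 1440 - TR - X)))
  }]
  dh[h == 0, d_other := D0]

  list(calendar = cal, si = si[, .(group, day, p_si)],
       stop_commute = sc[, .(group, work_wealth, day, p_stop)],
       d_other = dh[, .(group, day, d_other)],
       pandemic_day = pandemic_day, n_days = n_days, origin = origin)
}

# Weekly relocation hazards per group.
#
# Planted group effects are period-averaged relative changes of the *measured*
# net flow, so the solver inverts the measurement chain: the trailing-window
# home inference detects a week-start move `lag` days later (27 under the
# default 49-day/7-day scheme with nightly home attendance), which truncates
# what the first-3-months window can see; per-capita hazards act on the
# *current* urban pool while measured rates are normalised by the pool at the
# observation start; and the measured baseline rate itself reflects a mildly
# depleted pre-pandemic pool. Hazards are scaled so that the expected
# detected excess, per initial urban user and within the detectable part of
# the measurement window, equals the planted target exactly.
relocation_schedule <- function(world, behavior, n_urban, n_rural,
                                window_days = 49L, step_days = 7L) {
  cfg <- world$config
  n_days <- as.integer(cfg$observation_end - cfg$observation_start) + 1L
  n_weeks <- ceiling(n_days / 7)
  pandemic_day <- day_index(cfg$pandemic_date, cfg$observation_start)
  wk <- data.table(week = seq_len(n_weeks))
  wk[, start_day := (week - 1L) * 7L + 1L]
  rho_ur <- behavior$relocation_baseline_weekly[["urban_rural"]]
  rho_ru <- behavior$relocation_baseline_weekly[["rural_urban"]]
  n0 <- rho_ur - rho_ru * n_rural / max(n_urban, 1)  # baseline net rate
  W <- behavior$relocation_window_weeks
  w_start <- wk[start_day > pandemic_day, min(week)]
  post_w <- seq(w_start, min(w_start + W - 1L, n_weeks))
  shape <- 2^(-(post_w - w_start) * 7 / behavior$relocation_halflife_days)
  shape <- shape / sum(shape)
  # detection day of a move at each post week; the measurement window closes
  # W weeks after the declaration
  detect_day <- vapply(wk$start_day[post_w], function(d)
    ceiling((d + window_days / 2 - 0.5) / step_days) * step_days, numeric(1))
  detectable <- detect_day <= pandemic_day + 7 * W
  # measured baseline rate: pre-window transitions detect moves from the
  # weeks `lag` days earlier, when the pool had already lost a few movers
  lag <- ceiling((1 + window_days / 2 - 0.5) / step_days) * step_days - 1
  pre_ends <- seq(window_days + step_days,
                  max(window_days + step_days,
                      (pandemic_day %/% step_days) * step_days),
                  by = step_days)
  pre_mv_weeks <- pmax(1, (pre_ends - lag - 1) %/% 7 + 1)
  r0_det <- rho_ur * mean((1 - rho_ur)^(pre_mv_weeks - 1)) -
    rho_ru * n_rural / max(n_urban, 1)
  haz <- CJ(group = c("high", "medium", "low", "rural"), week = wk$week)
  haz[, p_ur := rho_ur]
  for (g in c("high", "medium", "low")) {
    target <- behavior$rel_relocation[[g]] / 100 * r0_det * W
    if (target > 0 && sum(shape[detectable]) > 0) {
      cg <- target / sum(shape[detectable])
      # iterate the expected pool so per-initial-user detections hit cg*shape
      K <- length(post_w)
      e <- pmin(0.9, cg * shape)
      for (it in 1:3) {
        pool <- numeric(K)
        pool[1] <- (1 - rho_ur)^(post_w[1] - 1)
        if (K > 1) for (i in 2:K)
          pool[i] <- pool[i - 1] * max(1 - rho_ur - e[i - 1], 0)
        e <- pmin(0.9, cg * shape / pmax(pool, 1e-9))
      }
      extra_haz <- e
    } else extra_haz <- rep(0, length(post_w))
    haz[group == g & week %in% post_w,
        p_ur := p_ur + extra_haz[match(week, post_w)]]
  }
  haz[, p_ur := pmin(1, pmax(0, p_ur))]
  haz[, p_ru := rho_ru]
  list(hazards = haz, weeks = wk, baseline_net_rate = n0,
       baseline_detected_rate = r0_det)
}

#' Simulate GPS ping trajectories with planted behavioural effects
#'
#' Draws, for every user-day, a routine (all-day stay-at-home; commute
#' home-work-home; home plus one fresh "other" outing) from the planted group-
#' and period-dependent probabilities, realises weekly home relocations, and
#' emits pings along the occupancy schedule: anchor pings at interval
#' transitions plus a Poisson stream inside each interval, with isotropic
#' positional jitter and lognormal accuracy. Nights (23:00-05:00 local) are
#' always spent at the current home; workday visits fall between 05:00 and
#' 23:00; "other" outing locations are drawn fresh each day within 1-5 km of
#' home so they never accrete into spurious work locations.
#'
#' @param users Output of [generate_population()].
#' @param world The `mobgap_world`.
#' @param behavior A [behavior_config()].
#' @param emission An [emission_config()].
#' @param seed Integer seed.
#' @param policy Optional policy/incidence table (from
#'   [generate_policy_incidence()]) used when `behavior$policy_effects`
#'   couples policy indices into stop-commuting propensities.
#' @return A list of class `mobgap_trajectories`: `pings` (user_id, t (POSIXct
#'   UTC), lat, lon, accuracy_m, sorted by user and time), `moves` (realised
#'   relocation ground truth), `users`, and the behaviour `schedule` lookup
#'   tables (planted truth).
#' @export
simulate_trajectories <- function(users, world, behavior, emission,
                                  seed = 1L, policy = NULL) {
  stopifnot(inherits(world, "mobgap_world"),
            inherits(behavior, "mobgap_behavior_config"),
            inherits(emission, "mobgap_emission_config"))
  set.seed(seed)
  sched <- behavior_schedule(world, behavior)
  n_days <- sched$n_days
  origin <- sched$origin
  units <- world$units

  ## -- weekly relocation realisation ---------------------------------------
  st <- copy(users)[, `:=`(cur_unit = home_unit, cur_lat = home_lat,
                           cur_lon = home_lon, cur_urban = urban_true)]
  rs <- relocation_schedule(world, behavior,
                            n_urban = sum(st$cur_urban),
                            n_rural = sum(!st$cur_urban))
  haz <- rs$hazards
  moves <- vector("list", nrow(rs$weeks))
  seg <- vector("list", nrow(rs$weeks) + 1L)
  seg_open <- copy(st[, .(user_id, day_from = 1L, unit = cur_unit,
                          lat = cur_lat, lon = cur_lon, urban = cur_urban)])
  for (w in rs$weeks$week) {
    if (w == 1L) next
    d0 <- rs$weeks$start_day[w]
    grp <- fifelse(st$cur_urban, st$group_true, "rural")
    grp[grp == "rural" & st$cur_urban] <- "low"  # rural-origin user now urban
    p <- fifelse(st$cur_urban,
                 haz[.(grp, w), p_ur, on = c("group", "week")],
                 haz[.(grp, w), p_ru, on = c("group", "week")])
    mv <- which(runif(nrow(st)) < p)
    if (!length(mv)) next
    dest <- integer(length(mv))
    for (i in seq_along(mv)) {
      u <- mv[i]
      pool <- if (st$cur_urban[u]) {
        which(units$country == st$country[u] & !units$urban)
      } else {
        which(units$country == st$country[u] & units$urban)
      }
      dest[i] <- resample(pool, 1L, prob = units$population[pool])
    }
    du <- units[dest]
    moves[[w]] <- data.table(
      user_id = st$user_id[mv], week = w, move_day = d0,
      from_unit = st$cur_unit[mv], to_unit = du$unit_id,
      from_urban = st$cur_urban[mv], to_urban = du$urban)
    # close open segments, open new ones
    closed <- seg_open[user_id %in% st$user_id[mv]]
    closed[, day_to := d0 - 1L]
    seg[[w]] <- closed
    nlat <- runif(length(mv), du$lat0, du$lat1)
    nlon <- runif(length(mv), du$lon0, du$lon1)
    st[mv, `:=`(cur_unit = du$unit_id, cur_lat = nlat, cur_lon = nlon,
                cur_urban = du$urban)]
    seg_open <- seg_open[!user_id %in% st$user_id[mv]]
    seg_open <- rbind(seg_open,
                      data.table(user_id = st$user_id[mv], day_from = d0,
                                 unit = du$unit_id, lat = nlat, lon = nlon,
                                 urban = du$urban))
  }
  seg_open[, day_to := n_days]
  segments <- rbindlist(c(seg, list(seg_open)), use.names = TRUE)
  setkey(segments, user_id, day_from)
  moves <- rbindlist(moves)
  if (nrow(moves) == 0)
    moves <- data.table(user_id = integer(), week = integer(),
                        move_day = integer(), from_unit = character(),
                        to_unit = character(), from_urban = logical(),
                        to_urban = logical())

  ## -- daily routine draws -------------------------------------------------
  ud <- CJ(user_id = users$user_id, day = seq_len(n_days))
  ud <- ud[runif(.N) < emission$p_active_day]
  ug <- users[, .(user_id, country, commuter, work_wealth_true,
                  group_b = fifelse(urban_true, group_true, "rural"))]
  ud <- ud[ug, on = "user_id", nomatch = NULL]
  ud[sched$si, p_si := i.p_si, on = c(group_b = "group", "day")]
  ud[, si := runif(.N) < p_si]
  ud[, routine := "other"]
  ud[si == TRUE, routine := "si"]
  cal <- sched$calendar
  ud[cal, is_weekday := i.is_weekday, on = "day"]
  cm <- ud[commuter == TRUE & si == FALSE & is_weekday == TRUE]
  cm[sched$stop_commute, p_stop := i.p_stop,
     on = c(group_b = "group", work_wealth_true = "work_wealth", "day")]
  cm[is.na(p_stop), p_stop := 0]
  if (!is.null(behavior$policy_effects) && !is.null(policy)) {
    pe <- as.data.table(behavior$policy_effects)
    pol <- as.data.table(policy)
    pol[, day := day_index(date, origin)]
    for (i in seq_len(nrow(pe))) {
      pv <- pol[index_name == pe$index_name[i], .(country, day, value)]
      cm[pv, pol_v := i.value, on = c("country", "day")]
      cm[group_b == pe$group[i] &
           (is.na(pe$work_wealth[i]) | work_wealth_true == pe$work_wealth[i]),
         p_stop := pmin(1, pmax(0, p_stop + pe$beta[i] * pol_v))]
      cm[, pol_v := NULL]
    }
  }
  cm[, commute_today := runif(.N) >= p_stop]
  ud[cm, commute_today := i.commute_today, on = c("user_id", "day")]
  ud[is.na(commute_today), commute_today := FALSE]
  ud[routine != "si" & commute_today == TRUE, routine := "commute"]
  ud[sched$d_other, d_other := i.d_other, on = c(group_b = "group", "day")]
  ud[routine == "other", d_other := d_other * runif(.N, 0.75, 1.25)]

  # current home coordinates per user-day (rolling join on segments)
  segs <- segments[, .(user_id, day = day_from, lat, lon)]
  setkey(segs, user_id, day)
  ud[, c("home_lat", "home_lon") :=
       segs[ud, on = c("user_id", "day"), roll = TRUE, .(x.lat, x.lon)]]
  wu <- users[, .(user_id, work_lat, work_lon)]
  ud[wu, `:=`(work_lat = i.work_lat, work_lon = i.work_lon), on = "user_id"]

  ## -- occupancy intervals -------------------------------------------------
  lv <- behavior$commute_leave_min
  rt <- behavior$commute_return_min
  tr <- behavior$transit_min
  iv_si <- ud[routine == "si",
              .(user_id, country, day, lat = home_lat, lon = home_lon,
                m0 = 0, m1 = 1440)]
  cmd <- ud[routine == "commute"]
  iv_cm <- rbindlist(list(
    cmd[, .(user_id, country, day, lat = home_lat, lon = home_lon, m0 = 0, m1 = lv)],
    cmd[, .(user_id, country, day, lat = work_lat, lon = work_lon,
            m0 = lv + tr, m1 = rt - tr)],
    cmd[, .(user_id, country, day, lat = home_lat, lon = home_lon, m0 = rt, m1 = 1440)]))
  oth <- ud[routine == "other"]
  if (nrow(oth)) {
    bear <- runif(nrow(oth), 0, 2 * pi)
    dist <- runif(nrow(oth), 1000, 5000)
    oth[, `:=`(o_lat = home_lat + dist * cos(bear) / m_per_deg_lat(),
               o_lon = home_lon + dist * sin(bear) / m_per_deg_lon(home_lat))]
  } else oth[, `:=`(o_lat = numeric(), o_lon = numeric())]
  iv_ot <- rbindlist(list(
    oth[, .(user_id, country, day, lat = home_lat, lon = home_lon,
            m0 = 0, m1 = 600 - tr)],
    oth[, .(user_id, country, day, lat = o_lat, lon = o_lon,
            m0 = 600, m1 = 600 + d_other)],
    oth[, .(user_id, country, day, lat = home_lat, lon = home_lon,
            m0 = 600 + d_other + tr, m1 = 1440)]))
  iv <- rbindlist(list(iv_si, iv_cm, iv_ot))

  ## -- merge contiguous same-place intervals across day boundaries ---------
  # (a device emits transition anchors; an unbroken overnight or multi-day
  # stay at one place is one occupancy interval, not one per calendar day)
  iv[, `:=`(am0 = (day - 1) * 1440 + m0, am1 = (day - 1) * 1440 + m1)]
  setorder(iv, user_id, am0)
  iv[, new_run := user_id != shift(user_id, fill = -1L) |
       lat != shift(lat, fill = Inf) | lon != shift(lon, fill = Inf) |
       am0 != shift(am1, fill = -1)]
  iv[, run := cumsum(new_run)]
  iv <- iv[, .(user_id = user_id[1], country = country[1], lat = lat[1],
               lon = lon[1], am0 = am0[1], am1 = am1[.N]), by = run]

  ## -- ping emission -------------------------------------------------------
  iv[, n_extra := rpois(.N, emission$pings_per_hour * (am1 - am0) / 60)]
  iv[, low_acc := runif(.N) < emission$frac_low_accuracy]
  ex_idx <- rep.int(seq_len(nrow(iv)), iv$n_extra)
  n_anch <- nrow(iv)
  pings <- data.table(
    user_id = c(iv$user_id, iv$user_id, iv$user_id[ex_idx]),
    country = c(iv$country, iv$country, iv$country[ex_idx]),
    lat = c(iv$lat, iv$lat, iv$lat[ex_idx]),
    lon = c(iv$lon, iv$lon, iv$lon[ex_idx]),
    minute = c(iv$am0 + 0.2, iv$am1 - 0.2,
               runif(length(ex_idx), iv$am0[ex_idx], iv$am1[ex_idx])),
    low_acc = c(iv$low_acc, iv$low_acc, iv$low_acc[ex_idx]))
  jm <- emission$jitter_sd_m
  pings[, `:=`(lat = lat + rnorm(.N, 0, jm / m_per_deg_lat()),
               lon = lon + rnorm(.N, 0, jm / m_per_deg_lon(lat)))]
  pings[, accuracy_m := rlnorm(.N, emission$accuracy_log_mean,
                               emission$accuracy_log_sd)]
  if (emission$frac_low_accuracy > 0)
    pings[low_acc == TRUE, accuracy_m := accuracy_m * 8]
  tz <- world$countries$tz_offset_hours[pings$country]
  origin_utc <- as.POSIXct(paste(origin, "00:00:00"), tz = "UTC")
  pings[, t := origin_utc + minute * 60 - tz * 3600]
  pings <- pings[, .(user_id, t, lat, lon, accuracy_m)]
  setkey(pings, user_id, t)

  out <- list(pings = pings, moves = moves, users = users,
              routines = ud[, .(user_id, day, routine)],
              schedule = sched, relocation = rs, seed = seed)
  class(out) <- "mobgap_trajectories"
  out
}

#' @export
print.mobgap_trajectories <- function(x, ...) {
  cat(sprintf("<mobgap_trajectories> %d users, %s pings, %d relocations\n",
              nrow(x$users), format(nrow(x$pings), big.mark = ","),
              nrow(x$moves)))
  invisible(x)
}

#' Expected and calibrated relocation planting
#'
#' `expected_relocation_excess` returns the expected cumulative excess net
#' urban-to-rural share (percent of urban users) implied by a behaviour
#' configuration and a realised population, over the planted relocation
#' window. `calibrate_relocation` rescales the group relocation effects so
#' that this expectation matches a target aggregate (keeping the group
#' ratios), making a printed aggregate net-flow figure the literal ground
#' truth of the simulation.
#'
#' @param users Output of [generate_population()].
#' @param behavior A [behavior_config()].
#' @param target_pct Target aggregate excess net share, in percent.
#' @return A percentage (`expected_relocation_excess`) or a modified
#'   behaviour config (`calibrate_relocation`).
#' @export
expected_relocation_excess <- function(users, behavior) {
  u <- as.data.table(users)[urban_true == TRUE]
  shares <- u[, .N, by = group_true][, share := N / sum(N)]
  n_urb <- nrow(u); n_rur <- nrow(as.data.table(users)) - n_urb
  rho <- behavior$relocation_baseline_weekly
  n0 <- rho[["urban_rural"]] - rho[["rural_urban"]] * n_rur / max(n_urb, 1)
  W <- behavior$relocation_window_weeks
  100 * sum(shares$share * behavior$rel_relocation[shares$group_true] / 100 *
              n0 * W)
}

#' @rdname expected_relocation_excess
#' @export
calibrate_relocation <- function(behavior, users, target_pct) {
  cur <- expected_relocation_excess(users, behavior)
  if (cur <= 0) stop("expected excess is not positive; cannot calibrate")
  behavior$rel_relocation <- behavior$rel_relocation * target_pct / cur
  behavior
}
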