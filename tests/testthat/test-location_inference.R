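# helper: build a stop-event table directly (UTC seconds on a day grid)
mk_events <- function(user, day, m0, m1, lat, lon, acc = 10) {
  epoch0 <- as.numeric(as.POSIXct("2020-01-01", tz = "UTC"))
  data.table::data.table(
    user_id = user,
    t_start = epoch0 + ((day - 1) * 1440 + m0) * 60,
    t_end = epoch0 + ((day - 1) * 1440 + m1) * 60,
    lat = lat, lon = lon, n_pings = 5L, mean_accuracy_m = acc)
}
users0 <- data.table::data.table(user_id = 1L, country = 1L)
countries0 <- data.table::data.table(country = 1L, tz_offset_hours = 0L)

test_that("eps-reachability clustering matches the transitive-closure oracle", {
  base <- c(10, 20)
  two <- function(d_m) {
    p2 <- offset_m(base[1], base[2], d_m, 0)
    mk_events(1L, c(1, 2), 600, 700, c(base[1], p2[1]), c(base[2], p2[2]))
  }
  expect_equal(nrow(cluster_stop_locations(two(10))$locations), 1L)
  expect_equal(nrow(cluster_stop_locations(two(60))$locations), 2L)
  # chain A-B-C at 20 m spacing: A and C are 40 m apart but density-reachable
  p_b <- offset_m(base[1], base[2], 20, 0)
  p_c <- offset_m(base[1], base[2], 40, 0)
  ch <- mk_events(1L, 1:3, 600, 700, c(base[1], p_b[1], p_c[1]),
                  c(base[2], p_b[2], p_c[2]))
  cl <- cluster_stop_locations(ch)
  expect_equal(nrow(cl$locations), 1L)
  # randomized agreement with the igraph closure oracle
  for (s in 1:15) {
    set.seed(s)
    n <- sample(3:40, 1)
    pos <- t(vapply(seq_len(n), function(i)
      offset_m(base[1], base[2], runif(1, 0, 200), runif(1, 0, 200)),
      numeric(2)))
    ev <- mk_events(1L, seq_len(n), 600, 700, pos[, 1], pos[, 2])
    got <- cluster_stop_locations(ev)$events$location_id
    want <- oracle_eps_components(pos[, 1], pos[, 2])
    # same partition up to relabelling
    expect_equal(length(unique(got)), length(unique(want)),
                 info = paste("seed", s))
    expect_true(all(table(got, want) %in%
                      c(0, tabulate(want))), info = paste("seed", s))
  }
})

test_that("min_samples > 1 marks sparse events as noise", {
  base <- c(10, 20)
  far <- offset_m(base[1], base[2], 500, 0)
  ev <- mk_events(1L, 1:3, 600, 700,
                  c(base[1], base[1], far[1]), c(base[2], base[2], far[2]))
  cl <- cluster_stop_locations(ev, min_samples = 2L)
  expect_equal(sum(cl$events$location_id == 0), 1L)
  expect_equal(nrow(cl$locations), 1L)
})

# a textbook commuter: home stop every night (18:00 -> 08:00), work stop 9-17
# on weekdays; runs over the full year
commuter_events <- function(n_days = 366, home = c(10, 20),
                            work_m = c(900, 1200), other = NULL) {
  w <- offset_m(home[1], home[2], work_m[1], work_m[2])
  ev <- list(
    # evening-to-morning home stay attributed via day overlap expansion
    mk_events(1L, seq_len(n_days), 1080, 1920, home[1], home[2]))
  wd <- ((3 - 1 + seq_len(n_days) - 1) %% 7) + 1  # Jan 1 2020 = Wednesday
  wdays <- which(wd <= 5)
  ev$work <- mk_events(1L, wdays, 540, 1020, w[1], w[2])
  rbindlist(ev)
}

test_that("the 49-day window classifier labels a textbook commuter", {
  ev <- commuter_events()
  cl <- cluster_stop_locations(ev)
  ed <- stop_event_days(cl$events, users0, countries0, "2020-01-01")
  pres <- data.table::data.table(user_id = 1L, day = 1:366)
  lab <- label_windows(ed, pres, 366)
  expect_equal(nrow(lab), 46L)  # weekly steps over a 366-day year
  home_loc <- cl$locations[abs(lat - 10) < 1e-6, location_id]
  expect_true(all(lab$home_location == home_loc))
  expect_true(all(!is.na(lab$work_location)))
  expect_true(all(lab$work_location != lab$home_location))
})

test_that("work labelling enforces the 20% visit-share and 1-hour dwell rules", {
  home <- c(10, 20)
  # candidate visited 9 of 49 active days (18%) with long dwell -> not work
  ev1 <- rbindlist(list(
    mk_events(1L, 1:49, 1080, 1920, home[1], home[2]),
    {
      w <- offset_m(home[1], home[2], 800, 0)
      mk_events(1L, seq(2, 42, by = 5), 540, 1020, w[1], w[2])
    }))
  cl1 <- cluster_stop_locations(ev1)
  ed1 <- stop_event_days(cl1$events, users0, countries0, "2020-01-01")
  lab1 <- label_windows(ed1, data.table::data.table(user_id = 1L, day = 1:49),
                        49)
  expect_true(all(is.na(lab1$work_location)))
  # candidate visited 30 days x 45 minutes -> fails the 1 h average dwell
  ev2 <- rbindlist(list(
    mk_events(1L, 1:49, 1080, 1920, home[1], home[2]),
    {
      w <- offset_m(home[1], home[2], 800, 0)
      wd <- ((3 - 1 + (1:49) - 1) %% 7) + 1
      mk_events(1L, which(wd <= 5)[1:30], 600, 645, w[1], w[2])
    }))
  cl2 <- cluster_stop_locations(ev2)
  ed2 <- stop_event_days(cl2$events, users0, countries0, "2020-01-01")
  lab2 <- label_windows(ed2, data.table::data.table(user_id = 1L, day = 1:49),
                        49)
  expect_true(all(is.na(lab2$work_location)))
})

test_that("sub-threshold 'other' visits never change home/work labels", {
  ev <- commuter_events(120)
  cl <- cluster_stop_locations(ev)
  ed <- stop_event_days(cl$events, users0, countries0, "2020-01-01")
  pres <- data.table::data.table(user_id = 1L, day = 1:120)
  lab0 <- label_windows(ed, pres, 120)
  # add noise visits: a fresh far-away location every 9th day, 30 min daytime
  set.seed(4)
  noise_days <- seq(3, 117, by = 9)
  noise <- rbindlist(lapply(noise_days, function(d) {
    p <- offset_m(10, 20, runif(1, 2000, 4000), runif(1, 2000, 4000))
    mk_events(1L, d, 700, 730, p[1], p[2])
  }))
  cl2 <- cluster_stop_locations(rbind(ev, noise))
  ed2 <- stop_event_days(cl2$events, users0, countries0, "2020-01-01")
  lab2 <- label_windows(ed2, pres, 120)
  # identify locations by centroid, not id, since ids can renumber
  loc0 <- cl$locations[lab0, on = c("user_id", location_id = "home_location")]
  loc2 <- cl2$locations[lab2, on = c("user_id", location_id = "home_location")]
  expect_equal(loc0$lat, loc2$lat, tolerance = 1e-9)
  w0 <- cl$locations[lab0, on = c("user_id", location_id = "work_location")]
  w2 <- cl2$locations[lab2, on = c("user_id", location_id = "work_location")]
  expect_equal(w0$lat, w2$lat, tolerance = 1e-9)
})

test_that("home histories detect planted relocations with primary home fixed pre-pandemic", {
  wc <- tiny_world(n_users = 80, seed = 13)
  w <- generate_world(wc)
  bc <- behavior_config(rel_relocation = c(high = 0, medium = 0, low = 0),
                        relocation_baseline_weekly = c(urban_rural = 0,
                                                       rural_urban = 0))
  ec <- emission_config(pings_per_hour = 0.5)
  users <- generate_population(w, bc, seed = 13)
  tr <- simulate_trajectories(users, w, bc, ec, seed = 13)
  ch <- run_chain(users, w, tr)
  # no planted churn: stable users, no relocation events
  expect_equal(nrow(ch$history$relocations), 0L)
  hh <- ch$history$home_history
  expect_true(all(hh[, data.table::uniqueN(home_unit), by = user_id]$V1 == 1))
  # high churn in April: every detected move matches a planted one, with the
  # deterministic 27-day inference lag of the weekly 49-day window scheme
  bc2 <- behavior_config(rel_relocation = c(high = 300, medium = 300, low = 300),
                         relocation_baseline_weekly = c(urban_rural = 2e-3,
                                                        rural_urban = 0))
  tr2 <- simulate_trajectories(users, w, bc2, ec, seed = 14)
  ch2 <- run_chain(users, w, tr2)
  movers <- tr2$moves[, .N, by = user_id][N == 1, user_id]
  det <- ch2$history$relocations[user_id %in% movers]
  tru <- tr2$moves[user_id %in% movers]
  m <- merge(det, tru, by = "user_id")
  expect_gt(nrow(m), 0)
  expect_true(all(m$window_end - m$move_day == 27))
  expect_equal(m$to_unit.x, m$to_unit.y)
  # primary home (wealth label) stays the pre-pandemic unit for April movers
  apr <- tru[move_day > 91 & move_day <= 121, user_id]
  if (length(apr)) {
    pr <- ch2$history$profiles[user_id %in% apr]
    u0 <- users[user_id %in% apr]
    expect_equal(pr$home_unit_primary,
                 u0$home_unit[match(pr$user_id, u0$user_id)])
  }
})

test_that("a location is never home and work in the same window", {
  ev <- commuter_events(120)
  cl <- cluster_stop_locations(ev)
  ed <- stop_event_days(cl$events, users0, countries0, "2020-01-01")
  lab <- label_windows(ed, data.table::data.table(user_id = 1L, day = 1:120),
                       120)
  expect_true(all(is.na(lab$work_location) |
                    lab$work_location != lab$home_location))
})
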