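#' Run configuration
#'
#' Bundles every stage parameter with its default: the stop-detection radius
#' (25 m) and minimum duration (5 min), the 100 m accuracy cutoff, the DBSCAN
#' eps (25 m), the 49-day/7-day labeling windows, the 20% activity and visit
#' thresholds, the 1 h work-dwell minimum, the 20/40/40 wealth split, and the
#' analysis calendar (baseline Feb 1 - Mar 15, regression from Apr 11). The
#' canonical defaults ship in `inst/config/paper_defaults.yml`; tests read
#' constants from there rather than re-hardcoding them.
#'
#' @param world A [world_config()] or list of its arguments.
#' @param behavior,emission Argument lists for [behavior_config()] /
#'   [emission_config()].
#' @param stages Named list of stage parameter overrides.
#' @param seed Integer seed for the whole run.
#' @return list of class `mobgap_run_config`.
#' @export
run_config <- function(world = list(), behavior = list(), emission = list(),
                       stages = list(), seed = 1L) {
  if (!inherits(world, "mobgap_world_config"))
    world <- do.call(world_config, c(world, list(seed = seed)))
  if (!inherits(behavior, "mobgap_behavior_config"))
    behavior <- do.call(behavior_config, behavior)
  if (!inherits(emission, "mobgap_emission_config"))
    emission <- do.call(emission_config, emission)
  defaults <- list(d_max_m = 25, t_min_s = 300, max_mean_accuracy_m = 100,
                   eps_m = 25, min_samples = 1L, window_days = 49L,
                   step_days = 7L, min_visit_share = 0.20,
                   work_min_dwell_min = 60, activity_threshold = 0.20,
                   high_pop_share = 0.20, low_pop_share = 0.40,
                   n_perm = 20L, run_null_model = FALSE, run_panel = TRUE)
  stages <- modifyList(defaults, stages)
  cfg <- list(world = world, behavior = behavior, emission = emission,
              stages = stages, seed = as.integer(seed))
  pre_ok <- world$baseline_start >= world$observation_start &&
    world$pandemic_date <= world$observation_end
  if (!pre_ok) stop("baseline window must nest inside the observation window")
  class(cfg) <- "mobgap_run_config"
  cfg
}

#' Read/write a run configuration as YAML
#'
#' The YAML round-trips losslessly: `read_run_config(write_run_config(x))`
#' reproduces `x`. Dates are serialized ISO-8601.
#'
#' @param config A `mobgap_run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  to_plain <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) {
      if (inherits(v, "Date")) format(v, "%Y-%m-%d")
      else if (is.data.frame(v)) lapply(as.list(v), identity)
      else if (is.list(v)) to_plain(v)
      else if (is.atomic(v) && !is.null(names(v))) as.list(v)
      else v
    })
  }
  yaml::write_yaml(to_plain(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  vecify <- function(v) if (is.list(v)) unlist(v) else v
  bc <- lapply(y$behavior, vecify)
  if (!is.null(bc$policy_effects)) bc$policy_effects <-
    as.data.table(lapply(y$behavior$policy_effects, unlist))
  run_config(world = y$world[setdiff(names(y$world), "seed")],
             behavior = bc,
             emission = lapply(y$emission, vecify),
             stages = lapply(y$stages, vecify),
             seed = y$seed)
}

# tiny FNV-1a hash of a deparsed object (manifest provenance)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline end to end
#'
#' Executes simulate -> stops -> locations -> wealth -> indicators
#' (-> null model) (-> panel) in dependency order, writing stage CSV outputs
#' and a JSON manifest (config hash, seed, row counts per stage) to
#' `out_dir`. Re-runs skip stages whose outputs exist unless `force = TRUE`;
#' a failing stage leaves a `.partial` marker and raises the error.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param force Recompute everything, ignoring existing outputs.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "mobgap_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  st <- config$stages
  wc <- config$world
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = list())
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!force && file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path)
    if (identical(prev$config_hash, manifest$config_hash) &&
        !file.exists(file.path(out_dir, "RUN.partial"))) {
      say("run already complete for this config hash; skipping (use force = TRUE)")
      return(invisible(list(results = NULL, manifest = prev)))
    }
  }
  partial <- file.path(out_dir, "RUN.partial")
  file.create(partial)
  res <- new.env()

  run_stage <- function(name, outputs, fun) {
    paths <- file.path(out_dir, outputs)
    t0 <- Sys.time()
    val <- fun(paths)
    manifest$stages[[name]] <<- list(
      outputs = outputs,
      rows = if (is.data.frame(val)) nrow(val) else NA,
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    say("[%s] done (%.1fs)", name, manifest$stages[[name]]$seconds)
    val
  }

  res$world <- run_stage("world", c("units.csv", "extents.geojson"), function(p) {
    w <- generate_world(wc)
    data.table::fwrite(w$units, p[1])
    write_geojson_rects(w$extents, p[2], id_col = "extent_id")
    w
  })
  res$users <- run_stage("population", "users_truth.csv", function(p) {
    u <- generate_population(res$world, config$behavior, seed = config$seed)
    data.table::fwrite(u, p[1])
    u
  })
  res$traj <- run_stage("simulate", "pings.csv", function(p) {
    tr <- simulate_trajectories(res$users, res$world, config$behavior,
                                config$emission, seed = config$seed)
    write_pings_csv(tr$pings, p[1])
    tr
  })
  res$stops <- run_stage("stops", "stop_events.csv", function(p) {
    ev <- detect_stop_events(res$traj$pings, st$d_max_m, st$t_min_s)
    ev <- filter_by_accuracy(ev, st$max_mean_accuracy_m)
    data.table::fwrite(ev, p[1])
    ev
  })
  origin <- wc$observation_start
  n_days <- as.integer(wc$observation_end - origin) + 1L
  pandemic_day <- day_index(wc$pandemic_date, origin)
  res$presence <- daily_presence(res$traj$pings, res$users,
                                 res$world$countries, origin)
  keep <- filter_active_users(
    res$presence, seq_len(n_days), seq_len(pandemic_day),
    st$activity_threshold)
  res$stops <- res$stops[user_id %in% keep]
  res$locs <- run_stage("locations", "stop_locations.csv", function(p) {
    cl <- cluster_stop_locations(res$stops, st$eps_m, st$min_samples)
    data.table::fwrite(cl$locations, p[1])
    cl
  })
  res$units <- run_stage("wealth", "units_wealth.csv", function(p) {
    wi <- compute_wealth_index(census_table(res$world))
    u <- copy(res$world$units)[wi, wealth_index := i.wealth_index,
                               on = "unit_id"]
    u <- classify_urban(u, res$world$extents)
    u <- assign_wealth_groups(u, st$high_pop_share, st$low_pop_share)
    data.table::fwrite(
      u[, .(unit_id, metro_id, population, wealth_index, wealth_group, urban)],
      p[1])
    u
  })
  res$labels <- run_stage("windows", "window_labels.csv", function(p) {
    ed <- stop_event_days(res$locs$events, res$users, res$world$countries,
                          origin)
    assign("event_days", ed, envir = res)
    lab <- label_windows(ed, res$presence[user_id %in% keep], n_days,
                         st$window_days, st$step_days, st$min_visit_share,
                         st$work_min_dwell_min)
    data.table::fwrite(lab, p[1])
    lab
  })
  res$history <- run_stage("profiles", c("profiles.csv", "relocations.csv"),
                           function(p) {
    h <- build_home_history(res$labels, res$locs$locations, res$units,
                            res$users, pandemic_day)
    data.table::fwrite(h$profiles, p[1])
    data.table::fwrite(h$relocations, p[2])
    h
  })
  base_days <- seq(day_index(wc$baseline_start, origin), pandemic_day)
  res$daily <- run_stage("daily", "daily_flags.csv", function(p) {
    d <- daily_flags(res$event_days, res$labels, res$history$profiles,
                     res$presence[user_id %in% keep], n_days)
    data.table::fwrite(d, p[1])
    d
  })
  res$series <- run_stage("indicators", "group_series.csv", function(p) {
    gs <- list(
      group_series(res$daily, res$history$profiles, res$units, origin,
                   base_days, "self_isolation", include_all = TRUE),
      group_series(res$daily, res$history$profiles, res$units, origin,
                   base_days, "non_commuting"),
      group_series(res$daily, res$history$profiles, res$units, origin,
                   base_days, "non_commuting", split_low_by_work = TRUE),
      group_series(res$daily, res$history$profiles, res$units, origin,
                   base_days, "minutes_home"))
    write_group_series_csv(gs, p[1])
    names(gs) <- c("self_isolation", "non_commuting", "non_commuting_split",
                   "minutes_home")
    gs
  })
  res$relocation_series <- run_stage("relocation", "relocation_series.csv",
                                     function(p) {
    nr <- net_relocation_series(res$history$relocations,
                                res$history$profiles, res$units,
                                pandemic_day, n_days, st$step_days,
                                st$window_days)
    data.table::fwrite(nr, p[1])
    nr
  })
  if (isTRUE(st$run_null_model)) {
    res$null <- run_stage("nullmodel", "null_model.csv", function(p) {
      nm <- null_model_reshuffle(res$daily, res$history$profiles, res$units,
                                 origin, base_days,
                                 n_perm = st$n_perm, seed = config$seed)
      data.table::fwrite(nm$summary, p[1])
      nm
    })
  }
  if (isTRUE(st$run_panel)) {
    res$policy <- run_stage("policy", "policy_incidence.csv", function(p) {
      pi_ <- generate_policy_incidence(res$world, seed = config$seed)
      data.table::fwrite(pi_$policy, p[1])
      pi_
    })
    res$panel_fits <- run_stage("panel", "panel_coefficients.csv", function(p) {
      pan <- build_panel(res$series$non_commuting, res$policy,
                         window = c(wc$regression_start, wc$observation_end))
      fits <- lapply(unique(pan$group), function(g)
        fit_group_model(pan, group = g))
      names(fits) <- unique(pan$group)
      ct <- rbindlist(lapply(fits, function(f)
        copy(f$coefficients)[, group := f$group]))
      data.table::fwrite(ct, p[1])
      fits
    })
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  file.remove(partial)
  invisible(list(results = as.list(res), manifest = manifest))
}
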