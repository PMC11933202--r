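# mobgap

Socioeconomic gaps in pandemic-era mobility, measured from raw GPS pings.

During COVID-19, how strongly people reduced their mobility depended on the
wealth of the neighbourhood they lived in. Quantifying that gap from
commercial smartphone location feeds takes a long chain of inference:
noisy, irregular pings must be turned into dwells, dwells into home and
workplace locations, homes into census-based wealth labels, and daily
behaviour into baseline-normalised indicators that can be compared across
socioeconomic groups and regressed on policy stringency. `mobgap`
implements that chain end to end for analysts working with GPS trajectory
panels, and ships a fully synthetic world generator with *planted*
behavioural effects, so every stage is testable against known ground truth
— the raw commercial feeds such studies use cannot be redistributed.

## The method

* **Stop events** — greedy sequential clustering of each user's pings: a
  cluster grows while each ping is within 25 m (Haversine) of the running
  centroid and becomes a stop event iff it spans ≥ 5 minutes; events with
  mean accuracy ≥ 100 m are dropped.
* **Stop locations** — per-user DBSCAN over event centroids (ε = 25 m,
  `min_samples = 1`), i.e. connected components of the ε-graph.
* **Home / work inference** — over trailing 49-day windows stepped weekly:
  home is the location with most nighttime-visit days (Mon–Fri 23:00–05:00,
  or any time Sat/Sun) among locations visited on ≥ 20% of active days;
  work adds a ≥ 1 h average daytime dwell requirement (Mon–Fri 05:00–23:00).
  Users must be active ≥ 20% of days overall and pre-pandemic.
* **Wealth labels** — census indicators → z-scores → first principal
  component per administrative unit; within each metro, urban units ranked
  by index are partitioned by population into high / medium / low
  (20 / 40 / 40); users inherit the label of their pre-pandemic primary
  home unit.
* **Indicators** — daily shares of users self-isolating (all stops at
  home), not commuting (commuters missing their workplace), minutes at
  home/work, and windowed net urban→rural relocation; all expressed as %
  change against the Feb 1 – Mar 15 baseline, population-weighted across
  units, with SEMs pooled over units and a wealth-label-reshuffling null
  model.
* **Policy panel** — for each group, pooled OLS across countries of the
  standardized outcome on standardized global/local case incidence and five
  policy stringency indices, `mb_ic(t) = a_i·inc_g(t) + b_i·inc_c(t) +
  Σ_n c_in·C_cn(t)`, with country fixed effects, HC2 country-clustered
  standard errors, BIC model selection and a VIF < 4 collinearity screen.

## A worked example

Simulate a small world, run the chain, and measure the self-isolation gap:

```r
library(mobgap)
library(data.table)

wc    <- world_config(n_users = 600, seed = 7)
world <- generate_world(wc)
bc    <- behavior_config()      # planted group effects (see vignette)
ec    <- emission_config()
users <- generate_population(world, bc, seed = 7)
traj  <- simulate_trajectories(users, world, bc, ec, seed = 7)

events <- filter_by_accuracy(detect_stop_events(traj$pings))
pres   <- daily_presence(traj$pings, users, world$countries, "2020-01-01")
keep   <- filter_active_users(pres, 1:366, 1:75)
locs   <- cluster_stop_locations(events[user_id %in% keep])
edays  <- stop_event_days(locs$events, users, world$countries, "2020-01-01")
labels <- label_windows(edays, pres[user_id %in% keep], 366)

wi    <- compute_wealth_index(census_table(world))
units <- copy(world$units)[wi, wealth_index := i.wealth_index, on = "unit_id"]
units <- assign_wealth_groups(classify_urban(units, world$extents))
hist  <- build_home_history(labels, locs$locations, units, users, 75)
daily <- daily_flags(edays, labels, hist$profiles, pres[user_id %in% keep], 366)

gs <- group_series(daily, hist$profiles, units, "2020-01-01", 32:75,
                   "self_isolation")
gs[day > 75, .(rel_change = mean(rel_change)), by = group]
```

```
    group rel_change
   <char>      <num>
1:   high   244.4378
2:    low   131.1543
3: medium   186.5387
```

Users in high-wealth neighbourhoods self-isolate about 244% more than
during the baseline period versus about 131% for low-wealth neighbourhoods
— at 600 users the gap (≈ 113 percentage points) is within Monte-Carlo
noise of the planted generator values (252 and 141; gap 111), which larger
cohorts recover closely. `run_pipeline(run_config(...), "out/")` performs
the same chain as one call with CSV outputs and a manifest, and
`inst/cli/mobgap.R` wraps it for the shell.

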