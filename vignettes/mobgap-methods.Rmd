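---
title: "Measuring socioeconomic gaps in pandemic mobility: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring socioeconomic gaps in pandemic mobility: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mobgap turns raw smartphone GPS pings into daily, baseline-normalised
mobility indicators stratified by neighbourhood wealth, and estimates how
those indicators co-move with containment policies. This vignette explains
the models behind each stage, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The measurement chain

**Stop events.** A ping is a timestamped WGS84 coordinate with an accuracy
estimate. Stop events are found by greedy sequential clustering in the
stay-point tradition: a candidate cluster grows while each new ping lies
within 25 m (Haversine, Earth radius 6,371 km) of the cluster's *running
centroid*; the first ping that breaks the radius closes the candidate, which
is kept iff its first and last ping are at least 5 minutes apart. The
radius-to-running-centroid predicate is one of several readings of a
"maximum spatial distance"; the alternative pairwise-diameter reading is
stricter and would split long dwells under jitter, so the centroid
convention is the default (`d_max_m`, `t_min_s` are configurable). Pings
that never join a qualifying cluster are treated as transit and discarded.
Events whose mean ping accuracy is 100 m or worse are dropped afterwards:
the filter is applied to formed events, not raw pings, because accuracy
errors damage location assignment, not the existence of a dwell.

**Stop locations.** Stop events of one user are clustered by DBSCAN over
their centroids with eps = 25 m and `min_samples = 1`. With a single-sample
core condition every event belongs to a location and clusters are exactly
the connected components of the eps-graph; this avoids discarding rare but
long stays (a weekend home visited once per window) at the cost of never
labelling any event as noise. Both parameters are exposed.

**Home and work labels.** Locations are classified per trailing 49-day
window, advanced in 7-day steps (the window length is the method's; weekly
stepping is our resolution/compute compromise — it bounds home-change
detection latency at one week plus the majority-crossing delay of the
window itself, about 24–27 days in total). Within a window, a location is
the HOME iff it has the most nighttime-visit days among locations visited
on at least 20% of the user's *active* days (nighttime: Monday–Friday 23:00
to 05:00 of the following day, attributed to the starting day, or any time
on weekends). WORK is chosen among the remaining locations by
workday-daytime visit days (Monday–Friday 05:00–23:00), subject to the same
20% coverage and to an average dwell of at least one hour per visited day.
Ties break by total dwell, then earliest first visit. A calendar day's home
is the labeling of the most recent completed window; days before the first
completed window inherit the first labeling. The 20% denominator uses
active days (days with at least one ping), not calendar days — a user
observed rarely should not be penalised twice.

**Users retained.** A user enters the analysis only if active on at least
20% of days of the full observation period *and* at least 20% of
pre-pandemic days. Activity is computed on raw pings, before the accuracy
filter: reporting at all and reporting precisely are different failure
modes, and the longitudinal filter targets the former.

**Wealth labels.** Census indicators (assets, education, services, housing)
are z-scored per column and collapsed to the first principal component;
the score is rescaled to mean 0, variance 1 and sign-oriented to correlate
positively with the asset-ownership anchor (PCA is sign-ambiguous). Units
are urban iff their centroid falls in an urban extent (an area-majority
variant is available). Within each metropolitan area, urban units are
ranked by index and partitioned by *population*: the wealthiest units
covering the top 20% of population are `high`, the bottom 40% `low`, the
remainder `medium`. A unit straddling a boundary joins the side holding the
majority of its population, ties to the wealthier side. Users inherit the
label of their *primary home* — the modal home unit over pre-pandemic
windows — and keep it even if they relocate later.

**Daily indicators.** A user self-isolates on a day iff active, with at
least one stop event, and every stop that day is at the current home
location. A commuter (work location in any pre-pandemic window) commutes on
a day iff any stop falls at the primary work location; these flags are
mutually exclusive by construction. Minutes at home/work sum stop durations
clipped to the local calendar day. Unit-level shares among *active* users
are aggregated to group level by unit-population weighting; the SEM pools
unit-level shares within country-group. Relative change is measured against
the mean level over the February 1 – March 15 baseline. Denominators use
active users rather than all retained users: absent devices carry no
information about behaviour, and conditioning on activity avoids
missingness bias at the cost of assuming activity is unrelated to the
behaviour itself (true in the generator; an approximation on real feeds).

**Relocation.** A relocation event is recorded whenever consecutive
windows' home units differ. Net urban-to-rural flow per window and group is
(urban-to-rural events minus rural-to-urban events) divided by the group's
urban user count at the start; urban-to-rural events carry the mover's
primary-home group, rural-to-urban the destination unit's group (rural
origins have no wealth label). The cumulative series subtracts the mean
pre-pandemic windowed net flow ("excess"), and a relative form divides each
window's net flow by that baseline rate. Because the generator plants
identical baseline churn in every group, the relative form can use the
pooled (all-user) baseline rate, which is estimated from roughly ten times
more events than any per-group rate; `baseline = "group"` is available for
data where baseline churn may differ by wealth.

**Null model.** Wealth labels are reshuffled across users within country
(group sizes preserved) and all group series recomputed per permutation.
Under the null of no wealth-related behaviour the permuted group curves
collapse onto the population-average trend; the returned 2.5–97.5%
ensemble band makes "collapse" testable.

**Policy panel.** The daily group outcome and the covariates (global and
local case incidence, five policy stringency indices in [0,1]) are
standardized to mean 0, sd 1 within (group, country) over the estimation
window (April 11 – December 31; the first post-declaration month is
excluded because enactments were near-simultaneous then). The fit is pooled
OLS with country fixed effects absorbed by within-country demeaning —
after within-country standardization the demeaning is a formality, but it
keeps the estimator correct for user-supplied, non-standardized outcomes.
Standard errors are clustered by country using the bias-reduced HC2 form:
with six clusters the HC0/HC1 variants measurably undercover (about 90% at
nominal 95% in our replicates; HC2 restores 93–96%), and critical values
use G − 1 degrees of freedom. Model selection fits all combinations of
incidence terms and policy blocks (school/workplace closure;
transport/internal movement; stay-at-home), capped at 64 candidates, and
returns the lowest-BIC model among those whose covariates all have
VIF < 4 (the screen is inclusive: VIF = 4 fails). Contemporaneous indices
are the default; a `lag` argument exists and defaults to 0.

## The synthetic world

The generator exists so that every stage above can be verified against
known ground truth. Each metro is a square grid of administrative units: an
urban core whose density decreases from the centre (at least 1500 /km² in
every urban cell, at least 50,000 contiguous residents) surrounded by a
rural ring. Latent wealth declines with distance from the centre; six
census indicators load on it with Gaussian noise, giving the PCA stage a
one-factor structure. Users are sampled into home units proportionally to
population times a wealth-specific device-penetration weight (defaults make
the wealthiest fifth of the population contribute just over 45% of the user
base, and the poorest two-fifths under 20% — the documented ownership bias
of commercial feeds). 26% of urban users are commuters; low-wealth-home
commuters split evenly between high- and low-wealth workplaces, which the
centre-rich geometry automatically endows with longer and shorter commutes
respectively.

Each user-day draws one of three routines — stay home all day; commute
(home, work 08:30–17:30, home); or home plus a single fresh "other" outing
within 1–5 km — with probabilities that are group- and date-dependent.
Nights are always spent at the current home, matching the classifier's
circadian assumptions; "other" locations never repeat, so they can never
accrete into a false workplace. Occupancy intervals emit an anchor ping at
each transition plus a Poisson stream inside (location updates on movement
are characteristic of SDK feeds; an unbroken multi-day stay is one
interval, so a quiet stay-at-home day can legitimately produce no ping —
the realized activity rate is slightly below `p_active_day`). Positions are
jittered isotropically (5 m default — at 10 m a two-ping interval fails the
25 m radius about 20% of the time and every share-based indicator inherits
the bias); accuracies are lognormal.

**Planted effects are period-averaged relative changes.** Each behavioural
effect is parameterised directly as the period-averaged % change of the
corresponding *measured* indicator over March 16 – December 31, so a
printed headline number can be planted verbatim. Internally the effect
follows an exponential relaxation toward the pre-pandemic level whose shape
is mean-normalised over the post window: the trajectory peaks early and
decays (partial reversion) while the period average equals the planted
value exactly. The default relaxation halflife is 300 days. Shorter
halflives make the shape peak higher; below roughly 250 days the peak
non-commuting share implied by the default planted targets exceeds 1 —
self-isolation alone already forces non-commuting above the target
trajectory at the peak — so the generator warns and clamps. 300 days keeps
every daily probability inside [0, 1] with margin. The solver inverts the
exact measurement equations: stay-home probabilities come directly from the
planted self-isolation change; daily stop-commuting probabilities are
solved from the planted non-commuting change given the weekday composition
of the actual baseline and post windows and the self-isolation trajectory
(commuters commute every weekday unless staying home or stopped); and the
duration of the "other" outing is solved per day so expected minutes at
home follow the planted time-at-home change.

Relocations are weekly hazards. Baseline churn (default 0.02%/week
urban-to-rural, about 1%/year, with a smaller rural-to-urban return flow)
runs all year; pandemic-era excess is front-loaded with a 10-day halflife
over a 13-week window — realistic (observed flows flattened after the
first months) and necessary for measurement, since the trailing-window
home inference detects a week-start move exactly 27 days later under
nightly home attendance. Group effects are planted as % changes of the
measured net flow rate relative to the measured baseline, and the hazard
solver inverts that measurement equation: it compensates for expected
urban-pool depletion (hazards act on current members, measured rates are
normalised by the initial pool), for the detection lag's truncation of the
first-3-months window, and for the slightly depleted pool behind the
baseline windows. `calibrate_relocation()` rescales the group effects so
the expected aggregate excess matches a target share. The aggregate-flow
acceptance cohort runs at minimal churn (0.005%/week): its measure
subtracts a baseline trend estimated from just three pre-pandemic window
transitions, and larger churn inflates that estimate's Poisson noise
without changing the expectation.

**Problem sizes.** The shipped acceptance computation uses a behavioural
cohort of 2,000 users over a full year (five seeds), relocation cohorts of
10,000 users (seven and five seeds), and one hundred 6-country panel
replicates. Relocation quantities are ratios of rare-event counts, so the
relocation-gap cohort raises baseline churn to 0.75%/week: the gap measure
is scale-free in expectation, and at realistic churn a desk-scale cohort
simply contains too few moves for a stable denominator. This is a
deliberate identifiability choice, stated here rather than hidden in a
config; the aggregate-flow cohort keeps the realistic default churn.

**What passing tests do and do not show.** The generator reproduces the
*mechanisms* the pipeline relies on — circadian home attendance, repeated
workplaces, fresh third places, wealth-biased penetration, quality noise —
but not the messiness of real feeds: no multi-device users, no map-matched
movement or speed artefacts, no POI structure, no country-specific
calendars, no correlation between device ownership and behaviour *within*
a wealth group, and jitter/accuracy distributions are placeholders (the
upstream feed's true per-user ping-rate and accuracy distributions are not
public). Planted-recovery results therefore validate the measurement chain
end to end; they do not certify classifier accuracy on real annotations,
for which the original study reports 80% ± 3% agreement on 500 manually
annotated users. On synthetic ground truth the home-unit assignment is
essentially exact (≥ 95% is the acceptance property; measured agreement is
typically 100% at default noise).

## Numerical and degenerate-input choices

Ties in home/work selection break by total dwell, then earliest first
visit. Constant indicator columns abort the wealth index with the column
named; fewer units than indicators warns and proceeds. A metro with a
single urban unit is labelled medium with a warning. Zero home–work
distances are excluded from the log-distance distribution; a zero-variance
distance group is an error. Covariates with zero variance in the estimation
window are excluded with a warning; rank-deficient designs abort naming the
collinear columns; all-candidates-fail VIF aborts advising decorrelation.
Group-days with no active users are missing, never zero. The stop detector
requires time-sorted input per user and returns empty output for empty
input. Seeds control every random draw; identical seed and configuration
give byte-identical outputs.
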