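#' Asset-based wealth index from census indicators
#'
#' Aggregates per-unit census indicator columns into a one-dimensional wealth
#' index: each indicator is z-scored across units and the index is the score
#' on the first principal component, rescaled to mean 0 and unit variance.
#' PCA is sign-ambiguous, so the index is oriented to correlate positively
#' with a designated anchor indicator (asset ownership by default).
#'
#' @param census A data.frame/data.table with one row per administrative unit,
#'   a `unit_id` column and at least two numeric indicator columns.
#' @param indicators Character vector naming the indicator columns; defaults to
#'   every numeric column except `unit_id`, `metro_id` and `population`.
#' @param anchor Name of the anchor indicator used to fix the sign; defaults to
#'   the first indicator.
#' @return A data.table with `unit_id` and `wealth_index`.
#' @export
compute_wealth_index <- function(census, indicators = NULL, anchor = NULL) {
  census <- as.data.table(census)
  if (is.null(indicators)) {
    skip <- c("unit_id", "metro_id", "population")
    indicators <- setdiff(names(census)[vapply(census, is.numeric, TRUE)], skip)
  }
  if (nrow(census) < 2) stop("need at least 2 units")
  if (length(indicators) < 2) stop("need at least 2 indicator columns")
  X <- as.matrix(census[, indicators, with = FALSE])
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant indicator column(s): ",
         paste(indicators[sds == 0], collapse = ", "))
  if (nrow(X) < ncol(X))
    warning("fewer units than indicators; PCA is rank-deficient but proceeds")
  Z <- scale(X)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  idx <- pc$x[, 1]
  idx <- (idx - mean(idx)) / sd(idx)
  anchor <- anchor %||% indicators[1]
  if (cor(idx, X[, anchor]) < 0) idx <- -idx
  data.table(unit_id = census$unit_id, wealth_index = idx)
}

#' Classify administrative units as urban or rural
#'
#' A unit is urban iff its centroid falls inside any urban-extent polygon
#' (`rule = "centroid"`, the default). `rule = "area"` instead requires the
#' majority of the unit's area to overlap an extent, evaluated by regular
#' point sampling inside the unit polygon (a documented approximation).
#'
#' @param units data.table with `unit_id`, `centroid_lat`, `centroid_lon` and,
#'   for the area rule, rectangle bounds `lat0/lat1/lon0/lon1`.
#' @param extents Either a data.table of rectangles (`lat0/lat1/lon0/lon1`) or
#'   a list of closed polygon rings (lon/lat matrices).
#' @param rule "centroid" or "area".
#' @return `units` with a logical `urban` column (replaced if present).
#' @export
classify_urban <- function(units, extents, rule = c("centroid", "area")) {
  rule <- match.arg(rule)
  units <- copy(as.data.table(units))
  polys <- extents_as_polygons(extents)
  bad <- !is.finite(units$centroid_lat) | !is.finite(units$centroid_lon)
  if (any(bad))
    stop("invalid geometry for unit(s): ",
         paste(units$unit_id[bad], collapse = ", "))
  if (rule == "centroid") {
    pts <- cbind(units$centroid_lon, units$centroid_lat)
    urban <- rep(FALSE, nrow(units))
    for (p in polys) urban <- urban | mgcv::in.out(p, pts)
    units[, urban := urban]
  } else {
    gx <- seq(0.05, 0.95, length.out = 8)
    urban <- vapply(seq_len(nrow(units)), function(i) {
      u <- units[i]
      pts <- as.matrix(expand.grid(
        lon = u$lon0 + gx * (u$lon1 - u$lon0),
        lat = u$lat0 + gx * (u$lat1 - u$lat0)))
      inside <- rep(FALSE, nrow(pts))
      for (p in polys) inside <- inside | mgcv::in.out(p, pts)
      mean(inside) > 0.5
    }, TRUE)
    units[, urban := urban]
  }
  units[]
}

extents_as_polygons <- function(extents) {
  if (is.list(extents) && !is.data.frame(extents) &&
      all(vapply(extents, is.matrix, TRUE))) return(extents)
  ex <- as.data.table(extents)
  lapply(seq_len(nrow(ex)), function(i)
    rect_polygon(ex$lat0[i], ex$lat1[i], ex$lon0[i], ex$lon1[i]))
}

#' Population-weighted wealth-group labels per metropolitan area
#'
#' Within each metro, urban units are ranked by wealth index (descending) and
#' population is accumulated: the wealthiest units covering the top
#' `high_pop_share` of the metro's urban population are labelled `high`, the
#' poorest units covering the bottom `low_pop_share` are `low`, and the
#' remainder `medium`. A unit straddling a boundary is assigned to the side
#' holding the majority of its population (ties go to the wealthier side).
#'
#' @param units data.table with `unit_id`, `metro_id`, `population`,
#'   `wealth_index` and logical `urban`. Only urban units in a metro are
#'   labelled; others get `NA`.
#' @param high_pop_share,low_pop_share Population shares of the high and low
#'   groups (defaults 0.20 and 0.40; their sum must be <= 1).
#' @return `units` with a `wealth_group` factor column (high/medium/low).
#' @export
assign_wealth_groups <- function(units, high_pop_share = 0.20,
                                 low_pop_share = 0.40) {
  if (high_pop_share + low_pop_share > 1 ||
      high_pop_share <= 0 || low_pop_share <= 0)
    stop("invalid group shares")
  units <- copy(as.data.table(units))
  if (!"urban" %in% names(units)) stop("units need an 'urban' column")
  units[, wealth_group := NA_character_]
  grouped <- units[urban == TRUE & !is.na(metro_id)]
  if (nrow(grouped) == 0) return(units[])
  if (anyNA(grouped$wealth_index) || anyNA(grouped$population))
    stop("urban units must have wealth_index and population")
  lab <- grouped[, assign_groups_metro(.SD, high_pop_share, low_pop_share),
                 by = metro_id]
  units[lab, wealth_group := i.group, on = "unit_id"]
  units[, wealth_group := factor(wealth_group, c("high", "medium", "low"))]
  units[]
}

# cumulative-population partition of one metro's urban units
assign_groups_metro <- function(sd, high_share, low_share) {
  if (nrow(sd) == 1) {
    warning("metro with a single urban unit labelled 'medium'")
    return(data.table(unit_id = sd$unit_id, group = "medium"))
  }
  o <- order(-sd$wealth_index)
  pop <- sd$population[o]
  total <- sum(pop)
  ca <- cumsum(pop)
  cb <- ca - pop
  b1 <- high_share * total
  b2 <- (1 - low_share) * total
  seg <- cbind(high = pmax(0, pmin(ca, b1) - cb),
               medium = pmax(0, pmin(ca, b2) - pmax(cb, b1)),
               low = pmax(0, ca - pmax(cb, b2)))
  # majority of the unit's population; ties resolved toward the wealthier side
  pick <- apply(seg, 1, function(s) names(s)[which.max(s)])
  data.table(unit_id = sd$unit_id[o], group = pick)
}
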