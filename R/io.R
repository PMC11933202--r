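#' Read and write ping tables
#'
#' Pings are exchanged as delimited text with columns
#' `user_id,timestamp_iso8601,lat,lon,accuracy_m` (UTC timestamps).
#'
#' @param pings Ping table.
#' @param path File path.
#' @return `read_pings_csv` returns a keyed data.table with POSIXct `t`.
#' @export
write_pings_csv <- function(pings, path) {
  p <- as.data.table(pings)
  out <- data.table(user_id = p$user_id,
                    timestamp_iso8601 = format(p$t, "%Y-%m-%dT%H:%M:%OS2Z",
                                               tz = "UTC"),
                    lat = p$lat, lon = p$lon, accuracy_m = p$accuracy_m)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_pings_csv
#' @export
write_pings_parquet <- function(pings, path) {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("the columnar binary variant requires the 'arrow' package")
  arrow::write_parquet(as.data.table(pings), path)
  invisible(path)
}

#' @rdname write_pings_csv
#' @export
read_pings_csv <- function(path) {
  p <- data.table::fread(path)
  p[, t := as.POSIXct(timestamp_iso8601, tz = "UTC",
                      format = "%Y-%m-%dT%H:%M:%OSZ")]
  p <- p[, .(user_id, t, lat, lon, accuracy_m)]
  setkey(p, user_id, t)
  p[]
}

#' Write polygons as GeoJSON (WGS84)
#'
#' Writes rectangle-bounded features (units or urban extents) as a GeoJSON
#' FeatureCollection; `read_geojson_polygons` reads any polygon
#' FeatureCollection back as a list of closed lon/lat rings with a properties
#' table.
#'
#' @param dt data.table with `lat0/lat1/lon0/lon1` bounds and property
#'   columns.
#' @param path File path.
#' @param id_col Name of the feature id column.
#' @export
write_geojson_rects <- function(dt, path, id_col = "unit_id") {
  dt <- as.data.table(dt)
  props <- setdiff(names(dt), c("lat0", "lat1", "lon0", "lon1"))
  feats <- lapply(seq_len(nrow(dt)), function(i) {
    ring <- rect_polygon(dt$lat0[i], dt$lat1[i], dt$lon0[i], dt$lon1[i])
    list(type = "Feature",
         properties = as.list(dt[i, props, with = FALSE]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) unname(ring[k, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson_rects
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  rings <- lapply(gj$features, function(f) {
    cc <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(cc, function(pt) c(pt[[1]], pt[[2]])))
    colnames(m) <- c("lon", "lat")
    m
  })
  props <- rbindlist(lapply(gj$features, function(f) as.data.table(f$properties)),
                     fill = TRUE)
  list(polygons = rings, properties = props)
}

#' Write a tidy group-series CSV
#'
#' Long format `country,group,date,indicator,level,rel_change,sem`.
#'
#' @param series A `mobgap_group_series` (or list of them).
#' @param path File path.
#' @export
write_group_series_csv <- function(series, path) {
  if (inherits(series, "data.frame")) series <- list(series)
  rows <- lapply(series, function(s) {
    ind <- attr(s, "indicator") %||% "indicator"
    as.data.table(s)[, .(country, group, date, indicator = ind, level,
                         rel_change, sem)]
  })
  data.table::fwrite(rbindlist(rows), path)
  invisible(path)
}

#' Read an OxCGRT-style long policy CSV
#'
#' Expects columns `country,date,index_name,value` with indices in [0, 1].
#'
#' @param path File path.
#' @export
read_policy_csv <- function(path) {
  p <- data.table::fread(path)
  stopifnot(all(c("country", "date", "index_name", "value") %in% names(p)))
  p[, date := as_date(date)]
  p[]
}
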