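# File interfaces. Roads and footprints travel as GeoJSON FeatureCollections
# (coordinates already in a projected planar CRS, meters); wind as CSV
# `timestamp,u,v`; tabular outputs as CSV. JSON handling is jsonlite's.

#' Read a road layer from GeoJSON
#'
#' Expects LineString features with an identifier property (`road_id`, falling
#' back to `id`) and AADT properties named `aadt_<year>`. Coordinates must be
#' planar meters (re-project real data before use).
#'
#' @param path GeoJSON file.
#' @return A `wm_roads` table (see [roads_table()]).
#' @export
read_roads_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  ids <- character(0); polys <- list(); aadts <- list()
  for (f in feats) {
    if (!identical(f$geometry$type, "LineString")) next
    props <- f$properties
    id <- props$road_id
    if (is.null(id)) id <- props$id
    if (is.null(id)) id <- sprintf("road%04d", length(ids) + 1L)
    coords <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    akeys <- grep("^aadt_[0-9]{4}$", names(props), value = TRUE)
    if (length(akeys) == 0) stop(sprintf("road '%s' has no aadt_<year> property", id))
    aadt <- stats::setNames(as.numeric(unlist(props[akeys])),
                            sub("^aadt_", "", akeys))
    ids <- c(ids, as.character(id))
    polys <- c(polys, list(coords))
    aadts <- c(aadts, list(aadt))
  }
  roads_table(ids, polys, aadts)
}

#' Write a road layer to GeoJSON
#'
#' @param roads A `wm_roads` table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_roads_geojson <- function(roads, path) {
  feats <- lapply(seq_len(nrow(roads)), function(i) {
    aadt <- roads$aadt_by_year[[i]]
    props <- c(list(road_id = roads$road_id[i]),
               stats::setNames(as.list(unname(aadt)),
                               paste0("aadt_", names(aadt))))
    list(type = "Feature", properties = props,
         geometry = list(type = "LineString",
                         coordinates = .coord_list(roads$polyline[[i]])))
  })
  .write_fc(feats, path)
}

#' Read building/tree footprints from GeoJSON
#'
#' Polygon features with a `kind` property (`building` or `tree`); only the
#' outer ring is used.
#'
#' @param path GeoJSON file.
#' @return A list of footprints, each `list(footprint_id, kind, polygon)`
#'   where `polygon` is a two-column vertex matrix.
#' @export
read_footprints_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "Polygon")) next
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    kind <- f$properties$kind
    if (is.null(kind)) kind <- "building"
    id <- f$properties$footprint_id
    if (is.null(id)) id <- sprintf("fp%05d", length(out) + 1L)
    out[[length(out) + 1L]] <- list(footprint_id = as.character(id),
                                    kind = kind, polygon = ring)
  }
  out
}

#' Write footprints to GeoJSON
#'
#' @param footprints List of footprints (`footprint_id`, `kind`, `polygon`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_footprints_geojson <- function(footprints, path) {
  feats <- lapply(footprints, function(fp) {
    ring <- as.matrix(fp$polygon)
    if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(footprint_id = fp$footprint_id, kind = fp$kind),
         geometry = list(type = "Polygon",
                         coordinates = list(.coord_list(ring))))
  })
  .write_fc(feats, path)
}

#' Export road segments as GeoJSON
#'
#' @param segments Segment table from [segment_roads()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segments_geojson <- function(segments, path) {
  feats <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    list(type = "Feature",
         properties = list(segment_id = s$segment_id,
                           parent_road_id = s$road_id,
                           length = s$length),
         geometry = list(type = "LineString",
                         coordinates = list(c(s$x0, s$y0), c(s$x1, s$y1))))
  })
  .write_fc(feats, path)
}

.coord_list <- function(m) lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))

.write_fc <- function(features, path) {
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an hourly wind series from CSV
#'
#' Columns `timestamp` (ISO 8601, UTC, hourly), `u`, `v` (m/s, eastward and
#' northward air-motion components).
#'
#' @param path CSV file.
#' @return A `data.frame` with `time` (POSIXct UTC), `u`, `v`.
#' @export
read_wind_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "u", "v") %in% names(d)))
  data.frame(time = as.POSIXct(d$timestamp, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                              "%Y-%m-%dT%H:%M:%OS",
                                              "%Y-%m-%d %H:%M:%OS",
                                              "%Y-%m-%d %H:%M",
                                              "%Y-%m-%d")),
             u = as.numeric(d$u), v = as.numeric(d$v))
}

#' Write an hourly wind series to CSV
#'
#' @param wind Data frame with `time`, `u`, `v`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_wind_csv <- function(wind, path) {
  utils::write.csv(
    data.frame(timestamp = format(wind$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               u = wind$u, v = wind$v),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
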