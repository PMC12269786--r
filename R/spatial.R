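# Geodesic distances, the 1 km aggregation rule, and habitat attributes
# (depth, distance to coast, slope with classes) from gridded bathymetry.

validate_latlon <- function(lat, lon) {
  if (!is.numeric(lat) || !is.numeric(lon) || anyNA(lat) || anyNA(lon) ||
      any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("coordinates must satisfy lat in [-90, 90], lon in [-180, 180]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6,371,000 m, vectorised over
#' point pairs.
#'
#' @param lat1,lon1,lat2,lon2 WGS84 decimal degrees.
#' @return Distance(s) in metres.
#' @export
haversine <- function(lat1, lon1, lat2, lon2) {
  validate_latlon(c(lat1, lat2), c(lon1, lon2))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = EARTH_RADIUS_M)
}

#' Cluster sightings into aggregations (the 1 km rule)
#'
#' An aggregation is a set of sperm whales observed within 1 km of each
#' other on one survey day. "Within 1 km of each other" is interpreted as
#' single-linkage connected components (chaining allowed), matching the
#' field practice of merging nearby GPS points into one aggregation;
#' complete linkage is available as an option. Clustering is strictly
#' per-day: sightings on different dates never merge.
#'
#' @param sightings Data frame with `lat`, `lon` and (optionally) `date`
#'   columns. A missing `date` treats all rows as one survey day.
#' @param radius_m Linkage radius in metres (inclusive).
#' @param linkage `"single"` (default) or `"complete"`.
#' @return `sightings` with an added `aggregation_id` column (unique across
#'   days, formed as `date/cluster`).
#' @export
cluster_aggregations <- function(sightings, radius_m = 1000,
                                 linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(is.data.frame(sightings), all(c("lat", "lon") %in% names(sightings)))
  if (!nrow(sightings)) {
    sightings$aggregation_id <- character(0)
    return(sightings)
  }
  validate_latlon(sightings$lat, sightings$lon)
  date <- if ("date" %in% names(sightings)) as.character(sightings$date)
          else rep("all", nrow(sightings))
  out_id <- character(nrow(sightings))
  for (d in unique(date)) {
    i <- which(date == d)
    if (length(i) == 1L) {
      out_id[i] <- paste0(d, "/1")
      next
    }
    pts <- cbind(sightings$lon[i], sightings$lat[i])
    dm <- geosphere::distm(pts, fun = function(a, b)
      geosphere::distHaversine(a, b, r = EARTH_RADIUS_M))
    hc <- stats::hclust(stats::as.dist(dm), method = linkage)
    cl <- stats::cutree(hc, h = radius_m)
    out_id[i] <- paste0(d, "/", cl)
  }
  sightings$aggregation_id <- out_id
  sightings
}

grid_index <- function(grid, lat, lon) {
  dl <- grid$lat[2] - grid$lat[1]
  dn <- grid$lon[2] - grid$lon[1]
  list(r = (lat - grid$lat[1]) / dl + 1, c = (lon - grid$lon[1]) / dn + 1)
}

#' Depth at a point
#'
#' Bilinear interpolation of the four surrounding grid cells; cells flagged
#' as land (`NA`) degrade the estimate to the nearest non-missing neighbour.
#' A point whose four neighbours are all land, or which falls outside the
#' grid, is an error.
#'
#' @param grid A [bathy_grid()].
#' @param lat,lon Query point, WGS84 decimal degrees.
#' @return Depth in metres (positive down).
#' @export
depth_at <- function(grid, lat, lon) {
  stopifnot(inherits(grid, "bathy_grid"))
  validate_latlon(lat, lon)
  ix <- grid_index(grid, lat, lon)
  nr <- nrow(grid$depths); nc <- ncol(grid$depths)
  if (ix$r < 1 || ix$r > nr || ix$c < 1 || ix$c > nc) {
    stop(sprintf("point (%.5f, %.5f) is outside the bathymetry grid extent", lat, lon),
         call. = FALSE)
  }
  r0 <- floor(ix$r); c0 <- floor(ix$c)
  r1 <- min(r0 + 1, nr); c1 <- min(c0 + 1, nc)
  fr <- ix$r - r0; fc <- ix$c - c0
  v <- c(grid$depths[r0, c0], grid$depths[r0, c1],
         grid$depths[r1, c0], grid$depths[r1, c1])
  w <- c((1 - fr) * (1 - fc), (1 - fr) * fc, fr * (1 - fc), fr * fc)
  if (anyNA(v)) {
    if (all(is.na(v))) {
      stop(sprintf("point (%.5f, %.5f) is on land", lat, lon), call. = FALSE)
    }
    # nearest non-missing of the four neighbours
    dist2 <- c((ix$r - r0)^2 + (ix$c - c0)^2, (ix$r - r0)^2 + (ix$c - c1)^2,
               (ix$r - r1)^2 + (ix$c - c0)^2, (ix$r - r1)^2 + (ix$c - c1)^2)
    ok <- which(!is.na(v))
    return(v[ok[which.min(dist2[ok])]])
  }
  sum(w * v)
}

#' Slope class from a percent gradient
#'
#' Light below 10 percent, medium in \[10, 20), steep at and above 20.
#'
#' @param slope_pct Slope(s) as percent rise over run; `NA` gives
#'   `"undefined"`.
#' @return Character class vector.
#' @export
slope_class <- function(slope_pct) {
  ifelse(is.na(slope_pct), "undefined",
         ifelse(slope_pct < 10, "light",
                ifelse(slope_pct < 20, "medium", "steep")))
}

#' Seabed slope at a point
#'
#' Percent slope over a ~500 m window around the point: central differences
#' of depth over +/- `window_m / 2` east-west and north-south give the
#' gradient, whose magnitude (unsigned, as the survey protocol reports) is
#' returned. Shelf rule: when the two opposite half-window directional
#' slopes along either axis both exceed 5 percent with opposite signs, the
#' point sits on a ridge or plateau edge where no single slope is defined,
#' and the result is (`NA`, `"undefined"`).
#'
#' @param grid A [bathy_grid()].
#' @param lat,lon Query point.
#' @param window_m Window diameter, metres.
#' @return List with `slope_pct` and `slope_class`.
#' @export
slope_at <- function(grid, lat, lon, window_m = 500) {
  stopifnot(inherits(grid, "bathy_grid"))
  h <- window_m / 2
  dlat <- h / M_PER_DEG_LAT
  dlon <- h / m_per_deg_lon(lat)
  d0 <- depth_at(grid, lat, lon)
  dN <- depth_at(grid, lat + dlat, lon); dS <- depth_at(grid, lat - dlat, lon)
  dE <- depth_at(grid, lat, lon + dlon); dW <- depth_at(grid, lat, lon - dlon)
  half <- list(c((dE - d0) / h, (d0 - dW) / h), c((dN - d0) / h, (d0 - dS) / h))
  for (hs in half) {
    s <- 100 * hs
    if (all(abs(s) > 5) && prod(sign(s)) < 0) {
      return(list(slope_pct = NA_real_, slope_class = "undefined"))
    }
  }
  sx <- (dE - dW) / window_m
  sy <- (dN - dS) / window_m
  pct <- 100 * sqrt(sx^2 + sy^2)
  list(slope_pct = pct, slope_class = slope_class(pct))
}

#' Distance from a point to the coastline
#'
#' Minimum great-circle distance from the point to the coastline polyline.
#' Segments are densified to at most `step_m` between vertices before the
#' vertex sweep, so the result is accurate to better than the survey's
#' 100 m requirement.
#'
#' @param lat,lon Query point.
#' @param coastline Data frame of polyline vertices (`lat`, `lon`), at least
#'   one row.
#' @param step_m Densification step, metres.
#' @return Distance in metres.
#' @export
distance_to_coast <- function(lat, lon, coastline, step_m = 50) {
  if (is.null(coastline) || !nrow(coastline)) {
    stop("`coastline` must contain at least one vertex", call. = FALSE)
  }
  validate_latlon(lat, lon)
  validate_latlon(coastline$lat, coastline$lon)
  dense <- densify_polyline(coastline, step_m)
  min(geosphere::distHaversine(cbind(lon, lat), cbind(dense$lon, dense$lat),
                               r = EARTH_RADIUS_M))
}

densify_polyline <- function(poly, step_m) {
  n <- nrow(poly)
  if (n == 1L) return(poly)
  out_lat <- list(); out_lon <- list()
  for (i in seq_len(n - 1L)) {
    seg_len <- haversine(poly$lat[i], poly$lon[i], poly$lat[i + 1L], poly$lon[i + 1L])
    k <- max(1L, ceiling(seg_len / step_m))
    f <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out_lat[[i]] <- poly$lat[i] + f * (poly$lat[i + 1L] - poly$lat[i])
    out_lon[[i]] <- poly$lon[i] + f * (poly$lon[i + 1L] - poly$lon[i])
  }
  data.frame(lat = c(unlist(out_lat), poly$lat[n]),
             lon = c(unlist(out_lon), poly$lon[n]))
}

#' Habitat attributes at a point
#'
#' Convenience wrapper returning depth, distance to coast, slope and slope
#' class at one GPS point.
#'
#' @param grid A [bathy_grid()] or `NULL`.
#' @param coastline Coastline polyline data frame or `NULL`.
#' @param lat,lon Query point.
#' @param window_m Slope window (metres).
#' @return Data frame row: `depth_m`, `dist_coast_m`, `slope_pct`,
#'   `slope_class` (fields are `NA` where the corresponding input is `NULL`
#'   or the slope is undefined).
#' @export
habitat_point <- function(grid, coastline, lat, lon, window_m = 500) {
  depth <- if (!is.null(grid)) depth_at(grid, lat, lon) else NA_real_
  dc <- if (!is.null(coastline)) distance_to_coast(lat, lon, coastline) else NA_real_
  sl <- if (!is.null(grid)) {
    tryCatch(slope_at(grid, lat, lon, window_m),
             error = function(e) list(slope_pct = NA_real_, slope_class = "undefined"))
  } else list(slope_pct = NA_real_, slope_class = "undefined")
  data.frame(depth_m = depth, dist_coast_m = dc,
             slope_pct = sl$slope_pct, slope_class = sl$slope_class,
             stringsAsFactors = FALSE)
}

# --- simple geospatial file formats -----------------------------------------

#' Read/write bathymetry as ESRI ASCII grid
#'
#' The ESRI ASCII raster format stores a regular grid with a plain-text
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize` in decimal
#' degrees, `NODATA_value`). Rows in the file run north to south; the
#' `bathy_grid` convention is south to north, so rows are flipped on the way
#' in and out. The metric cell size is reconstructed from the latitude step.
#'
#' @param grid A [bathy_grid()].
#' @param path File path.
#' @return `read_esri_ascii` returns a [bathy_grid()]; `write_esri_ascii`
#'   returns `path` invisibly.
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "bathy_grid"))
  d <- grid$depths
  cell_deg <- grid$lat[2] - grid$lat[1]
  hdr <- c(
    sprintf("ncols %d", ncol(d)),
    sprintf("nrows %d", nrow(d)),
    sprintf("xllcorner %.10f", grid$lon[1] - cell_deg / 2),
    sprintf("yllcorner %.10f", grid$lat[1] - cell_deg / 2),
    sprintf("cellsize %.10f", cell_deg),
    "NODATA_value -9999"
  )
  d[is.na(d)] <- -9999
  body <- apply(d[rev(seq_len(nrow(d))), , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m[m == (hdr$nodata_value %||% -9999)] <- NA
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  lat0 <- hdr$yllcorner + hdr$cellsize / 2
  lon0 <- hdr$xllcorner + hdr$cellsize / 2
  bathy_grid(m, origin = c(lat = lat0, lon = lon0),
             cell_m = hdr$cellsize * M_PER_DEG_LAT)
}

#' Read/write a coastline polyline as GeoJSON
#'
#' @param coastline Data frame of `lat`, `lon` vertices.
#' @param path File path.
#' @return `read_coastline_geojson` returns the vertex data frame;
#'   `write_coastline_geojson` returns `path` invisibly.
#' @export
write_coastline_geojson <- function(coastline, path) {
  obj <- list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = unname(as.matrix(coastline[, c("lon", "lat")]))),
    properties = list(name = "coastline")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coastline_geojson
#' @export
read_coastline_geojson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(obj$geometry)) obj$geometry else obj
  cc <- geom$coordinates
  data.frame(lat = cc[, 2], lon = cc[, 1])
}
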