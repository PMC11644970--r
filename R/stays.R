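# Trajectory ingest and stay / home detection.
#
# A stay is a maximal run of consecutive fixes that remain within
# `spatial_radius_km` of the run's incremental centroid and span at least
# `min_stop_minutes`. Stay locations are then grouped with a deterministic
# density-based clustering, and home is the cluster with the largest
# cumulative dwell time.

#' Construct a trajectory object
#'
#' @param subject_id Subject identifier.
#' @param t Numeric times, seconds since epoch (UTC), strictly increasing.
#' @param lat,lon Coordinates in decimal degrees.
#' @return A `trajectory` object.
#' @export
trajectory <- function(subject_id, t, lat, lon) {
  stopifnot(length(t) == length(lat), length(t) == length(lon))
  if (length(t) < 2) stop("empty trajectory: need at least 2 points")
  o <- order(t)
  t <- t[o]; lat <- lat[o]; lon <- lon[o]
  if (any(diff(t) == 0)) stop("duplicate timestamps in trajectory")
  if (any(lat < -90 | lat > 90)) stop("latitude out of [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("longitude out of [-180, 180]")
  structure(list(subject_id = as.character(subject_id),
                 points = data.frame(t = t, lat = lat, lon = lon)),
            class = "trajectory")
}

#' Read a trajectory from CSV or GPX
#'
#' CSV dialect: header `subject_id,timestamp,lat,lon` with ISO-8601 UTC
#' timestamps (or numeric epoch seconds). GPX 1.1 track points
#' (`<trkpt lat lon><time>`) are also accepted, keyed on file extension.
#'
#' @param path File path.
#' @return A `trajectory` with points sorted by time.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.gpx$", path, ignore.case = TRUE)) return(.read_gpx(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "lat", "lon")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  t <- suppressWarnings(as.numeric(df$timestamp))
  if (anyNA(t)) {
    t <- as.numeric(as.POSIXct(df$timestamp, tz = "UTC",
                               format = "%Y-%m-%dT%H:%M:%SZ"))
  }
  bad <- which(is.na(t) | is.na(df$lat) | is.na(df$lon))
  if (length(bad))
    stop("unparseable trajectory row(s) at line ", bad[1] + 1L,
         " of ", path)
  trajectory(df$subject_id[1], t, df$lat, df$lon)
}

.read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (length(pts) < 2) stop("empty trajectory: fewer than 2 track points")
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  tstr <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
  t <- as.numeric(as.POSIXct(tstr, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ"))
  name <- xml2::xml_text(xml2::xml_find_first(doc, ".//trk/name"))
  if (is.na(name) || !nzchar(name)) name <- "gpx"
  trajectory(name, t, lat, lon)
}

#' Write a trajectory as GPX 1.1
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gpx <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  p <- traj$points
  tstr <- format(as.POSIXct(p$t, origin = "1970-01-01", tz = "UTC"),
                 "%Y-%m-%dT%H:%M:%SZ")
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gpx version="1.1" creator="mobgait" xmlns="http://www.topografix.com/GPX/1/1">',
    "<trk>", paste0("<name>", traj$subject_id, "</name>"), "<trkseg>",
    sprintf('<trkpt lat="%.9f" lon="%.9f"><time>%s</time></trkpt>',
            p$lat, p$lon, tstr),
    "</trkseg>", "</trk>", "</gpx>")
  writeLines(lines, path)
  invisible(path)
}

#' Detect stays in a trajectory
#'
#' Scans fixes in time order; a run grows while each new fix lies within
#' `spatial_radius_km` of the centroid of the fixes already in the run.
#' Runs spanning at least `min_stop_minutes` become stays; all other fixes
#' are travel. Stay intervals are half-open `[arrival, departure)`.
#'
#' @param traj A `trajectory`.
#' @param spatial_radius_km Stay radius in km (the study value is 0.1).
#' @param min_stop_minutes Minimum stop duration in minutes (study: 15).
#' @return A `stay_table`: list with `subject_id`, data frame `stays`
#'   (`centroid_lat`, `centroid_lon`, `arrival`, `departure`, `first_idx`,
#'   `last_idx`, `cluster` all `NA` until clustered), and `home_cluster`
#'   (`NA` until [detect_home()]).
#' @export
detect_stays <- function(traj, spatial_radius_km = 0.1,
                         min_stop_minutes = 15) {
  stopifnot(inherits(traj, "trajectory"),
            spatial_radius_km > 0, min_stop_minutes > 0)
  p <- traj$points
  lat <- p$lat; lon <- p$lon; tt <- p$t
  n <- length(tt)
  min_s <- min_stop_minutes * 60
  clat <- clon <- arr <- dep <- numeric(0)
  i1 <- i2 <- integer(0)
  i <- 1L
  while (i <= n) {
    # grow run [i, j]
    sum_lat <- lat[i]; sum_lon <- lon[i]; m <- 1L
    j <- i + 1L
    while (j <= n) {
      d <- .dist_km_local(sum_lat / m, sum_lon / m, lat[j], lon[j])
      if (d > spatial_radius_km) break
      sum_lat <- sum_lat + lat[j]; sum_lon <- sum_lon + lon[j]
      m <- m + 1L; j <- j + 1L
    }
    last <- j - 1L
    if (tt[last] - tt[i] >= min_s) {
      clat <- c(clat, sum_lat / m); clon <- c(clon, sum_lon / m)
      arr <- c(arr, tt[i]); dep <- c(dep, tt[last])
      i1 <- c(i1, i); i2 <- c(i2, last)
      i <- last + 1L
    } else i <- i + 1L
  }
  stays <- data.frame(centroid_lat = clat, centroid_lon = clon,
                      arrival = arr, departure = dep,
                      first_idx = i1, last_idx = i2)
  stays$cluster <- rep(NA_integer_, nrow(stays))
  structure(list(subject_id = traj$subject_id, stays = stays,
                 home_cluster = NA_integer_),
            class = "stay_table")
}

#' Density-based clustering of stay locations
#'
#' DBSCAN on stay centroids with geodesic distances. To make labels
#' independent of input order, clusters are the connected components of the
#' graph on core points (points with at least `min_samples` neighbours
#' within `max_distance_km`, counting themselves), labelled in order of
#' their smallest member index; non-core points join the cluster of their
#' nearest core neighbour within range, or are labelled noise (`0`).
#'
#' @param stay_table A `stay_table` from [detect_stays()].
#' @param max_distance_km Neighbourhood radius in km.
#' @param min_samples Minimum neighbourhood size for a core point.
#' @return The `stay_table` with the `cluster` column filled (noise = 0).
#' @export
cluster_stays <- function(stay_table, max_distance_km = 0.1,
                          min_samples = 1) {
  stopifnot(inherits(stay_table, "stay_table"))
  if (max_distance_km <= 0) stop("max_distance_km must be positive")
  s <- stay_table$stays
  n <- nrow(s)
  if (n == 0) return(stay_table)
  dmat <- outer(seq_len(n), seq_len(n), function(i, j)
    .dist_km_local(s$centroid_lat[i], s$centroid_lon[i],
                   s$centroid_lat[j], s$centroid_lon[j]))
  nb <- dmat <= max_distance_km
  core <- rowSums(nb) >= min_samples
  labels <- integer(n)                      # 0 = noise
  next_label <- 1L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    # BFS over core points
    comp <- i; frontier <- i
    labels[i] <- next_label
    while (length(frontier)) {
      new <- unique(unlist(lapply(frontier, function(k)
        which(nb[k, ] & core & labels == 0L))))
      labels[new] <- next_label
      frontier <- new
    }
    next_label <- next_label + 1L
  }
  for (i in which(!core)) {
    cand <- which(nb[i, ] & core)
    if (length(cand)) {
      best <- cand[order(dmat[i, cand], cand)][1]
      labels[i] <- labels[best]
    }
  }
  stay_table$stays$cluster <- labels
  stay_table
}

#' Detect the home cluster
#'
#' Home is the cluster with the maximum cumulative dwell time; exact ties
#' go to the cluster whose earliest arrival is earliest.
#'
#' @param stay_table A clustered `stay_table`.
#' @return The `stay_table` with `home_cluster` set.
#' @export
detect_home <- function(stay_table) {
  stopifnot(inherits(stay_table, "stay_table"))
  s <- stay_table$stays
  s <- s[!is.na(s$cluster) & s$cluster > 0, ]
  if (nrow(s) == 0) stop("no clustered stays: cannot determine home")
  dwell <- tapply(s$departure - s$arrival, s$cluster, sum)
  first_arr <- tapply(s$arrival, s$cluster, min)
  ids <- as.integer(names(dwell))
  best <- ids[order(-dwell, first_arr, ids)][1]
  stay_table$home_cluster <- best
  stay_table
}

#' Write a stay table to CSV
#'
#' Columns: `subject_id,cluster_id,arrival_iso,departure_iso,lat,lon`.
#' @param stay_table A `stay_table`.
#' @param path Output path.
#' @export
write_stay_table <- function(stay_table, path) {
  s <- stay_table$stays
  iso <- function(t) format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
                            "%Y-%m-%dT%H:%M:%SZ")
  utils::write.csv(
    data.frame(subject_id = stay_table$subject_id, cluster_id = s$cluster,
               arrival_iso = iso(s$arrival), departure_iso = iso(s$departure),
               lat = s$centroid_lat, lon = s$centroid_lon),
    path, row.names = FALSE)
  invisible(path)
}
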