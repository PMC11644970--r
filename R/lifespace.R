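# Life-space (GPS) metrics.
#
# Areas and angles are computed in the local equirectangular projection;
# every point-to-point distance metric uses geodesic (WGS84) distance.

#' Minimum convex polygon area
#'
#' Area (km^2) of the convex hull of the projected points via the closed
#' shoelace formula. Fewer than 3 distinct non-collinear points give a
#' zero-area result with a warning.
#'
#' @param lat,lon Coordinates in degrees.
#' @return Area in km^2, with attribute `perimeter_km` (hull perimeter).
#' @export
mcp_area <- function(lat, lon) {
  pr <- project_local(lat, lon)
  xy <- unique(cbind(pr$x, pr$y))
  if (nrow(xy) < 3) {
    warning("fewer than 3 distinct points: zero-area hull")
    return(structure(0, perimeter_km = 0, degenerate = TRUE))
  }
  h <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(h) < 3) {
    warning("collinear points: zero-area hull")
    return(structure(0, perimeter_km = 0, degenerate = TRUE))
  }
  hx <- xy[h, 1]; hy <- xy[h, 2]
  j <- c(seq_along(hx)[-1], 1L)
  area <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  per <- sum(sqrt((hx[j] - hx)^2 + (hy[j] - hy)^2))
  structure(area, perimeter_km = per, degenerate = FALSE)
}

#' Standard deviational ellipse compactness
#'
#' `4 * pi * A_SDE / P_MCP^2`, where `A_SDE = pi * s1 * s2` is the area of
#' the 1-SD principal-axis ellipse of the projected points (population SDs
#' along the principal axes) and `P_MCP` is the convex hull perimeter.
#'
#' @param lat,lon Coordinates in degrees.
#' @return Dimensionless compactness (0 for a degenerate cloud, with a
#'   warning).
#' @export
sde_compactness <- function(lat, lon) {
  a <- mcp_area(lat, lon)
  if (attr(a, "degenerate") || attr(a, "perimeter_km") <= 0) {
    warning("degenerate point cloud: compactness 0")
    return(0)
  }
  pr <- project_local(lat, lon)
  xy <- cbind(pr$x, pr$y)
  n <- nrow(xy)
  cc <- sweep(xy, 2, colMeans(xy))
  cov_p <- crossprod(cc) / n
  ev <- eigen(cov_p, symmetric = TRUE)$values
  ev[ev < 0] <- 0
  a_sde <- pi * sqrt(ev[1]) * sqrt(ev[2])
  4 * pi * a_sde / attr(a, "perimeter_km")^2
}

#' Number of visited places
#'
#' Count of distinct non-noise stay clusters, excluding the home cluster by
#' default.
#'
#' @param stay_table A clustered `stay_table` (with home detected when
#'   `include_home = FALSE`).
#' @param include_home Count the home cluster too?
#' @return Integer count.
#' @export
n_visited_places <- function(stay_table, include_home = FALSE) {
  cl <- stay_table$stays$cluster
  cl <- cl[!is.na(cl) & cl > 0]
  u <- unique(cl)
  if (!include_home && !is.na(stay_table$home_cluster))
    u <- setdiff(u, stay_table$home_cluster)
  length(u)
}

#' Time outside home
#'
#' Trajectory span minus the cumulative dwell time of home-cluster stays.
#'
#' @param stay_table A clustered `stay_table` with `home_cluster` set.
#' @param traj The corresponding `trajectory`.
#' @return Hours.
#' @export
time_outside_home <- function(stay_table, traj) {
  if (is.na(stay_table$home_cluster)) stop("home cluster not set")
  s <- stay_table$stays
  home_dwell <- sum((s$departure - s$arrival)[
    !is.na(s$cluster) & s$cluster == stay_table$home_cluster])
  span <- diff(range(traj$points$t))
  (span - home_dwell) / 3600
}

#' Maximum geodesic distance from home
#'
#' @param traj A `trajectory`.
#' @param home `c(lat, lon)` of home.
#' @return km.
#' @export
max_distance <- function(traj, home) {
  max(geodesic_km(traj$points$lat, traj$points$lon, home[1], home[2]))
}

#' Cumulative straight-line (path) distance
#'
#' Sum of geodesic distances between consecutive fixes.
#' @param traj A `trajectory`.
#' @return km.
#' @export
straight_line_distance <- function(traj) {
  p <- traj$points
  if (nrow(p) < 2) stop("need at least 2 fixes")
  sum(geodesic_km(p$lat[-nrow(p)], p$lon[-nrow(p)], p$lat[-1], p$lon[-1]))
}

#' Mean turning radius
#'
#' For each consecutive triplet of points, the circumradius
#' `R = l / (2 sin(theta))` with `l` the chord between the outer points and
#' `theta` the turning angle at the middle point (law of sines). Collinear
#' triplets (sin(theta) ~ 0) are skipped; if no triplet yields a finite
#' radius, `NA` is returned.
#'
#' @param lat,lon Coordinates (degrees) of the path, in order.
#' @return Mean finite circumradius in km, or `NA_real_`.
#' @export
turning_radius <- function(lat, lon) {
  if (length(lat) < 3) return(NA_real_)
  pr <- project_local(lat, lon)
  x <- pr$x; y <- pr$y
  n <- length(x)
  i <- 1:(n - 2)
  ux <- x[i + 1] - x[i];     uy <- y[i + 1] - y[i]
  vx <- x[i + 2] - x[i + 1]; vy <- y[i + 2] - y[i + 1]
  cross <- ux * vy - uy * vx
  nu <- sqrt(ux^2 + uy^2); nv <- sqrt(vx^2 + vy^2)
  sin_theta <- abs(cross) / (nu * nv)
  l <- sqrt((x[i + 2] - x[i])^2 + (y[i + 2] - y[i])^2)
  r <- l / (2 * sin_theta)
  ok <- is.finite(r) & nu > 1e-12 & nv > 1e-12 & sin_theta > 1e-9
  if (!any(ok)) return(NA_real_)
  mean(r[ok])
}

#' Radius of gyration (as reported)
#'
#' Population standard deviation of the per-fix geodesic distances to home:
#' `sqrt(mean((d_i - dbar)^2))`. Note this is the spread of home distances,
#' not the conventional root-mean-square distance about the centroid; set
#' `conventional = TRUE` for the latter.
#'
#' @param traj A `trajectory`.
#' @param home `c(lat, lon)`.
#' @param conventional Use `sqrt(mean(d_i^2))` about the centroid instead.
#' @return km.
#' @export
k_radius_of_gyration <- function(traj, home, conventional = FALSE) {
  p <- traj$points
  if (conventional) {
    ctr <- c(mean(p$lat), mean(p$lon))
    d <- geodesic_km(p$lat, p$lon, ctr[1], ctr[2])
    return(sqrt(mean(d^2)))
  }
  d <- geodesic_km(p$lat, p$lon, home[1], home[2])
  sqrt(mean((d - mean(d))^2))
}

#' GPS feature names, in schema order
#' @export
gps_feature_names <- function() {
  c("activity_space_km2", "sde_compactness", "n_visited_places",
    "time_outside_h", "max_distance_km", "straight_line_km",
    "turning_radius_km", "k_radius_gyration_km")
}

#' Compute all life-space metrics for one subject
#'
#' Aggregates the metric kernels into one feature row. The turning radius
#' is computed over travel fixes (fixes not inside any stay); home
#' coordinates are the centroid of the home cluster's stays. Undefined
#' members are `NA`.
#'
#' @param traj A `trajectory`.
#' @param stay_table Clustered `stay_table` with home set (as produced by
#'   [detect_stays()] + [cluster_stays()] + [detect_home()]).
#' @return One-row data frame with columns [gps_feature_names()].
#' @export
compute_gps_features <- function(traj, stay_table) {
  p <- traj$points
  s <- stay_table$stays
  home_stays <- s[!is.na(s$cluster) & s$cluster == stay_table$home_cluster, ,
                  drop = FALSE]
  if (nrow(home_stays) == 0) stop("home cluster not present in stay table")
  home <- c(mean(home_stays$centroid_lat), mean(home_stays$centroid_lon))
  in_stay <- rep(FALSE, nrow(p))
  for (k in seq_len(nrow(s))) in_stay[s$first_idx[k]:s$last_idx[k]] <- TRUE
  travel <- p[!in_stay, , drop = FALSE]
  area <- suppressWarnings(mcp_area(p$lat, p$lon))
  comp <- suppressWarnings(sde_compactness(p$lat, p$lon))
  d_home <- geodesic_km(p$lat, p$lon, home[1], home[2])
  data.frame(
    activity_space_km2 = as.numeric(area),
    sde_compactness = comp,
    n_visited_places = n_visited_places(stay_table),
    time_outside_h = time_outside_home(stay_table, traj),
    max_distance_km = max(d_home),
    straight_line_km = straight_line_distance(traj),
    turning_radius_km = if (nrow(travel) >= 3)
      turning_radius(travel$lat, travel$lon) else NA_real_,
    k_radius_gyration_km = sqrt(mean((d_home - mean(d_home))^2)))
}
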