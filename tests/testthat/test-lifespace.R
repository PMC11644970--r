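# life-space metric kernels

square_km <- function(side = 1, home = fix_home) {
  pts <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  p <- offset_latlon(home[1], home[2], pts[, 1], pts[, 2])
  list(lat = p$lat, lon = p$lon)
}

test_that("MCP area: unit square, degenerate cases, hull oracle", {
  sq <- square_km(1)
  expect_equal(as.numeric(mcp_area(sq$lat, sq$lon)), 1, tolerance = 1e-3)
  expect_warning(a0 <- mcp_area(fix_home[1] + c(0, 0.01, 0.02),
                                rep(fix_home[2], 3)), "collinear")
  expect_identical(as.numeric(a0), 0)
  set.seed(7)
  for (rep in 1:5) {
    lat <- fix_home[1] + rnorm(200, 0, 0.02)
    lon <- fix_home[2] + rnorm(200, 0, 0.02)
    got <- as.numeric(mcp_area(lat, lon))
    pr <- project_local(lat, lon)
    expect_equal(got, fan_hull_area(pr$x, pr$y), tolerance = 1e-9)
  }
})

test_that("SDE compactness: scale invariance, degenerate, isotropic oracle", {
  set.seed(2)
  lat <- fix_home[1] + rnorm(300, 0, 0.02)
  lon <- fix_home[2] + rnorm(300, 0, 0.02)
  c1 <- sde_compactness(lat, lon)
  lat2 <- fix_home[1] + 2 * (lat - mean(lat))
  lon2 <- fix_home[2] + 2 * (lon - mean(lon))
  expect_equal(sde_compactness(lat2, lon2), c1, tolerance = 1e-3)
  z <- suppressWarnings(sde_compactness(rep(fix_home[1], 5),
                                        rep(fix_home[2], 5)))
  expect_identical(z, 0)
  # isotropic cloud: compactness = 4*pi * pi*sigma^2 / P^2
  set.seed(10)
  x <- rnorm(1e5); y <- rnorm(1e5)
  sig_km <- 0.5
  p <- offset_latlon(fix_home[1], fix_home[2], sig_km * x, sig_km * y)
  got <- sde_compactness(p$lat, p$lon)
  pr <- project_local(p$lat, p$lon)
  s1 <- sqrt(mean((pr$x - mean(pr$x))^2)); s2 <- sqrt(mean((pr$y - mean(pr$y))^2))
  P <- attr(mcp_area(p$lat, p$lon), "perimeter_km")
  expect_equal(got, 4 * pi * pi * s1 * s2 / P^2, tolerance = 0.01)
})

test_that("visited places exclude home unless asked", {
  off <- rbind(c(1, 0), c(0, 1.2), c(-1, 0.4))
  tr <- make_itinerary_traj(off, dwell_min = c(20, 20, 20))
  st <- detect_home(cluster_stays(detect_stays(tr)))
  expect_identical(n_visited_places(st), 3L)
  expect_identical(n_visited_places(st, include_home = TRUE), 4L)

  home_only <- make_itinerary_traj(matrix(numeric(0), 0, 2), numeric(0),
                                   tail_min = 40)
  st0 <- detect_home(cluster_stays(detect_stays(home_only)))
  expect_identical(n_visited_places(st0), 0L)
})

test_that("visited-place counts recover the generator truth", {
  hits <- vapply(1:10, function(s) {
    m <- mobility_profile(n_places = 3, outside_hours = 2)
    tr <- generate_trajectory(m, seed = 300 + s)
    st <- detect_home(cluster_stays(detect_stays(tr)))
    n_visited_places(st) == 3L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("time outside home is the span minus home dwell", {
  off <- rbind(c(1, 0))
  tr <- make_itinerary_traj(off, dwell_min = 60, tail_min = 120)
  st <- detect_home(cluster_stays(detect_stays(tr)))
  span_h <- diff(range(tr$points$t)) / 3600
  home_h <- sum((st$stays$departure - st$stays$arrival)[
    st$stays$cluster == st$home_cluster]) / 3600
  expect_equal(time_outside_home(st, tr), span_h - home_h)
  # planned outside time recovered within 2 GPS intervals
  m <- mobility_profile(outside_hours = 1.63)
  for (s in 1:4) {
    tr <- generate_trajectory(m, seed = 400 + s)
    st <- detect_home(cluster_stays(detect_stays(tr)))
    got <- time_outside_home(st, tr)
    expect_lt(abs(got - attr(tr, "truth")$outside_planned_h), 2 * 60 / 3600)
  }
})

test_that("distance metrics: closed forms and oracles", {
  # all fixes at home
  tr0 <- trajectory("A", 0:9 * 60, rep(fix_home[1], 10), rep(fix_home[2], 10))
  expect_identical(max_distance(tr0, fix_home), 0)
  expect_identical(k_radius_of_gyration(tr0, fix_home), 0)

  # farthest fix 0.01 degrees north of a mid-latitude home: ~1.111 km
  home45 <- c(45, 7)
  tr1 <- trajectory("A", c(0, 60), home45[1] + c(0, 0.01),
                    rep(home45[2], 2))
  expect_equal(max_distance(tr1, home45), 1.11132, tolerance = 1e-3)

  # adding a closer fix leaves the max unchanged
  tr2 <- trajectory("A", c(0, 60, 120), home45[1] + c(0, 0.01, 0.002),
                    rep(home45[2], 3))
  expect_equal(max_distance(tr2, home45), max_distance(tr1, home45))

  # out-and-back path doubles the straight-line sum
  p1 <- offset_latlon(fix_home[1], fix_home[2], 1, 0)
  tr3 <- trajectory("A", c(0, 600, 1200),
                    c(fix_home[1], p1$lat, fix_home[1]),
                    c(fix_home[2], p1$lon, fix_home[2]))
  expect_equal(straight_line_distance(tr3), 2, tolerance = 5e-3)

  # random walk vs direct pairwise sum
  set.seed(4)
  lat <- fix_home[1] + cumsum(rnorm(50, 0, 0.003))
  lon <- fix_home[2] + cumsum(rnorm(50, 0, 0.003))
  tr4 <- trajectory("A", seq_len(50) * 60, lat, lon)
  manual <- sum(vapply(1:49, function(i)
    geodesic_km(lat[i], lon[i], lat[i + 1], lon[i + 1]), numeric(1)))
  expect_equal(straight_line_distance(tr4), manual, tolerance = 1e-9)

  # distances {0, 2} km from home: population SD is 1
  p2 <- offset_latlon(fix_home[1], fix_home[2], 2, 0)
  tr5 <- trajectory("A", c(0, 60), c(fix_home[1], p2$lat),
                    c(fix_home[2], p2$lon))
  expect_equal(k_radius_of_gyration(tr5, fix_home), 1, tolerance = 5e-3)

  # brute-force SD oracle
  d <- geodesic_km(lat, lon, fix_home[1], fix_home[2])
  expect_equal(k_radius_of_gyration(tr4, fix_home),
               sqrt(sum((d - mean(d))^2) / length(d)), tolerance = 1e-12)
})

test_that("turning radius recovers circles and degenerates on lines", {
  # points on a circle of radius 1 km
  th <- seq(0, 1.6 * pi, length.out = 20)
  p <- offset_latlon(fix_home[1], fix_home[2], cos(th), sin(th))
  expect_equal(turning_radius(p$lat, p$lon), 1, tolerance = 5e-3)
  # right angle with 1 km legs: circumradius = sqrt(2)/2
  p <- offset_latlon(fix_home[1], fix_home[2], c(0, 1, 1), c(0, 0, 1))
  expect_equal(turning_radius(p$lat, p$lon), sqrt(2) / 2, tolerance = 5e-3)
  # straight track: undefined
  p <- offset_latlon(fix_home[1], fix_home[2], 0:5, rep(0, 6))
  expect_true(is.na(turning_radius(p$lat, p$lon)))
  # triangle circumradius oracle on random triplets
  set.seed(6)
  for (rep in 1:20) {
    xy <- matrix(runif(6, -2, 2), 3, 2)
    p <- offset_latlon(fix_home[1], fix_home[2], xy[, 1], xy[, 2])
    a <- dist(xy)
    expect_equal(turning_radius(p$lat, p$lon),
                 circumradius_sides(a[1], a[2], a[3]), tolerance = 1e-2)
  }
})

test_that("full GPS feature rows behave on degenerate and generated days", {
  # stay-at-home day (tiny jitter, all within metres of home)
  set.seed(8)
  jit <- offset_latlon(fix_home[1], fix_home[2],
                       rnorm(480, 0, 0.004), rnorm(480, 0, 0.004))
  tr <- trajectory("A", seq_len(480) * 60, jit$lat, jit$lon)
  st <- detect_home(cluster_stays(detect_stays(tr)))
  f <- suppressWarnings(compute_gps_features(tr, st))
  expect_identical(names(f), gps_feature_names())
  expect_lt(f$activity_space_km2, 0.005)
  expect_lt(f$max_distance_km, 0.05)
  expect_identical(f$n_visited_places, 0L)

  # generated subject: fields near generator truth
  m <- mobility_profile()
  tr <- generate_trajectory(m, seed = 77)
  f <- extract_gps_features(tr)
  truth <- attr(tr, "truth")
  expect_equal(f$n_visited_places, m$n_places)
  expect_lt(abs(f$max_distance_km - truth$d_max_planned_km), 0.1)
  expect_lt(abs(f$time_outside_h - truth$outside_planned_h), 0.05)
  # D_max <= D_total
  expect_lte(f$max_distance_km, f$straight_line_km)
})
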