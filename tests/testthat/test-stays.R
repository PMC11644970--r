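# trajectory ingest, stay detection, clustering, home

test_that("trajectory ingest sorts, validates, and rejects bad rows", {
  tr <- trajectory("A", c(120, 0, 60), c(1, 1, 1), c(2, 2, 2))
  expect_identical(tr$points$t, c(0, 60, 120))
  expect_error(trajectory("A", c(0, 0), c(1, 1), c(2, 2)), "duplicate")
  expect_error(trajectory("A", 0, 1, 2), "at least 2")
  expect_error(trajectory("A", c(0, 60), c(91, 0), c(0, 0)), "latitude")

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,timestamp,lat,lon",
               "A,1970-01-01T00:02:00Z,1,2",
               "A,1970-01-01T00:00:00Z,1,2.001"), csv)
  tr <- read_trajectory(csv)
  expect_identical(tr$points$t, c(0, 120))
  writeLines(c("subject_id,timestamp,lat,lon",
               "A,1970-01-01T00:00:00Z,1,2",
               "A,not-a-time,1,2"), csv)
  expect_error(read_trajectory(csv), "line 3")
})

test_that("GPX round-trips to an equal trajectory", {
  tr <- generate_trajectory(mobility_profile(n_places = 2,
                                             outside_hours = 1.2), seed = 4)
  gpx <- withr::local_tempfile(fileext = ".gpx")
  write_gpx(tr, gpx)
  back <- read_trajectory(gpx)
  expect_identical(back$subject_id, tr$subject_id)
  expect_equal(back$points$lat, tr$points$lat, tolerance = 1e-8)
  expect_equal(back$points$lon, tr$points$lon, tolerance = 1e-8)
  expect_equal(back$points$t, round(tr$points$t))
})

test_that("stay detection applies the radius and duration gates", {
  # 20 one-minute fixes at one point, then departure
  tt <- c(0:19 * 60, 20 * 60 + c(0, 60, 120))
  far <- offset_latlon(fix_home[1], fix_home[2], c(0.3, 0.6, 0.9), 0)
  tr <- trajectory("A", tt, c(rep(fix_home[1], 20), far$lat),
                   c(rep(fix_home[2], 20), far$lon))
  st <- detect_stays(tr)
  expect_identical(nrow(st$stays), 1L)
  dur_min <- (st$stays$departure - st$stays$arrival) / 60
  expect_gte(dur_min, 19)
  expect_lte(dur_min, 21)

  # 10-minute dwell only: below the duration gate
  tt <- 0:10 * 60
  tr <- trajectory("A", tt, rep(fix_home[1], 11), rep(fix_home[2], 11))
  st <- detect_stays(tr)
  expect_identical(nrow(st$stays), 0L)
})

test_that("planned multi-dwell itineraries are recovered", {
  off <- rbind(c(1, 0), c(0, 1.2), c(-0.8, -0.6))
  tr <- make_itinerary_traj(off, dwell_min = c(20, 20, 20))
  st <- detect_stays(tr)
  expect_identical(nrow(st$stays), 4L)
  planned <- offset_latlon(fix_home[1], fix_home[2], off[, 1], off[, 2])
  for (k in 1:3) {
    d <- geodesic_km(st$stays$centroid_lat, st$stays$centroid_lon,
                     planned$lat[k], planned$lon[k])
    expect_lt(min(d), 0.05)
  }
})

test_that("raising the duration gate never increases the stay count", {
  tr <- generate_trajectory(mobility_profile(), seed = 8)
  counts <- vapply(c(5, 10, 15, 25, 40),
                   function(m) nrow(detect_stays(tr,
                                                 min_stop_minutes = m)$stays),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("stay structure is invariant under rigid translation", {
  tr <- generate_trajectory(mobility_profile(), seed = 13)
  st1 <- detect_stays(tr)
  # a pure longitude shift leaves every local distance identical
  tr2 <- tr
  tr2$points$lon <- tr2$points$lon - 35
  st2 <- detect_stays(tr2)
  expect_identical(nrow(st1$stays), nrow(st2$stays))
  expect_equal(st1$stays$arrival, st2$stays$arrival)
  expect_equal(st1$stays$departure, st2$stays$departure)
  # a modest latitude shift preserves the stay count
  tr3 <- tr
  tr3$points$lat <- tr3$points$lat + 1
  expect_identical(nrow(detect_stays(tr3)$stays), nrow(st1$stays))
})

test_that("total stay time never exceeds the trajectory span", {
  for (s in 1:3) {
    tr <- generate_trajectory(mobility_profile(), seed = 100 + s)
    st <- detect_stays(tr)
    expect_lte(sum(st$stays$departure - st$stays$arrival),
               diff(range(tr$points$t)))
  }
})

test_that("clustering separates distant groups and flags sparse points", {
  off <- rbind(c(2, 0), c(7, 0))
  tr <- make_itinerary_traj(off, dwell_min = c(20, 20), tail_min = 30)
  st <- cluster_stays(detect_stays(tr), max_distance_km = 0.2,
                      min_samples = 1)
  expect_identical(length(unique(st$stays$cluster)), 3L)  # 2 places + home

  one <- detect_stays(make_itinerary_traj(rbind(c(1, 0)), 20, tail_min = 5))
  one$stays <- one$stays[1, ]
  one <- cluster_stays(one, max_distance_km = 0.2, min_samples = 2)
  expect_identical(one$stays$cluster, 0L)
  expect_error(cluster_stays(one, max_distance_km = -1), "positive")
})

test_that("clustering matches the brute-force density oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 50
    lat <- fix_home[1] + rnorm(n, 0, 0.01)
    lon <- fix_home[2] + rnorm(n, 0, 0.01)
    st <- structure(list(
      subject_id = "A",
      stays = data.frame(centroid_lat = lat, centroid_lon = lon,
                         arrival = seq_len(n) * 1000,
                         departure = seq_len(n) * 1000 + 900,
                         first_idx = seq_len(n), last_idx = seq_len(n),
                         cluster = NA_integer_),
      home_cluster = NA_integer_), class = "stay_table")
    eps <- 0.4; ms <- 3
    got <- cluster_stays(st, eps, ms)$stays$cluster
    dmat <- outer(seq_len(n), seq_len(n), function(i, j)
      mobgait:::.dist_km_local(lat[i], lon[i], lat[j], lon[j]))
    expect_identical(got, as.integer(bf_density_cluster(dmat, eps, ms)))
  }
})

test_that("home is the cluster with maximal dwell, ties to earliest", {
  mk <- function(dwells, arrivals, clusters) {
    structure(list(subject_id = "A",
                   stays = data.frame(
                     centroid_lat = 0, centroid_lon = 0,
                     arrival = arrivals, departure = arrivals + dwells,
                     first_idx = 1, last_idx = 2, cluster = clusters),
                   home_cluster = NA_integer_), class = "stay_table")
  }
  st <- detect_home(mk(c(6 * 3600, 0.5 * 3600), c(0, 1e5), c(1L, 2L)))
  expect_identical(st$home_cluster, 1L)
  st <- detect_home(mk(c(3600, 3600), c(5000, 100), c(1L, 2L)))
  expect_identical(st$home_cluster, 2L)   # same dwell, earlier arrival
  noise <- mk(3600, 0, 0L)
  expect_error(detect_home(noise), "no clustered stays")
})

test_that("detected home matches the generator home", {
  for (s in 1:6) {
    tr <- generate_trajectory(mobility_profile(), seed = 200 + s)
    st <- detect_home(cluster_stays(detect_stays(tr)))
    hs <- st$stays[st$stays$cluster == st$home_cluster, ]
    home <- attr(tr, "truth")$home
    expect_lt(min(geodesic_km(hs$centroid_lat, hs$centroid_lon,
                              home[1], home[2])), 0.1)
  }
})

test_that("stay table CSV writer emits the documented columns", {
  tr <- generate_trajectory(mobility_profile(), seed = 3)
  st <- detect_home(cluster_stays(detect_stays(tr)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_stay_table(st, f)
  out <- utils::read.csv(f)
  expect_identical(names(out), c("subject_id", "cluster_id", "arrival_iso",
                                 "departure_iso", "lat", "lon"))
  expect_identical(nrow(out), nrow(st$stays))
})
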