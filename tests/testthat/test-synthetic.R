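# synthetic cohort generator

test_that("noiseless constant cadence gives peaks spaced exactly one step", {
  a <- generate_accel_stream(constant_gait(), fs = 50, seed = 1)
  pk <- detect_peaks(bandpass(a$vt, fs = 50), 50, 0.5)
  expect_length(pk, 40)
  expect_setequal(unique(diff(pk)), 50L)
})

test_that("generation is bit-identical for equal seeds", {
  p <- gait_profile()
  a1 <- generate_accel_stream(p, fs = 50, seed = 42)
  a2 <- generate_accel_stream(p, fs = 50, seed = 42)
  expect_identical(a1, a2)
  m <- mobility_profile()
  t1 <- generate_trajectory(m, seed = 9)
  t2 <- generate_trajectory(m, seed = 9)
  expect_identical(t1, t2)
  co1 <- generate_cohort(cohort_spec(2, seed = 5))
  co2 <- generate_cohort(cohort_spec(2, seed = 5))
  expect_identical(co1, co2)
})

test_that("capacity errors are explicit", {
  expect_error(generate_accel_stream(gait_profile(), fs = 50, duration = 10,
                                     seed = 1),
               "cannot hold")
  expect_error(generate_trajectory(
    mobility_profile(n_places = 6, outside_hours = 7.9,
                     day_length_hours = 8, place_radius_km = 3),
    seed = 1), "exceed the day length")
})

test_that("generated step-time jitter matches the requested cv", {
  # measured on the generator's own truth log, before any estimation
  cvs <- vapply(1:10, function(s) {
    a <- generate_accel_stream(
      gait_profile(mean_step_time = 1, step_time_cv = 0.04, asymmetry = 0,
                   bout_count = 1, bout_steps = 200), fs = 50, seed = s)
    iv <- diff(attr(a, "truth")$bouts[[1]]$step_times)
    sd(iv) / mean(iv)
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 0.04) / 0.04, 0.2)
})

test_that("harmonic stack realises the in-band even:odd energy target", {
  for (r in c(4, 2, 1.5)) {
    p <- gait_profile(mean_step_time = 0.9, step_time_cv = 0, asymmetry = 0,
                      noise_sd = 0, bout_count = 1, bout_steps = 120,
                      even_odd_energy_ratio = r)
    a <- generate_accel_stream(p, fs = 50, seed = 2)
    b <- attr(a, "truth")$bouts[[1]]
    filt <- bandpass(a$vt, fs = 50)
    hr <- harmonic_ratio(filt[b$start:b$end], 50,
                         1 / (2 * p$mean_step_time))
    expect_lt(abs(as.numeric(hr) - r) / r, 0.15)
  }
})

test_that("degenerate itinerary yields a single home stay", {
  tr <- generate_trajectory(mobility_profile(n_places = 0,
                                             outside_hours = 0.5), seed = 3)
  st <- detect_stays(tr)
  expect_identical(nrow(st$stays), 1L)
})

test_that("planned places come back as stays at the planned spots", {
  m <- mobility_profile(n_places = 3, outside_hours = 2.2,
                        place_radius_km = 1.2)
  tr <- generate_trajectory(m, seed = 7)
  st <- detect_stays(tr)
  expect_identical(nrow(st$stays), 4L)     # 3 places + home
  log <- attr(tr, "truth")$stay_log
  for (k in seq_len(nrow(log))) {
    d <- geodesic_km(st$stays$centroid_lat, st$stays$centroid_lon,
                     log$lat[k], log$lon[k])
    expect_lt(min(d), 0.05)
  }
})

test_that("farthest trajectory point sits at the planned distance", {
  for (s in 1:5) {
    tr <- generate_trajectory(mobility_profile(), seed = s)
    truth <- attr(tr, "truth")
    d <- max(geodesic_km(tr$points$lat, tr$points$lon,
                         truth$home[1], truth$home[2]))
    expect_lt(abs(d - truth$d_max_planned_km) / truth$d_max_planned_km,
              0.05)
  }
})

test_that("itinerary durations fill the day", {
  tr <- generate_trajectory(mobility_profile(), seed = 11)
  segs <- attr(tr, "truth")$segments
  total <- sum(vapply(segs, function(s) s$t1 - s$t0, numeric(1)))
  expect_equal(total, 8 * 3600, tolerance = 60 / (8 * 3600))
  expect_equal(diff(range(tr$points$t)), 8 * 3600, tolerance = 60)
})

test_that("cohort bookkeeping and truth table are complete", {
  co <- generate_cohort(cohort_spec(5, seed = 7))
  expect_length(co$subjects, 10)
  expect_identical(as.integer(table(co$truth$group)), c(5L, 5L))
  expect_identical(nrow(co$truth), 10L)
  expect_true(all(c("mean_step_time", "n_places", "outside_planned_h",
                    "d_max_planned_km") %in% names(co$truth)))
})

test_that("default profiles separate groups in the reported directions", {
  tab <- cohort_features(cohort_spec(12, seed = 31))
  med <- aggregate(tab[, -(1:2)], list(group = tab$group), median,
                   na.rm = TRUE)
  f <- med[med$group == "faller", ]; nf <- med[med$group == "nonfaller", ]
  expect_gt(f$mean_step_time_s, nf$mean_step_time_s)
  expect_gt(f$step_time_cv, nf$step_time_cv)
  expect_lt(f$walking_speed_mps, nf$walking_speed_mps)
  expect_lt(f$stride_regularity, nf$stride_regularity)
  expect_lt(f$step_regularity, nf$step_regularity)
  expect_gt(f$rms_vt, nf$rms_vt)
  expect_gt(f$rms_ml, nf$rms_ml)
  expect_gt(f$rms_ap, nf$rms_ap)
  expect_lt(f$hr_vt, nf$hr_vt)
  expect_lt(f$hr_ml, nf$hr_ml)
  expect_lt(f$hr_ap, nf$hr_ap)
  expect_lt(f$activity_space_km2, nf$activity_space_km2)
  expect_lt(f$max_distance_km, nf$max_distance_km)
  expect_lt(f$straight_line_km, nf$straight_line_km)
})

test_that("cohort CSVs round-trip through the ingest functions", {
  co <- generate_cohort(cohort_spec(1, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  s <- co$subjects[[1]]
  tr <- read_trajectory(file.path(dir, paste0(s$subject_id, "_gps.csv")))
  expect_equal(tr$points$lat, s$traj$points$lat, tolerance = 1e-9)
  # CSV timestamps are whole seconds
  expect_equal(tr$points$t, round(s$traj$points$t), tolerance = 1e-9)
  ac <- read_accel(file.path(dir, paste0(s$subject_id, "_accel.csv")))
  expect_equal(ac$vt, s$accel$vt, tolerance = 1e-9)
  expect_equal(ac$fs, s$accel$fs, tolerance = 1e-6)
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_identical(nrow(truth), 2L)
})
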