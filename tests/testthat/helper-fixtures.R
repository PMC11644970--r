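# Small fixtures built in code.

fix_home <- c(-33.45, -70.66)

# trajectory visiting fixed offsets (km east/north of home) with given
# dwell minutes at each, sampled at 1-min fixes; no positional jitter
make_itinerary_traj <- function(offsets_km, dwell_min, home = fix_home,
                                speed_kmh = 4.5, interval_s = 60,
                                tail_min = 60, subject_id = "T1") {
  stopifnot(nrow(offsets_km) == length(dwell_min))
  pts_lat <- c(); pts_lon <- c(); tt <- c()
  cur <- home; t <- 0
  add_dwell <- function(pos, minutes) {
    k <- seq(0, minutes * 60, by = interval_s)
    tt <<- c(tt, t + k)
    pts_lat <<- c(pts_lat, rep(pos[1], length(k)))
    pts_lon <<- c(pts_lon, rep(pos[2], length(k)))
    t <<- t + minutes * 60 + interval_s
  }
  travel_to <- function(from, to) {
    d <- geodesic_km(from[1], from[2], to[1], to[2])
    dur <- d / speed_kmh * 3600
    if (dur < interval_s) { t <<- t + interval_s; return(invisible()) }
    k <- seq(interval_s, dur, by = interval_s)
    if (length(k)) {
      frac <- k / dur
      tt <<- c(tt, t + k - interval_s)
      pts_lat <<- c(pts_lat, from[1] + frac * (to[1] - from[1]))
      pts_lon <<- c(pts_lon, from[2] + frac * (to[2] - from[2]))
    }
    t <<- t + max(k, interval_s)
  }
  for (i in seq_along(dwell_min)) {
    p <- offset_latlon(home[1], home[2], offsets_km[i, 1], offsets_km[i, 2])
    pos <- c(p$lat, p$lon)
    travel_to(cur, pos)
    add_dwell(pos, dwell_min[i])
    cur <- pos
  }
  travel_to(cur, home)
  add_dwell(home, tail_min)
  keep <- !duplicated(tt)
  trajectory(subject_id, tt[keep], pts_lat[keep], pts_lon[keep])
}

# noiseless constant-cadence gait profile
constant_gait <- function(step_time = 1.0, steps = 40, bouts = 1) {
  gait_profile(mean_step_time = step_time, step_time_cv = 0, asymmetry = 0,
               noise_sd = 0, bout_count = bouts, bout_steps = steps)
}

# feature table with two well-separated (or identical) classes, for
# classifier tests that do not need the signal chain
make_feature_table <- function(n_per_class = 20, sep = 0, seed = 1,
                               p_signal = 4) {
  set.seed(seed)
  n <- 2 * n_per_class
  cols <- c(gps_feature_names(), gait_feature_names())
  X <- matrix(rnorm(n * length(cols)), n, length(cols))
  colnames(X) <- cols
  y <- rep(c("nonfaller", "faller"), each = n_per_class)
  X[y == "faller", seq_len(p_signal)] <-
    X[y == "faller", seq_len(p_signal)] + sep
  data.frame(subject_id = sprintf("S%03d", 1:n), group = y, X,
             check.names = FALSE)
}
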