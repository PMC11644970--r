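# End-to-end feature extraction: raw streams -> CohortTable.

#' Extract life-space features from a trajectory
#'
#' Runs stay detection, location clustering, and home detection with the
#' study parameters, then computes the GPS metrics.
#'
#' @param traj A `trajectory`.
#' @param spatial_radius_km,min_stop_minutes Stay-detection parameters.
#' @param cluster_eps_km,cluster_min_samples Clustering parameters.
#' @return One-row data frame of GPS features (all `NA` if no home can be
#'   determined).
#' @export
extract_gps_features <- function(traj, spatial_radius_km = 0.1,
                                 min_stop_minutes = 15,
                                 cluster_eps_km = 0.1,
                                 cluster_min_samples = 1) {
  st <- detect_stays(traj, spatial_radius_km, min_stop_minutes)
  if (nrow(st$stays) == 0) {
    out <- as.data.frame(as.list(stats::setNames(
      rep(NA_real_, length(gps_feature_names())), gps_feature_names())))
    return(out)
  }
  st <- cluster_stays(st, cluster_eps_km, cluster_min_samples)
  st <- detect_home(st)
  compute_gps_features(traj, st)
}

#' Extract gait features from an accelerometer stream
#'
#' Band-passes the vertical axis, detects step peaks, gates walking bouts
#' by peak count and GPS speed, and computes the gait metrics.
#'
#' @param signal An `accel_signal`.
#' @param traj Matching `trajectory` for the speed gate, or `NULL`.
#' @param min_height Peak height threshold on the filtered vertical axis.
#' @param min_peaks,max_speed_kmh,max_gap_s Bout gates.
#' @inheritParams compute_gait_features
#' @return One-row data frame of gait features.
#' @export
extract_gait_features <- function(signal, traj = NULL, min_height = 0.5,
                                  min_peaks = 30, max_speed_kmh = 5,
                                  max_gap_s = 2.5, low = 0.5, high = 20,
                                  order = 4, step_length_m = 0.7) {
  filt <- bandpass(signal, low = low, high = high, order = order)
  peaks <- detect_peaks(filt$vt, signal$fs, min_height)
  speeds <- if (is.null(traj)) NULL else gps_speed_series(traj)
  bouts <- segment_bouts(peaks, signal$fs, t0 = signal$t0, speeds = speeds,
                         min_peaks = min_peaks,
                         max_speed_kmh = max_speed_kmh,
                         max_gap_s = max_gap_s)
  compute_gait_features(signal, bouts, low, high, order, step_length_m,
                        filtered = filt)
}

#' Build the cohort feature table
#'
#' The single interchange object between extraction, statistics, and
#' classification: one row per subject with `subject_id`, `group`, the GPS
#' features and the gait features.
#'
#' @param cohort A `cohort` from [generate_cohort()], or a
#'   [cohort_spec()] (then the cohort is generated subject by subject,
#'   keeping memory flat).
#' @return A data frame (`cohort_table`).
#' @export
cohort_features <- function(cohort) {
  if (inherits(cohort, "cohort_spec")) {
    spec <- cohort
    groups <- rep(c("nonfaller", "faller"), each = spec$n_per_group)
    seeds <- .subject_seeds(spec$seed, length(groups))
    rows <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      g <- groups[i]
      gait <- if (g == "faller") spec$faller_gait else spec$nonfaller_gait
      mob <- if (g == "faller") spec$faller_mob else spec$nonfaller_mob
      rp <- .randomize_profiles(gait, mob, spec$heterogeneity, seeds[i, 2])
      s <- .generate_subject(rp$gait, rp$mob, spec$fs, spec$gps_interval,
                             seeds[i, 1], sprintf("S%03d", i))
      rows[[i]] <- cbind(data.frame(subject_id = s$subject_id, group = g),
                         extract_gps_features(s$traj),
                         extract_gait_features(s$accel, s$traj))
    }
    return(do.call(rbind, rows))
  }
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s) {
    cbind(data.frame(subject_id = s$subject_id, group = s$group),
          extract_gps_features(s$traj),
          extract_gait_features(s$accel, s$traj))
  }))
}

#' Plain-text stay report
#'
#' A chronological listing of detected stays (arrival, departure, duration,
#' cluster, home flag) for one subject; the package's text replacement for
#' a daily-mobility timeline plot.
#'
#' @param stay_table A clustered `stay_table` with home set.
#' @return Character vector of report lines, invisibly; also printed.
#' @export
stay_report <- function(stay_table) {
  s <- stay_table$stays
  iso <- function(t) format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
                            "%H:%M")
  lines <- c(sprintf("Stay report for %s (%d stays, home cluster %s)",
                     stay_table$subject_id, nrow(s),
                     stay_table$home_cluster),
             sprintf("%2d. %s-%s (%5.1f min) cluster %d%s  [%.5f, %.5f]",
                     seq_len(nrow(s)), iso(s$arrival), iso(s$departure),
                     (s$departure - s$arrival) / 60, s$cluster,
                     ifelse(!is.na(stay_table$home_cluster) &
                            s$cluster == stay_table$home_cluster,
                            " (home)", ""),
                     s$centroid_lat, s$centroid_lon))
  cat(lines, sep = "\n")
  invisible(lines)
}
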