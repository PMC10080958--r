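#' Analysis configuration
#'
#' Options controlling [analyze_session()]: which retinal regions to
#' sample, offset counts and seeds, whether to run the optical-flow /
#' optokinetic stage (expensive; most useful for locomotion sessions),
#' spectrum subsampling, and the blink source (a trained classifier, or
#' the gaze validity flags as a proxy when no classifier is supplied).
#'
#' @param regions named list of [retinal_region()] specs.
#' @param n_offsets offsets per region.
#' @param seed base RNG seed for offset draws (region `i` uses
#'   `seed + i`).
#' @param classifier a [classifier_config()].
#' @param do_flow run the horizontal-flow / OKN stage.
#' @param do_spectrum compute the average power spectrum.
#' @param spectrum_step analyse every n-th frame for the spectrum.
#' @param aperture_diameters_deg diameters for the aperture-gradient
#'   stage, or `NULL` to skip it.
#' @param blink_model optional trained [train_blink_classifier()] model.
#' @param triggered_window_s half-window of head-triggered eye averages.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(regions = list(
                              fovea = retinal_region("fovea"),
                              periphery = retinal_region("periphery")),
                            n_offsets = 1000,
                            seed = 1,
                            classifier = classifier_config(),
                            do_flow = FALSE,
                            do_spectrum = TRUE,
                            spectrum_step = 25L,
                            aperture_diameters_deg = NULL,
                            blink_model = NULL,
                            triggered_window_s = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "analysis_config"
  cfg
}

#' Analyse one session end to end
#'
#' Runs the full pipeline in the canonical order: classify eye movements,
#' detect blinks, sample gaze-centred luminance for each configured
#' retinal region during fixation/pursuit epochs, compute the
#' spatiotemporal statistics, spectra, visuomotor tables (fixations,
#' saccades, blinks), head-event triggered eye averages, and (optionally)
#' the horizontal-flow / optokinetic-nystagmus stage. Deterministic given
#' the configuration and its seeds.
#'
#' @param session a `session_bundle` or a session directory path.
#' @param config an [analysis_config()].
#' @return An `analysis_report` list with elements `stats` (per region),
#'   `intervals`, `fixations`, `saccades`, `blinks`, `triggered`,
#'   `spectrum`, `aperture`, `flow`, `okn`, and `provenance`.
#' @export
analyze_session <- function(session, config = analysis_config()) {
  if (is.character(session)) session <- load_session(session)
  stopifnot(inherits(session, "session_bundle"))
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  }
  intervals <- stage("classify", classify_eye_movements(session,
                                                        config$classifier))
  report$intervals <- intervals
  report$fixations <- fixation_metrics(intervals)
  report$saccades <- stage("saccades", saccade_metrics(intervals))

  # blinks: CNN when a model is given, validity-gap proxy otherwise
  report$blinks <- stage("blinks", {
    if (!is.null(config$blink_model)) {
      labels <- classify_eye_frames(config$blink_model, session$eye_frames)
      blinks_from_labels(labels$label, rate_hz = session$camera$eye_rate_hz)
    } else {
      b <- blinks_from_labels(!session$gaze$validity,
                              rate_hz = session$camera$eye_rate_hz)
      b$source <- "gaze-validity proxy (no blink classifier supplied)"
      b
    }
  })

  report$stats <- stage("stats", {
    out <- list()
    for (i in seq_along(config$regions)) {
      offs <- draw_region_offsets(config$regions[[i]], config$n_offsets,
                                  seed = config$seed + i)
      L <- gaze_centered_luminance(session, offs, intervals)
      st <- spatio_temporal_stats(L)
      st$mean_intensity <- mean_pixel_intensity(L)$grand_mean
      out[[names(config$regions)[i]]] <- st
    }
    out
  })

  if (!is.null(config$aperture_diameters_deg)) {
    report$aperture <- stage("aperture", {
      mats <- aperture_profile(session, intervals,
                               diameters_deg = config$aperture_diameters_deg,
                               n = config$n_offsets, seed = config$seed + 100)
      lapply(mats, spatio_temporal_stats)
    })
  }

  if (isTRUE(config$do_spectrum)) {
    report$spectrum <- stage("spectrum",
      average_power_spectrum(session$scene_frames, session$camera,
                             frame_step = config$spectrum_step))
  }

  report$triggered <- stage("triggered", {
    ang <- gaze_to_degrees(session$gaze$gp3)
    el <- ang[, 2]; el[!session$gaze$validity] <- NA
    out <- list()
    for (dir in c("up", "down")) {
      ev <- head_velocity_events(session$imu$t, session$imu$gy[, 1], dir)
      out[[dir]] <- tryCatch(
        triggered_eye_average(session$gaze$t, el, ev$times,
                              window_s = config$triggered_window_s,
                              blink_mask = !session$gaze$validity),
        error = function(e) NULL)
    }
    out$pitch_peak_hz <- tryCatch(
      dominant_pitch_frequency(session$imu$t, session$imu$gy[, 1]),
      error = function(e) NA_real_)   # sessions shorter than 5 s
    out
  })

  if (isTRUE(config$do_flow)) {
    report$flow <- stage("flow", average_horizontal_flow(session))
    report$okn <- stage("okn", {
      peaks <- detect_flow_peaks(report$flow)
      ang <- gaze_to_degrees(session$gaze$gp3)
      azd <- ang[, 1]
      segs <- extract_okn_segments(session$gaze$t, azd, peaks$peak_t,
                                   blink_mask = !session$gaze$validity,
                                   rate_hz = session$camera$eye_rate_hz)
      okn <- lapply(segs, okn_amplitude_frequency)
      data.frame(peak_t = vapply(segs, function(s) s$peak_t, 0),
                 n_valid = vapply(segs, function(s) s$n_valid, 0),
                 amplitude = vapply(okn, function(o) o$amplitude, 0),
                 freq_hz = vapply(okn, function(o) o$freq_hz, 0),
                 low_confidence = vapply(okn, function(o) o$low_confidence,
                                         FALSE))
    })
  }

  report$provenance <- list(task_label = session$task_label,
                            duration_s = session$duration_s,
                            seed = config$seed,
                            n_offsets = config$n_offsets,
                            config_hash = config_hash(config),
                            timestamp = "deterministic")
  class(report) <- "analysis_report"
  report
}

# order-independent FNV-1a hash of the serialized configuration
config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)   # xor low byte only
    # 32-bit modular multiply in 16-bit halves (stays exact in doubles)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Write an analysis report as a directory of CSV tables
#'
#' @param report an `analysis_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report_csvs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_intervals_csv(report$intervals, file.path(dir, "intervals.csv"))
  utils::write.csv(report$saccades, file.path(dir, "saccades.csv"),
                   row.names = FALSE)
  utils::write.csv(report$blinks$events, file.path(dir, "blinks.csv"),
                   row.names = FALSE)
  utils::write.csv(report$blinks$rate, file.path(dir, "blink_rate.csv"),
                   row.names = FALSE)
  for (nm in names(report$stats))
    write_stats_csv(report$stats[[nm]], dir, prefix = nm)
  if (!is.null(report$spectrum))
    write_spectrum_csv(report$spectrum, file.path(dir, "spectrum.csv"))
  if (!is.null(report$flow))
    utils::write.csv(report$flow, file.path(dir, "flow.csv"),
                     row.names = FALSE)
  if (!is.null(report$okn))
    utils::write.csv(report$okn, file.path(dir, "okn.csv"),
                     row.names = FALSE)
  prov <- report$provenance
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA),
             file.path(dir, "provenance.json"))
  invisible(dir)
}

#' Compare a metric between two analysis reports
#'
#' Two-tailed Wilcoxon rank-sum (unpaired) test on the per-frame or
#' per-offset values of one metric from two sessions. A paired
#' signed-rank mode is available for matched summaries.
#'
#' @param report_a,report_b `analysis_report`s (or plain numeric vectors).
#' @param metric metric path `"<region>.<stat>"` (e.g. `"fovea.C_S"`);
#'   ignored for vector inputs.
#' @param paired use the signed-rank test on paired values.
#' @return List: `statistic` (rank-sum W or signed-rank V), `p_value`,
#'   `n_a`, `n_b`, `metric`.
#' @export
compare_sessions <- function(report_a, report_b, metric = "fovea.C_S",
                             paired = FALSE) {
  get_vals <- function(rep) {
    if (is.numeric(rep)) return(rep[is.finite(rep)])
    parts <- strsplit(metric, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || is.null(rep$stats[[parts[1]]]))
      stop("metric not found in report: ", metric)
    v <- rep$stats[[parts[1]]][[parts[2]]]
    if (is.null(v)) stop("metric not found in report: ", metric)
    v[is.finite(v)]
  }
  a <- get_vals(report_a); b <- get_vals(report_b)
  # report-level comparisons need a minimally informative sample; raw
  # vectors are accepted down to the exact-test regime (n >= 4)
  min_n <- if (is.numeric(report_a) && is.numeric(report_b)) 4 else 5
  if (length(a) < min_n || length(b) < min_n)
    stop(sprintf("need at least %d finite values per group", min_n))
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                            alternative = "two.sided",
                                            exact = length(a) < 50 &&
                                              length(b) < 50))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(a), n_b = length(b), metric = metric,
       method = wt$method)
}
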