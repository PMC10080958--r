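#' Eye-movement classifier configuration
#'
#' Parameters for the segmented-linear-regression + state-classification
#' pipeline. Velocity priors are Gaussians in log velocity (deg/s) with
#' literature-typical means: fixations drift around 1 deg/s, smooth pursuit
#' near 8 deg/s, saccades near 150 deg/s, and postsaccadic oscillations
#' (PSO) near 30 deg/s. Transition constraints are uniform except that a
#' PSO may only follow a saccade and a saccade may not immediately follow
#' a PSO. The split penalty scales the residual-variance gain a breakpoint
#' must achieve; the exponential duration prior is expressed through the
#' minimum segment length.
#'
#' Velocity priors assume head-free recordings: "fixation" includes the
#' slow (2-4 deg/s) eye-in-head drift of vestibulo-ocular compensation,
#' so its prior mean is 2 deg/s rather than the sub-deg/s values typical
#' of head-fixed work; pursuit (and the slow phases of optokinetic
#' nystagmus) centre near 12 deg/s.
#'
#' @param velocity_prior_mean named numeric, prior mean velocity per state
#'   (deg/s; internally log-transformed).
#' @param velocity_prior_sd named numeric, prior sd in log-velocity units.
#' @param angle_prior_mean,angle_prior_sd priors on the intersegment
#'   direction change (degrees, 0 = continuation, 180 = reversal).
#' @param angle_weight weight of the angle term relative to velocity.
#' @param split_penalty breakpoint acceptance penalty (multiples of the
#'   estimated noise variance).
#' @param saccade_seed_dps central-difference speed (deg/s) above which a
#'   sample run is forced into its own segment, so brief saccades survive
#'   segmentation at 50 Hz.
#' @param transition_matrix 4 x 4 state transition probabilities (rows =
#'   from, columns = to) encoding oculomotor structure: fixations and
#'   pursuit are persistent, saccades are brief and usually return to
#'   fixation (possibly via a PSO), a PSO only follows a saccade and is
#'   never followed directly by another saccade. Zero entries are
#'   forbidden transitions.
#' @param initial_probs state probabilities at a chunk start.
#' @param viterbi if `TRUE` (default) decode the full sequence with the
#'   Viterbi algorithm; otherwise use a greedy left-to-right
#'   maximum-posterior pass.
#' @param min_seg_samples minimum samples per segment.
#' @param max_gap_s gaps in valid samples longer than this split the trace.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(velocity_prior_mean = c(fixation = 2,
                                                      smooth_pursuit = 12,
                                                      saccade = 150,
                                                      pso = 30),
                              velocity_prior_sd = c(fixation = 1.0,
                                                    smooth_pursuit = 0.7,
                                                    saccade = 0.8,
                                                    pso = 0.7),
                              angle_prior_mean = c(fixation = 90,
                                                   smooth_pursuit = 0,
                                                   saccade = 0,
                                                   pso = 180),
                              angle_prior_sd = c(fixation = 360,
                                                 smooth_pursuit = 60,
                                                 saccade = 90,
                                                 pso = 90),
                              angle_weight = 0.2,
                              split_penalty = 25,
                              saccade_seed_dps = 30,
                              transition_matrix = default_em_transitions(),
                              initial_probs = c(fixation = 0.6,
                                                saccade = 0.2,
                                                smooth_pursuit = 0.2,
                                                pso = 0),
                              viterbi = TRUE,
                              min_seg_samples = 2L,
                              max_gap_s = 0.04) {
  cfg <- list(velocity_prior_mean = velocity_prior_mean,
              velocity_prior_sd = velocity_prior_sd,
              angle_prior_mean = angle_prior_mean,
              angle_prior_sd = angle_prior_sd,
              angle_weight = angle_weight,
              split_penalty = split_penalty,
              saccade_seed_dps = saccade_seed_dps,
              transition_matrix = transition_matrix,
              initial_probs = initial_probs,
              viterbi = isTRUE(viterbi),
              min_seg_samples = as.integer(min_seg_samples),
              max_gap_s = max_gap_s)
  class(cfg) <- "classifier_config"
  cfg
}

em_states <- c("fixation", "saccade", "smooth_pursuit", "pso")

#' Default eye-movement state transition table
#'
#' Probabilities reflect the temporal structure of natural gaze: saccades
#' last one or two segments and end in fixation (or a postsaccadic
#' oscillation); fixations and pursuit persist over several segments; a
#' PSO can only follow a saccade and never leads straight into one.
#'
#' @return A 4 x 4 row-stochastic matrix over
#'   fixation/saccade/smooth_pursuit/pso.
#' @export
default_em_transitions <- function() {
  m <- matrix(c(
    # to: fixation, saccade, smooth_pursuit, pso   (from:)
    0.60, 0.30, 0.10, 0.00,   # fixation
    0.50, 0.15, 0.10, 0.25,   # saccade
    0.25, 0.20, 0.55, 0.00,   # smooth_pursuit
    0.60, 0.00, 0.25, 0.15),  # pso
    nrow = 4, byrow = TRUE, dimnames = list(em_states, em_states))
  m
}

#' Piecewise-linear segmentation of a gaze trace
#'
#' Reconstructs the horizontal/vertical gaze-angle trace as a sequence of
#' linear segments by minimizing the difference between the original
#' recording and the reconstructed segments: the joint (azimuth +
#' elevation) squared reconstruction error plus a per-segment penalty of
#' `split_penalty * sigma2` is minimized exactly by dynamic programming,
#' where `sigma2` is a robust estimate of the sample noise variance from
#' second differences. A breakpoint is therefore only introduced where it
#' buys more error reduction than the penalty -- the penalty plays the
#' role of a prior against over-segmentation -- and very short segments
#' are excluded by the minimum-length constraint. Invalid samples and
#' gaps longer than `max_gap_s` split the trace unconditionally; no
#' segment spans a gap.
#'
#' @param t sample times (s).
#' @param azimuth,elevation gaze angles (degrees); `NA` marks invalid
#'   samples.
#' @param config a [classifier_config()].
#' @return A `gaze_segmentation`: data.frame of segments with columns
#'   `i0`, `i1` (sample indices), `start_s`, `end_s`, `slope_az`,
#'   `slope_el`, `velocity_dps`, `rss`, `chunk`.
#' @export
segment_piecewise_linear <- function(t, azimuth, elevation,
                                     config = classifier_config()) {
  ok <- is.finite(t) & is.finite(azimuth) & is.finite(elevation)
  if (sum(ok) < 10) stop("need at least 10 valid gaze samples")
  # contiguous valid chunks, split at invalid samples or long gaps
  idx <- which(ok)
  brk <- which(diff(t[idx]) > config$max_gap_s | diff(idx) > 1L)
  chunk_id <- cumsum(c(1L, seq_along(idx)[-1] %in% (brk + 1L)))
  segs <- list()
  for (ch in unique(chunk_id)) {
    ci <- idx[chunk_id == ch]
    if (length(ci) < 2L) next
    tt <- t[ci]; az <- azimuth[ci]; el <- elevation[ci]
    m <- length(ci)
    sigma2 <- robust_noise_var(az) + robust_noise_var(el)
    sigma2 <- max(sigma2, 1e-10)
    # central-difference speed seeds breakpoints at high-velocity runs, so
    # brief saccades cannot be absorbed into neighbouring slow segments.
    # A genuinely in-flight sample moves on BOTH sides; requiring the
    # smaller one-sided speed too keeps plateau samples next to a saccade
    # from being swallowed into the fast run.
    speed <- rep(0, m)
    minside <- rep(Inf, m)
    if (m >= 3) {
      dt2 <- tt[3:m] - tt[1:(m - 2)]
      speed[2:(m - 1)] <- sqrt(((az[3:m] - az[1:(m - 2)]) / dt2)^2 +
                                 ((el[3:m] - el[1:(m - 2)]) / dt2)^2)
      dstep <- sqrt(diff(az)^2 + diff(el)^2) / diff(tt)
      minside[2:(m - 1)] <- pmin(dstep[1:(m - 2)], dstep[2:(m - 1)])
    }
    fast <- speed > config$saccade_seed_dps &
      minside > 0.4 * config$saccade_seed_dps
    r <- rle(fast)
    r_end <- cumsum(r$lengths); r_start <- r_end - r$lengths + 1L
    bounds <- c(1L, r_start[r$values], r_end[r$values] + 1L, m + 1L)
    bounds <- sort(unique(pmin(bounds, m + 1L)))
    for (k in seq_len(length(bounds) - 1L)) {
      s0 <- bounds[k]; s1 <- bounds[k + 1L] - 1L
      span <- s1 - s0 + 1L
      if (!fast[s0] && span >= 2L * config$min_seg_samples) {
        sub <- dp_segments(tt[s0:s1], az[s0:s1], el[s0:s1],
                           config$min_seg_samples,
                           config$split_penalty * sigma2) + s0 - 1L
      } else sub <- s0
      sub_bounds <- c(sub, s1 + 1L)
      dt_med <- stats::median(diff(tt))
      for (q in seq_len(length(sub_bounds) - 1L)) {
        q0 <- sub_bounds[q]; q1 <- sub_bounds[q + 1L] - 1L
        fit_a <- lm_slope(tt[q0:q1], az[q0:q1])
        fit_e <- lm_slope(tt[q0:q1], el[q0:q1])
        vel <- sqrt(fit_a$slope^2 + fit_e$slope^2)
        # standard error of the fitted slope given the sample noise level:
        # short segments carry little velocity information
        tc2 <- sum((tt[q0:q1] - mean(tt[q0:q1]))^2)
        vel_se <- if (tc2 > 0) sqrt(sigma2 / tc2) else sqrt(sigma2) / dt_med
        if (q1 == q0) vel <- speed[q0]   # 1-sample segment: sample speed
        segs[[length(segs) + 1L]] <- data.frame(
          i0 = ci[q0], i1 = ci[q1], start_s = tt[q0], end_s = tt[q1],
          slope_az = fit_a$slope, slope_el = fit_e$slope,
          velocity_dps = vel, vel_se_dps = vel_se,
          rss = fit_a$rss + fit_e$rss, chunk = ch)
      }
    }
  }
  if (!length(segs)) stop("gaze trace is entirely invalid")
  out <- do.call(rbind, segs)
  # intersegment direction change (deg), NA at chunk starts
  ang <- rep(NA_real_, nrow(out))
  if (nrow(out) > 1) {
    for (k in 2:nrow(out)) {
      if (out$chunk[k] == out$chunk[k - 1]) {
        v1 <- c(out$slope_az[k - 1], out$slope_el[k - 1])
        v2 <- c(out$slope_az[k], out$slope_el[k])
        n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
        if (n1 > 0 && n2 > 0)
          ang[k] <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
      }
    }
  }
  out$intersegment_angle <- ang
  class(out) <- c("gaze_segmentation", class(out))
  out
}

# robust per-sample noise variance from second differences
robust_noise_var <- function(x) {
  if (length(x) < 3) return(0)
  d2 <- diff(x, differences = 2)
  stats::median(d2^2) / 6
}

lm_slope <- function(t, y) {
  n <- length(y)
  if (n == 1) return(list(slope = 0, rss = 0))
  tc <- t - mean(t)
  den <- sum(tc^2)
  slope <- if (den == 0) 0 else sum(tc * (y - mean(y))) / den
  res <- y - mean(y) - slope * tc
  list(slope = slope, rss = sum(res^2))
}

# exact penalized least-squares segmentation by dynamic programming:
# minimizes sum of per-segment linear-fit SSE + beta per segment, with a
# minimum segment length. Returns sorted segment start indices.
dp_segments <- function(t, az, el, min_len, beta) {
  n <- length(t)
  ps <- prefix_sums(t, az, el)
  D <- rep(Inf, n + 1); D[1] <- 0       # D[j + 1]: best cost of prefix j
  prev <- integer(n + 1)
  for (j in seq_len(n)) {
    if (j < min_len) next
    is <- 1:(j - min_len + 1L)
    costs <- D[is] + interval_sse_vec(ps, is, j) + beta
    k <- which.min(costs)
    D[j + 1] <- costs[k]; prev[j + 1] <- is[k]
  }
  starts <- integer(0); j <- n
  while (j >= 1) { s <- prev[j + 1]; starts <- c(s, starts); j <- s - 1L }
  starts
}

prefix_sums <- function(t, az, el) {
  list(t = c(0, cumsum(t)), t2 = c(0, cumsum(t^2)),
       a = c(0, cumsum(az)), a2 = c(0, cumsum(az^2)),
       ta = c(0, cumsum(t * az)),
       e = c(0, cumsum(el)), e2 = c(0, cumsum(el^2)),
       te = c(0, cumsum(t * el)))
}

# SSE of per-axis linear fits on [i0, i1], O(1) via prefix sums (vectorized)
interval_sse_vec <- function(ps, i0, i1) {
  n <- i1 - i0 + 1
  st <- ps$t[i1 + 1] - ps$t[i0]; st2 <- ps$t2[i1 + 1] - ps$t2[i0]
  sxx <- st2 - st^2 / n
  sse_axis <- function(sy, sy2, sty) {
    syy <- sy2 - sy^2 / n
    sxy <- sty - st * sy / n
    ifelse(sxx <= 0, syy, pmax(0, syy - sxy^2 / sxx))
  }
  sa <- ps$a[i1 + 1] - ps$a[i0]; sa2 <- ps$a2[i1 + 1] - ps$a2[i0]
  sta <- ps$ta[i1 + 1] - ps$ta[i0]
  se <- ps$e[i1 + 1] - ps$e[i0]; se2 <- ps$e2[i1 + 1] - ps$e2[i0]
  ste <- ps$te[i1 + 1] - ps$te[i0]
  sse_axis(sa, sa2, sta) + sse_axis(se, se2, ste)
}

interval_sse <- function(ps, i0, i1) interval_sse_vec(ps, i0, i1)

#' Classify gaze segments into eye-movement states
#'
#' Assigns each linear segment the maximum-posterior state given the
#' log-velocity and intersegment-angle priors and the transition
#' constraints (PSO only immediately after a saccade; no saccade
#' immediately after a PSO), in a deterministic left-to-right pass.
#' Contiguous segments with the same label are merged into intervals.
#'
#' @param seg a `gaze_segmentation` from [segment_piecewise_linear()].
#' @param config a [classifier_config()].
#' @param azimuth,elevation optional gaze angle vectors used to compute
#'   interval amplitudes from endpoint positions; slopes are used if
#'   omitted.
#' @return Data.frame of `eye_movement_interval`s: `label`, `start_s`,
#'   `end_s`, `mean_velocity_dps`, `amplitude_deg`.
#' @export
classify_segments <- function(seg, config = classifier_config(),
                              azimuth = NULL, elevation = NULL) {
  stopifnot(inherits(seg, "gaze_segmentation"))
  n <- nrow(seg)
  eps <- 1e-3
  # per-segment emission log-likelihoods
  emis <- matrix(0, n, 4, dimnames = list(NULL, em_states))
  vel_se <- if ("vel_se_dps" %in% names(seg)) seg$vel_se_dps else rep(0, n)
  for (k in seq_len(n)) {
    lv <- log(seg$velocity_dps[k] + eps)
    # widen the prior by the log-scale measurement error of this
    # segment's velocity estimate
    se_log <- log1p(vel_se[k] / max(seg$velocity_dps[k], eps))
    sds <- sqrt(config$velocity_prior_sd[em_states]^2 + se_log^2)
    ll <- stats::dnorm(lv, log(config$velocity_prior_mean[em_states]),
                       sds, log = TRUE)
    if (is.finite(seg$intersegment_angle[k])) {
      ll <- ll + config$angle_weight *
        stats::dnorm(seg$intersegment_angle[k],
                     config$angle_prior_mean[em_states],
                     config$angle_prior_sd[em_states], log = TRUE)
    }
    emis[k, ] <- ll
  }
  trans <- log(config$transition_matrix[em_states, em_states])
  init <- log(config$initial_probs[em_states])
  lab <- character(n)
  chunks <- unique(seg$chunk)
  for (ch in chunks) {
    kk <- which(seg$chunk == ch)
    m <- length(kk)
    if (config$viterbi) {
      score <- matrix(-Inf, m, 4); back <- matrix(0L, m, 4)
      score[1, ] <- emis[kk[1], ] + init
      if (m > 1) for (q in 2:m) for (s in 1:4) {
        cand <- score[q - 1, ] + trans[, s]
        back[q, s] <- which.max(cand)
        score[q, s] <- cand[back[q, s]] + emis[kk[q], s]
      }
      s <- which.max(score[m, ])
      for (q in m:1) { lab[kk[q]] <- em_states[s]; s <- back[q, s] }
    } else {
      # greedy left-to-right maximum-posterior pass
      prev <- 0L
      for (q in seq_len(m)) {
        ll <- emis[kk[q], ]
        if (prev == 0L) ll <- ll + init else ll <- ll + trans[prev, ]
        prev <- which.max(ll)
        lab[kk[q]] <- em_states[prev]
      }
    }
  }
  # merge contiguous same-label segments within a chunk
  grp <- cumsum(c(1L, (lab[-1] != lab[-n]) | (seg$chunk[-1] != seg$chunk[-n])))
  out <- do.call(rbind, lapply(split(seq_len(n), grp), function(ii) {
    i0 <- seg$i0[ii[1]]; i1 <- seg$i1[ii[length(ii)]]
    dur <- seg$end_s[ii[length(ii)]] - seg$start_s[ii[1]]
    if (!is.null(azimuth)) {
      amp <- sqrt((azimuth[i1] - azimuth[i0])^2 +
                    (elevation[i1] - elevation[i0])^2)
    } else {
      amp <- sum(seg$velocity_dps[ii] * (seg$end_s[ii] - seg$start_s[ii]))
    }
    data.frame(label = lab[ii[1]], start_s = seg$start_s[ii[1]],
               end_s = seg$end_s[ii[length(ii)]],
               mean_velocity_dps = if (dur > 0)
                 sum(seg$velocity_dps[ii] * (seg$end_s[ii] - seg$start_s[ii])) / dur
               else seg$velocity_dps[ii[1]],
               amplitude_deg = amp, i0 = i0, i1 = i1,
               chunk = seg$chunk[ii[1]])
  }))
  rownames(out) <- NULL
  class(out) <- c("eye_movement_intervals", class(out))
  out
}

#' Full gaze classification for a session
#'
#' Converts the session's 3-D gaze stream to visual angles, segments it,
#' classifies the segments, and refines saccade onset/offset boundaries
#' at sample resolution (a 40 ms saccade straddles sample boundaries at
#' 50 Hz; boundary samples are reassigned by whether their position is
#' statistically distinguishable from the neighbouring fixation
#' plateaus). Blink/tracking-loss samples (invalid flags) split the
#' trace.
#'
#' @param session a `session_bundle`.
#' @param config a [classifier_config()].
#' @return `eye_movement_intervals` data.frame (see [classify_segments()]).
#' @export
classify_eye_movements <- function(session, config = classifier_config()) {
  g <- session$gaze
  ang <- gaze_to_degrees(g$gp3)
  az <- ang[, 1]; el <- ang[, 2]
  az[!g$validity] <- NA; el[!g$validity] <- NA
  seg <- segment_piecewise_linear(g$t, az, el, config)
  iv <- classify_segments(seg, config, azimuth = az, elevation = el)
  refine_saccade_boundaries(iv, g$t, az, el)
}

# move +/- 1 sample at each saccade boundary to the side its position
# supports: a sample belongs to the flight phase iff it is farther than
# max(2*noise_sd, 10% of amplitude) from both neighbouring plateaus
refine_saccade_boundaries <- function(iv, t, az, el) {
  sigma <- sqrt(max(robust_noise_var(az[is.finite(az)]) +
                      robust_noise_var(el[is.finite(el)]), 1e-12))
  plateau <- function(idx) c(mean(az[idx], na.rm = TRUE),
                             mean(el[idx], na.rm = TRUE))
  d2 <- function(i, p) sqrt((az[i] - p[1])^2 + (el[i] - p[2])^2)
  n <- nrow(iv)
  for (k in seq_len(n)) {
    if (iv$label[k] != "saccade") next
    has_prev <- k > 1 && iv$chunk[k - 1] == iv$chunk[k] &&
      iv$label[k - 1] != "saccade"
    has_next <- k < n && iv$chunk[k + 1] == iv$chunk[k] &&
      iv$label[k + 1] != "saccade"
    if (!has_prev || !has_next) next
    # one-sample moves only: at 50 Hz the onset/offset ambiguity is +/- 1
    # sample, and fixation plateaus may drift (vestibulo-ocular
    # compensation), so larger moves are not supported by the data.
    # Extension requires clear separation from both plateaus; trimming
    # requires the sample to sit within one noise sd of a plateau.
    c_on <- iv$i1[k - 1]
    pA <- plateau(max(iv$i0[k - 1], c_on - 2):max(iv$i0[k - 1], c_on - 1))
    c_off <- iv$i0[k + 1]
    pB <- plateau(min(iv$i1[k + 1], c_off + 1):min(iv$i1[k + 1], c_off + 2))
    amp <- sqrt(sum((pB - pA)^2))
    # maximum-likelihood boundary: in-flight positions are ~uniform over
    # the amplitude, plateau positions ~Gaussian(sd sig_ax per axis); a
    # sample is in-flight iff its plateau distance exceeds the density
    # crossover
    sig_ax <- sigma / sqrt(2)
    thr <- sig_ax * sqrt(2 * max(log(amp / (2 * pi * sig_ax^2)), 1))
    if (iv$i1[k - 1] > iv$i0[k - 1] && is.finite(az[c_on]) &&
        d2(c_on, pA) > thr && d2(c_on, pB) > thr) {
      iv$i1[k - 1] <- c_on - 1L; iv$i0[k] <- c_on
    } else if (iv$i0[k] < iv$i1[k] && is.finite(az[iv$i0[k]]) &&
               d2(iv$i0[k], pA) <= thr) {
      iv$i1[k - 1] <- iv$i0[k]; iv$i0[k] <- iv$i0[k] + 1L
    }
    if (is.finite(az[c_off]) &&
        d2(c_off, pA) > thr && d2(c_off, pB) > thr) {
      iv$i0[k + 1] <- c_off + 1L; iv$i1[k] <- c_off   # may empty k + 1
    } else if (iv$i1[k] > iv$i0[k] && is.finite(az[iv$i1[k]]) &&
               d2(iv$i1[k], pB) <= thr) {
      iv$i0[k + 1] <- iv$i1[k]; iv$i1[k] <- iv$i1[k] - 1L
    }
  }
  iv <- iv[iv$i0 <= iv$i1, , drop = FALSE]
  rownames(iv) <- NULL
  n <- nrow(iv)
  # intervals tile each chunk: an interval ends where the next begins;
  # the last interval of a chunk extends one frame period past its final
  # sample
  dt <- stats::median(diff(t))
  iv$start_s <- t[iv$i0]
  iv$end_s <- t[iv$i1] + dt
  nn <- nrow(iv)
  if (nn > 1) {
    same <- iv$chunk[-nn] == iv$chunk[-1]
    iv$end_s[-nn][same] <- iv$start_s[-1][same]
  }
  # saccade amplitude measured plateau-to-plateau (flanking samples)
  i_lo <- pmax(iv$i0 - 1L, 1L); i_hi <- pmin(iv$i1 + 1L, length(t))
  if (nn > 1) {
    bad_lo <- c(TRUE, iv$chunk[-1] != iv$chunk[-nn])
    bad_hi <- c(iv$chunk[-nn] != iv$chunk[-1], TRUE)
    i_lo[bad_lo] <- iv$i0[bad_lo]; i_hi[bad_hi] <- iv$i1[bad_hi]
  }
  amp <- sqrt((az[i_hi] - az[i_lo])^2 + (el[i_hi] - el[i_lo])^2)
  dur <- pmax(iv$end_s - iv$start_s, 1e-9)
  sel <- iv$label == "saccade" & is.finite(amp)
  iv$amplitude_deg[sel] <- amp[sel]
  iv$mean_velocity_dps[sel] <- amp[sel] / dur[sel]
  iv
}

#' Per-sample labels implied by an interval table
#'
#' @param intervals `eye_movement_intervals`.
#' @param t times to label.
#' @return Character vector of labels (`NA` outside any interval).
#' @export
interval_labels_at <- function(intervals, t) {
  lab <- rep(NA_character_, length(t))
  for (k in seq_len(nrow(intervals)))
    lab[t >= intervals$start_s[k] & t <= intervals$end_s[k]] <- intervals$label[k]
  lab
}

#' Saccade amplitude and velocity metrics
#'
#' Amplitude is the Euclidean combination of the horizontal and vertical
#' displacement, `sqrt(dh^2 + dv^2)`; velocity is amplitude divided by
#' duration. PSOs are not merged into their parent saccade.
#'
#' @param intervals `eye_movement_intervals`.
#' @param azimuth,elevation optional gaze angle vectors indexed by the
#'   intervals' `i0`/`i1` sample indices; the stored amplitudes are used if
#'   omitted.
#' @return Data.frame with one row per saccade: `start_s`, `end_s`,
#'   `amplitude_deg`, `velocity_dps`.
#' @export
saccade_metrics <- function(intervals, azimuth = NULL, elevation = NULL) {
  sac <- intervals[intervals$label == "saccade", , drop = FALSE]
  if (nrow(sac) == 0) return(data.frame(start_s = numeric(0), end_s = numeric(0),
                                        amplitude_deg = numeric(0),
                                        velocity_dps = numeric(0)))
  dur <- sac$end_s - sac$start_s
  if (any(dur <= 0)) stop("zero-duration saccade interval")
  amp <- if (!is.null(azimuth)) {
    sqrt((azimuth[sac$i1] - azimuth[sac$i0])^2 +
           (elevation[sac$i1] - elevation[sac$i0])^2)
  } else sac$amplitude_deg
  data.frame(start_s = sac$start_s, end_s = sac$end_s,
             amplitude_deg = amp, velocity_dps = amp / dur)
}

#' Fixation (and smooth-pursuit) durations
#'
#' Stable-projection epochs: fixations and smooth-pursuit intervals both
#' count, since both hold the image steady on the retina.
#'
#' @param intervals `eye_movement_intervals`.
#' @return List with `durations_s` and `count`.
#' @export
fixation_metrics <- function(intervals) {
  fx <- intervals[intervals$label %in% c("fixation", "smooth_pursuit"), ,
                  drop = FALSE]
  list(durations_s = fx$end_s - fx$start_s, count = nrow(fx))
}

#' Write an interval table as CSV
#' @param intervals `eye_movement_intervals`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intervals_csv <- function(intervals, path) {
  utils::write.csv(intervals[, c("start_s", "end_s", "label",
                                 "amplitude_deg", "mean_velocity_dps")],
                   path, row.names = FALSE)
  invisible(path)
}
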