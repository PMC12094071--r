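#' Subtract the media-only background from a fluorescence signal
#'
#' Elementwise background correction: the fluorescence intensity (FI) of a
#' fluorophore is its raw signal minus the signal of a media-only control
#' well at the same timepoint. Negative results are retained, not clamped
#' (clamping would bias downstream ratios for low expressers), and marked in
#' the \code{"low_signal"} attribute.
#'
#' @param signal Numeric vector of raw fluorescence (AU).
#' @param media_control Numeric vector of the media-only control, same length.
#' @return Numeric FI vector with a logical \code{"low_signal"} attribute
#'   marking timepoints that fell below the media background.
#' @export
background_correct <- function(signal, media_control) {
  if (length(signal) != length(media_control)) {
    stop("signal and media control have different lengths", call. = FALSE)
  }
  fi <- signal - media_control
  attr(fi, "low_signal") <- fi < 0
  fi
}

#' Biomass-normalized reporter signal (RFU)
#'
#' The promoter-driven mCherry FI is divided elementwise by the FI of the
#' constitutively expressed genomic GFP, which tracks biomass. Timepoints
#' where the GFP FI does not exceed a positivity floor are masked as
#' \code{NA}; if every timepoint is masked there is no usable signal.
#'
#' @param fi_mcherry,fi_gfp Background-corrected FI vectors.
#' @param eps Positivity floor for the GFP denominator (signal units).
#' @return RFU vector (mCherry/GFP), \code{NA} where masked.
#' @export
compute_rfu <- function(fi_mcherry, fi_gfp, eps = 1e-9) {
  if (length(fi_mcherry) != length(fi_gfp)) {
    stop("FI vectors have different lengths", call. = FALSE)
  }
  rfu <- ifelse(fi_gfp > eps, fi_mcherry / fi_gfp, NA_real_)
  if (all(is.na(rfu))) {
    stop("no usable signal: GFP FI never exceeds the positivity floor",
         call. = FALSE)
  }
  rfu
}

#' Savitzky-Golay smoothing of a measurement series
#'
#' Local least-squares polynomial smoothing; polynomials of degree at most
#' \code{polyorder} pass through unchanged, so essential curve features
#' (inflection, plateau height) are preserved while high-frequency noise is
#' attenuated. Output has the same length as the input.
#'
#' @param values Numeric vector.
#' @param window Odd filter width in samples (default 11).
#' @param polyorder Polynomial degree, less than \code{window} (default 3).
#' @return Smoothed numeric vector.
#' @export
smooth_series <- function(values, window = 11L, polyorder = 3L) {
  if (window %% 2L == 0L || window <= polyorder) {
    stop("window must be odd and greater than polyorder", call. = FALSE)
  }
  if (window > length(values)) {
    stop("window (", window, ") exceeds series length (", length(values), ")",
         call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(values, p = polyorder, n = window))
}

# central-difference slope on a possibly non-uniform grid
central_slope <- function(y, t) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

#' Locate the mid-exponential and stationary timepoints of a growth curve
#'
#' The mid-exponential timepoint is where the (smoothed) OD600 has its
#' maximum slope — for a logistic curve this is the inflection at the
#' half-capacity point. The stationary timepoint is the earliest time
#' attaining the maximum smoothed OD. Pass the OD through
#' \code{\link{smooth_series}} first; this function does not smooth.
#'
#' @param od_series Smoothed OD600 vector (>= 5 points).
#' @param time Strictly increasing time vector (hours).
#' @param plateau_frac The slope search is restricted to samples below this
#'   fraction of the OD range (default 0.95): the mid-exponential point lies
#'   below the stationary plateau by definition, and excluding the plateau
#'   keeps residual noise there (largest at the filter's one-sided edges)
#'   from masquerading as growth.
#' @return List with \code{t_midexp} and \code{t_stat} (hours). A curve that
#'   is still rising at the last sample gets \code{t_stat} = final timepoint
#'   with a warning.
#' @export
find_growth_phases <- function(od_series, time, plateau_frac = 0.95) {
  n <- length(od_series)
  if (n < 5L || length(time) != n) {
    stop("need >= 5 matched OD/time points", call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  rng <- max(od_series) - min(od_series)
  if (!is.finite(rng) || rng < 1e-12 * max(abs(od_series), 1)) {
    stop("phase detection failed: OD series is flat", call. = FALSE)
  }
  slope <- central_slope(od_series, time)
  if (max(slope) <= 0) {
    stop("phase detection failed: OD series never increases", call. = FALSE)
  }
  # the slope of a noisy series is noisier still; re-smooth it before the
  # argmax so the maximum reflects the curve, not pointwise jitter
  if (n >= 11L) slope <- smooth_series(slope, 11L, 3L)
  # search only up to the first time the curve reaches the plateau band:
  # the mid-exponential point precedes stationary phase by definition, and
  # this keeps residual plateau noise out of the argmax
  cross <- which(od_series >= min(od_series) + plateau_frac * rng)[1]
  eligible <- seq_len(max(cross, 3L))
  i_mid <- eligible[which.max(slope[eligible])]
  i_stat <- which(od_series == max(od_series))[1]
  if (i_stat == n) {
    warning("OD still rising at the final sample; stationary timepoint set ",
            "to the end of the series", call. = FALSE)
  }
  list(t_midexp = time[i_mid], t_stat = time[i_stat])
}

window_mean <- function(x, i, half) {
  idx <- max(1L, i - half):min(length(x), i + half)
  mean(x[idx], na.rm = TRUE)
}

#' Differential activity between growth phases
#'
#' Ratio of the biomass-normalized reporter signal (RFU) at the
#' mid-exponential timepoint to the RFU at the stationary timepoint,
#' each averaged over a symmetric window of samples. Values below ~0.7
#' indicate stationary-biased promoters, above ~1.3 exponential-biased
#' (see \code{\link{classify_phase_bias}}).
#'
#' @param rfu RFU vector.
#' @param time Time vector (hours), same length.
#' @param t_midexp,t_stat Phase timepoints from
#'   \code{\link{find_growth_phases}}; must lie in the time range.
#' @param window Odd number of samples averaged around each timepoint
#'   (default 3; 1 = point estimate).
#' @return The differential-activity ratio (positive scalar).
#' @export
differential_activity <- function(rfu, time, t_midexp, t_stat, window = 3L) {
  if (length(rfu) != length(time)) stop("length mismatch", call. = FALSE)
  if (t_midexp < min(time) || t_midexp > max(time) ||
      t_stat < min(time) || t_stat > max(time)) {
    stop("phase timepoints outside the measured time range", call. = FALSE)
  }
  half <- (as.integer(window) - 1L) %/% 2L
  i_mid <- which.min(abs(time - t_midexp))
  i_stat <- which.min(abs(time - t_stat))
  num <- window_mean(rfu, i_mid, half)
  den <- window_mean(rfu, i_stat, half)
  if (!is.finite(den) || den <= 0) {
    stop("undefined ratio: stationary-phase RFU is not positive", call. = FALSE)
  }
  num / den
}

#' Classify a promoter's temporal bias from its differential activity
#'
#' Ratios strictly below \code{low} mark promoters more active in the
#' stationary phase; strictly above \code{high}, more active in the
#' exponential phase; the boundary values themselves classify as unbiased.
#'
#' @param ratio Positive differential-activity ratio.
#' @param low,high Class thresholds (defaults 0.7 and 1.3).
#' @return One of \code{"stationary_biased"}, \code{"unbiased"},
#'   \code{"exponential_biased"} (vectorized over \code{ratio}).
#' @export
classify_phase_bias <- function(ratio, low = 0.7, high = 1.3) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("differential activity must be positive", call. = FALSE)
  }
  ifelse(ratio < low, "stationary_biased",
         ifelse(ratio > high, "exponential_biased", "unbiased"))
}

#' Decide whether a strain shows detectable reporter expression
#'
#' A strain counts as detectable when its stationary-phase RFU exceeds the
#' background strain's RFU by more than \code{k} standard deviations above
#' the background mean. The background statistics are taken over the
#' background strain's full (unmasked) RFU series.
#'
#' @param stationary_rfu The strain's stationary-phase RFU (scalar).
#' @param background_rfu RFU vector of the reporter-free background strain.
#' @param k Detection stringency in background SDs (default 3).
#' @return Logical.
#' @export
detect_active <- function(stationary_rfu, background_rfu, k = 3) {
  if (is.null(background_rfu) || all(is.na(background_rfu))) {
    stop("missing background-strain profile", call. = FALSE)
  }
  mu <- mean(background_rfu, na.rm = TRUE)
  sdv <- stats::sd(background_rfu, na.rm = TRUE)
  isTRUE(stationary_rfu > mu + k * sdv)
}

#' Default flow-cytometry quadrant gate
#'
#' Closed AU intervals splitting the sorted subpopulation into four
#' quadrants: genomic-GFP "high green" 100,000-500,000 AU, "low green"
#' 25,000-70,000 AU; reporter-mCherry "high red" 8,000-90,000 AU, "low red"
#' 3,500-4,000 AU.
#'
#' @return A \code{quadrant_gate} list of interval pairs.
#' @export
default_quadrant_gate <- function() {
  structure(list(green_high = c(100000, 500000),
                 green_low = c(25000, 70000),
                 red_high = c(8000, 90000),
                 red_low = c(3500, 4000)),
            class = "quadrant_gate")
}

#' Assign flow-cytometry events to fluorescence quadrants
#'
#' Membership is a closed-interval test on both channels; an event whose
#' green or red value falls in neither interval of that channel is
#' \code{"ungated"}.
#'
#' @param gfp_au,mcherry_au Nonnegative event intensities (vectors, AU).
#' @param gate A \code{\link{default_quadrant_gate}}-style gate.
#' @return Character vector over \{"HH","HL","LH","LL","ungated"\}; the first
#'   letter is the green level, the second the red level.
#' @export
gate_quadrant <- function(gfp_au, mcherry_au, gate = default_quadrant_gate()) {
  if (length(gfp_au) != length(mcherry_au)) stop("length mismatch", call. = FALSE)
  if (any(gfp_au < 0) || any(mcherry_au < 0)) {
    stop("event intensities must be nonnegative", call. = FALSE)
  }
  in_iv <- function(x, iv) x >= iv[1] & x <= iv[2]
  green <- ifelse(in_iv(gfp_au, gate$green_high), "H",
                  ifelse(in_iv(gfp_au, gate$green_low), "L", NA))
  red <- ifelse(in_iv(mcherry_au, gate$red_high), "H",
                ifelse(in_iv(mcherry_au, gate$red_low), "L", NA))
  ifelse(is.na(green) | is.na(red), "ungated", paste0(green, red))
}

#' Derive a full activity profile for one strain
#'
#' Runs the complete normalization arc for one plate-reader series:
#' media-background correction of both channels, GFP normalization to RFU,
#' Savitzky-Golay smoothing, growth-phase timepointing on the smoothed OD,
#' windowed differential activity and three-way classification, plus a
#' detectability call against the background strain when provided.
#'
#' @param time,od600,mcherry,gfp Measurement vectors for the strain.
#' @param media_mcherry,media_gfp Media-control vectors (same timebase).
#' @param background_rfu Optional RFU vector of the reporter-free background
#'   strain for the detectability call.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters (defaults 11, 3).
#' @param ratio_window Samples averaged around each phase timepoint.
#' @param low,high Classification thresholds.
#' @param k Detectability stringency in background SDs.
#' @param eps GFP positivity floor.
#' @return List of class \code{activity_profile}: FI and RFU series,
#'   \code{t_midexp}, \code{t_stat}, RFU at both phases,
#'   \code{differential_activity}, \code{phase_class}, \code{detectable}.
#' @export
activity_profile <- function(time, od600, mcherry, gfp, media_mcherry,
                             media_gfp, background_rfu = NULL,
                             sg_window = 11L, sg_polyorder = 3L,
                             ratio_window = 3L, low = 0.7, high = 1.3,
                             k = 3, eps = 1e-9) {
  fi_mch <- background_correct(mcherry, media_mcherry)
  fi_gfp <- background_correct(gfp, media_gfp)
  rfu <- compute_rfu(fi_mch, fi_gfp, eps = eps)
  rfu_s <- rfu
  ok <- !is.na(rfu)
  if (sum(ok) >= sg_window) rfu_s[ok] <- smooth_series(rfu[ok], sg_window, sg_polyorder)
  od_s <- smooth_series(od600, sg_window, sg_polyorder)
  phases <- suppressWarnings(find_growth_phases(od_s, time))
  # promoterless strains can have non-positive stationary RFU: their ratio
  # is undefined, but the profile (and the detectability call) still exists
  ratio <- tryCatch(
    differential_activity(rfu_s, time, phases$t_midexp, phases$t_stat,
                          window = ratio_window),
    error = function(e) NA_real_)
  half <- (as.integer(ratio_window) - 1L) %/% 2L
  i_stat <- which.min(abs(time - phases$t_stat))
  i_mid <- which.min(abs(time - phases$t_midexp))
  rfu_stat <- window_mean(rfu_s, i_stat, half)
  rfu_mid <- window_mean(rfu_s, i_mid, half)
  detectable <- if (is.null(background_rfu)) NA else {
    detect_active(rfu_stat, background_rfu, k = k)
  }
  structure(list(fi_mcherry = fi_mch, fi_gfp = fi_gfp, rfu = rfu,
                 rfu_smoothed = rfu_s, t_midexp = phases$t_midexp,
                 t_stat = phases$t_stat, rfu_midexp = rfu_mid,
                 rfu_stationary = rfu_stat, differential_activity = ratio,
                 phase_class = if (!is.finite(ratio) || ratio <= 0) {
                   NA_character_
                 } else {
                   classify_phase_bias(ratio, low, high)
                 },
                 detectable = detectable),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf(
    "activity_profile: t_midexp=%.2f h, t_stat=%.2f h, RFU %0.4g -> %0.4g, ratio=%.3f (%s)%s\n",
    x$t_midexp, x$t_stat, x$rfu_midexp, x$rfu_stationary,
    x$differential_activity, x$phase_class,
    if (is.na(x$detectable)) "" else paste0(", detectable=", x$detectable)))
  invisible(x)
}

#' Profile every strain on a plate and summarize class counts
#'
#' Takes a long-format plate table and a well map, averages replicate wells
#' per strain and timepoint, derives one \code{\link{activity_profile}} per
#' strain (against the mean media-control and background-strain wells) and
#' tabulates temporal classes over the detectable strains.
#'
#' @param plate data.frame with columns \code{well}, \code{strain},
#'   \code{time_h}, \code{od600}, \code{mcherry}, \code{gfp}.
#' @param well_map data.frame with columns \code{well}, \code{role}
#'   (\code{sample}/\code{media}/\code{background}) and \code{strain}.
#' @param ... Tuning parameters forwarded to \code{\link{activity_profile}}.
#' @return List with \code{profiles} (one row per sample strain: timepoints,
#'   RFUs, ratio, class, detectable) and \code{summary} (class counts among
#'   detectable strains plus the detectability tally).
#' @export
analyze_plate <- function(plate, well_map, ...) {
  need <- c("well", "strain", "time_h", "od600", "mcherry", "gfp")
  if (!all(need %in% names(plate))) {
    stop("plate table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  media_wells <- well_map$well[well_map$role == "media"]
  if (!length(media_wells)) {
    stop("no media-control wells in the well map", call. = FALSE)
  }
  bg_strains <- unique(well_map$strain[well_map$role == "background"])

  avg_series <- function(rows) {
    agg <- stats::aggregate(rows[, c("od600", "mcherry", "gfp")],
                            by = list(time_h = rows$time_h), FUN = mean)
    agg[order(agg$time_h), ]
  }

  media <- avg_series(plate[plate$well %in% media_wells, ])

  profile_of <- function(strain, background_rfu = NULL) {
    rows <- plate[plate$strain == strain & plate$well %in%
                    well_map$well[well_map$strain == strain], ]
    s <- avg_series(rows)
    if (!isTRUE(all.equal(s$time_h, media$time_h))) {
      stop("strain ", strain, " and media controls are on different timebases",
           call. = FALSE)
    }
    activity_profile(s$time_h, s$od600, s$mcherry, s$gfp,
                     media$mcherry, media$gfp,
                     background_rfu = background_rfu, ...)
  }

  background_rfu <- NULL
  if (length(bg_strains)) {
    bgp <- profile_of(bg_strains[1])
    background_rfu <- bgp$rfu_smoothed
  }

  strains <- unique(well_map$strain[well_map$role == "sample"])
  rows <- lapply(strains, function(st) {
    p <- profile_of(st, background_rfu = background_rfu)
    data.frame(strain = st, t_midexp = p$t_midexp, t_stat = p$t_stat,
               rfu_midexp = p$rfu_midexp, rfu_stationary = p$rfu_stationary,
               differential_activity = p$differential_activity,
               phase_class = p$phase_class, detectable = p$detectable,
               stringsAsFactors = FALSE)
  })
  profiles <- do.call(rbind, rows)
  sel <- if (all(is.na(profiles$detectable))) {
    rep(TRUE, nrow(profiles))  # no background strain: classify everything
  } else {
    profiles$detectable %in% TRUE
  }
  detectable <- profiles[sel, , drop = FALSE]
  counts <- table(factor(detectable$phase_class,
                         levels = c("stationary_biased", "unbiased",
                                    "exponential_biased")))
  summary <- data.frame(phase_class = names(counts),
                        n = as.integer(counts), stringsAsFactors = FALSE)
  summary <- rbind(summary,
                   data.frame(phase_class = "detectable",
                              n = sum(profiles$detectable %in% TRUE)),
                   data.frame(phase_class = "total", n = nrow(profiles)))
  list(profiles = profiles, summary = summary)
}
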