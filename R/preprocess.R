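#' Sex-specific BMI category cutoffs
#'
#' Operational BMI cutoffs for 9-11-year-olds, one row per sex. Children
#' below \code{normal_upper} are "normal" (underweight/regular weight),
#' children strictly above \code{obese_lower} are "obese"; everything in
#' between, including both boundary values, is "overweight". Assigning the
#' exact boundary to the middle class is conservative here because
#' overweight children are excluded from the analysis downstream.
#'
#' @return a data.frame with columns \code{sex}, \code{normal_upper},
#'   \code{obese_lower} (kg/m^2).
#' @export
bmi_cutoffs <- function() {
  data.frame(
    sex = c("female", "male"),
    normal_upper = c(19.0, 18.5),
    obese_lower = c(22.6, 21.4),
    stringsAsFactors = FALSE
  )
}

#' Body mass index
#'
#' @param weight_kg weight in kilograms (> 0).
#' @param height_m height in metres (> 0).
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight_kg, height_m) {
  abort_if(any(!is.finite(weight_kg)) || any(weight_kg <= 0),
           "weight_kg must be a positive finite number")
  abort_if(any(!is.finite(height_m)) || any(height_m <= 0),
           "height_m must be a positive finite number")
  weight_kg / height_m^2
}

#' Classify BMI into normal / overweight / obese
#'
#' @param bmi BMI value(s) in kg/m^2.
#' @param sex "male" or "female" (recycled against \code{bmi}).
#' @param cutoffs cutoff table, see [bmi_cutoffs()].
#' @return character vector in \code{c("normal", "overweight", "obese")}.
#' @export
classify_bmi <- function(bmi, sex, cutoffs = bmi_cutoffs()) {
  abort_if(any(!is.finite(bmi)) || any(bmi <= 0), "bmi must be positive")
  abort_if(!all(sex %in% cutoffs$sex),
           sprintf("unknown sex: %s", paste(setdiff(sex, cutoffs$sex), collapse = ", ")))
  n <- max(length(bmi), length(sex))
  bmi <- rep_len(bmi, n)
  sex <- rep_len(sex, n)
  i <- match(sex, cutoffs$sex)
  out <- rep("overweight", n)
  out[bmi < cutoffs$normal_upper[i]] <- "normal"
  out[bmi > cutoffs$obese_lower[i]] <- "obese"
  out
}

#' FIR band-pass filter specification
#'
#' The record sampling rate is fixed at 500 Hz. Band edges and tap count
#' are implementation choices (documented in the methods vignette): the low
#' edge of 0.5 Hz is the conventional diagnostic-ECG high-pass corner that
#' removes baseline wander, 40 Hz suppresses powerline and EMG noise, and
#' 2001 taps give a transition band narrow enough (~0.8 Hz) that the filter
#' genuinely rejects DC despite the low 0.5 Hz corner.
#'
#' @param low_cut_Hz,high_cut_Hz band edges in Hz.
#' @param num_taps odd number of coefficients (linear-phase type I).
#' @param window_name window function; only "hamming" is implemented.
#' @param sampling_rate_Hz sampling rate, 500 Hz.
#' @return an object of class \code{fir_spec}.
#' @export
fir_spec <- function(low_cut_Hz = 0.5, high_cut_Hz = 40, num_taps = 2001,
                     window_name = "hamming", sampling_rate_Hz = 500) {
  abort_if(!(low_cut_Hz > 0 && low_cut_Hz < high_cut_Hz &&
               high_cut_Hz < sampling_rate_Hz / 2),
           "band edges must satisfy 0 < low < high < Nyquist")
  abort_if(num_taps %% 2 != 1 || num_taps < 3,
           "num_taps must be odd (linear-phase type I)")
  abort_if(!identical(window_name, "hamming"), "only the Hamming window is supported")
  structure(list(low_cut_Hz = low_cut_Hz, high_cut_Hz = high_cut_Hz,
                 num_taps = num_taps, window_name = window_name,
                 sampling_rate_Hz = sampling_rate_Hz),
            class = "fir_spec")
}

#' Design a linear-phase FIR band-pass filter
#'
#' Windowed-sinc design (Hamming window) via \code{signal::fir1}.
#'
#' @param spec a [fir_spec()].
#' @return numeric coefficient vector of length \code{spec$num_taps}.
#' @export
design_fir_bandpass <- function(spec = fir_spec()) {
  stopifnot(inherits(spec, "fir_spec"))
  nyq <- spec$sampling_rate_Hz / 2
  h <- signal::fir1(spec$num_taps - 1,
                    c(spec$low_cut_Hz, spec$high_cut_Hz) / nyq,
                    type = "pass",
                    window = signal::hamming(spec$num_taps))
  as.numeric(h)
}

#' Frequency response magnitude of an FIR filter
#'
#' @param coefficients FIR coefficients.
#' @param freq_Hz frequencies at which to evaluate the response.
#' @param sampling_rate_Hz sampling rate.
#' @return magnitude response at each frequency.
#' @export
fir_response <- function(coefficients, freq_Hz, sampling_rate_Hz = 500) {
  n <- seq_along(coefficients) - 1
  vapply(freq_Hz, function(f) {
    Mod(sum(coefficients * exp(-2i * pi * f * n / sampling_rate_Hz)))
  }, numeric(1))
}

#' Apply an FIR filter with zero net delay
#'
#' Forward convolution followed by an explicit group-delay shift of
#' \code{(num_taps - 1) / 2} samples, so that output sample \code{t} is
#' aligned with input sample \code{t} and R-peak indices refer to the raw
#' record's time base. Edges are zero-padded.
#'
#' @param x numeric signal, length >= number of coefficients.
#' @param coefficients odd-length linear-phase FIR coefficients.
#' @return filtered signal, same length as \code{x}.
#' @export
filter_signal <- function(x, coefficients) {
  abort_if(length(x) < length(coefficients),
           "signal shorter than the filter")
  nt <- length(coefficients)
  delay <- (nt - 1) / 2
  full <- stats::convolve(c(x), rev(coefficients), type = "open")
  full[(delay + 1):(delay + length(x))]
}

# ---- Hamilton-style R-peak detection --------------------------------------

# zero-phase moving average of odd width w
moving_average_centered <- function(x, w) {
  k <- rep(1 / w, w)
  full <- stats::convolve(x, rev(k), type = "open")
  d <- (w - 1) / 2
  full[(d + 1):(d + length(x))]
}

#' Detect R peaks with an adaptive dual-threshold (Hamilton-style) detector
#'
#' Classical QRS detection chain: a narrow detection band-pass (8-16 Hz)
#' emphasises the QRS complex, the signal is differentiated (central
#' difference, zero phase), rectified, and smoothed with an 80 ms centred
#' moving-average window. Candidate peaks of the detection function are then
#' classified as QRS or noise by an adaptive threshold
#' \code{noise + 0.3125 * (signal - noise)} maintained from running means of
#' the last eight accepted signal peaks and noise peaks, with a refractory
#' period during which no second QRS may fire. Each accepted detection is
#' finally refined to the local maximum of the input signal within
#' \code{refine_window} samples.
#'
#' @param x filtered ECG signal (amplitude units are irrelevant; thresholds
#'   adapt).
#' @param sampling_rate_Hz sampling rate; the pipeline uses 500 Hz.
#' @param refractory_s minimum R-to-R separation in seconds (default 0.2 s).
#' @param refine_window half-width, in samples, of the local-maximum
#'   refinement search (default 10).
#' @return integer vector of ascending R-peak sample indices (1-based).
#' @export
detect_r_peaks <- function(x, sampling_rate_Hz = 500, refractory_s = 0.2,
                           refine_window = 10) {
  fs <- sampling_rate_Hz
  ma_w <- 2 * floor(0.04 * fs) + 1 # ~80 ms, odd
  abort_if(length(x) <= ma_w, "signal shorter than the integration window")
  if (all(x == 0)) return(integer(0))

  # detection band 8-16 Hz; modest order keeps the transition wide, which is
  # fine for a detection (not reconstruction) filter
  nt <- 2 * floor(0.1 * fs) + 1
  hb <- signal::fir1(nt - 1, c(8, 16) / (fs / 2), type = "pass",
                     window = signal::hamming(nt))
  xb <- filter_signal(x, as.numeric(hb))

  # central-difference derivative (zero phase), rectify, integrate
  d <- c(0, (xb[-(1:2)] - xb[1:(length(xb) - 2)]) / 2, 0)
  det <- moving_average_centered(abs(d), ma_w)

  # candidate local maxima of the detection function
  n <- length(det)
  is_peak <- det[2:(n - 1)] > det[1:(n - 2)] & det[2:(n - 1)] >= det[3:n]
  cand <- which(is_peak) + 1L
  cand <- cand[det[cand] > 0]
  if (length(cand) == 0) return(integer(0))

  refractory <- round(refractory_s * fs)
  # non-maximum suppression: a candidate must dominate its refractory
  # neighbourhood of the detection function, so P/T-wave shoulders never
  # pre-empt the nearby QRS
  cand <- cand[vapply(cand, function(p) {
    lo <- max(1L, p - refractory)
    hi <- min(n, p + refractory)
    det[p] >= max(det[lo:hi])
  }, logical(1))]
  spk <- numeric(0) # running signal-peak levels (last 8)
  npk <- numeric(0) # running noise-peak levels (last 8)
  # seed the signal level from the largest detection peaks so the detector
  # does not latch onto noise at the start of the record
  init_spk <- stats::quantile(det[cand], 0.95, names = FALSE)
  r_idx <- integer(0)
  for (p in cand) {
    s_lvl <- if (length(spk)) mean(spk) else init_spk
    n_lvl <- if (length(npk)) mean(npk) else 0.1 * init_spk
    thr <- n_lvl + 0.3125 * (s_lvl - n_lvl)
    if (det[p] >= thr && (length(r_idx) == 0 || p - r_idx[length(r_idx)] > refractory)) {
      r_idx <- c(r_idx, p)
      spk <- utils::tail(c(spk, det[p]), 8)
    } else {
      npk <- utils::tail(c(npk, det[p]), 8)
    }
  }
  if (length(r_idx) == 0) return(integer(0))

  # refine to the local maximum of the input signal: hill-climb in
  # refine_window-sized steps until the argmax is interior, so a peak a
  # little beyond the first window is still reached
  refined <- vapply(r_idx, function(p) {
    p <- as.integer(p)
    for (iter in 1:5) {
      lo <- max(1L, as.integer(p - refine_window))
      hi <- min(length(x), as.integer(p + refine_window))
      q <- lo + which.max(x[lo:hi]) - 1L
      if (q == p) break
      p <- q
      if (q > lo && q < hi) break
    }
    p
  }, integer(1))
  refined <- sort(unique(refined))
  # drop refinements that collapsed within the refractory distance
  keep <- c(TRUE, diff(refined) > refractory)
  refined[keep]
}

#' Extract complete beats around R peaks
#'
#' A complete beat is the half-open window \code{[r - 100, r + 200)} of the
#' filtered record: 100 samples (200 ms) before the R peak and 200 samples
#' (400 ms) from the R peak on, 300 samples (600 ms) in total, with the R
#' peak at local index 101 (1-based). R peaks too close to either end of
#' the record to supply a full window are discarded and logged.
#'
#' @param x filtered signal (typically 5000 samples).
#' @param r_indices ascending 1-based R-peak sample indices.
#' @param pre,post samples before / from the R peak (defaults 100 / 200).
#' @return list with \code{beats} (matrix, one row per kept beat,
#'   \code{pre + post} columns), \code{r_kept} (their R indices) and
#'   \code{discarded} (data.frame of dropped R indices with reasons).
#' @export
extract_beats <- function(x, r_indices, pre = 100, post = 200) {
  stopifnot(!is.unsorted(r_indices))
  n <- length(x)
  width <- pre + post
  reason <- rep(NA_character_, length(r_indices))
  reason[r_indices - pre < 1] <- "incomplete_head"
  reason[is.na(reason) & r_indices + post - 1 > n] <- "incomplete_tail"
  keep <- is.na(reason)
  beats <- if (any(keep)) {
    t(vapply(r_indices[keep], function(r) x[(r - pre):(r + post - 1)],
             numeric(width)))
  } else {
    matrix(numeric(0), 0, width)
  }
  list(
    beats = beats,
    r_kept = as.integer(r_indices[keep]),
    discarded = data.frame(r_index = as.integer(r_indices[!keep]),
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  )
}

#' Filter a record and extract its complete beats
#'
#' Convenience wrapper chaining [filter_signal()], [detect_r_peaks()] and
#' [extract_beats()] on one record's signal (in whatever amplitude unit the
#' record carries).
#'
#' @param signal numeric signal vector.
#' @param coefficients FIR coefficients; defaults to the package filter.
#' @inheritParams detect_r_peaks
#' @return as [extract_beats()], plus \code{r_detected} (all detections).
#' @export
segment_record <- function(signal, coefficients = design_fir_bandpass(),
                           sampling_rate_Hz = 500) {
  xf <- filter_signal(signal, coefficients)
  r <- detect_r_peaks(xf, sampling_rate_Hz)
  out <- extract_beats(xf, r)
  out$r_detected <- r
  out
}
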