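#' Build a PQRST morphology template
#'
#' Beats are modelled as a sum of five Gaussians, one per PQRST deflection,
#' parameterised by centre (ms relative to the R peak), width (Gaussian SD,
#' ms) and signed amplitude (mV). The two class templates are identical
#' except inside a configurable "difference window" (default: the T-wave
#' region, +150 to +350 ms after R) where the obese template's T wave is
#' scaled down and shifted later. The window is a simulation parameter, not
#' a claim about where real obesity-related differences lie.
#'
#' @param class_label "normal" or "obese".
#' @param effect_size nonnegative scalar; 0 makes the classes identical,
#'   1 halves the obese T amplitude and shifts its centre by +8 ms.
#' @return object of class \code{morphology_template}: a list with
#'   \code{components} (data.frame label/center_ms/width_ms/amplitude_mV),
#'   \code{class_label} and \code{diff_window_ms} (c(+150, +350)).
#' @export
build_template <- function(class_label = c("normal", "obese"), effect_size = 0) {
  class_label <- match.arg(class_label)
  abort_if(!is.finite(effect_size) || effect_size < 0,
           "effect_size must be a nonnegative number")
  comp <- data.frame(
    label = c("P", "Q", "R", "S", "T"),
    center_ms = c(-140, -22, 0, 25, 250),
    width_ms = c(22, 9, 11, 9, 35),
    amplitude_mV = c(0.15, -0.10, 1.10, -0.25, 0.35),
    stringsAsFactors = FALSE
  )
  if (class_label == "obese" && effect_size > 0) {
    t_row <- comp$label == "T"
    comp$amplitude_mV[t_row] <- comp$amplitude_mV[t_row] *
      max(0, 1 - 0.5 * effect_size)
    comp$center_ms[t_row] <- comp$center_ms[t_row] + 8 * effect_size
  }
  structure(list(components = comp, class_label = class_label,
                 diff_window_ms = c(150, 350)),
            class = "morphology_template")
}

#' Evaluate a morphology template
#'
#' @param template a [build_template()] result.
#' @param t_ms times in milliseconds relative to the R peak.
#' @return waveform amplitude in mV at each time.
#' @export
eval_template <- function(template, t_ms) {
  stopifnot(inherits(template, "morphology_template"))
  comp <- template$components
  out <- numeric(length(t_ms))
  for (i in seq_len(nrow(comp))) {
    out <- out + comp$amplitude_mV[i] *
      exp(-((t_ms - comp$center_ms[i])^2) / (2 * comp$width_ms[i]^2))
  }
  out
}

#' Noise specification for synthetic records
#'
#' Emulates the disturbances seen in paediatric ECG acquisition: wideband
#' Gaussian sensor noise, low-frequency baseline wander from respiration and
#' motion, powerline interference, and occasional transient motion
#' artefacts (smooth bumps at random positions).
#'
#' @param gaussian_sd_mV white-noise standard deviation.
#' @param baseline_wander_amp_mV,baseline_wander_Hz sinusoidal wander.
#' @param powerline_amp_mV,powerline_Hz mains interference (50 Hz).
#' @param artifact_rate_per_record expected count of transient artefacts.
#' @return object of class \code{noise_spec}.
#' @export
noise_spec <- function(gaussian_sd_mV = 0.03,
                       baseline_wander_amp_mV = 0.10, baseline_wander_Hz = 0.25,
                       powerline_amp_mV = 0.02, powerline_Hz = 50,
                       artifact_rate_per_record = 0.5) {
  amps <- c(gaussian_sd_mV, baseline_wander_amp_mV, powerline_amp_mV,
            artifact_rate_per_record)
  abort_if(any(amps < 0), "noise amplitudes and rates must be >= 0")
  abort_if(baseline_wander_Hz <= 0 || powerline_Hz <= 0,
           "noise frequencies must be > 0")
  structure(list(gaussian_sd_mV = gaussian_sd_mV,
                 baseline_wander_amp_mV = baseline_wander_amp_mV,
                 baseline_wander_Hz = baseline_wander_Hz,
                 powerline_amp_mV = powerline_amp_mV,
                 powerline_Hz = powerline_Hz,
                 artifact_rate_per_record = artifact_rate_per_record),
            class = "noise_spec")
}

#' Zero-noise specification
#' @return a [noise_spec()] with every amplitude and rate set to zero.
#' @export
noise_spec_none <- function() {
  noise_spec(0, 0, 0.25, 0, 50, 0)
}

#' Sample a synthetic subject
#'
#' Height is drawn from a sex-specific normal distribution typical of
#' 9-11-year-olds; a BMI is drawn uniformly inside the target category's
#' interval (with a 0.25 kg/m^2 guard margin against the category
#' boundaries, so that rounding height/weight for storage can never flip
#' the recomputed category); weight is then solved from BMI and height.
#' This construction guarantees label consistency by design. Age at the
#' generated collection date is uniform over 9, 10 and 11 completed years.
#'
#' @param seed integer seed for this subject's substream.
#' @param target_class "normal", "overweight" or "obese".
#' @param sex "male" or "female".
#' @param subject_id opaque identifier; default derived from the seed.
#' @return object of class \code{subject_meta}: subject_id, sex, birth_date,
#'   collection_date, height_m, weight_kg, target_class.
#' @export
sample_subject <- function(seed, target_class = c("normal", "overweight", "obese"),
                           sex = c("female", "male"), subject_id = NULL) {
  target_class <- match.arg(target_class)
  sex <- match.arg(sex)
  cuts <- bmi_cutoffs()
  cut <- cuts[cuts$sex == sex, ]
  margin <- 0.25
  with_seed(seed, {
    height_m <- round(stats::rnorm(1,
                                   mean = if (sex == "male") 1.40 else 1.39,
                                   sd = 0.065), 3)
    height_m <- min(max(height_m, 1.15), 1.70)
    bmi_range <- switch(target_class,
      normal = c(13.5, cut$normal_upper - margin),
      overweight = c(cut$normal_upper + margin, cut$obese_lower - margin),
      obese = c(cut$obese_lower + margin, cut$obese_lower + 8)
    )
    bmi <- stats::runif(1, bmi_range[1], bmi_range[2])
    weight_kg <- round(bmi * height_m^2, 1)
    # rounding weight moves BMI by < 0.05/height^2 < 0.04 kg/m^2 -- inside
    # the guard margin, so the category is preserved
    collection_date <- as.Date("2015-06-01") + sample.int(420, 1) - 1
    age_years <- sample.int(3, 1) + 8L # 9, 10 or 11 completed years
    # 1..358 days past the anniversary: strictly inside the year, so the
    # completed-years age is exactly age_years even across leap days
    extra_days <- sample.int(358, 1)
    birth_date <- seq(collection_date, by = sprintf("-%d years", age_years),
                      length.out = 2)[2] - extra_days
    structure(list(
      subject_id = subject_id %||% sprintf("S%09d", seed %% 1000000000),
      sex = sex,
      birth_date = birth_date,
      collection_date = collection_date,
      height_m = height_m,
      weight_kg = weight_kg,
      target_class = target_class
    ), class = "subject_meta")
  })
}

#' Synthesise one 10-s lead-I ECG record
#'
#' Places R peaks along the 10-s record with R-to-R intervals drawn
#' uniformly from the period range implied by \code{hr_bpm_range} (a
#' degenerate range gives perfectly regular beats), superimposes the
#' subject-class morphology template at each R peak, adds the configured
#' noise, and quantises to integer microvolts for storage. The true R-peak
#' sample positions and the noise-free continuous waveform are retained as
#' attributes (\code{r_truth}, \code{clean_mV}) so detector and template
#' recovery can be tested against ground truth.
#'
#' @param subject a [sample_subject()] result.
#' @param template a [build_template()] result.
#' @param noise a [noise_spec()].
#' @param hr_bpm_range length-2 heart-rate range in beats/min, inside
#'   \code{[40, 200]}.
#' @param seed integer seed for this record's substream.
#' @param abnormal if TRUE, the report text states an abnormality drawn
#'   from the cardiologist-report lexicon instead of "normal".
#' @param n_samples,sampling_rate_Hz record geometry (5000 samples, 500 Hz).
#' @return object of class \code{ecg_record}; \code{signal} is the integer
#'   microvolt waveform (attribute \code{scale_uV} = 1).
#' @export
synth_record <- function(subject, template, noise = noise_spec(),
                         hr_bpm_range = c(70, 110), seed = 1,
                         abnormal = FALSE,
                         n_samples = 5000, sampling_rate_Hz = 500) {
  stopifnot(inherits(subject, "subject_meta"),
            inherits(template, "morphology_template"),
            inherits(noise, "noise_spec"))
  abort_if(length(hr_bpm_range) != 2 || any(!is.finite(hr_bpm_range)) ||
             hr_bpm_range[1] > hr_bpm_range[2] ||
             hr_bpm_range[1] < 40 || hr_bpm_range[2] > 200,
           "hr_bpm_range must be an ascending pair within [40, 200]")
  fs <- sampling_rate_Hz
  dur_s <- n_samples / fs
  with_seed(seed, {
    rr_lo <- 60 / hr_bpm_range[2]
    rr_hi <- 60 / hr_bpm_range[1]
    t0 <- stats::runif(1, 0.1, 0.9) * rr_lo + 0.1
    r_times <- t0
    while (TRUE) {
      nxt <- r_times[length(r_times)] + stats::runif(1, rr_lo, rr_hi)
      if (nxt >= dur_s) break
      r_times <- c(r_times, nxt)
    }
    # snap R peaks to the sample grid so the stored ground-truth indices
    # are exact and the template is evaluated at sample-aligned offsets
    r_times <- round(r_times * fs) / fs
    t_ms <- (seq_len(n_samples) - 1) / fs * 1000
    clean <- numeric(n_samples)
    for (rt in r_times) {
      clean <- clean + eval_template(template, t_ms - rt * 1000)
    }
    x <- clean
    if (noise$gaussian_sd_mV > 0) {
      x <- x + stats::rnorm(n_samples, 0, noise$gaussian_sd_mV)
    }
    if (noise$baseline_wander_amp_mV > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      x <- x + noise$baseline_wander_amp_mV *
        sin(2 * pi * noise$baseline_wander_Hz * t_ms / 1000 + ph)
    }
    if (noise$powerline_amp_mV > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      x <- x + noise$powerline_amp_mV *
        sin(2 * pi * noise$powerline_Hz * t_ms / 1000 + ph)
    }
    n_art <- if (noise$artifact_rate_per_record > 0) {
      stats::rpois(1, noise$artifact_rate_per_record)
    } else 0L
    if (n_art > 0) {
      for (k in seq_len(n_art)) {
        ctr <- stats::runif(1, 0, dur_s) * 1000
        amp <- stats::runif(1, -0.4, 0.4)
        wid <- stats::runif(1, 40, 150)
        x <- x + amp * exp(-((t_ms - ctr)^2) / (2 * wid^2))
      }
    }
    report <- if (abnormal) {
      sample(abnormality_lexicon(), 1)
    } else {
      "normal ECG, sinus rhythm"
    }
    signal_uV <- as.integer(round(x * 1000))
    rec <- structure(list(
      subject_id = subject$subject_id,
      birth_date = subject$birth_date,
      collection_date = subject$collection_date,
      sex = subject$sex,
      weight_kg = subject$weight_kg,
      height_cm = round(subject$height_m * 100, 1),
      signal = signal_uV,
      report_text = report,
      source_path = NA_character_
    ), class = "ecg_record")
    attr(rec, "scale_uV") <- 1
    attr(rec, "r_truth") <- as.integer(round(r_times * fs) + 1)
    attr(rec, "clean_mV") <- clean
    rec
  })
}

#' Cardiologist-report abnormality lexicon
#'
#' Phrases used both to label injected abnormal synthetic records and as
#' the keyword list for the downstream report filter: arrhythmia variants
#' (early repolarisation, bradycardia), atrioventricular block, ventricular
#' hypertrophy and axis deviation.
#'
#' @return character vector of abnormality phrases.
#' @export
abnormality_lexicon <- function() {
  c("arrhythmia", "early repolarisation pattern", "sinus bradycardia",
    "auriculoventricular heart block", "atrioventricular block",
    "ventricular hypertrophy", "electrical axis deviation")
}

#' Write a synthetic cohort to disk
#'
#' Generates \code{n_per_class} subjects per class, one XML record each (in
#' the dialect [parse_record()] reads), plus a manifest CSV. A configurable
#' fraction of records per class is made deliberately invalid (alternating
#' between a missing waveform and an implausible height) and a further
#' fraction carries an abnormal cardiologist report; both fractions are
#' allocated deterministically to the first records of each class so counts
#' are exact (\code{floor(fraction * n)} rounded to nearest).
#'
#' @param n_per_class records per class (>= 1).
#' @param class_list subset of c("normal", "overweight", "obese").
#' @param out_dir output directory (created if needed).
#' @param seed root seed; per-record substreams via [derive_seed()].
#' @param effect_size class morphology difference, see [build_template()].
#' @param noise a [noise_spec()].
#' @param hr_bpm_range heart-rate range passed to [synth_record()].
#' @param invalid_fraction,abnormal_fraction per-class fractions of
#'   deliberately invalid / abnormal-report records.
#' @return invisibly, the manifest data.frame (also written to
#'   \code{manifest.csv}): file, subject_id, target_class, sex, invalid,
#'   invalid_kind, abnormal, r_truth (semicolon-separated sample indices).
#' @export
write_cohort <- function(n_per_class, class_list = c("normal", "obese"),
                         out_dir, seed = 1, effect_size = 1,
                         noise = noise_spec(), hr_bpm_range = c(70, 110),
                         invalid_fraction = 0, abnormal_fraction = 0) {
  abort_if(n_per_class < 1, "n_per_class must be >= 1")
  stopifnot(all(class_list %in% c("normal", "overweight", "obese")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  abort_if(!dir.exists(out_dir), sprintf("cannot create directory %s", out_dir))
  n_invalid <- round(invalid_fraction * n_per_class)
  n_abnormal <- round(abnormal_fraction * n_per_class)
  rows <- list()
  idx <- 0L
  for (cl in class_list) {
    # the obese morphology applies only to the obese class; overweight
    # subjects (generated only to exercise the exclusion filter) share the
    # normal template
    tpl <- build_template(if (cl == "obese") "obese" else "normal", effect_size)
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      sseed <- derive_seed(seed, 2L * idx)
      rseed <- derive_seed(seed, 2L * idx + 1L)
      sex <- if (i %% 2 == 0) "male" else "female"
      subj <- sample_subject(sseed, cl, sex,
                             subject_id = sprintf("S%s%04d", substr(cl, 1, 3), idx))
      invalid <- i <= n_invalid
      invalid_kind <- if (!invalid) {
        NA_character_
      } else if (i %% 2 == 1) "missing_signal" else "implausible_height"
      abnormal <- !invalid && i <= n_invalid + n_abnormal
      rec <- synth_record(subj, tpl, noise, hr_bpm_range, seed = rseed,
                          abnormal = abnormal)
      if (identical(invalid_kind, "missing_signal")) rec$signal <- integer(0)
      if (identical(invalid_kind, "implausible_height")) rec$height_cm <- 999
      file <- sprintf("rec_%04d_%s.xml", idx, subj$subject_id)
      write_record_xml(rec, file.path(out_dir, file))
      rows[[idx]] <- data.frame(
        file = file, subject_id = subj$subject_id, target_class = cl,
        sex = sex, invalid = invalid, invalid_kind = invalid_kind,
        abnormal = abnormal,
        r_truth = paste(attr(rec, "r_truth"), collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Write one ECG record as XML
#'
#' Dialect: root \code{<ecg_record>} with children \code{subject_id},
#' \code{birth_date} (ISO-8601), \code{collection_date}, \code{sex},
#' \code{weight_kg}, \code{height_cm}, \code{report}, and \code{waveform}
#' (whitespace-separated integers, attribute \code{scale_uV} giving
#' microvolts per unit).
#'
#' @param record an \code{ecg_record}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_record_xml <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  doc <- xml2::xml_new_root("ecg_record")
  add <- function(name, value) {
    xml2::xml_add_child(doc, name, as.character(value))
  }
  add("subject_id", record$subject_id)
  add("birth_date", format(record$birth_date, "%Y-%m-%d"))
  add("collection_date", format(record$collection_date, "%Y-%m-%d"))
  add("sex", record$sex)
  add("weight_kg", record$weight_kg)
  add("height_cm", record$height_cm)
  add("report", record$report_text)
  wf <- xml2::xml_add_child(doc, "waveform",
                            paste(record$signal, collapse = " "))
  xml2::xml_set_attr(wf, "scale_uV", attr(record, "scale_uV") %||% 1)
  xml2::write_xml(doc, path)
  invisible(path)
}
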