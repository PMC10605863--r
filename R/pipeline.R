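#' Run the ingest-to-dataset pipeline on a directory of XML records
#'
#' Parses every record, validates (duplicates, missing/abnormal signal,
#' dates, anthropometry), restricts to the cohort ID list and the 9-11-year
#' age band, applies the overweight and abnormal-report exclusions,
#' filters each remaining signal, detects R peaks, extracts complete
#' beats and labels them with the subject's BMI class.
#'
#' @param in_dir directory of XML records.
#' @param cohort_ids cohort subject IDs; defaults to all subjects found.
#' @param coefficients FIR coefficients (default package filter).
#' @param age_min,age_max inclusive completed-years band.
#' @return list with \code{dataset} (a \code{beat_dataset}),
#'   \code{validation} (per-record status data.frame), \code{filter_counts},
#'   \code{exclusions} and \code{records} (the included records).
#' @export
build_cohort_dataset <- function(in_dir, cohort_ids = NULL,
                                 coefficients = design_fir_bandpass(),
                                 age_min = 9, age_max = 11) {
  records <- parse_record_dir(in_dir)
  abort_if(length(records) == 0, sprintf("no XML records found in %s", in_dir))
  validation <- validate_records(records)
  valid <- records[validation$status == "valid"]
  if (is.null(cohort_ids)) {
    cohort_ids <- unique(vapply(valid, function(r) r$subject_id, character(1)))
  }
  flt <- filter_cohort(valid, cohort_ids, age_min, age_max)
  exc <- apply_exclusions(flt$kept)
  segments <- lapply(exc$kept, function(r) segment_record(r$signal, coefficients))
  dataset <- label_beats(exc$kept, segments)
  list(dataset = dataset, validation = validation,
       filter_counts = flt$counts, exclusions = exc$exclusions,
       records = exc$kept)
}

#' Generate, ingest, split and return a ready-to-train synthetic dataset
#'
#' End-to-end convenience used by examples and experiments: writes a
#' two-class synthetic cohort to a temporary directory, runs the full
#' ingest/preprocess/dataset pipeline, and splits.
#'
#' @param n_per_class subjects per class.
#' @param effect_size class morphology difference.
#' @param seed root seed.
#' @param noise a [noise_spec()].
#' @param split_level "subject" or "beat".
#' @param dir cohort directory; a temporary directory by default.
#' @param fractions train/val/test fractions.
#' @return a split \code{beat_dataset}.
#' @export
synthetic_beat_dataset <- function(n_per_class, effect_size = 1, seed = 1,
                                   noise = noise_spec(),
                                   split_level = "subject",
                                   dir = tempfile("cohort"),
                                   fractions = c(0.70, 0.20, 0.10)) {
  write_cohort(n_per_class, c("normal", "obese"), dir, seed = seed,
               effect_size = effect_size, noise = noise)
  res <- build_cohort_dataset(dir)
  split_dataset(res$dataset, fractions, level = split_level,
                seed = derive_seed(seed, 17L))
}
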