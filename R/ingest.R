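#' Parse one XML ECG record
#'
#' Reads the XML dialect written by [write_record_xml()]. An empty
#' \code{waveform} element parses successfully into an empty signal (the
#' missing-signal classification happens in [validate_record()], not here);
#' a missing mandatory element is a schema error naming the element.
#'
#' @param path path to the XML file.
#' @return an \code{ecg_record} with \code{source_path} set.
#' @export
parse_record <- function(path) {
  abort_if(!file.exists(path), sprintf("file does not exist: %s", path))
  doc <- xml2::read_xml(path)
  get1 <- function(name) {
    node <- xml2::xml_find_first(doc, name)
    abort_if(inherits(node, "xml_missing"),
             sprintf("schema error: missing element '%s' in %s", name, path))
    node
  }
  txt <- function(name) xml2::xml_text(get1(name))
  wf_node <- get1("waveform")
  wf_txt <- trimws(xml2::xml_text(wf_node))
  signal <- if (nzchar(wf_txt)) {
    as.integer(strsplit(wf_txt, "\\s+")[[1]])
  } else {
    integer(0)
  }
  scale <- as.numeric(xml2::xml_attr(wf_node, "scale_uV"))
  if (is.na(scale)) scale <- 1
  rec <- structure(list(
    subject_id = txt("subject_id"),
    birth_date = as.Date(txt("birth_date")),
    collection_date = as.Date(txt("collection_date")),
    sex = txt("sex"),
    weight_kg = as.numeric(txt("weight_kg")),
    height_cm = as.numeric(txt("height_cm")),
    signal = signal,
    report_text = txt("report"),
    source_path = path
  ), class = "ecg_record")
  attr(rec, "scale_uV") <- scale
  rec
}

#' Parse every XML record in a directory
#'
#' @param dir directory containing \code{.xml} record files.
#' @return list of \code{ecg_record} objects, in file-name order.
#' @export
parse_record_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  lapply(files, parse_record)
}

#' Completed-years age at a collection date
#'
#' Standard birthday arithmetic: the age increments on (and including) the
#' anniversary of the birth date.
#'
#' @param birth_date,collection_date Date scalars or vectors,
#'   \code{collection_date >= birth_date}.
#' @return integer completed years.
#' @export
compute_age_years <- function(birth_date, collection_date) {
  birth_date <- as.Date(birth_date)
  collection_date <- as.Date(collection_date)
  abort_if(any(collection_date < birth_date),
           "collection_date must not precede birth_date")
  bl <- as.POSIXlt(birth_date)
  cl <- as.POSIXlt(collection_date)
  age <- cl$year - bl$year
  before_birthday <- (cl$mon < bl$mon) | (cl$mon == bl$mon & cl$mday < bl$mday)
  as.integer(age - before_birthday)
}

#' Default signal sanity limits
#'
#' Operational heuristics for "abnormal signal data"; the thresholds are
#' implementation choices (see the methods vignette). A record is abnormal
#' if its signal length differs from \code{expected_length}, if it contains
#' a constant run longer than \code{flatline_run} samples (1 s), if more
#' than \code{clip_fraction} of samples sit at the record's absolute
#' maximum (amplifier clipping), or if any amplitude exceeds
#' \code{max_abs_uV}.
#'
#' @return named list of limits.
#' @export
signal_sanity_limits <- function() {
  list(expected_length = 5000, flatline_run = 500, clip_fraction = 0.05,
       max_abs_uV = 10000)
}

#' Default anthropometry plausibility bounds
#'
#' Generous paediatric ranges; values outside are treated as data-entry
#' errors rather than biology.
#'
#' @return named list with height_cm and weight_kg ranges.
#' @export
anthropometry_bounds <- function() {
  list(height_cm = c(100, 200), weight_kg = c(10, 120))
}

longest_constant_run <- function(x) {
  if (length(x) < 2) return(length(x))
  r <- rle(diff(x) == 0)
  runs <- r$lengths[r$values]
  if (length(runs) == 0) 1L else max(runs) + 1L
}

#' Validate one record
#'
#' Classifies (never raises on content). Checks run in a fixed order and
#' the first failure decides the status: duplicate (same subject and
#' collection date already seen) -> missing_signal -> abnormal_signal
#' (wrong length, flatline, clipping, out-of-range amplitude) ->
#' invalid_dates (collection before birth) -> invalid_anthropometry
#' (height/weight outside plausibility bounds) -> valid.
#'
#' @param record an \code{ecg_record}.
#' @param seen_ids character vector of \code{subject_id|collection_date}
#'   keys already encountered (see [validate_records()]).
#' @param limits signal sanity limits, see [signal_sanity_limits()].
#' @param bounds anthropometry bounds, see [anthropometry_bounds()].
#' @return list with \code{status} and \code{detail}.
#' @export
validate_record <- function(record, seen_ids = character(0),
                            limits = signal_sanity_limits(),
                            bounds = anthropometry_bounds()) {
  key <- paste(record$subject_id, format(record$collection_date, "%Y-%m-%d"),
               sep = "|")
  res <- function(status, detail = "") list(status = status, detail = detail,
                                            key = key)
  if (key %in% seen_ids) {
    return(res("duplicate", key))
  }
  if (length(record$signal) == 0 || all(is.na(record$signal))) {
    return(res("missing_signal", "empty waveform"))
  }
  if (length(record$signal) != limits$expected_length) {
    return(res("abnormal_signal",
               sprintf("length %d != %d", length(record$signal),
                       limits$expected_length)))
  }
  run <- longest_constant_run(record$signal)
  if (run > limits$flatline_run) {
    return(res("abnormal_signal", sprintf("flatline run %d", run)))
  }
  mx <- max(abs(record$signal))
  if (mx > limits$max_abs_uV) {
    return(res("abnormal_signal", sprintf("amplitude %d uV out of range", mx)))
  }
  if (mx > 0 && mean(abs(record$signal) == mx) > limits$clip_fraction) {
    return(res("abnormal_signal", "clipping"))
  }
  if (is.na(record$birth_date) || is.na(record$collection_date) ||
      record$collection_date < record$birth_date) {
    return(res("invalid_dates", "collection precedes birth or missing"))
  }
  if (is.na(record$height_cm) || is.na(record$weight_kg) ||
      record$height_cm < bounds$height_cm[1] ||
      record$height_cm > bounds$height_cm[2] ||
      record$weight_kg < bounds$weight_kg[1] ||
      record$weight_kg > bounds$weight_kg[2]) {
    return(res("invalid_anthropometry",
               sprintf("height %.1f cm / weight %.1f kg", record$height_cm,
                       record$weight_kg)))
  }
  res("valid")
}

#' Validate a list of records
#'
#' Applies [validate_record()] in order, threading the duplicate-key set.
#'
#' @param records list of \code{ecg_record}s.
#' @inheritParams validate_record
#' @return data.frame with one row per record: index, subject_id, status,
#'   detail.
#' @export
validate_records <- function(records, limits = signal_sanity_limits(),
                             bounds = anthropometry_bounds()) {
  seen <- character(0)
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    v <- validate_record(records[[i]], seen, limits, bounds)
    if (v$status != "duplicate") seen <- c(seen, v$key)
    rows[[i]] <- data.frame(index = i,
                            subject_id = records[[i]]$subject_id,
                            status = v$status, detail = v$detail,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Restrict records to a cohort and age band
#'
#' Keeps records whose subject is in the cohort ID list and whose
#' completed-years age at collection lies in \code{[age_min, age_max]}
#' (inclusive integer band, default 9-11).
#'
#' @param records list of valid \code{ecg_record}s.
#' @param cohort_id_list non-empty character vector of cohort subject IDs.
#' @param age_min,age_max inclusive completed-years bounds.
#' @return list with \code{kept} (records) and \code{counts} (named counts:
#'   kept, not_in_cohort, outside_age_band).
#' @export
filter_cohort <- function(records, cohort_id_list, age_min = 9, age_max = 11) {
  abort_if(length(cohort_id_list) == 0, "cohort_id_list must be non-empty")
  if (length(records) == 0) {
    return(list(kept = list(),
                counts = c(kept = 0L, not_in_cohort = 0L,
                           outside_age_band = 0L)))
  }
  in_cohort <- vapply(records, function(r) r$subject_id %in% cohort_id_list,
                      logical(1))
  age <- vapply(records, function(r) {
    compute_age_years(r$birth_date, r$collection_date)
  }, integer(1))
  in_age <- age >= age_min & age <= age_max
  keep <- in_cohort & in_age
  list(
    kept = records[keep],
    counts = c(kept = sum(keep),
               not_in_cohort = sum(!in_cohort),
               outside_age_band = sum(in_cohort & !in_age))
  )
}
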