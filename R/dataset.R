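#' BMI category of one record
#'
#' @param record an \code{ecg_record} carrying weight_kg and height_cm.
#' @param cutoffs see [bmi_cutoffs()].
#' @return "normal", "overweight" or "obese".
#' @export
record_bmi_class <- function(record, cutoffs = bmi_cutoffs()) {
  classify_bmi(compute_bmi(record$weight_kg, record$height_cm / 100),
               record$sex, cutoffs)
}

#' Classify a cardiologist report as normal or abnormal
#'
#' Case-insensitive substring match against an abnormality lexicon.
#'
#' @param report_text free-text report.
#' @param lexicon abnormality phrases, see [abnormality_lexicon()].
#' @return TRUE if any lexicon phrase occurs in the report.
#' @export
report_is_abnormal <- function(report_text, lexicon = abnormality_lexicon()) {
  txt <- tolower(report_text)
  any(vapply(tolower(lexicon), function(p) grepl(p, txt, fixed = TRUE),
             logical(1)))
}

#' Apply the analysis inclusion/exclusion rules
#'
#' Keeps records whose BMI category is normal or obese (overweight children
#' are excluded so the two compared groups are well separated) and whose
#' cardiologist report carries no abnormality keyword (so morphology
#' differences are not confounded by diagnosed cardiac conditions).
#'
#' @param records list of \code{ecg_record}s.
#' @param cutoffs BMI cutoffs.
#' @param lexicon abnormality lexicon for the report filter.
#' @return list with \code{kept} (records, each annotated with a
#'   \code{bmi_class} attribute), \code{exclusions} (data.frame
#'   subject_id/reason) and \code{counts} (kept, overweight,
#'   abnormal_report).
#' @export
apply_exclusions <- function(records, cutoffs = bmi_cutoffs(),
                             lexicon = abnormality_lexicon()) {
  kept <- list()
  excl <- list()
  for (r in records) {
    cls <- record_bmi_class(r, cutoffs)
    if (cls == "overweight") {
      excl[[length(excl) + 1L]] <- data.frame(subject_id = r$subject_id,
                                              reason = "overweight",
                                              stringsAsFactors = FALSE)
    } else if (report_is_abnormal(r$report_text, lexicon)) {
      excl[[length(excl) + 1L]] <- data.frame(subject_id = r$subject_id,
                                              reason = "abnormal_report",
                                              stringsAsFactors = FALSE)
    } else {
      attr(r, "bmi_class") <- cls
      kept[[length(kept) + 1L]] <- r
    }
  }
  exclusions <- if (length(excl)) {
    do.call(rbind, excl)
  } else {
    data.frame(subject_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  list(kept = kept, exclusions = exclusions,
       counts = c(kept = length(kept),
                  overweight = sum(exclusions$reason == "overweight"),
                  abnormal_report = sum(exclusions$reason == "abnormal_report")))
}

#' Label segmented beats with their subject's BMI class
#'
#' @param records list of included \code{ecg_record}s (each must carry the
#'   \code{bmi_class} attribute set by [apply_exclusions()], with value
#'   "normal" or "obese").
#' @param segments parallel list of [segment_record()] results (or any list
#'   with elements \code{beats} and \code{r_kept}).
#' @return object of class \code{beat_dataset}: \code{beats} (matrix, one
#'   300-sample row per beat) and \code{info} (data.frame subject_id,
#'   record, r_index, label). Warns if only one class is present.
#' @export
label_beats <- function(records, segments) {
  abort_if(length(records) != length(segments),
           "records and segments must be parallel lists")
  mats <- list()
  infos <- list()
  for (i in seq_along(records)) {
    cls <- attr(records[[i]], "bmi_class")
    abort_if(is.null(cls) || !cls %in% c("normal", "obese"),
             "every record must carry a bmi_class of normal or obese; run apply_exclusions first")
    b <- segments[[i]]$beats
    if (nrow(b) == 0) next
    mats[[length(mats) + 1L]] <- b
    infos[[length(infos) + 1L]] <- data.frame(
      subject_id = records[[i]]$subject_id,
      record = i,
      r_index = segments[[i]]$r_kept,
      label = cls,
      stringsAsFactors = FALSE
    )
  }
  if (length(mats) == 0) {
    ds <- structure(list(beats = matrix(numeric(0), 0, 300),
                         info = data.frame(subject_id = character(0),
                                           record = integer(0),
                                           r_index = integer(0),
                                           label = character(0))),
                    class = "beat_dataset")
    return(ds)
  }
  info <- do.call(rbind, infos)
  if (length(unique(info$label)) < 2) {
    warning("beat dataset contains a single class: ", unique(info$label))
  }
  structure(list(beats = do.call(rbind, mats), info = info),
            class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset> %d beats x %d samples, %d subjects\n",
              nrow(x$beats), ncol(x$beats), length(unique(x$info$subject_id))))
  print(table(x$info$label))
  if (!is.null(x$info$split)) print(table(x$info$split, x$info$label))
  invisible(x)
}

# largest-remainder allocation of n items to fractions
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a beat dataset into train / validation / test
#'
#' Stratified by class. At \code{level = "subject"} (default) all beats of
#' one subject land in the same split, preventing subject leakage between
#' training and evaluation; \code{level = "beat"} assigns beats
#' independently (this inflates apparent accuracy because near-identical
#' beats from one child can appear on both sides).
#'
#' @param ds a \code{beat_dataset}.
#' @param fractions train/val/test fractions summing to 1.
#' @param level "subject" or "beat".
#' @param seed integer seed.
#' @return the dataset with an added \code{info$split} column (factor with
#'   levels train, val, test).
#' @export
split_dataset <- function(ds, fractions = c(0.70, 0.20, 0.10),
                          level = c("subject", "beat"), seed = 1) {
  stopifnot(inherits(ds, "beat_dataset"))
  level <- match.arg(level)
  abort_if(length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9,
           "fractions must be three numbers summing to 1")
  splits <- c("train", "val", "test")
  assign_vec <- rep(NA_character_, nrow(ds$beats))
  with_seed(seed, {
    for (cls in unique(ds$info$label)) {
      in_cls <- which(ds$info$label == cls)
      if (level == "beat") {
        sh <- sample(in_cls)
        cnt <- allocate_counts(length(sh), fractions)
        assign_vec[sh] <- rep(splits, cnt)
      } else {
        subs <- unique(ds$info$subject_id[in_cls])
        sh <- sample(subs)
        cnt <- allocate_counts(length(sh), fractions)
        sub_split <- stats::setNames(rep(splits, cnt), sh)
        assign_vec[in_cls] <- sub_split[ds$info$subject_id[in_cls]]
      }
    }
  })
  ds$info$split <- factor(assign_vec, levels = splits)
  ds
}

#' Extract the design matrix and labels of one split
#'
#' @param ds a split \code{beat_dataset}.
#' @param split "train", "val" or "test".
#' @return list with \code{x} (beats matrix) and \code{y} (factor with
#'   levels normal, obese).
#' @export
dataset_split <- function(ds, split) {
  abort_if(is.null(ds$info$split), "dataset has not been split")
  i <- which(ds$info$split == split)
  list(x = ds$beats[i, , drop = FALSE],
       y = factor(ds$info$label[i], levels = c("normal", "obese")))
}
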