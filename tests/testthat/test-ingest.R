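test_that("XML round-trip preserves the record", {
  s <- sample_subject(11, "normal", "male")
  rec <- synth_record(s, build_template("normal", 1), noise_spec(), seed = 12)
  path <- withr::local_tempfile(fileext = ".xml")
  write_record_xml(rec, path)
  back <- parse_record(path)
  for (f in c("subject_id", "sex", "weight_kg", "height_cm", "report_text")) {
    expect_identical(back[[f]], rec[[f]], info = f)
  }
  expect_identical(back$birth_date, rec$birth_date)
  expect_identical(back$collection_date, rec$collection_date)
  expect_identical(back$signal, rec$signal)
})

test_that("empty waveform parses to an empty signal; missing element errors", {
  s <- sample_subject(13, "normal", "female")
  rec <- synth_record(s, build_template("normal", 0), noise_spec(), seed = 14)
  rec$signal <- integer(0)
  path <- withr::local_tempfile(fileext = ".xml")
  write_record_xml(rec, path)
  back <- parse_record(path)
  expect_length(back$signal, 0)

  txt <- readLines(path, warn = FALSE)
  txt <- gsub("<height_cm>[^<]*</height_cm>", "", txt)
  path2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt, path2)
  expect_error(parse_record(path2), "height")
})

test_that("completed-years age follows birthday arithmetic", {
  expect_identical(compute_age_years("2005-06-01", "2015-06-01"), 10L)
  expect_identical(compute_age_years("2005-06-02", "2015-06-01"), 9L)
  expect_identical(compute_age_years("2005-06-01", "2016-08-01"), 11L)
  expect_error(compute_age_years("2015-06-01", "2005-06-01"), "precede")
})

test_that("validation classifies by the documented first-failure order", {
  s <- sample_subject(15, "normal", "male")
  rec <- synth_record(s, build_template("normal", 0), noise_spec(), seed = 16)

  expect_identical(validate_record(rec)$status, "valid")

  key <- paste(rec$subject_id, format(rec$collection_date, "%Y-%m-%d"), sep = "|")
  expect_identical(validate_record(rec, seen_ids = key)$status, "duplicate")

  r2 <- rec; r2$signal <- integer(0)
  expect_identical(validate_record(r2)$status, "missing_signal")

  r3 <- rec; r3$signal <- rep(0L, 5000)
  v3 <- validate_record(r3)
  expect_identical(v3$status, "abnormal_signal")
  expect_match(v3$detail, "flatline")

  r4 <- rec; r4$signal[100] <- 50000L
  expect_identical(validate_record(r4)$status, "abnormal_signal")

  r5 <- rec; r5$collection_date <- rec$birth_date - 1
  expect_identical(validate_record(r5)$status, "invalid_dates")

  r6 <- rec; r6$height_cm <- 999
  expect_identical(validate_record(r6)$status, "invalid_anthropometry")

  # a duplicate that is also broken is still reported as duplicate first
  r7 <- r6
  expect_identical(validate_record(r7, seen_ids = key)$status, "duplicate")
})

test_that("cohort filter keeps only listed subjects aged 9-11 and conserves counts", {
  mk <- function(id, age) {
    s <- sample_subject(derive_seed(17, age * 7), "normal", "male",
                        subject_id = id)
    r <- synth_record(s, build_template("normal", 0), noise_spec(), seed = age)
    r$birth_date <- as.Date("2015-06-15") - round(age * 365.25) - 10
    r$collection_date <- as.Date("2015-06-15")
    r
  }
  recs <- list(mk("A", 8), mk("B", 9), mk("C", 10), mk("D", 11), mk("E", 12),
               mk("X", 10))
  res <- filter_cohort(recs, c("A", "B", "C", "D", "E"))
  expect_setequal(vapply(res$kept, `[[`, character(1), "subject_id"),
                  c("B", "C", "D"))
  expect_equal(sum(res$counts), length(recs))
  # idempotence
  res2 <- filter_cohort(res$kept, c("A", "B", "C", "D", "E"))
  expect_identical(vapply(res2$kept, `[[`, character(1), "subject_id"),
                   vapply(res$kept, `[[`, character(1), "subject_id"))
  # empty input
  res3 <- filter_cohort(list(), "A")
  expect_length(res3$kept, 0)
  expect_true(all(res3$counts == 0))
})

test_that("written cohorts survive the full ingest pipeline with the planned losses", {
  dir <- withr::local_tempdir()
  manifest <- write_cohort(5, c("normal", "overweight", "obese"), dir,
                           seed = 23, invalid_fraction = 0.2,
                           abnormal_fraction = 0.2)
  res <- build_cohort_dataset(dir)
  # 3 invalid (1 per class), 3 abnormal reports, 5 overweight records
  expect_equal(sum(res$validation$status != "valid"), 3)
  expect_equal(sum(res$exclusions$reason == "abnormal_report"), 2) # normal+obese classes
  expect_equal(sum(res$exclusions$reason == "overweight"), 4) # 5 - 1 invalid
  expect_setequal(unique(res$dataset$info$label), c("normal", "obese"))
})
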