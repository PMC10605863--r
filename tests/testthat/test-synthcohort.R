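test_that("sampled subjects land in their target BMI class and age band", {
  for (cls in c("normal", "overweight", "obese")) {
    for (sex in c("male", "female")) {
      s <- sample_subject(derive_seed(1, match(cls, c("normal", "overweight", "obese"))),
                          cls, sex)
      bmi <- compute_bmi(s$weight_kg, s$height_m)
      expect_identical(classify_bmi(bmi, sex), cls)
      expect_true(compute_age_years(s$birth_date, s$collection_date) %in% 9:11)
    }
  }
  s_ob <- sample_subject(1, "obese", "female")
  expect_gt(compute_bmi(s_ob$weight_kg, s_ob$height_m), 22.6)
  s_no <- sample_subject(1, "normal", "male")
  expect_lt(compute_bmi(s_no$weight_kg, s_no$height_m), 18.5)
})

test_that("subject sampling is deterministic under a fixed seed", {
  a <- sample_subject(99, "obese", "male")
  b <- sample_subject(99, "obese", "male")
  expect_identical(a, b)
})

test_that("zero effect size gives identical class templates", {
  tn <- build_template("normal", 0)
  to <- build_template("obese", 0)
  expect_identical(tn$components, to$components)
  expect_error(build_template("obese", -1), "nonnegative")
})

test_that("effect size shrinks the obese T wave and acts only in the window", {
  tn <- build_template("normal", 1)
  to <- build_template("obese", 1)
  t_amp <- function(tpl) tpl$components$amplitude_mV[tpl$components$label == "T"]
  expect_lt(t_amp(to), t_amp(tn))
  t_ms <- seq(-200, 398, by = 2)
  diff <- abs(eval_template(tn, t_ms) - eval_template(to, t_ms))
  outside <- t_ms < tn$diff_window_ms[1] | t_ms >= tn$diff_window_ms[2]
  # Gaussian tails leak outside the window: with a 35 ms T width the
  # largest tail difference at the window edge is ~2.5% of the in-window
  # peak difference; assert it stays below 3%
  expect_lt(max(diff[outside]), 0.03 * max(diff[!outside]))
  # R remains the global maximum of both templates
  for (tpl in list(tn, to)) {
    expect_equal(t_ms[which.max(eval_template(tpl, t_ms))], 0)
  }
})

test_that("synthetic records have 5000 samples and regular peaks at fixed HR", {
  s <- sample_subject(5, "normal", "female")
  rec <- synth_record(s, build_template("normal", 1), noise_spec_none(),
                      c(60, 60), seed = 6)
  expect_length(rec$signal, 5000)
  rt <- attr(rec, "r_truth")
  expect_true(length(rt) %in% c(10, 11))
  expect_true(all(diff(rt) == 500))
})

test_that("detector recovers hidden R truth on a noise-free record", {
  s <- sample_subject(7, "obese", "male")
  rec <- synth_record(s, build_template("obese", 1), noise_spec_none(),
                      c(60, 90), seed = 8)
  rt <- attr(rec, "r_truth")
  det <- detect_r_peaks(filter_signal(rec$signal / 1000, design_fir_bandpass()))
  expect_length(det, length(rt))
  expect_true(all(abs(det - rt) <= 5))
})

test_that("synth_record validates its heart-rate range", {
  s <- sample_subject(5, "normal", "female")
  tpl <- build_template("normal", 0)
  expect_error(synth_record(s, tpl, noise_spec_none(), c(90, 60)), "ascending")
  expect_error(synth_record(s, tpl, noise_spec_none(), c(10, 60)), "40")
})

test_that("write_cohort produces the expected files, manifest and determinism", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- write_cohort(5, c("normal", "obese"), dir1, seed = 7)
  expect_length(list.files(dir1, pattern = "\\.xml$"), 10)
  expect_equal(nrow(m1), 10)
  m2 <- write_cohort(5, c("normal", "obese"), dir2, seed = 7)
  f1 <- sort(list.files(dir1, pattern = "\\.xml$"))
  expect_identical(f1, sort(list.files(dir2, pattern = "\\.xml$")))
  for (f in f1) {
    expect_identical(readLines(file.path(dir1, f), warn = FALSE),
                     readLines(file.path(dir2, f), warn = FALSE))
  }
})

test_that("invalid and abnormal fractions are allocated exactly", {
  dir <- withr::local_tempdir()
  m <- write_cohort(10, c("normal", "obese"), dir, seed = 3,
                    invalid_fraction = 0.2, abnormal_fraction = 0.1)
  for (cl in c("normal", "obese")) {
    expect_equal(sum(m$invalid[m$target_class == cl]), 2)
    expect_equal(sum(m$abnormal[m$target_class == cl]), 1)
  }
})

test_that("class-mean difference is confined to the difference window", {
  # zero-noise cohort: pointwise class-mean beat difference is (nearly)
  # zero outside the configured T-wave window
  dir <- withr::local_tempdir()
  write_cohort(3, c("normal", "obese"), dir, seed = 31, effect_size = 1,
               noise = noise_spec_none())
  recs <- parse_record_dir(dir)
  cls_means <- lapply(c("normal", "obese"), function(cl) {
    beats <- list()
    for (r in recs) {
      if (!startsWith(r$subject_id, paste0("S", substr(cl, 1, 3)))) next
      seg <- segment_record(r$signal / 1000)
      beats[[length(beats) + 1]] <- seg$beats
    }
    colMeans(do.call(rbind, beats))
  })
  d <- abs(cls_means[[1]] - cls_means[[2]])
  win <- t_wave_window()
  inside <- seq_len(300) > win["start"] & seq_len(300) <= win["end"]
  expect_gt(max(d[inside]), 0.05)
  # the 0.5 Hz high-pass leg of the band-pass subtracts a ~1 s local
  # mean, which smears a slice of the in-window difference across the
  # beat (~13% of the in-window peak, plus ~2.5% Gaussian tail leakage);
  # locality therefore holds to ~15%, not exactly
  expect_lt(max(d[!inside]), 0.15 * max(d[inside]))
})
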