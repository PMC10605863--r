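test_that("BMI formula and validation", {
  expect_equal(compute_bmi(45, 1.5), 20)
  expect_error(compute_bmi(50, 0), "height")
  expect_error(compute_bmi(-1, 1.5), "weight")
  # scale invariance: quadrupled weight at doubled height leaves BMI unchanged
  expect_equal(compute_bmi(4 * 45, 2 * 1.5), compute_bmi(45, 1.5))
})

test_that("BMI categories follow the sex-specific cutoffs with boundary->overweight", {
  expect_identical(classify_bmi(22.7, "female"), "obese")
  expect_identical(classify_bmi(18.4, "male"), "normal")
  expect_identical(classify_bmi(21.4, "male"), "overweight")
  expect_identical(classify_bmi(19.0, "female"), "overweight")
  expect_identical(classify_bmi(22.6, "female"), "overweight")
  expect_identical(classify_bmi(18.9, "female"), "normal")
  expect_identical(classify_bmi(21.5, "male"), "obese")
  expect_error(classify_bmi(20, "unknown"), "sex")
})

test_that("FIR design passes mid-band, rejects DC and keeps finite support", {
  h <- design_fir_bandpass()
  expect_length(h, fir_spec()$num_taps)
  resp <- fir_response(h, c(0, 10, 20))
  expect_lte(resp[1], 0.01)
  expect_gte(resp[2], 0.95)
  expect_lte(resp[2], 1.05)
  expect_gte(resp[3], 0.95)
  # impulse response support equals the tap count (FIR definition);
  # threshold guards against FFT round-off in the convolution
  imp <- c(1, rep(0, 4999))
  y <- stats::convolve(imp, rev(h), type = "open")
  expect_lte(max(which(abs(y) > 1e-9 * max(abs(y)))), length(h))
  expect_error(fir_spec(40, 0.5), "band edges")
  expect_error(fir_spec(num_taps = 500), "odd")
})

test_that("zero-delay filtering preserves in-band tones and removes DC", {
  h <- design_fir_bandpass()
  fs <- 500
  t <- (0:4999) / fs
  tone <- sin(2 * pi * 10 * t)
  y <- filter_signal(tone, h)
  core <- 1000:4000 # away from zero-padded edges
  expect_lt(max(abs(y[core] - tone[core])) / max(abs(tone)), 0.05)
  dc <- rep(1, 5000)
  ydc <- filter_signal(dc, h)
  expect_lt(max(abs(ydc[core])), 0.01)
  expect_true(all(filter_signal(rep(0, 5000), h) == 0))
  expect_error(filter_signal(rep(0, 100), h), "shorter")
})

test_that("the filter is linear and time-invariant", {
  h <- design_fir_bandpass(fir_spec(num_taps = 501))
  set.seed(42)
  a <- rnorm(3000)
  b <- rnorm(3000)
  expect_equal(filter_signal(2 * a + 3 * b, h),
               2 * filter_signal(a, h) + 3 * filter_signal(b, h),
               tolerance = 1e-10)
  # time invariance: shifting the input shifts the output (interior samples)
  ya <- filter_signal(a, h)
  shifted <- c(rep(0, 7), a[1:(3000 - 7)])
  ys <- filter_signal(shifted, h)
  expect_equal(ys[500:2500], ya[493:2493], tolerance = 1e-10)
})

test_that("flat signal yields no peaks; close peaks are suppressed", {
  expect_length(detect_r_peaks(rep(0, 5000)), 0)
  # two QRS-like bumps 80 ms apart: the refractory distance admits only
  # one detection for the pair
  t_ms <- (0:4999) * 2
  tpl <- build_template("normal", 0)
  x <- eval_template(tpl, t_ms - 2000) + eval_template(tpl, t_ms - 2080)
  x <- x + eval_template(tpl, t_ms - 6000) # an honest far-away beat too
  det <- detect_r_peaks(x)
  expect_equal(sum(abs(det - 1021) <= 30), 1)
  expect_true(all(diff(det) > 100))
})

test_that("detector keeps full sensitivity at the default noise profile", {
  hits <- 0
  total <- 0
  h <- design_fir_bandpass()
  for (i in 1:50) {
    cls <- if (i %% 2) "normal" else "obese"
    su <- sample_subject(derive_seed(909, 2 * i), cls, "male")
    r <- synth_record(su, build_template(cls, 1), noise_spec(), c(70, 110),
                      seed = derive_seed(909, 2 * i + 1))
    tr <- attr(r, "r_truth")
    d <- detect_r_peaks(filter_signal(r$signal / 1000, h))
    hits <- hits + sum(vapply(tr, function(t) any(abs(d - t) <= 5), logical(1)))
    total <- total + length(tr)
  }
  expect_gte(hits / total, 0.99)
})

test_that("beat windows are half-open with R at offset 100 and conserve counts", {
  x <- seq_len(5000) / 1000
  # 1-based convention: the earliest complete window starts at sample 1
  # (R at 101) and the latest ends at sample 5000 (R at 4801)
  r <- c(100, 101, 2500, 4801, 4802)
  res <- extract_beats(x, r)
  expect_equal(res$r_kept, c(101L, 2500L, 4801L))
  expect_equal(res$discarded$r_index, c(100L, 4802L))
  expect_equal(res$discarded$reason, c("incomplete_head", "incomplete_tail"))
  expect_equal(nrow(res$beats) + nrow(res$discarded), length(r))
  expect_equal(ncol(res$beats), 300)
  # window content: [r-100, r+200) so local position 101 is the R sample
  expect_equal(res$beats[1, ], x[1:300])
  expect_equal(res$beats[2, 101], x[2500])
  expect_equal(res$beats[3, ], x[4701:5000])
})

test_that("kept synthetic beats peak at the R offset", {
  s <- sample_subject(77, "normal", "female")
  rec <- synth_record(s, build_template("normal", 1), noise_spec_none(),
                      c(60, 80), seed = 78)
  seg <- segment_record(rec$signal / 1000)
  expect_gt(nrow(seg$beats), 5)
  expect_true(all(apply(seg$beats, 1, which.max) == 101))
  expect_equal(length(seg$r_detected),
               nrow(seg$beats) + nrow(seg$discarded))
})
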