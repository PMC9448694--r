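test_that("generation is bit-reproducible and respects trajectory bounds", {
  tr <- depth_trajectory(c(0, 60, 120, 180), c(97.7, 97.7, 50, 50))
  r1 <- synth_eeg(180, tr, seed = 7)
  r2 <- synth_eeg(180, tr, seed = 7)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$bis, r2$bis)
  r3 <- synth_eeg(180, tr, seed = 8)
  expect_false(identical(r1$samples, r3$samples))
  truth <- attr(r1, "truth_depth")
  expect_true(all(truth >= 0 & truth <= 100))
  expect_length(truth, 180)
  expect_error(synth_eeg(60, constant_trajectory(50, 60)), "120")
  expect_error(synth_eeg(300, tr), "cover")
})

test_that("trajectory interpolation is piecewise linear with clamped ends", {
  tr <- depth_trajectory(c(0, 100, 200), c(90, 50, 50))
  expect_equal(depth_at(tr, c(0, 50, 100, 150, 250)), c(90, 70, 50, 50, 50))
  expect_error(depth_trajectory(c(0, 10), c(50, 101)), "\\[0, 100\\]")
  expect_error(depth_trajectory(c(10, 20), c(50, 50)), "time 0")
  expect_error(depth_trajectory(c(0, 0), c(50, 50)), "increasing")
})

test_that("awake recordings carry more windowed entropy than deep ones", {
  awake <- synth_eeg(600, constant_trajectory(95, 600), seed = 11)
  deep <- synth_eeg(600, constant_trajectory(12, 600), seed = 11)
  mean_de <- function(rec) {
    seg <- segment_eeg(rec)
    mean(vapply(seq(1, length(seg$starts), by = 30),
                function(i) dispersion_entropy(segment_window(seg, i)),
                numeric(1)))
  }
  expect_gt(mean_de(awake), mean_de(deep))
})

test_that("windowed entropy decreases across the depth grid", {
  de_at_depth <- function(d, seeds = 1:3) {
    mean(vapply(seeds, function(s) {
      rec <- synth_eeg(240, constant_trajectory(d, 240), seed = s * 1000 + d)
      seg <- segment_eeg(rec)
      mean(vapply(seq(1, length(seg$starts), by = 40),
                  function(i) dispersion_entropy(segment_window(seg, i)),
                  numeric(1)))
    }, numeric(1)))
  }
  des <- vapply(c(95, 70, 50, 30, 10), de_at_depth, numeric(1))
  expect_true(all(diff(des) < 0))
})

test_that("artifact injection is annotated, seeded and spectrally visible", {
  rec <- synth_eeg(180, constant_trajectory(60, 180), seed = 21)
  expect_identical(inject_artifacts(rec, rate = 0), rec)
  expect_error(inject_artifacts(rec, kinds = "blink"), "unknown")
  # 50 Hz line pickup appears as a new spectral peak
  with_line <- inject_artifacts(rec, kinds = "line50", seed = 22)
  spec_at_50 <- function(r) {
    sp <- Mod(stats::fft(r$samples))^2
    f <- (seq_along(sp) - 1) * r$fs / length(sp)
    sum(sp[abs(f - 50) < 0.5])
  }
  expect_gt(spec_at_50(with_line), 3 * spec_at_50(rec))
  expect_equal(with_line$annotations$kind, "line50")
  # EMG bursts: one annotation per injected epoch, reproducible
  a1 <- inject_artifacts(rec, kinds = "emg", rate = 3, seed = 23)
  a2 <- inject_artifacts(rec, kinds = "emg", rate = 3, seed = 23)
  expect_identical(a1$samples, a2$samples)
  expect_identical(a1$annotations, a2$annotations)
  expect_gt(nrow(a1$annotations), 0)
  expect_true(all(a1$annotations$kind == "emg"))
})

test_that("SQI simulation blanks the reference exactly where quality is poor", {
  rec <- synth_eeg(1000, seed = 31)
  clean <- simulate_sqi(rec)
  expect_true(all(clean$sqi == 100))      # no artifacts, no dropouts
  expect_false(anyNA(clean$bis))
  dropped <- simulate_sqi(rec, dropout_spans = list(c(500, 900)))
  expect_true(all(dropped$sqi[501:900] < 15))
  expect_true(all(is.na(dropped$bis[501:900])))
  expect_false(anyNA(dropped$bis[c(1:500, 901:1000)]))
  # truth survives the blanking
  expect_false(anyNA(attr(dropped, "truth_depth")))
  expect_error(simulate_sqi(rec, dropout_spans = list(c(900, 500))), "malformed")
  expect_error(simulate_sqi(rec, dropout_spans = list(c(100, 300), c(200, 400))),
               "overlapping")
})

test_that("cohorts are reproducible with distinct, state-complete subjects", {
  c1 <- make_cohort(5, seed = 7, duration_s = 300, artifact_rate = 0)
  c2 <- make_cohort(5, seed = 7, duration_s = 300, artifact_rate = 0)
  for (i in seq_along(c1)) expect_identical(c1[[i]]$samples, c2[[i]]$samples)
  # subjects differ pairwise in their changepoint times
  cps <- lapply(c1, function(r) r$trajectory$times)
  for (i in 1:4) for (j in (i + 1):5)
    expect_false(isTRUE(all.equal(cps[[i]], cps[[j]])))
  # every subject's truth visits all three states
  for (r in c1)
    expect_setequal(unique(r$truth_state), c("awake", "moderate", "deep"))
  expect_error(make_cohort(1), "at least 2")
})
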