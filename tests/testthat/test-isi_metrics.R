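test_that("spike detection recovers closed-form sinusoid peaks", {
  t <- seq(0, 100, by = 0.05)
  tr <- structure(data.frame(t = t, V = -20 + 30 * sin(2 * pi * t / 10)),
                  class = c("prebotc_traj", "data.frame"))
  train <- detect_spikes(tr, threshold = -35, min_prominence = 5)
  # peaks at 2.5, 12.5, ..., 92.5
  expect_equal(length(train$peak_times), 10)
  expect_equal(train$peak_times, seq(2.5, 92.5, by = 10), tolerance = 1e-3)
  expect_equal(train$peak_values, rep(10, 10), tolerance = 1e-3)
})

test_that("flat and subthreshold traces yield an empty spike train", {
  t <- seq(0, 1000, by = 0.5)
  flat <- structure(data.frame(t = t, V = rep(-60, length(t))),
                    class = c("prebotc_traj", "data.frame"))
  expect_length(detect_spikes(flat)$peak_times, 0)
  # oscillation below threshold
  low <- structure(data.frame(t = t, V = -50 + 3 * sin(t / 5)),
                   class = c("prebotc_traj", "data.frame"))
  expect_length(detect_spikes(low, threshold = -35)$peak_times, 0)
})

test_that("interspike intervals and their log10 transform", {
  train <- structure(list(peak_times = c(0, 10, 20), peak_values = rep(0, 3)),
                     class = "prebotc_spikes")
  expect_equal(spike_isi(train), c(10, 10))
  expect_equal(spike_isi(train, log10 = TRUE), c(1, 1))
  one <- structure(list(peak_times = 5, peak_values = 0),
                   class = "prebotc_spikes")
  expect_length(spike_isi(one), 0)
})

test_that("baseline bursting has a bimodal ISI distribution", {
  isi <- spike_isi(detect_spikes(baseline_traj()))
  expect_gt(length(isi), 50)
  intra <- isi[isi < 100]
  inter <- isi[isi > 800]          # quiescent-phase intervals
  expect_gt(length(intra), 10)     # millisecond-scale within-burst intervals
  expect_gt(length(inter), 2)
  expect_lt(median(intra), 50)
  expect_gt(min(inter), 1000)      # quiescent phase of order 1 s
})

test_that("phase segmentation splits a symmetric synthetic burst evenly", {
  seg <- segment_phases(synthetic_burst())
  expect_equal(seg$phase, 1:4)
  expect_true(all(seg$duration[c(1, 2, 4)] > 0))
  # symmetric envelope: decay and regrowth stages have equal length
  expect_equal(seg$duration[2], seg$duration[4], tolerance = 0.05)
  expect_gt(seg$duration[1], 900)  # the constructed 1 s quiescent stage
})

test_that("patterns classify from phase presence", {
  t <- seq(0, 5000, by = 0.5)
  flat <- structure(data.frame(t = t, V = rep(-60, length(t))),
                    class = c("prebotc_traj", "data.frame"))
  expect_equal(classify_pattern(flat), "quiescent")
  tonic <- structure(data.frame(t = t, V = -20 + 30 * sin(2 * pi * t / 10)),
                     class = c("prebotc_traj", "data.frame"))
  expect_equal(classify_pattern(tonic), "continuous_spiking")
  expect_equal(classify_pattern(synthetic_burst()),
               "bursting_low_quiescence")
  expect_error(classify_pattern(flat[t < 1000, ]), "short")
})

test_that("sweep bookkeeping: transitions and empty grids", {
  sw <- pattern_sweep("Iextz", numeric(0), botc_params())
  expect_length(sw$values, 0)
  expect_equal(nrow(sw$transitions), 0)
  # two-point sweep across the quiescence-loss transition
  sw2 <- pattern_sweep("Iextz", c(33, 34), botc_params(k1 = 0.1),
                       t_end = 46000, transient = 20000)
  expect_equal(sw2$labels,
               c("bursting_low_quiescence", "continuous_spiking"))
  expect_equal(nrow(sw2$transitions), 1)
  expect_equal(sw2$transitions$lower, 33)
})
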