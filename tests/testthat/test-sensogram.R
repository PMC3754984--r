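# helpers to fabricate feature tables without the optics engine
fab_sensogram <- function(times, d_angle = 0, d_intensity = 0,
                          base_angle = 71.85, base_intensity = 0.076,
                          injections = data.frame(start_s = 120,
                                                  end_s = 480,
                                                  label = "x",
                                                  concentration = 1)) {
  n <- length(times)
  rep_len2 <- function(x) rep_len(x, n)
  sensogram(data.frame(time_s = times,
                       peak_angle_deg = base_angle + rep_len2(d_angle),
                       peak_intensity = base_intensity +
                         rep_len2(d_intensity),
                       tir_angle_deg = 62.7, tir_intensity = 0.7),
            injections)
}

# first-order pulse shape on the scan clock
pulse <- function(times, amp, t0 = 120, t1 = 480, tau_on = 60,
                  tau_off = 120, offset = 0) {
  x <- numeric(length(times))
  inj <- times >= t0 & times <= t1
  x[inj] <- amp * (1 - exp(-(times[inj] - t0) / tau_on))
  xe <- amp * (1 - exp(-(t1 - t0) / tau_on))
  post <- times > t1
  x[post] <- offset + (xe - offset) * exp(-(times[post] - t1) / tau_off)
  x
}

times <- seq(0, 1080, by = 4)

test_that("sensogram construction checks times and injection windows", {
  expect_error(fab_sensogram(c(0, 4, 4, 12)), "strictly ascending")
  expect_error(fab_sensogram(times,
                             injections = data.frame(start_s = -10,
                                                     end_s = 480)),
               "within the recorded time range")
  expect_error(features_over_time(list()), "at least two")
})

test_that("a constant sensogram yields all-zero deltas and no response", {
  sg <- fab_sensogram(times)
  d <- baseline_deltas(sg)
  for (v in c("d_peak_angle", "d_peak_intensity", "d_tir_angle",
              "d_tir_intensity"))
    expect_true(all(d[[v]] == 0))
  s <- trajectory(d)
  expect_true("degenerate-window" %in% s$flags)
  expect_equal(as.character(classify_response(s)), "no-response")
  # too little baseline is refused
  late <- fab_sensogram(seq(100, 1080, 4))
  expect_error(baseline_deltas(late), "30 s of pre-injection")
})

test_that("trajectory slope recovers exact linear angle-intensity coupling", {
  da <- pulse(times, -0.2)
  c_true <- 0.05   # positive coupling: both deltas go negative together
  sg <- fab_sensogram(times, d_angle = da, d_intensity = c_true * da)
  s <- trajectory(baseline_deltas(sg))
  expect_equal(abs(s$slope), abs(c_true), tolerance = 1e-6)
  expect_lt(s$delta_angle_extremum, 0)
  expect_lt(s$delta_intensity_extremum, 0)
  # intensity flat: horizontal trajectory
  sg0 <- fab_sensogram(times, d_angle = da, d_intensity = 0)
  s0 <- trajectory(baseline_deltas(sg0))
  expect_equal(s0$slope, 0)
  expect_false(s0$reversal)
})

test_that("recovery fraction separates returning from persistent responses", {
  full <- fab_sensogram(times, d_angle = pulse(times, -0.1, offset = 0))
  s_full <- trajectory(baseline_deltas(full))
  expect_gte(s_full$recovery_fraction, 0.9)
  held <- fab_sensogram(times, d_angle = pulse(times, -0.1, offset = 0.05))
  s_held <- trajectory(baseline_deltas(held))
  expect_lt(s_held$recovery_fraction, 0.6)
})

test_that("reversal is flagged when the angular change flips sign", {
  da <- pulse(times, -0.15) + pulse(times, 0.4, t0 = 300)
  sg <- fab_sensogram(times, d_angle = da,
                      d_intensity = 0.05 * da)
  s <- trajectory(baseline_deltas(sg))
  expect_true(s$reversal)
})

test_that("classification follows the four-scenario decision rules", {
  mk <- function(ext_a, ext_i, recovery) {
    structure(list(delta_angle_extremum = ext_a,
                   delta_intensity_extremum = ext_i, slope = 0,
                   recovery_fraction = recovery, reversal = FALSE,
                   flags = character(0)),
              noise = c(d_peak_angle = 0.003, d_peak_intensity = 0.0003,
                        d_tir_angle = 0.003, d_tir_intensity = 0.001),
              class = "spr_trajectory")
  }
  expect_equal(as.character(classify_response(mk(-0.1, -0.01, 0.4))),
               "transcellular-like")
  expect_equal(as.character(classify_response(mk(-0.05, 0.0005, 0.98))),
               "paracellular-like")
  expect_equal(as.character(classify_response(mk(0.08, 0.0002, 0.9))),
               "accumulation-only")
  expect_equal(as.character(classify_response(mk(0.08, 0.012, 0.2))),
               "spreading")
  expect_equal(as.character(classify_response(mk(0.001, 0.0001, 1))),
               "no-response")
  # opposite-sign pattern that fits no scenario
  amb <- classify_response(mk(-0.1, 0.02, 0.2))
  expect_equal(as.character(amb), "no-response")
  expect_true("ambiguous" %in% attr(amb, "flags"))
})

test_that("classification is invariant to time rescaling and offsets", {
  da <- pulse(times, -0.12)
  di <- -0.04 * da
  base <- fab_sensogram(times, d_angle = da, d_intensity = di)
  lab0 <- as.character(classify_sensogram(base))
  # uniform time rescaling (and matching injection window)
  sc <- 3
  resc <- sensogram(transform(base$features, time_s = time_s * sc),
                    data.frame(start_s = 120 * sc, end_s = 480 * sc,
                               label = "x", concentration = 1))
  expect_equal(as.character(classify_sensogram(resc, lag = 60 * sc,
                                               tail_window = 60 * sc)),
               lab0)
  # constant offsets on the raw features are removed by the baseline
  off <- base
  off$features$peak_angle_deg <- off$features$peak_angle_deg + 1.3
  off$features$peak_intensity <- off$features$peak_intensity + 0.05
  expect_equal(as.character(classify_sensogram(off)), lab0)
})

test_that("feature series from identical spectra produce identical rows", {
  sp <- simulate_scan(build_cell_stack(), spr_angle_grid(by = 0.05))
  sp1 <- sp; sp1$timestamp <- 0
  sp2 <- sp; sp2$timestamp <- 4
  sg <- features_over_time(list(sp1, sp2))
  expect_equal(sg$features$peak_angle_deg[1], sg$features$peak_angle_deg[2])
  expect_equal(sg$features$tir_intensity[1], sg$features$tir_intensity[2])
  bad <- list(sp2, sp1)
  expect_error(features_over_time(bad), "ascending")
})
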