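test_that("decimation reduces the rate with anti-aliasing", {
  rec <- white_recording(rate = 1000, dur = 3)
  out <- decimate(rec, 250)
  expect_equal(out$rate, 250)
  expect_equal(ncol(out$data), 750)          # floor(3000 * 250/1000)

  expect_identical(decimate(rec, 1000), rec) # factor 1 is the identity
  expect_error(decimate(rec, 300), "unsupported rate")

  # a 5 Hz sinusoid survives 1000 -> 250 Hz with amplitude within 1%
  tone <- tone_recording(5, rate = 1000, dur = 4)
  dec <- decimate(tone, 250)
  t_dec <- seq(0, by = 4 / 1000, length.out = ncol(dec$data))
  ref <- sin(2 * pi * 5 * t_dec)
  i <- 200:800
  expect_lt(max(abs(dec$data[1, i] - ref[i])), 0.01)
})

test_that("notch removes the line frequency and spares neighbours", {
  tone <- tone_recording(50, rate = 250, dur = 8)
  out <- notch(tone, 50)
  expect_lt(mid_rms(out), mid_rms(tone) / 30)      # >= 30 dB at 50 Hz

  for (f in c(40, 60)) {                           # <= 3 dB at 50 +/- 10 Hz
    t2 <- tone_recording(f, rate = 250, dur = 8)
    o2 <- notch(t2, 50)
    expect_gt(mid_rms(o2) / mid_rms(t2), 10^(-3 / 20))
  }

  z <- eeg_recording(matrix(0, 2, 1000), 250)
  expect_equal(notch(z, 50)$data, z$data)
  expect_error(notch(white_recording(), 125), "invalid frequency")

  # broadband power away from the notch is preserved within 1 dB
  wn <- white_recording(rate = 250, dur = 20, seed = 2)
  nf <- notch(wn, 50)
  for (band in list(c(5, 40), c(60, 110))) {
    ratio <- band_power(nf$data[1, ], 250, band[1], band[2]) /
             band_power(wn$data[1, ], 250, band[1], band[2])
    expect_gt(ratio, 10^(-1 / 10))
    expect_lt(ratio, 10^(1 / 10))
  }
})

test_that("band-pass keeps the pass band and rejects outside", {
  # DC is in the stop band: away from the edge transients the constant
  # offset is removed to well within 1%
  dc <- eeg_recording(matrix(5, 1, 4000), 250)
  out <- bandpass(dc, 0.5, 80)
  expect_lt(abs(mean(out$data[1, 1000:3000])), 0.05)

  # 10 Hz tone through 0.5-80 Hz: within 1 dB
  t10 <- tone_recording(10, rate = 250, dur = 8)
  o10 <- bandpass(t10, 0.5, 80)
  expect_gt(mid_rms(o10) / mid_rms(t10), 10^(-1 / 20))
  expect_lt(mid_rms(o10) / mid_rms(t10), 10^(1 / 20))

  # 100 Hz tone at rate 250: attenuated by >= 20 dB
  t100 <- tone_recording(100, rate = 250, dur = 8)
  o100 <- bandpass(t100, 0.5, 80)
  expect_lt(mid_rms(o100) / mid_rms(t100), 10^(-20 / 20))

  # one octave below the low edge: >= 20 dB down
  t_low <- tone_recording(0.25, rate = 250, dur = 60)
  o_low <- bandpass(t_low, 0.5, 80)
  expect_lt(mid_rms(o_low) / mid_rms(t_low), 10^(-20 / 20))

  expect_error(bandpass(t10, 0.5, 150), "invalid frequencies")
  expect_error(bandpass(t10, -1, 80), "invalid frequencies")
})

test_that("re-referencing subtracts the mastoid mean", {
  # constant reference channels shift every channel by -c
  dat <- rbind(sin(1:100), cos(1:100), rep(3, 100), rep(3, 100))
  rec <- eeg_recording(dat, 250, labels = c("a", "b", "m1", "m2"))
  out <- rereference(rec, c("m1", "m2"))
  expect_equal(out$data[1, ], dat[1, ] - 3)
  expect_equal(out$reference, "mean(m1,m2)")

  # 3-channel toy against hand-computed differences
  d3 <- matrix(c(1, 2, 3,
                 4, 5, 6,
                 7, 8, 9), 3, 3, byrow = TRUE)
  r3 <- eeg_recording(d3, 100, labels = c("x", "r1", "r2"))
  o3 <- rereference(r3, c("r1", "r2"))
  refmean <- (d3[2, ] + d3[3, ]) / 2
  expect_equal(o3$data[1, ], d3[1, ] - refmean)
  expect_equal(o3$data[2, ], d3[2, ] - refmean)

  # referenced twice: reference channels are a zero-mean pair, so the
  # second application changes nothing
  oo <- rereference(o3, c("r1", "r2"))
  expect_equal(oo$data, o3$data)

  expect_error(rereference(r3, c("r1", "zz")), "unknown channel")
})

test_that("channel exclusion drops the listed electrodes in order", {
  rec <- white_recording(rate = 250, dur = 1, n_ch = 128)
  out <- exclude_channels(rec)        # default 9-electrode dense-array list
  expect_equal(nrow(out$data), 119)
  expect_equal(out$labels, setdiff(as.character(1:128),
                                   c("8", "14", "17", "21", "25",
                                     "125", "126", "127", "128")))
  expect_identical(exclude_channels(rec, character(0)), rec)
  small <- white_recording(rate = 250, dur = 1, n_ch = 2)
  expect_error(exclude_channels(small, c("1", "2")), "empty recording")
  expect_error(exclude_channels(small, "99"), "unknown channel")
})

test_that("band decomposition covers the five analysis bands", {
  bt <- band_table()
  expect_equal(bt$band, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(bt$low, c(0.5, 3.5, 7.5, 12.5, 30))
  expect_equal(bt$high, c(3.5, 7.5, 12.5, 30, 45))
  expect_error(band_table(low = c(1, 2), high = c(0.5, 3), band = c("a", "b")),
               "strictly increasing")

  # 4 Hz tone lands in theta
  t4 <- tone_recording(4, rate = 250, dur = 8)
  bands <- band_decompose(t4)
  expect_named(bands, bt$band)
  pw <- vapply(bands, mid_rms, numeric(1))
  expect_equal(names(which.max(pw)), "theta")

  # zero input gives five zero outputs
  z <- eeg_recording(matrix(0, 1, 1000), 250)
  expect_true(all(vapply(band_decompose(z),
                         function(b) max(abs(b$data)), numeric(1)) < 1e-12))

  # band powers tile broadband power (white noise, 0.5-45 Hz) within 20%
  wn <- white_recording(rate = 250, dur = 30, seed = 9)
  bands <- band_decompose(wn)
  p_band <- sum(vapply(bands, function(b)
    band_power(b$data[1, ], 250, 0.5, 45), numeric(1)))
  p_broad <- band_power(wn$data[1, ], 250, 0.5, 45)
  expect_gt(p_band / p_broad, 0.8)
  expect_lt(p_band / p_broad, 1.2)
})

test_that("preprocessing stages are linear and keep samples finite", {
  a <- white_recording(rate = 250, dur = 4, seed = 3)
  b <- white_recording(rate = 250, dur = 4, seed = 4)
  mix <- eeg_recording(2 * a$data - 0.5 * b$data, 250)
  for (stage in list(function(r) notch(r, 50),
                     function(r) bandpass(r, 0.5, 80))) {
    lhs <- stage(mix)$data
    rhs <- 2 * stage(a)$data - 0.5 * stage(b)$data
    expect_equal(lhs, rhs, tolerance = 1e-6)
    expect_true(all(is.finite(lhs)))
  }
})

test_that("the orchestrated chain runs in the documented stage order", {
  rec <- white_recording(rate = 1000, dur = 2, n_ch = 4, seed = 12)
  cfg <- preprocess_config(target_rate = 250, reference_pair = c("1", "2"),
                           exclusion = "4", bands = band_table())
  out <- preprocess_recording(rec, cfg)
  expect_equal(out$broadband$rate, 250)
  expect_equal(out$broadband$labels, c("1", "2", "3"))
  expect_named(out$bands, band_table()$band)
  # hook stage is applied
  cfg$artifact_hook <- function(r) { r$data <- r$data * 0; r }
  out2 <- preprocess_recording(rec, cfg)
  expect_equal(max(abs(out2$broadband$data)), 0)
})
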