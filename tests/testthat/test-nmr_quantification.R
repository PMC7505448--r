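# compact FID builder: damped complex oscillations at given ppm/area/fwhm
toy_fid <- function(ppm, area, fwhm_ppm, n = 4096, sweep_ppm = 12,
                    carrier = 242.93) {
  dt <- 1 / (sweep_ppm * carrier)
  t <- (seq_len(n) - 1) * dt
  sig <- Reduce(`+`, Map(function(p, a, w) {
    a * exp(2i * pi * p * carrier * t) * exp(-pi * w * carrier * t)
  }, ppm, area, fwhm_ppm))
  nmr_fid(sig, dt, carrier)
}

test_that("exponential apodization has the stated envelope", {
  dt <- 1e-3
  fid <- nmr_fid(rep(1 + 0i, 100), dt)
  expect_equal(apodize_fid(fid, 0)$points, fid$points)     # identity at lb = 0
  ap <- apodize_fid(fid, 3.0)
  k <- 0:99
  expect_equal(Mod(ap$points), exp(-pi * 3 * k * dt), tolerance = 1e-12)
  expect_equal(ap$points[1], fid$points[1])                # first point unchanged
  expect_error(apodize_fid(fid, -1), "lb_hz")
})

test_that("Fourier transform recovers Lorentzians with correct areas", {
  # one damped oscillation -> one line at its ppm position
  fid <- toy_fid(0.8, 1, 0.04)
  sp <- transform_and_scale(fid)
  expect_equal(sp$ppm[which.max(sp$intensity)], 0.8, tolerance = 0.01)
  # two well-separated lines: area ratio equals amplitude ratio
  # (integrate equal +/- 1 ppm windows so tail truncation cancels)
  fid2 <- toy_fid(c(1.5, -1.5), c(3, 1), c(0.04, 0.04))
  sp2 <- transform_and_scale(fid2)
  hi <- abs(sp2$ppm - 1.5) < 1
  lo <- abs(sp2$ppm + 1.5) < 1
  expect_equal(sum(sp2$intensity[hi]) / sum(sp2$intensity[lo]), 3,
               tolerance = 0.01)
  # zero FID -> zero spectrum
  sp0 <- transform_and_scale(nmr_fid(rep(0 + 0i, 64), 1e-3))
  expect_true(all(sp0$intensity == 0))
})

test_that("baseline correction removes a ramp but preserves peak areas", {
  fid <- toy_fid(0.5, 1, 0.05)
  sp <- transform_and_scale(fid)
  area0 <- sum(sp$intensity)
  ramp <- seq(-2, 5, length.out = length(sp$ppm))
  spr <- nmr_spectrum(sp$ppm, sp$intensity + ramp)
  cor <- baseline_correct(spr, polynomial_order = 1)
  expect_equal(sum(cor$intensity), area0, tolerance = 0.01)
  # flat zero spectrum unchanged
  flat <- nmr_spectrum(sp$ppm, rep(0, length(sp$ppm)))
  expect_equal(baseline_correct(flat, 2)$intensity, flat$intensity)
  # idempotence
  twice <- baseline_correct(cor, 1)
  expect_lt(max(abs(twice$intensity - cor$intensity)),
            1e-6 * max(abs(cor$intensity)))
  expect_error(baseline_correct(nmr_spectrum(c(2, 1), c(0, 0)), 5), "shorter")
})

test_that("calibration puts the tallest peak at exactly 0 ppm", {
  fid <- toy_fid(c(-0.84, -1.4), c(1, 0.3), c(0.04, 0.04))
  sp <- calibrate(baseline_correct(transform_and_scale(fid), 1))
  expect_true(sp$ppm[which.max(sp$intensity)] == 0)
  # idempotence
  sp2 <- calibrate(sp)
  expect_equal(sp2$ppm, sp$ppm)
  # all-noise spectrum fails
  set.seed(1)
  noisy <- nmr_spectrum(seq(6, -6, length.out = 512), rnorm(512))
  expect_error(calibrate(noisy), "calibration-failure")
  # exact tie: leftmost (highest ppm) chosen with a warning
  tie <- nmr_spectrum(seq(2, -2, length.out = 401),
                      c(rep(0, 100), 10, rep(0, 199), 10, rep(0, 100)))
  expect_warning(ct <- calibrate(tie, min_snr = 0), "highest ppm")
  expect_true(ct$ppm[which.max(ct$intensity)] == 0)
})

test_that("deconvolution recovers Lorentzian parameters within 2%", {
  ppm_axis <- seq(3, -3, length.out = 4096)
  set.seed(5)
  y1 <- evlipid:::lorentz(ppm_axis, -0.1, 0.05, 1) +
    rnorm(4096, 0, 0.01)
  f1 <- deconvolute(nmr_spectrum(ppm_axis, y1))
  expect_equal(nrow(f1), 1)
  expect_equal(f1$center, -0.1, tolerance = 0.02)
  expect_equal(f1$fwhm, 0.05, tolerance = 0.02)
  expect_equal(f1$area, 1 * 0.05 * pi / 2, tolerance = 0.02)
  # closed-form area consistency
  expect_equal(f1$area, f1$amplitude * f1$fwhm * pi / 2, tolerance = 1e-9)

  # two peaks separated by 3x fwhm: areas within 2%
  y2 <- evlipid:::lorentz(ppm_axis, 0.0, 0.05, 2) +
    evlipid:::lorentz(ppm_axis, 0.15, 0.05, 1) + rnorm(4096, 0, 0.01)
  f2 <- deconvolute(nmr_spectrum(ppm_axis, y2))
  f2 <- f2[order(f2$center), ]
  expect_equal(nrow(f2), 2)
  expect_equal(f2$area[1] / f2$area[2], 2, tolerance = 0.02)

  # zero spectrum: empty fit
  f0 <- deconvolute(nmr_spectrum(ppm_axis, rep(0, 4096)))
  expect_equal(nrow(f0), 0)
})

test_that("class assignment and percentages follow the shift table", {
  tab <- nmr_shift_table()
  single <- data.frame(center = 0.0, fwhm = 0.05, amplitude = 1,
                       area = 0.05 * pi / 2)
  q1 <- assign_and_quantify(single, tab)
  expect_identical(q1$class, "PC")
  expect_equal(q1$percent, 100)

  # Fig-3-style arithmetic: three classes, PE below the 3% limit
  fits <- data.frame(center = c(0, -0.45, 0.95), fwhm = 0.05,
                     amplitude = c(0.767, 0.203, 0.030),
                     area = c(0.767, 0.203, 0.030))
  q <- assign_and_quantify(fits, tab)
  expect_equal(sum(q$percent), 100, tolerance = 1e-6)
  expect_equal(q$percent[q$class == "PC"], 76.7, tolerance = 1e-6)
  expect_equal(q$percent[q$class == "SM"], 20.3, tolerance = 1e-6)
  # boundary: exactly 3% is still quantifiable; strictly below is not
  expect_true(q$quantifiable[q$class == "PE"])
  expect_true(all(q$quantifiable[q$class %in% c("PC", "SM")]))
  fits2 <- fits; fits2$area[3] <- 0.020
  q2 <- assign_and_quantify(fits2, tab)
  expect_false(q2$quantifiable[q2$class == "PE"])

  # unassignable peak excluded with warning; none assignable errors
  far <- rbind(fits, data.frame(center = 10, fwhm = 0.05, amplitude = 1,
                                area = 1))
  expect_warning(qf <- assign_and_quantify(far, tab), "no shift-table entry")
  expect_equal(sum(qf$percent), 100, tolerance = 1e-6)
  lonely <- data.frame(center = 10, fwhm = 0.05, amplitude = 1, area = 1)
  expect_error(assign_and_quantify(lonely, tab), "no assignable peaks")
})

test_that("pipeline is invariant to intensity scale and axis shifts", {
  truth <- exact_truth(2)
  fid <- simulate_nmr(truth, snr = 200, seed = 2)
  q1 <- suppressWarnings(quantify_nmr(fid))
  fid2 <- nmr_fid(fid$points * 50, fid$dwell_time, fid$carrier_frequency)
  q2 <- suppressWarnings(quantify_nmr(fid2))
  expect_equal(q1$percent, q2$percent, tolerance = 1e-6)
})

test_that("apodization broadens fitted lines by lb/carrier ppm", {
  w_in <- 0.03
  fid <- toy_fid(0.5, 1, w_in, n = 8192)
  lb <- 3.0
  sp <- baseline_correct(transform_and_scale(apodize_fid(fid, lb)), 1)
  fit <- deconvolute(sp)
  expect_equal(fit$fwhm[1], w_in + lb / 242.93, tolerance = 0.1)
})
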