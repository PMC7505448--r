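test_that("lipidome generation is deterministic, normalized and PS-free", {
  t1 <- generate_lipidome("paper-like", seed = 9)
  t2 <- generate_lipidome("paper-like", seed = 9)
  expect_identical(t1, t2)
  expect_equal(sum(t1$species$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(t1$nmr_class_fractions), 1, tolerance = 1e-12)
  expect_false("PS" %in% t1$species$class)

  u <- generate_lipidome("uniform", seed = 1)
  expect_true(all(abs(u$species$fraction - 1 / nrow(u$species)) < 1e-12))

  bad <- data.frame(class = "PC", chains = "16:0/18:1", fraction = -1)
  expect_error(generate_lipidome("custom", custom_species = bad), "negative")
})

test_that("MS simulation honours iterative exclusion and determinism", {
  truth <- exact_truth(1)
  s1 <- simulate_ms_run(truth, "positive", seed = 4)
  s2 <- simulate_ms_run(truth, "positive", seed = 4)
  expect_equal(s1$truth_table, s2$truth_table)
  expect_equal(lapply(s1$ms2_spectra, `[[`, "mz"),
               lapply(s2$ms2_spectra, `[[`, "mz"))
  # a precursor triggered in run k never reappears in a later run
  prec <- vapply(s1$ms2_spectra, `[[`, numeric(1), "precursor_mz")
  runs <- vapply(s1$ms2_spectra, `[[`, integer(1), "run_id")
  expect_equal(length(prec), length(unique(round(prec, 3))))
  expect_true(all(runs %in% 1:4))
  # spectra and scans pass their own validators (constructed through them)
  expect_s3_class(s1$ms2_spectra[[1]], "ms2_spectrum")
  expect_s3_class(s1$ms1_scans[[1]], "ms1_scan")
})

test_that("ppm jitter at sigma 5 stays within 20 ppm for >99% of fragments", {
  set.seed(8)
  jit <- rnorm(1000, 0, 5)
  expect_gt(mean(abs(jit) <= 20), 0.99)
  # and through the simulator: noise-free assignment still succeeds
  truth <- exact_truth(3)
  sim <- simulate_ms_run(truth, "positive", seed = 5, ppm_jitter = 5)
  lib <- build_lipid_library()
  hits <- vapply(seq_along(sim$ms2_spectra), function(i) {
    r <- assign_spectrum(sim$ms2_spectra[[i]], lib)
    nrow(r) > 0 &&
      r$species[1] == paste0(sim$truth_table$class[i], " ",
                             sim$truth_table$chains[i])
  }, logical(1))
  expect_true(all(hits))
})

test_that("NMR simulation is deterministic and area-faithful", {
  truth <- exact_truth(2)
  f1 <- simulate_nmr(truth, snr = 50, seed = 6)
  f2 <- simulate_nmr(truth, snr = 50, seed = 6)
  expect_identical(f1$points, f2$points)
  tr <- attr(f1, "truth")
  expect_equal(sum(tr$class_fractions), 1, tolerance = 1e-12)
  # infinite-SNR two-class truth: deconvoluted area ratio = fraction ratio
  two <- truth
  two$nmr_class_fractions <- c(PC = 0.75, SM = 0.25)
  fid <- simulate_nmr(two, snr = Inf, seed = 1)
  q <- quantify_nmr(fid)
  expect_equal(q$percent[q$class == "PC"] / q$percent[q$class == "SM"], 3,
               tolerance = 0.01)
})

test_that("BBB reading simulation inverts exactly without noise", {
  part <- c(passed_filter = 7.7, passed_bbb = 1.3,
            retained_apical = 88.4, retained_cells = 2.6)
  r <- simulate_bbb_readings(part)
  p <- permeability_percentages(r)
  expect_equal(unname(p), unname(part), tolerance = 1e-9)
  r0 <- simulate_bbb_readings(c(passed_filter = 0, passed_bbb = 0,
                                retained_apical = 100, retained_cells = 0))
  expect_equal(unname(permeability_percentages(r0)["pct_retained_apical"]),
               100)
  expect_error(simulate_bbb_readings(part * 2), "sum to 100")
  # with 1% read noise the recovered partition stays near truth
  set.seed(10)
  recs <- vapply(1:50, function(s) {
    permeability_percentages(simulate_bbb_readings(part, noise_sd = 0.01,
                                                   seed = s))
  }, numeric(4))
  expect_true(all(abs(rowMeans(recs) - part) < 0.5))
})

test_that("end-to-end structure mirrors a PC-dominant, PS-free lipidome", {
  # PC class largest, SM second, PS absent, lyso-PC 16:0 among the top 3
  # choline-family species -- in >= 18 of 20 seeds
  ok <- vapply(1:20, function(s) {
    tr <- generate_lipidome("paper-like", seed = s)
    cf <- sort(tr$class_fractions, decreasing = TRUE)
    sp <- tr$species[tr$species$class %in% c("PC", "LPC"), ]
    top3 <- sp$chains[order(-sp$fraction)][1:3]
    names(cf)[1] == "PC" && names(cf)[2] == "SM" &&
      !"PS" %in% tr$species$class &&
      any(sp$class[order(-sp$fraction)][1:3] == "LPC")
  }, logical(1))
  expect_gte(sum(ok), 18)
})

test_that("simulate_dataset writes a complete, loadable text dataset", {
  out <- file.path(tempdir(), "evlipid-ds")
  on.exit(unlink(out, recursive = TRUE))
  paths <- simulate_dataset(out, seed = 1, n_nmr_replicates = 1, snr = 50)
  expect_true(all(file.exists(paths)))
  spectra <- read_mgf(file.path(out, "ms2_positive.mgf"))
  expect_gt(length(spectra), 5)
  # only scans where some species elutes carry peaks
  scans <- read_ms1_csv(file.path(out, "ms1_positive.csv"))
  expect_gt(length(scans), 20)
  fid <- read_fid_csv(file.path(out, "nmr_fid_rep1.csv"))
  expect_s3_class(fid, "nmr_fid")
  gt <- jsonlite::read_json(file.path(out, "ground_truth.json"))
  expect_equal(gt$seed, 1)
})
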