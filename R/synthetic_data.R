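#' @title Synthetic-data generators with known ground truth
#' @description Emulates every input the pipeline consumes — LC-MS/MS
#'   runs with iterative exclusion, 31P NMR FIDs, transwell fluorescence
#'   readings and DLS intensity distributions — from editable setpoint
#'   configs, so each stage can be validated against ground truth with
#'   no instrument data.
#' @name synthetic_data
NULL

#' Load the paper-like setpoint configuration
#'
#' The packaged JSON stores the ground-truth composition of a plasma-EV
#' lipidome emulation: a PC-dominant lipidome with SM second, a
#' prominent lyso-PC 16:0, minor PI and PE, and no PS; NMR class
#' setpoints PC/SM/PE; default noise parameters; the four-compartment
#' transwell partition; and DLS size parameters. Edit a copy to define
#' a different world.
#'
#' @param path JSON path; defaults to the packaged config.
#' @return Nested list mirroring the JSON.
#' @export
paper_like_setpoints <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "paper_like_setpoints.json",
                        package = "evlipid")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Generate a ground-truth lipidome
#'
#' Species abundances are drawn log-normally around the profile
#' setpoints (multiplicative sigma `intensity_lognormal_sigma`) and
#' renormalized; the `"paper-like"` profile contains no PS by
#' construction. `"uniform"` assigns every setpoint species 1/n.
#'
#' @param profile `"paper-like"`, `"uniform"`, or `"custom"` (supply
#'   `custom_species`).
#' @param seed Integer RNG seed.
#' @param custom_species data.frame `class`, `chains`, `fraction` for
#'   `profile = "custom"`.
#' @param setpoints Config list as from [paper_like_setpoints()].
#' @param jitter_sigma Log-normal sigma; `NULL` uses the config value.
#' @return A `ground_truth` list: `species` (data.frame with drawn
#'   `fraction`), `class_fractions` (MS, summed over species),
#'   `nmr_class_fractions`, `nmr_shift_table`, `noise_params`, `seed`.
#' @export
generate_lipidome <- function(profile = c("paper-like", "uniform", "custom"),
                              seed = 1, custom_species = NULL,
                              setpoints = paper_like_setpoints(),
                              jitter_sigma = NULL) {
  profile <- match.arg(profile)
  set.seed(seed)
  sp <- if (profile == "custom") {
    if (is.null(custom_species)) stop("custom profile needs custom_species")
    custom_species
  } else {
    as.data.frame(setpoints$ms_species)
  }
  if (any(sp$fraction < 0)) stop("negative fractions in profile")
  if (profile == "uniform") sp$fraction <- rep(1 / nrow(sp), nrow(sp))
  if (is.null(jitter_sigma)) {
    jitter_sigma <- setpoints$noise_params$intensity_lognormal_sigma
  }
  if (profile != "uniform" && jitter_sigma > 0) {
    sp$fraction <- sp$fraction * stats::rlnorm(nrow(sp), 0, jitter_sigma)
  }
  sp$fraction <- sp$fraction / sum(sp$fraction)
  nmr_frac <- unlist(setpoints$nmr_class_fractions)
  nmr_sigma <- setpoints$noise_params$nmr_replicate_sigma
  if (!is.null(nmr_sigma) && nmr_sigma > 0) {
    nmr_frac <- nmr_frac * stats::rlnorm(length(nmr_frac), 0, nmr_sigma)
  }
  nmr_frac <- nmr_frac / sum(nmr_frac)
  structure(list(
    species = sp,
    class_fractions = tapply(sp$fraction, sp$class, sum),
    nmr_class_fractions = nmr_frac,
    nmr_shift_table = nmr_shift_table(),
    noise_params = setpoints$noise_params,
    seed = seed
  ), class = "ground_truth")
}

# Species objects + precursor table for a ground truth, restricted to
# the classes informative in one ionization mode.
truth_species <- function(truth, polarity) {
  classes <- if (polarity == "positive") c("PC", "LPC", "SM") else c("PE", "PI")
  sp <- truth$species[truth$species$class %in% classes, , drop = FALSE]
  adduct <- if (polarity == "positive") "[M+H]+" else "[M-H]-"
  objs <- Map(function(cls, ch) {
    lipid_species(cls, strsplit(ch, "/", fixed = TRUE)[[1]])
  }, sp$class, sp$chains)
  sp$mz <- vapply(objs, precursor_mz, numeric(1), adduct = adduct)
  list(table = sp, objects = unname(objs), adduct = adduct)
}

#' Simulate an LC-MS/MS acquisition with iterative exclusion
#'
#' Every ground-truth species (in the classes informative for the
#' requested polarity) gets a Gaussian elution profile at a random
#' retention time in 1-16 min; MS1 scans sample all profiles on a
#' regular grid with log-normal intensity noise. One MS2 spectrum per
#' species is emitted, built from [predict_fragments()] with Gaussian
#' ppm jitter plus `n_decoys` uniform decoy peaks; the triggering run is
#' drawn from 1..`n_runs` and a precursor triggered in run k never
#' reappears in later runs (iterative exclusion).
#'
#' @param truth A `ground_truth` from [generate_lipidome()].
#' @param polarity `"positive"` or `"negative"`.
#' @param n_decoys Decoy peaks per MS2 spectrum (default 0).
#' @param seed Integer RNG seed.
#' @param n_runs Number of exclusion runs (default 4).
#' @param scan_interval MS1 scan spacing in minutes (default 0.05).
#' @param ppm_jitter Gaussian m/z jitter in ppm; `NULL` uses the truth's
#'   noise parameters.
#' @param intensity_sigma Log-normal sigma of the MS1 intensity noise;
#'   `NULL` uses the truth's noise parameters, 0 gives noise-free
#'   intensities.
#' @return List with `ms1_scans` (list of [ms1_scan()]), `ms2_spectra`
#'   (list of [ms2_spectrum()]) and `truth_table` (species, adduct,
#'   retention time, run, abundance).
#' @export
simulate_ms_run <- function(truth, polarity = "positive", n_decoys = 0,
                            seed = 1, n_runs = 4, scan_interval = 0.05,
                            ppm_jitter = NULL, intensity_sigma = NULL) {
  set.seed(seed)
  if (is.null(ppm_jitter)) ppm_jitter <- truth$noise_params$ms_ppm_jitter
  isig <- if (is.null(intensity_sigma))
    truth$noise_params$intensity_lognormal_sigma else intensity_sigma
  ts <- truth_species(truth, polarity)
  sp <- ts$table
  n <- nrow(sp)
  if (n == 0) stop("no species in this polarity")
  rt <- stats::runif(n, 1, 16)
  peak_sd <- 0.04  # chromatographic sigma, min
  height <- sp$fraction * 1e6 * stats::rlnorm(n, 0, isig)
  run <- sample.int(n_runs, n, replace = TRUE)

  scan_rt <- seq(0.5, 16.5, by = scan_interval)
  ms1 <- lapply(scan_rt, function(t) {
    h <- height * exp(-(t - rt)^2 / (2 * peak_sd^2))
    keep <- h > 1e-3
    ms1_scan(t, sp$mz[keep], h[keep])
  })

  jit <- function(mz) mz * (1 + stats::rnorm(length(mz), 0, ppm_jitter) * 1e-6)
  mz_lo <- 100
  mz_hi <- max(sp$mz) * 1.1
  ms2 <- lapply(seq_len(n), function(i) {
    frags <- predict_fragments(ts$objects[[i]], polarity, ts$adduct)
    fmz <- jit(frags$mz)
    fint <- stats::runif(length(fmz), 0.2, 1) * height[i]
    if (n_decoys > 0) {
      fmz <- c(fmz, stats::runif(n_decoys, mz_lo, mz_hi))
      fint <- c(fint, stats::runif(n_decoys, 0.05, 1) * height[i])
    }
    ms2_spectrum(jit(sp$mz[i]), polarity, rt[i], fmz, fint, run_id = run[i])
  })
  sp$retention_time <- rt
  sp$adduct <- ts$adduct
  sp$run <- run
  list(ms1_scans = ms1, ms2_spectra = ms2, truth_table = sp)
}

#' Simulate a 31P NMR FID of a phospholipid extract
#'
#' Builds a sum of exponentially damped complex oscillations, one per
#' class in the ground truth's NMR class fractions, positioned at the
#' shift-table ppm values plus a global axis offset (absorbed later by
#' calibration). Amplitudes are proportional to class fractions, so
#' ground-truth spectral areas equal the fractions. All classes share
#' one linewidth per spectrum, drawn uniformly from 0.02-0.08 ppm.
#' Complex white noise is scaled so the tallest spectral peak divided by
#' the spectral noise sd equals `snr`.
#'
#' @param truth A `ground_truth` from [generate_lipidome()].
#' @param snr Target spectral signal-to-noise ratio (> 0); `Inf` for a
#'   noise-free FID.
#' @param seed Integer RNG seed.
#' @param n_points FID length (default 8192).
#' @param sweep_ppm Spectral width in ppm (default 12).
#' @param carrier_frequency 31P carrier in MHz (default 242.93).
#' @param offset_range Global ppm-axis offset drawn uniformly from this
#'   interval (default +/- 0.3 ppm).
#' @return An [nmr_fid()] with ground truth in `attr(, "truth")`:
#'   `class_fractions`, `fwhm_ppm`, `offset_ppm`, `centers_ppm`.
#' @export
simulate_nmr <- function(truth, snr = 100, seed = 1, n_points = 8192,
                         sweep_ppm = 12, carrier_frequency = 242.93,
                         offset_range = c(-0.3, 0.3)) {
  stopifnot(snr > 0)
  set.seed(seed)
  frac <- truth$nmr_class_fractions
  tab <- truth$nmr_shift_table
  centers <- tab$center_ppm[match(names(frac), tab$class)]
  if (any(is.na(centers))) stop("class missing from shift table")
  offset <- stats::runif(1, offset_range[1], offset_range[2])
  fwhm_ppm <- stats::runif(1, 0.02, 0.08)
  fwhm_hz <- fwhm_ppm * carrier_frequency
  sw_hz <- sweep_ppm * carrier_frequency
  dt <- 1 / sw_hz
  t <- (seq_len(n_points) - 1) * dt
  sig <- Reduce(`+`, lapply(seq_along(frac), function(i) {
    f_hz <- (centers[i] + offset) * carrier_frequency
    frac[i] * exp(2i * pi * f_hz * t) * exp(-pi * fwhm_hz * t)
  }))
  if (is.finite(snr)) {
    # tallest noise-free spectral peak: amplitude of a Lorentzian line
    peak_height <- max(frac) / (pi * fwhm_hz * dt)  # discrete-FT height
    sigma_t <- peak_height / (snr * sqrt(n_points))
    sig <- sig + complex(real = stats::rnorm(n_points, 0, sigma_t),
                         imaginary = stats::rnorm(n_points, 0, sigma_t))
  }
  fid <- nmr_fid(sig, dt, carrier_frequency)
  attr(fid, "truth") <- list(class_fractions = frac, fwhm_ppm = fwhm_ppm,
                             offset_ppm = offset, centers_ppm = centers)
  fid
}

#' Simulate transwell fluorescence readings from a known partition
#'
#' Compartment totals are set proportional to the percentage partition
#' (basal and apical pools split 70/30 between supernatant and pellet),
#' then back-computed through the volume factors so that
#' [compartment_totals()] followed by [permeability_percentages()]
#' inverts them exactly in the noise-free case.
#'
#' @param partition Named numeric `passed_filter`, `passed_bbb`,
#'   `retained_apical`, `retained_cells` summing to 100.
#' @param volumes List with `sampled_volume`/`total_volume` (default
#'   [default_bbb_volumes()]).
#' @param noise_sd Relative Gaussian read noise (default 0).
#' @param seed Integer RNG seed.
#' @param total_fluorescence Grand total in instrument units.
#' @return A [fluorescence_readings()].
#' @export
simulate_bbb_readings <- function(partition, volumes = default_bbb_volumes(),
                                  noise_sd = 0, seed = 1,
                                  total_fluorescence = 1e5) {
  req <- c("passed_filter", "passed_bbb", "retained_apical", "retained_cells")
  if (!all(req %in% names(partition))) {
    stop("partition must name: ", paste(req, collapse = ", "))
  }
  if (any(partition < 0) || abs(sum(partition) - 100) > 1e-6) {
    stop("partition must be non-negative and sum to 100")
  }
  set.seed(seed)
  totals <- c(
    apical_supernatant = 0.7 * partition[["retained_apical"]],
    apical_pellet = 0.3 * partition[["retained_apical"]],
    basal_supernatant = 0.7 * partition[["passed_bbb"]],
    basal_pellet = 0.3 * partition[["passed_bbb"]],
    cell_lysate = partition[["retained_cells"]],
    filter = partition[["passed_filter"]]
  ) / 100 * total_fluorescence
  readings <- totals * volumes$sampled_volume / volumes$total_volume
  if (noise_sd > 0) {
    readings <- readings * (1 + stats::rnorm(length(readings), 0, noise_sd))
    readings[readings < 0] <- 0
  }
  fluorescence_readings(readings, volumes$sampled_volume, volumes$total_volume)
}

#' Simulate a DLS intensity distribution
#'
#' Log-normal size distribution on a diameter grid, parameterized by the
#' target intensity-weighted mean diameter and PDI (relative variance),
#' with optional multiplicative weight noise.
#'
#' @param mean_hd Target mean hydrodynamic diameter (nm).
#' @param pdi Target polydispersity index.
#' @param n_points Grid size (default 200).
#' @param noise_sd Relative log-normal noise on the weights (default 0).
#' @param seed Integer RNG seed.
#' @return List `diameters`, `intensity` usable with [dls_summary()].
#' @export
simulate_dls <- function(mean_hd = 68.8, pdi = 0.21, n_points = 200,
                         noise_sd = 0, seed = 1) {
  stopifnot(mean_hd > 0, pdi >= 0)
  set.seed(seed)
  sdlog <- sqrt(log(1 + pdi))
  meanlog <- log(mean_hd) - sdlog^2 / 2
  d <- exp(seq(meanlog - 4 * sdlog, meanlog + 4 * sdlog,
               length.out = n_points))
  w <- stats::dlnorm(d, meanlog, sdlog) * d  # weight per log-spaced bin
  if (noise_sd > 0) w <- w * stats::rlnorm(n_points, 0, noise_sd)
  list(diameters = d, intensity = w)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits everything a real study would hand the pipeline: an MGF of MS2
#' spectra and an MS1 CSV per polarity, a 31P FID CSV + metadata JSON
#' per replicate, a transwell readings CSV, a DLS distribution CSV, and
#' a ground-truth JSON.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer RNG seed.
#' @param profile Lipidome profile (see [generate_lipidome()]).
#' @param n_nmr_replicates Number of NMR replicate spectra (default 5).
#' @param snr NMR signal-to-noise (default 100).
#' @param n_decoys Decoy peaks per MS2 spectrum (default 0).
#' @return Invisibly, the list of written file paths.
#' @export
simulate_dataset <- function(out_dir, seed = 1, profile = "paper-like",
                             n_nmr_replicates = 5, snr = 100, n_decoys = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- paper_like_setpoints()
  paths <- character(0)
  truth <- generate_lipidome(profile, seed = seed, setpoints = cfg)
  for (pol in c("positive", "negative")) {
    sim <- simulate_ms_run(truth, pol, n_decoys = n_decoys, seed = seed + 1)
    p1 <- file.path(out_dir, paste0("ms2_", pol, ".mgf"))
    p2 <- file.path(out_dir, paste0("ms1_", pol, ".csv"))
    write_mgf(sim$ms2_spectra, p1)
    write_ms1_csv(sim$ms1_scans, p2)
    paths <- c(paths, p1, p2)
  }
  for (r in seq_len(n_nmr_replicates)) {
    rep_truth <- generate_lipidome(profile, seed = seed + r, setpoints = cfg)
    fid <- simulate_nmr(rep_truth, snr = snr, seed = seed + r)
    p <- file.path(out_dir, sprintf("nmr_fid_rep%d.csv", r))
    write_fid_csv(fid, p)
    paths <- c(paths, p)
  }
  rd <- simulate_bbb_readings(unlist(cfg$bbb_partition), seed = seed)
  p <- file.path(out_dir, "bbb_readings.csv")
  utils::write.csv(data.frame(compartment = names(rd$readings),
                              reading = as.numeric(rd$readings),
                              sampled_volume = as.numeric(rd$sampled_volume),
                              total_volume = as.numeric(rd$total_volume)),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  dls <- simulate_dls(cfg$dls$mean_hd, cfg$dls$pdi, seed = seed)
  p <- file.path(out_dir, "dls_distribution.csv")
  utils::write.csv(data.frame(diameter_nm = dls$diameters,
                              intensity = dls$intensity), p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(list(seed = seed, profile = profile,
                            species = truth$species,
                            class_fractions = as.list(truth$class_fractions),
                            nmr_class_fractions = as.list(truth$nmr_class_fractions)),
                       p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
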