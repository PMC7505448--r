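#' @title 31P NMR phospholipid quantification
#' @description Time-domain to class-percentage pipeline for 31P spectra
#'   of phospholipid extracts: exponential apodization, Fourier
#'   transform with automatic zero-order phasing, polynomial baseline
#'   correction, chemical-shift calibration to the PC signal at 0 ppm,
#'   Lorentzian deconvolution, and class assignment/quantification
#'   against a chemical-shift table.
#' @name nmr_quantification
NULL

#' Construct a 31P FID
#'
#' @param points Complex time-domain series (length >= 2).
#' @param dwell_time Sampling interval in seconds (> 0).
#' @param carrier_frequency Spectrometer 31P carrier in MHz; 242.93 MHz
#'   for a 600 MHz (1H) instrument.
#' @return An `nmr_fid` object.
#' @export
nmr_fid <- function(points, dwell_time, carrier_frequency = 242.93) {
  if (length(points) < 2) stop("FID needs >= 2 points")
  if (dwell_time <= 0) stop("dwell_time must be > 0")
  structure(list(points = as.complex(points), dwell_time = dwell_time,
                 carrier_frequency = carrier_frequency),
            class = "nmr_fid")
}

#' @export
format.nmr_fid <- function(x, ...) {
  sprintf("31P FID: %d points, dwell %.3g s, carrier %.2f MHz",
          length(x$points), x$dwell_time, x$carrier_frequency)
}

#' @export
print.nmr_fid <- function(x, ...) cat(format(x), "\n")

#' Construct a frequency-domain spectrum
#'
#' @param ppm Strictly monotonic ppm axis (stored descending, the NMR
#'   plotting convention).
#' @param intensity Real intensities, same length.
#' @return An `nmr_spectrum` object.
#' @export
nmr_spectrum <- function(ppm, intensity) {
  if (length(ppm) != length(intensity)) stop("axis length mismatch")
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm axis must be strictly monotonic")
  if (d[1] > 0) { ppm <- rev(ppm); intensity <- rev(intensity) }
  structure(list(ppm = ppm, intensity = intensity), class = "nmr_spectrum")
}

#' @export
format.nmr_spectrum <- function(x, ...) {
  sprintf("31P spectrum: %d points, %.2f to %.2f ppm",
          length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)])
}

#' @export
print.nmr_spectrum <- function(x, ...) cat(format(x), "\n")

#' Exponential line-broadening apodization
#'
#' Multiplies FID point k (0-based) by `exp(-pi * lb_hz * k * dwell_time)`,
#' trading resolution for signal-to-noise; the first point is unchanged.
#' In the spectrum this adds `lb_hz` to every Lorentzian full width at
#' half maximum.
#'
#' @param fid An [nmr_fid()].
#' @param lb_hz Line broadening in Hz (>= 0); 3.0 Hz is the conventional
#'   value for 31P phospholipid spectra.
#' @return Apodized [nmr_fid()].
#' @export
apodize_fid <- function(fid, lb_hz = 3.0) {
  if (lb_hz < 0) stop("lb_hz must be >= 0")
  k <- seq_along(fid$points) - 1
  nmr_fid(fid$points * exp(-pi * lb_hz * k * fid$dwell_time),
          fid$dwell_time, fid$carrier_frequency)
}

#' Fourier transform a FID into a ppm-scaled spectrum
#'
#' Discrete Fourier transform with the first point halved (removes the
#' DC baseline offset), frequency axis converted to ppm through the
#' carrier frequency, and automatic zero-order phase correction chosen
#' to maximize the total positive area of the real part.
#'
#' @param fid An [nmr_fid()].
#' @return An [nmr_spectrum()] (real part, descending ppm axis).
#' @export
transform_and_scale <- function(fid) {
  x <- fid$points
  x[1] <- x[1] / 2
  n <- length(x)
  S <- stats::fft(x)
  m <- seq_len(n) - 1
  freq <- ifelse(m < n / 2, m, m - n) / (n * fid$dwell_time)  # Hz
  ppm <- freq / fid$carrier_frequency
  ord <- order(ppm, decreasing = TRUE)
  S <- S[ord]; ppm <- ppm[ord]
  # zero-order phasing: rotate so the total spectral integral is real and
  # maximal (closed form; pure absorptive lines then carry all their area
  # as positive real signal)
  tot <- sum(S)
  phi <- if (Mod(tot) > 0) -Arg(tot) else 0
  nmr_spectrum(ppm, Re(S * exp(1i * phi)))
}

# Robust noise level: median absolute deviation of the intensity,
# scaled for consistency with a Gaussian sd. Signal peaks are sparse so
# the MAD is dominated by baseline noise.
robust_noise <- function(intensity) {
  s <- stats::mad(intensity, center = stats::median(intensity))
  if (s == 0) s <- stats::sd(intensity)  # e.g. noise-free synthetic spectra
  if (is.na(s)) s <- 0
  s
}

#' Automatic polynomial baseline correction
#'
#' Fits a polynomial to signal-free points, identified by iterative
#' sigma clipping (points more than 3 robust sd above the current
#' baseline are excluded), and subtracts it.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param polynomial_order Degree of the baseline polynomial (<= 5).
#' @param max_iter Clipping iterations (default 10).
#' @return Baseline-corrected [nmr_spectrum()].
#' @export
baseline_correct <- function(spectrum, polynomial_order = 2, max_iter = 10) {
  if (polynomial_order > 5) stop("polynomial_order must be <= 5")
  y <- spectrum$intensity
  n <- length(y)
  if (n < polynomial_order + 1) stop("spectrum shorter than order + 1")
  x <- seq(-1, 1, length.out = n)  # scaled abscissa for conditioning
  X <- outer(x, 0:polynomial_order, `^`)
  keep <- rep(TRUE, n)
  baseline <- rep(0, n)
  for (it in seq_len(max_iter)) {
    co <- stats::lm.fit(X[keep, , drop = FALSE], y[keep])$coefficients
    co[is.na(co)] <- 0
    baseline <- drop(X %*% co)
    resid <- y - baseline
    s <- robust_noise(resid[keep])
    new_keep <- resid <= 3 * s
    if (all(new_keep == keep) || sum(new_keep) < polynomial_order + 2) break
    keep <- new_keep
  }
  nmr_spectrum(spectrum$ppm, y - baseline)
}

#' Calibrate the chemical-shift axis to PC = 0 ppm
#'
#' Shifts the ppm axis so the apex of the most intense peak — the PC
#' signal in a phospholipid extract — sits at exactly 0 ppm. With ties,
#' the peak at highest ppm (leftmost) is used and a warning emitted.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param min_snr Calibration fails if no point exceeds `min_snr` times
#'   the robust noise (default 5).
#' @return Calibrated [nmr_spectrum()].
#' @export
calibrate <- function(spectrum, min_snr = 5) {
  y <- spectrum$intensity
  noise <- robust_noise(y)
  if (max(y) <= min_snr * noise || max(y) <= 0) {
    stop("calibration-failure: no peak above ", min_snr, "x noise")
  }
  apex <- which(y == max(y))
  if (length(apex) > 1) {
    warning("multiple equal-intensity apex candidates; using highest ppm")
    apex <- apex[which.max(spectrum$ppm[apex])]
  }
  nmr_spectrum(spectrum$ppm - spectrum$ppm[apex], y)
}

# Lorentzian with unit-amplitude parameterization:
# L(x) = a / (1 + ((x - c) / (w/2))^2); area = a * w * pi / 2.
lorentz <- function(x, center, fwhm, amplitude) {
  amplitude / (1 + ((x - center) / (fwhm / 2))^2)
}

# Local maxima above a prominence threshold, for deconvolution seeds.
# Prominence = height above the higher of the two bounding minima (walk
# outwards until a taller point is met); rejects noise ripples riding on
# the tails of strong lines.
find_peaks <- function(ppm, y, min_height) {
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  idx <- idx[y[idx] > min_height]
  prom <- vapply(idx, function(i) {
    l <- i; m_l <- y[i]
    while (l > 1 && y[l] <= y[i]) { l <- l - 1; m_l <- min(m_l, y[l]) }
    r <- i; m_r <- y[i]
    while (r < n && y[r] <= y[i]) { r <- r + 1; m_r <- min(m_r, y[r]) }
    y[i] - max(m_l, m_r)
  }, numeric(1))
  idx[prom > min_height]
}

# Half-height width estimate around a local maximum (in ppm).
estimate_fwhm <- function(ppm, y, i) {
  half <- y[i] / 2
  l <- i; while (l > 1 && y[l] > half) l <- l - 1
  r <- i; while (r < length(y) && y[r] > half) r <- r + 1
  w <- abs(ppm[l] - ppm[r])
  if (w <= 0) w <- 2 * abs(ppm[2] - ppm[1])
  w
}

#' Deconvolute a spectrum into Lorentzian components
#'
#' Seeds one Lorentzian per detected local maximum (prominence above
#' `min_snr` times the robust noise), or per user-supplied initial peak,
#' then refines all centers, widths and amplitudes by bounded nonlinear
#' least squares. Areas come from the closed form
#' `amplitude * fwhm * pi / 2`.
#'
#' @param spectrum An [nmr_spectrum()] (baseline-corrected).
#' @param init_peaks Optional data.frame `center`, `fwhm`, `amplitude`
#'   seeding the fit; detected automatically when `NULL`.
#' @param min_snr Detection threshold in robust-noise units (default 5).
#' @param max_iter Maximum optimizer iterations (default 500).
#' @return data.frame `center`, `fwhm`, `amplitude`, `area` sorted by
#'   descending area, with the residual RMS in `attr(, "rms")` and
#'   convergence flag in `attr(, "converged")`.
#' @export
deconvolute <- function(spectrum, init_peaks = NULL, min_snr = 5,
                        max_iter = 2000) {
  ppm <- spectrum$ppm
  y <- spectrum$intensity
  if (is.null(init_peaks)) {
    noise <- robust_noise(y)
    if (max(y) <= 0 || (noise > 0 && max(y) <= min_snr * noise)) {
      out <- data.frame(center = numeric(0), fwhm = numeric(0),
                        amplitude = numeric(0), area = numeric(0))
      attr(out, "rms") <- sqrt(mean(y^2))
      attr(out, "converged") <- TRUE
      return(out)
    }
    idx <- find_peaks(ppm, y, min_snr * noise)
    if (length(idx) == 0) idx <- which.max(y)
    init_peaks <- data.frame(
      center = ppm[idx],
      fwhm = vapply(idx, function(i) estimate_fwhm(ppm, y, i), numeric(1)),
      amplitude = y[idx]
    )
  }
  k <- nrow(init_peaks)
  if (k == 0) {
    out <- data.frame(center = numeric(0), fwhm = numeric(0),
                      amplitude = numeric(0), area = numeric(0))
    attr(out, "rms") <- sqrt(mean(y^2))
    attr(out, "converged") <- TRUE
    return(out)
  }
  # normalize intensities so the fit (and its stopping rules) are exactly
  # invariant to the overall intensity scale
  yscale <- max(abs(y))
  y <- y / yscale
  init_peaks$amplitude <- init_peaks$amplitude / yscale
  span <- abs(ppm[1] - ppm[length(ppm)])
  par0 <- c(init_peaks$center, log(init_peaks$fwhm),
            log(pmax(init_peaks$amplitude, 1e-12)))
  model <- function(p) {
    centers <- p[1:k]; fwhms <- exp(p[(k + 1):(2 * k)])
    amps <- exp(p[(2 * k + 1):(3 * k)])
    rowSums(vapply(seq_len(k), function(i)
      lorentz(ppm, centers[i], fwhms[i], amps[i]), numeric(length(ppm))))
  }
  obj <- function(p) sum((y - model(p))^2)
  # centers stay near their seeds and widths below half a ppm: keeps the
  # optimizer from turning a line into a baseline-wide pedestal
  wiggle <- pmax(2 * init_peaks$fwhm, 0.02)
  lower <- c(init_peaks$center - wiggle, rep(log(1e-5), k), rep(-30, k))
  upper <- c(init_peaks$center + wiggle, rep(log(min(0.5, span)), k),
             rep(log(max(y) * 10 + 1e-12), k))
  fit <- stats::nlminb(par0, obj, lower = lower, upper = upper,
                       control = list(iter.max = max_iter,
                                      eval.max = 4 * max_iter,
                                      rel.tol = 1e-10, x.tol = 1e-9))
  converged <- fit$convergence == 0
  p <- fit$par
  out <- data.frame(center = p[1:k], fwhm = exp(p[(k + 1):(2 * k)]),
                    amplitude = exp(p[(2 * k + 1):(3 * k)]) * yscale)
  out$area <- out$amplitude * out$fwhm * pi / 2
  out <- out[order(-out$area), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rms") <- sqrt(fit$objective / length(y)) * yscale
  attr(out, "converged") <- converged
  if (!converged) {
    warning("deconvolution did not fully converge; returning best-so-far fit")
  }
  out
}

#' Load a phospholipid 31P chemical-shift table
#'
#' Reads a CSV `class, center_ppm, tolerance_ppm` with shifts relative
#' to PC = 0 ppm. The packaged default emulates the shift dispersion of
#' the CUBO (dimethylformamide/triethylamine/guanidinium chloride)
#' solvent system and is deliberately user-editable: replace it with
#' measured shifts for any other solvent.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return data.frame `class`, `center_ppm`, `tolerance_ppm`.
#' @export
nmr_shift_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cubo_shifts.csv", package = "evlipid")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "center_ppm", "tolerance_ppm") %in% names(df)))
  df
}

#' Assign fitted peaks to phospholipid classes and quantify
#'
#' Each fitted Lorentzian is assigned to the nearest shift-table class
#' within that class's tolerance; unassigned peaks are excluded from
#' the total with a warning. Class percentage = 100 x class area /
#' total assigned area. Classes under `quantify_limit` percent are
#' flagged non-quantifiable (reported, but below the reliable limit of
#' 31P NMR for minor phospholipids).
#'
#' @param peak_fits data.frame from [deconvolute()].
#' @param shift_table data.frame from [nmr_shift_table()].
#' @param quantify_limit Percent threshold for the `quantifiable` flag
#'   (default 3).
#' @return data.frame `class`, `percent`, `quantifiable` (percent sums
#'   to 100 over assigned classes).
#' @export
assign_and_quantify <- function(peak_fits, shift_table, quantify_limit = 3) {
  if (nrow(peak_fits) == 0) stop("no peaks to assign")
  assigned <- character(nrow(peak_fits))
  for (i in seq_len(nrow(peak_fits))) {
    d <- abs(shift_table$center_ppm - peak_fits$center[i])
    j <- which.min(d)
    assigned[i] <- if (d[j] <= shift_table$tolerance_ppm[j])
      shift_table$class[j] else NA_character_
  }
  if (all(is.na(assigned))) stop("no assignable peaks")
  if (any(is.na(assigned))) {
    warning(sum(is.na(assigned)), " peak(s) matched no shift-table entry; excluded")
  }
  ok <- !is.na(assigned)
  cls_area <- tapply(peak_fits$area[ok], assigned[ok], sum)
  pct <- 100 * cls_area / sum(cls_area)
  out <- data.frame(class = names(pct), percent = as.numeric(pct),
                    quantifiable = as.numeric(pct) >= quantify_limit,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full 31P NMR quantification pipeline
#'
#' Apodize (3 Hz exponential), Fourier transform with automatic phasing,
#' baseline-correct, calibrate PC to 0 ppm, deconvolute into
#' Lorentzians, and assign/quantify classes.
#'
#' @param fid An [nmr_fid()] (or an already-transformed
#'   [nmr_spectrum()], in which case apodization/FT are skipped).
#' @param shift_table Shift table (default: packaged CUBO-style table).
#' @param lb_hz Line broadening in Hz (default 3.0).
#' @param polynomial_order Baseline polynomial order (default 2).
#' @param ... Passed to [deconvolute()].
#' @return data.frame as from [assign_and_quantify()], with the peak
#'   fits in `attr(, "peak_fits")`.
#' @export
quantify_nmr <- function(fid, shift_table = nmr_shift_table(), lb_hz = 3.0,
                         polynomial_order = 2, ...) {
  spec <- if (inherits(fid, "nmr_spectrum")) fid else
    transform_and_scale(apodize_fid(fid, lb_hz))
  spec <- baseline_correct(spec, polynomial_order)
  spec <- calibrate(spec)
  fits <- deconvolute(spec, ...)
  res <- assign_and_quantify(fits, shift_table)
  attr(res, "peak_fits") <- fits
  res
}
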