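#' @title Plain-text instrument-file I/O
#' @description Readers/writers for the small text formats the pipeline
#'   consumes: MGF peak lists for MS2, CSV scan tables for MS1, CSV+JSON
#'   for NMR FIDs, and CSVs for plate readings and DLS distributions.
#' @name io
NULL

#' Write MS2 spectra to an MGF file
#'
#' Standard BEGIN IONS / END IONS blocks with PEPMASS, RTINSECONDS and
#' CHARGE (`1+` / `1-` encodes the polarity). Run index is carried in a
#' SCANS-style `RUN=` line.
#'
#' @param spectra List of [ms2_spectrum()].
#' @param path Output file.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      sprintf("RTINSECONDS=%.3f", s$retention_time * 60),
      sprintf("CHARGE=1%s", if (s$polarity == "positive") "+" else "-"),
      sprintf("RUN=%d", s$run_id),
      sprintf("%.6f %.6g", s$mz, s$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Read MS2 spectra from an MGF file
#'
#' @param path MGF file written by [write_mgf()] or a compatible dialect.
#' @return List of [ms2_spectrum()].
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) stop("malformed MGF: unbalanced blocks")
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1):(ends[i] - 1)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, character(1), 1))
    vals <- vapply(kv, `[`, character(1), 2)
    get <- function(k, default = NA) if (k %in% keys) vals[match(k, keys)] else default
    peaks <- do.call(rbind, strsplit(trimws(block[!hdr & nzchar(block)]), "[ \t]+"))
    charge <- get("CHARGE", "1+")
    ms2_spectrum(
      precursor_mz = as.numeric(strsplit(get("PEPMASS"), " ")[[1]][1]),
      polarity = if (grepl("-", charge, fixed = TRUE)) "negative" else "positive",
      retention_time = as.numeric(get("RTINSECONDS", "0")) / 60,
      mz = as.numeric(peaks[, 1]),
      intensity = if (ncol(peaks) > 1) as.numeric(peaks[, 2]) else rep(1, nrow(peaks)),
      run_id = as.integer(get("RUN", "1"))
    )
  })
}

#' Write / read MS1 scans as a CSV of (scan_rt, mz, intensity)
#'
#' @param scans List of [ms1_scan()].
#' @param path CSV path.
#' @export
write_ms1_csv <- function(scans, path) {
  df <- do.call(rbind, lapply(scans, function(s) {
    if (length(s$mz) == 0) return(NULL)
    data.frame(scan_rt = s$retention_time, mz = s$mz, intensity = s$intensity)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ms1_csv
#' @export
read_ms1_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$scan_rt), function(d) {
    ms1_scan(d$scan_rt[1], d$mz, d$intensity)
  })
}

#' Write / read an NMR FID as CSV (index, real, imag) plus JSON metadata
#'
#' @param fid A [nmr_fid()].
#' @param path CSV path; metadata goes to `paste0(path, ".json")`.
#' @export
write_fid_csv <- function(fid, path) {
  utils::write.csv(data.frame(index = seq_along(fid$points) - 1,
                              real = Re(fid$points), imag = Im(fid$points)),
                   path, row.names = FALSE)
  jsonlite::write_json(list(dwell_time = fid$dwell_time,
                            carrier_frequency = fid$carrier_frequency),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fid_csv
#' @export
read_fid_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  nmr_fid(complex(real = df$real, imaginary = df$imag),
          dwell_time = meta$dwell_time,
          carrier_frequency = meta$carrier_frequency)
}
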