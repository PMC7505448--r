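#' @title MS1 chromatogram reconstruction and relative quantification
#' @description Extracted-ion chromatograms (XICs) for assigned lipid
#'   species, within-headgroup relative abundances per replicate, and
#'   Tukey box-plot summaries across replicates.
#' @name ms1_quantification
NULL

#' Construct an MS1 scan
#'
#' @param retention_time Minutes (>= 0).
#' @param mz,intensity Centroided peak list; stored sorted by m/z.
#' @return An `ms1_scan` object.
#' @export
ms1_scan <- function(retention_time, mz, intensity) {
  stopifnot(retention_time >= 0, length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be >= 0")
  ord <- order(mz)
  structure(list(retention_time = retention_time,
                 mz = mz[ord], intensity = intensity[ord]),
            class = "ms1_scan")
}

#' Reconstruct an extracted-ion chromatogram
#'
#' One point per scan inside the retention-time window: the summed
#' intensity of all peaks within `tol_ppm` of `target_mz` (zero if none).
#' The area is the trapezoidal integral over retention time.
#'
#' @param scans List of [ms1_scan()].
#' @param target_mz m/z to extract.
#' @param tol_ppm Extraction tolerance in ppm (> 0).
#' @param rt_window Length-2 numeric `c(lo, hi)` in minutes, or `NULL`
#'   for the full run.
#' @return An `xic`: list with `target_mz`, `rt`, `intensity`, `area`.
#' @export
reconstruct_xic <- function(scans, target_mz, tol_ppm = 20, rt_window = NULL) {
  stopifnot(tol_ppm > 0)
  if (length(scans) == 0) stop("empty scan list")
  rts <- vapply(scans, `[[`, numeric(1), "retention_time")
  ord <- order(rts)
  scans <- scans[ord]; rts <- rts[ord]
  if (!is.null(rt_window)) {
    keep <- rts >= rt_window[1] & rts <= rt_window[2]
    scans <- scans[keep]; rts <- rts[keep]
  }
  tol <- target_mz * tol_ppm * 1e-6
  intens <- vapply(scans, function(s) {
    sum(s$intensity[abs(s$mz - target_mz) <= tol])
  }, numeric(1))
  area <- if (length(rts) > 1) {
    sum(diff(rts) * (utils::head(intens, -1) + utils::tail(intens, -1)) / 2)
  } else 0
  structure(list(target_mz = target_mz, rt = rts, intensity = intens,
                 area = area), class = "xic")
}

#' @export
format.xic <- function(x, ...) {
  sprintf("XIC m/z %.4f: %d points, area %.4g", x$target_mz,
          length(x$rt), x$area)
}

#' @export
print.xic <- function(x, ...) cat(format(x), "\n")

#' Within-headgroup relative abundances
#'
#' Normalizes XIC areas within each (class, replicate) group so species
#' fractions sum to 1. Classes whose total area is zero in a replicate
#' are dropped with a warning.
#'
#' @param areas data.frame with columns `class`, `species`,
#'   `replicate_id`, `area` (areas >= 0).
#' @return A `composition_table`: data.frame `class`, `species`,
#'   `replicate_id`, `relative_abundance`.
#' @examples
#' a <- data.frame(class = "PC", species = c("A", "B"),
#'                 replicate_id = 1, area = c(3, 1))
#' class_relative_abundance(a)
#' @export
class_relative_abundance <- function(areas) {
  stopifnot(all(c("class", "species", "replicate_id", "area") %in% names(areas)))
  if (any(areas$area < 0)) stop("areas must be >= 0")
  pieces <- lapply(split(areas, list(areas$class, areas$replicate_id),
                         drop = TRUE), function(d) {
    tot <- sum(d$area)
    if (tot == 0) {
      warning("class ", d$class[1], " replicate ", d$replicate_id[1],
              " has zero total area; excluded")
      return(NULL)
    }
    data.frame(class = d$class, species = d$species,
               replicate_id = d$replicate_id,
               relative_abundance = d$area / tot,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), pieces))
  if (is.null(out)) {
    out <- data.frame(class = character(0), species = character(0),
                      replicate_id = integer(0),
                      relative_abundance = numeric(0))
  }
  out <- out[order(out$class, out$species, out$replicate_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("composition_table", "data.frame")
  out
}

#' Tukey box-plot statistics per species across replicates
#'
#' Median, quartiles (type-7), whiskers to the most extreme points
#' within 1.5 IQR of the box, and points beyond flagged as outliers —
#' the convention of a standard box plot.
#'
#' @param composition A `composition_table` from
#'   [class_relative_abundance()].
#' @return data.frame with one row per (class, species): `median`, `q25`,
#'   `q75`, `whisker_lo`, `whisker_hi`, `n`, and outliers in a
#'   semicolon-separated string column.
#' @export
replicate_summary <- function(composition) {
  pieces <- lapply(split(composition,
                         list(composition$class, composition$species),
                         drop = TRUE), function(d) {
    v <- d$relative_abundance
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    out <- v[v < lo_fence | v > hi_fence]
    data.frame(class = d$class[1], species = d$species[1],
               median = q[2], q25 = q[1], q75 = q[3],
               whisker_lo = min(inside), whisker_hi = max(inside),
               n = length(v),
               outliers = paste(sort(out), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$class, -out$median), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantify assigned species from MS1 scans
#'
#' Convenience wrapper: for each assigned species, reconstructs the XIC
#' at the assigned adduct's precursor m/z in a window of +/- `rt_half`
#' minutes around the assigning MS2 spectrum's retention time, then
#' returns the per-class composition table.
#'
#' @param assignments data.frame with columns `species`, `class`,
#'   `adduct`, `retention_time`, `precursor_mz` (e.g. top-ranked rows of
#'   a [review_table()]).
#' @param scans List of [ms1_scan()] for one replicate.
#' @param replicate_id Replicate label attached to the output.
#' @param tol_ppm XIC extraction tolerance (ppm).
#' @param rt_half Half-width of the XIC retention-time window (minutes).
#' @return data.frame `class`, `species`, `replicate_id`, `area`.
#' @export
quantify_species <- function(assignments, scans, replicate_id = 1,
                             tol_ppm = 20, rt_half = 0.5) {
  areas <- vapply(seq_len(nrow(assignments)), function(i) {
    rt <- assignments$retention_time[i]
    reconstruct_xic(scans, assignments$precursor_mz[i], tol_ppm,
                    c(rt - rt_half, rt + rt_half))$area
  }, numeric(1))
  data.frame(class = assignments$class, species = assignments$species,
             replicate_id = replicate_id, area = areas,
             stringsAsFactors = FALSE)
}
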