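# Reading/writing MRM chromatograms and EPI spectra, and peak detection /
# integration "in three dimensions" (time, intensity, m/z).

#' MRM chromatogram (XIC)
#'
#' Intensity versus retention time for one Q1/Q3 transition.
#'
#' @param rt_min Strictly increasing retention times (minutes).
#' @param intensity Non-negative ion counts, same length.
#' @param q1_mz,q3_mz Transition masses (Th).
#' @param id Optional transition identifier (e.g. `"PA(16:1/18:1)|16:1"`).
#' @return Object of class `chromatogram`.
#' @export
chromatogram <- function(rt_min, intensity, q1_mz = NA_real_,
                         q3_mz = NA_real_, id = NA_character_) {
  rt_min <- as.numeric(rt_min); intensity <- as.numeric(intensity)
  if (length(rt_min) != length(intensity))
    stop("rt and intensity lengths differ")
  if (length(rt_min) > 1 && any(diff(rt_min) <= 0))
    stop("retention times must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(list(rt_min = rt_min, intensity = intensity,
                 q1_mz = q1_mz, q3_mz = q3_mz, id = id),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s Q1=%.2f Q3=%.2f, %d points, rt %.2f-%.2f min\n",
              x$id, x$q1_mz, x$q3_mz, length(x$rt_min),
              min(x$rt_min), max(x$rt_min)))
  invisible(x)
}

#' Enhanced product ion (EPI) spectrum
#'
#' A fragment peak list attached to a precursor m/z and retention time — the
#' input of the positional-isomer interpreter.
#'
#' @param mz Fragment m/z values (sorted internally).
#' @param intensity Non-negative intensities, same length.
#' @param precursor_mz Precursor (Q1) m/z.
#' @param rt_min Retention time of the triggering MRM hit (minutes).
#' @param id Optional identifier.
#' @return Object of class `epi_spectrum`.
#' @export
epi_spectrum <- function(mz, intensity, precursor_mz, rt_min = NA_real_,
                         id = NA_character_) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  ord <- order(mz)
  structure(list(mz = mz[ord], intensity = intensity[ord],
                 precursor_mz = as.numeric(precursor_mz),
                 rt_min = rt_min, id = id),
            class = "epi_spectrum")
}

#' @export
print.epi_spectrum <- function(x, ...) {
  cat(sprintf("<epi_spectrum> precursor %.4f, %d peaks, rt %.2f min\n",
              x$precursor_mz, length(x$mz), x$rt_min))
  invisible(x)
}

# ---- CSV dialects ----------------------------------------------------------
# Chromatogram CSV header: id,q1_mz,q3_mz,rt_min,intensity (long format, one
# row per point, multiple chromatograms keyed by id).
# Peak-list CSV header:    precursor_mz,rt_min,mz,intensity (one spectrum per
# distinct (precursor_mz, rt_min)).

#' Write chromatograms to the package CSV dialect
#' @param chroms List of `chromatogram`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chromatogram_csv <- function(chroms, path) {
  if (inherits(chroms, "chromatogram")) chroms <- list(chroms)
  df <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(id = ch$id, q1_mz = ch$q1_mz, q3_mz = ch$q3_mz,
               rt_min = ch$rt_min, intensity = ch$intensity)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write EPI spectra to the package peak-list CSV dialect
#' @param spectra List of `epi_spectrum`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peaklist_csv <- function(spectra, path) {
  if (inherits(spectra, "epi_spectrum")) spectra <- list(spectra)
  df <- do.call(rbind, lapply(spectra, function(sp) {
    data.frame(precursor_mz = sp$precursor_mz, rt_min = sp$rt_min,
               mz = sp$mz, intensity = sp$intensity)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read chromatograms and/or spectra from disk
#'
#' Supported formats: the package's chromatogram CSV and peak-list CSV
#' dialects (auto-detected from the header) and minimal mzML (see
#' [write_mzml()]). The load is lossless for these dialects.
#'
#' @param path File path.
#' @param format `"auto"` (default), `"csv"` or `"mzml"`.
#' @return List with elements `chromatograms` (list of `chromatogram`) and
#'   `spectra` (list of `epi_spectrum`).
#' @export
read_spectra <- function(path, format = c("auto", "csv", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "csv"
  if (format == "mzml") return(read_mzml(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  header <- names(df)
  if (nrow(df) == 0) stop("empty run: no rows in ", path)
  if (all(c("id", "q1_mz", "q3_mz", "rt_min", "intensity") %in% header)) {
    chroms <- lapply(split(df, df$id), function(d) {
      d <- d[order(d$rt_min), ]
      chromatogram(d$rt_min, d$intensity, d$q1_mz[1], d$q3_mz[1], d$id[1])
    })
    list(chromatograms = unname(chroms), spectra = list())
  } else if (all(c("precursor_mz", "rt_min", "mz", "intensity") %in% header)) {
    key <- paste(df$precursor_mz, df$rt_min)
    spectra <- lapply(split(df, key), function(d) {
      epi_spectrum(d$mz, d$intensity, d$precursor_mz[1], d$rt_min[1])
    })
    list(chromatograms = list(), spectra = unname(spectra))
  } else {
    stop("malformed file: unrecognized CSV header in ", path)
  }
}

# ---- minimal mzML ----------------------------------------------------------

.b64_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little"))
}

.doubles_b64 <- function(s) {
  readBin(jsonlite::base64_dec(s), what = "numeric", size = 8,
          n = nchar(s), endian = "little")
}

#' Write a minimal mzML file
#'
#' Self-contained mzML subset: SRM chromatograms and MS2 (EPI) spectra with
#' 64-bit little-endian, uncompressed, base64-encoded arrays. Intended to
#' exercise the reader and interchange with standard tooling on these
#' elements; it is not a complete PSI mzML implementation.
#'
#' @param run List with elements `chromatograms` and/or `spectra` as
#'   returned by [simulate_run()] or [read_spectra()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  chroms <- run$chromatograms %||% list()
  spectra <- run$spectra %||% list()
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"utf-8\"?>",
    "<mzML xmlns=\"http://psi.hupo.org/ms/mzml\" version=\"1.1.0\">",
    sprintf("  <run id=\"run\" defaultInstrumentConfigurationRef=\"IC1\">"))
  if (length(spectra)) {
    lines <- c(lines, sprintf("    <spectrumList count=\"%d\">",
                              length(spectra)))
    for (i in seq_along(spectra)) {
      sp <- spectra[[i]]
      lines <- c(lines, sprintf(
        paste0("      <spectrum index=\"%d\" id=\"%s\" defaultArrayLength=\"%d\"",
               " msLevel=\"2\" precursorMz=\"%.6f\" rtMinutes=\"%.6f\">"),
        i - 1L, esc(sp$id %||% sprintf("spectrum=%d", i)), length(sp$mz),
        sp$precursor_mz, sp$rt_min),
        sprintf("        <binaryDataArray arrayType=\"mz\"><binary>%s</binary></binaryDataArray>",
                .b64_doubles(sp$mz)),
        sprintf("        <binaryDataArray arrayType=\"intensity\"><binary>%s</binary></binaryDataArray>",
                .b64_doubles(sp$intensity)),
        "      </spectrum>")
    }
    lines <- c(lines, "    </spectrumList>")
  }
  if (length(chroms)) {
    lines <- c(lines, sprintf("    <chromatogramList count=\"%d\">",
                              length(chroms)))
    for (i in seq_along(chroms)) {
      ch <- chroms[[i]]
      lines <- c(lines, sprintf(
        paste0("      <chromatogram index=\"%d\" id=\"%s\"",
               " defaultArrayLength=\"%d\" q1=\"%.6f\" q3=\"%.6f\">"),
        i - 1L, esc(ch$id %||% sprintf("chromatogram=%d", i)),
        length(ch$rt_min), ch$q1_mz, ch$q3_mz),
        sprintf("        <binaryDataArray arrayType=\"time\"><binary>%s</binary></binaryDataArray>",
                .b64_doubles(ch$rt_min)),
        sprintf("        <binaryDataArray arrayType=\"intensity\"><binary>%s</binary></binaryDataArray>",
                .b64_doubles(ch$intensity)),
        "      </chromatogram>")
    }
    lines <- c(lines, "    </chromatogramList>")
  }
  lines <- c(lines, "  </run>", "</mzML>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal mzML file
#' @param path mzML path written by [write_mzml()] (or any file using the
#'   same uncompressed 64-bit arrays and attributes).
#' @return List with `chromatograms` and `spectra`.
#' @export
read_mzml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed mzML file ", path, ": ", conditionMessage(e)))
  ns <- c(m = "http://psi.hupo.org/ms/mzml")
  arrays_of <- function(node) {
    arr <- xml2::xml_find_all(node, ".//m:binaryDataArray", ns)
    types <- xml2::xml_attr(arr, "arrayType")
    vals <- lapply(arr, function(a)
      .doubles_b64(xml2::xml_text(xml2::xml_find_first(a, ".//m:binary", ns))))
    names(vals) <- types
    vals
  }
  sp_nodes <- xml2::xml_find_all(doc, ".//m:spectrum", ns)
  spectra <- lapply(sp_nodes, function(node) {
    a <- arrays_of(node)
    epi_spectrum(a$mz, a$intensity,
                 as.numeric(xml2::xml_attr(node, "precursorMz")),
                 as.numeric(xml2::xml_attr(node, "rtMinutes")),
                 xml2::xml_attr(node, "id"))
  })
  ch_nodes <- xml2::xml_find_all(doc, ".//m:chromatogram", ns)
  chroms <- lapply(ch_nodes, function(node) {
    a <- arrays_of(node)
    chromatogram(a$time, a$intensity,
                 as.numeric(xml2::xml_attr(node, "q1")),
                 as.numeric(xml2::xml_attr(node, "q3")),
                 xml2::xml_attr(node, "id"))
  })
  if (length(spectra) == 0 && length(chroms) == 0)
    stop("empty run: no spectra or chromatograms in ", path)
  list(chromatograms = chroms, spectra = spectra)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# ---- peak integration ------------------------------------------------------

.moving_average <- function(x, k = 5L) {
  if (length(x) < k) return(x)
  f <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  f[is.na(f)] <- x[is.na(f)]  # edges: fall back to raw values
  f
}

#' Detect and integrate a chromatographic peak
#'
#' Apex detection on a 5-point moving average; baseline is the straight line
#' between the window edges; area is the trapezoidal integral of the signal
#' above baseline (intensity x minutes). With `window = "auto"` the window
#' is the widest contiguous region above 3x the median-absolute-deviation
#' noise estimate. A trace with no signal above the noise threshold yields a
#' zero-area result flagged `not_detected`.
#'
#' @param chrom A `chromatogram`.
#' @param window `"auto"` or a numeric `c(t0, t1)` retention-time window in
#'   minutes.
#' @return A one-row data.frame (class `peak_area`): `id`, `q1_mz`, `q3_mz`,
#'   `rt_apex_min`, `area`, `height`, `fwhm_min`, `not_detected`.
#' @export
integrate_peak <- function(chrom, window = "auto") {
  stopifnot(inherits(chrom, "chromatogram"))
  rt <- chrom$rt_min; y <- chrom$intensity
  res <- function(apex = NA_real_, area = 0, height = 0, fwhm = NA_real_,
                  nd = TRUE) {
    structure(data.frame(id = chrom$id, q1_mz = chrom$q1_mz,
                         q3_mz = chrom$q3_mz, rt_apex_min = apex,
                         area = area, height = height, fwhm_min = fwhm,
                         not_detected = nd, stringsAsFactors = FALSE),
              class = c("peak_area", "data.frame"))
  }
  if (is.numeric(window)) {
    keep <- rt >= window[1] & rt <= window[2]
  } else {
    smooth_all <- .moving_average(y)
    noise <- stats::mad(y)
    thr <- 3 * noise
    above <- smooth_all > thr
    if (!any(above) || max(smooth_all) <= 0) return(res())
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    w <- which(runs$values)
    widest <- w[which.max(runs$lengths[w])]
    keep <- rep(FALSE, length(rt))
    # pad one point each side so the baseline anchors at near-background
    keep[max(1L, starts[widest] - 1L):min(length(rt), ends[widest] + 1L)] <- TRUE
  }
  if (sum(keep) < 5) return(res())
  rtw <- rt[keep]; yw <- y[keep]
  sm <- .moving_average(yw)
  if (max(sm) <= 0) return(res())
  # linear baseline between window edges
  base <- yw[1] + (yw[length(yw)] - yw[1]) *
    (rtw - rtw[1]) / (rtw[length(rtw)] - rtw[1])
  sig <- pmax(yw - base, 0)
  i_apex <- which.max(sm)
  apex <- rtw[i_apex]
  height <- sig[i_apex]
  area <- sum(diff(rtw) * (sig[-1] + sig[-length(sig)]) / 2)
  # FWHM with linear interpolation of the half-height crossings
  half <- height / 2
  above_half <- which(sig >= half)
  fwhm <- NA_real_
  if (length(above_half) >= 2) {
    lo <- min(above_half); hi <- max(above_half)
    t_lo <- rtw[lo]
    if (lo > 1 && sig[lo] > sig[lo - 1])
      t_lo <- rtw[lo - 1] + (half - sig[lo - 1]) / (sig[lo] - sig[lo - 1]) *
        (rtw[lo] - rtw[lo - 1])
    t_hi <- rtw[hi]
    if (hi < length(sig) && sig[hi] > sig[hi + 1])
      t_hi <- rtw[hi] + (sig[hi] - half) / (sig[hi] - sig[hi + 1]) *
        (rtw[hi + 1] - rtw[hi])
    fwhm <- t_hi - t_lo
  }
  res(apex, area, height, fwhm, nd = FALSE)
}

#' Integrate a list of chromatograms
#' @param chroms List of `chromatogram`s.
#' @param window Passed to [integrate_peak()].
#' @return data.frame with one row per chromatogram.
#' @export
integrate_peaks <- function(chroms, window = "auto") {
  out <- do.call(rbind, lapply(chroms, integrate_peak, window = window))
  rownames(out) <- NULL
  out
}
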