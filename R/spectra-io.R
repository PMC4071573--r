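#' Construct a scan-mode descriptor
#'
#' Four acquisition modes of a triple-quadrupole instrument are modeled:
#' `Q1` (survey of intact ions), `PIS` (precursor-ion scan for a diagnostic
#' fragment), `NL` (neutral-loss scan), and `PRODUCT` (product-ion scan of
#' one precursor). `parameter` is the diagnostic fragment m/z for PIS, the
#' neutral-loss mass for NL, and the precursor m/z for PRODUCT; it is
#' required for every kind except Q1.
#'
#' @param kind One of `"Q1"`, `"PIS"`, `"NL"`, `"PRODUCT"`.
#' @param polarity `"+"` or `"-"`.
#' @param parameter Numeric, see above.
#' @return A list of class `"scan_mode"`.
#' @examples
#' scan_mode("PIS", "+", 184.07)
#' @export
scan_mode <- function(kind, polarity, parameter = NULL) {
  kind <- match.arg(kind, c("Q1", "PIS", "NL", "PRODUCT"))
  if (!polarity %in% c("+", "-")) {
    stop("polarity must be '+' or '-', got: ", polarity, call. = FALSE)
  }
  if (kind != "Q1" && (is.null(parameter) || is.na(parameter))) {
    stop(kind, " scans require a parameter (diagnostic/loss/precursor m/z)",
         call. = FALSE)
  }
  if (kind == "Q1") parameter <- NA_real_
  structure(list(kind = kind, polarity = polarity,
                 parameter = as.numeric(parameter)),
            class = "scan_mode")
}

# Gating key used by the candidate index ("PIS184+", "NL162+", "Q1-", ...).
# PRODUCT scans do not gate classes and have no key.
mode_key <- function(mode) {
  stopifnot(inherits(mode, "scan_mode"))
  switch(mode$kind,
    Q1 = paste0("Q1", mode$polarity),
    PIS = paste0("PIS", round(mode$parameter), mode$polarity),
    NL = paste0("NL", round(mode$parameter), mode$polarity),
    PRODUCT = NA_character_
  )
}

#' Construct a spectrum
#'
#' A spectrum is a scan mode plus a fraction label (`"PL"` phospholipid,
#' `"GL"` glycolipid) and a peak list. Peaks are stored sorted by m/z;
#' unsorted input is sorted with a warning.
#'
#' @param mode A [scan_mode()].
#' @param fraction `"PL"` or `"GL"`.
#' @param peaks A data frame with numeric columns `mz` (> 0) and
#'   `intensity` (>= 0).
#' @return A list of class `"difi_spectrum"`.
#' @export
new_spectrum <- function(mode, fraction, peaks) {
  stopifnot(inherits(mode, "scan_mode"))
  if (!fraction %in% c("PL", "GL")) {
    stop("fraction must be 'PL' or 'GL'", call. = FALSE)
  }
  peaks <- tibble::as_tibble(peaks[, c("mz", "intensity")])
  peaks$mz <- unname(peaks$mz)
  peaks$intensity <- unname(peaks$intensity)
  if (nrow(peaks) > 0) {
    if (any(!is.finite(peaks$mz)) || any(peaks$mz <= 0)) {
      stop("peak m/z must be finite and > 0", call. = FALSE)
    }
    if (any(!is.finite(peaks$intensity)) || any(peaks$intensity < 0)) {
      stop("peak intensities must be finite and >= 0", call. = FALSE)
    }
    if (is.unsorted(peaks$mz)) {
      warning("peak list was not sorted by m/z; sorting", call. = FALSE)
      peaks <- peaks[order(peaks$mz), ]
    }
  }
  structure(list(mode = mode, fraction = fraction, peaks = peaks),
            class = "difi_spectrum")
}

#' @export
print.difi_spectrum <- function(x, ...) {
  par <- if (is.na(x$mode$parameter)) "" else sprintf(" (%.4g)", x$mode$parameter)
  cat(sprintf("<difi_spectrum> %s%s%s, fraction %s, %d peaks\n",
              x$mode$kind, x$mode$polarity, par, x$fraction, nrow(x$peaks)))
  invisible(x)
}

#' Plot a spectrum as a stick plot
#'
#' @param object A `difi_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot difi_spectrum
#' @export
autoplot.difi_spectrum <- function(object, ...) {
  pk <- object$peaks
  ggplot2::ggplot(pk, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                   y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    ggplot2::labs(
      x = "m/z", y = "intensity",
      title = sprintf("%s%s scan, %s fraction", object$mode$kind,
                      object$mode$polarity, object$fraction)
    ) +
    ggplot2::theme_minimal()
}

# ---- TSV dialect -------------------------------------------------------------

#' Read a peak list
#'
#' The TSV dialect has header lines `#mode=`, `#polarity=`, `#param=`,
#' `#fraction=`, then two tab-separated columns `mz`, `intensity`.
#' MGF files are parsed per the Mascot generic format, with the scan-mode
#' metadata carried in `TITLE` as `key=value` pairs separated by `;`
#' (`PEPMASS` supplies the product-scan precursor); an MGF file may hold
#' several spectra, in which case a list is returned.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"mgf"`.
#' @return A `difi_spectrum` (TSV, or single-block MGF) or a list of them.
#' @export
read_peaklist <- function(path, format = c("tsv", "mgf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "mgf") return(read_mgf(path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(hit) != 1) {
      stop("peak list is missing required header '#", key, "='", call. = FALSE)
    }
    sub(paste0("^#", key, "="), "", hit)
  }
  kind <- get("mode"); polarity <- get("polarity")
  param <- get("param"); fraction <- get("fraction")
  if (!polarity %in% c("+", "-")) {
    stop("bad #polarity= header (must be + or -): ", polarity, call. = FALSE)
  }
  param <- if (nzchar(param)) as.numeric(param) else NULL
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  peaks <- if (length(body) == 0) {
    tibble::tibble(mz = numeric(0), intensity = numeric(0))
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2)) stop("malformed peak row in ", path, call. = FALSE)
    tibble::tibble(
      mz = as.numeric(vapply(parts, `[`, character(1), 1)),
      intensity = as.numeric(vapply(parts, `[`, character(1), 2))
    )
  }
  new_spectrum(scan_mode(kind, polarity, param), fraction, peaks)
}

#' Write a peak list in the TSV dialect
#'
#' m/z is serialized at 4 decimals and intensity at 1 decimal so files
#' are diff-stable.
#'
#' @param spectrum A `difi_spectrum`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "difi_spectrum"))
  m <- spectrum$mode
  param <- if (is.na(m$parameter)) "" else sprintf("%.4f", m$parameter)
  hdr <- c(paste0("#mode=", m$kind), paste0("#polarity=", m$polarity),
           paste0("#param=", param), paste0("#fraction=", spectrum$fraction))
  rows <- sprintf("%.4f\t%.1f", spectrum$peaks$mz, spectrum$peaks$intensity)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- grep("^BEGIN IONS$", lines)
  ends <- grep("^END IONS$", lines)
  if (length(begins) == 0 || length(begins) != length(ends)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path, call. = FALSE)
  }
  out <- purrr::map2(begins, ends, function(b, e) {
    block <- lines[(b + 1):(e - 1)]
    kv <- block[grepl("^[A-Z]+=", block)]
    fields <- stats::setNames(sub("^[A-Z]+=", "", kv), sub("=.*$", "", kv))
    title <- fields[["TITLE"]]
    meta <- strsplit(strsplit(title, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    meta <- stats::setNames(
      vapply(meta, function(x) if (length(x) > 1) x[2] else "", character(1)),
      vapply(meta, `[`, character(1), 1)
    )
    param <- if ("PEPMASS" %in% names(fields)) {
      as.numeric(strsplit(fields[["PEPMASS"]], " ")[[1]][1])
    } else if (nzchar(meta["param"] %||% "")) as.numeric(meta[["param"]]) else NULL
    body <- block[!grepl("^[A-Z]+=", block) & nzchar(block)]
    peaks <- if (length(body) == 0) {
      tibble::tibble(mz = numeric(0), intensity = numeric(0))
    } else {
      parts <- strsplit(body, "[ \t]+")
      tibble::tibble(
        mz = as.numeric(vapply(parts, `[`, character(1), 1)),
        intensity = as.numeric(vapply(parts, `[`, character(1), 2))
      )
    }
    new_spectrum(scan_mode(meta[["mode"]], meta[["polarity"]], param),
                 meta[["fraction"]], peaks)
  })
  if (length(out) == 1) out[[1]] else out
}

#' Write one or more spectra as MGF
#'
#' @param spectra A `difi_spectrum` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "difi_spectrum")) spectra <- list(spectra)
  blocks <- purrr::map(spectra, function(s) {
    m <- s$mode
    title <- sprintf("TITLE=mode=%s;polarity=%s;fraction=%s",
                     m$kind, m$polarity, s$fraction)
    pep <- if (!is.na(m$parameter)) sprintf("PEPMASS=%.4f", m$parameter) else NULL
    c("BEGIN IONS", title, pep,
      sprintf("%.4f %.1f", s$peaks$mz, s$peaks$intensity), "END IONS")
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' Write an annotation table as TSV
#'
#' Stable column order (fraction, scan_mode, observed_mz, class,
#' composition, positional, adduct, theoretical_mz, error_mDa, error_ppm,
#' flags) and deterministic row order (class, then observed m/z), so
#' re-runs are byte-identical.
#'
#' @param annotations Annotation tibble from [match_peaks()] (a
#'   `positional` column is added as `"NA"` when absent).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  cols <- c("fraction", "scan_mode", "observed_mz", "class", "composition",
            "positional", "adduct", "theoretical_mz", "error_mDa",
            "error_ppm", "flags")
  if (nrow(annotations) == 0) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  ann <- annotations
  if (!"positional" %in% names(ann)) ann$positional <- NA_character_
  ann <- ann[order(ann$class, ann$observed_mz, ann$adduct), ]
  out <- data.frame(
    fraction = ann$fraction, scan_mode = ann$scan_mode,
    observed_mz = sprintf("%.4f", ann$observed_mz),
    class = ann$class, composition = ann$composition,
    positional = ifelse(is.na(ann$positional), "NA", ann$positional),
    adduct = ann$adduct,
    theoretical_mz = sprintf("%.4f", ann$theoretical_mz),
    error_mDa = sprintf("%.3f", ann$error_mDa),
    error_ppm = sprintf("%.2f", ann$error_ppm),
    flags = ifelse(is.na(ann$flags) | ann$flags == "", "", ann$flags)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
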