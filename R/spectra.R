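#' Construct a Raman spectrum
#'
#' The atomic data object of the package: a wavenumber axis (Raman shift,
#' cm^-1, stored in ascending order) with one intensity per point and a list
#' of acquisition metadata. All downstream quantification consumes this
#' object.
#'
#' @param wavenumbers numeric vector of Raman shifts in cm^-1. May be given
#'   in descending order; it is stored ascending with intensities reordered
#'   to match.
#' @param intensities numeric vector of intensities (arbitrary counts), same
#'   length as `wavenumbers`, all finite.
#' @param meta named list of acquisition metadata. Recognised fields:
#'   `cup_id`, `material` (one of `r paste(pe_materials(), collapse = ", ")`),
#'   `state` (`"unworn"` or `"worn"`), `point_index`, `polarization`
#'   (`"unpolarized"`, `"XYYX"`, `"XZYX"`), `accumulations`.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumbers`, `intensities`, `meta`.
#' @examples
#' s <- raman_spectrum(seq(1000, 1500, by = 5), rexp(101), list(cup_id = "STD1"))
#' range(s$wavenumbers)
#' @export
raman_spectrum <- function(wavenumbers, intensities, meta = list()) {
  if (!is.numeric(wavenumbers) || !is.numeric(intensities)) {
    stop("wavenumbers and intensities must be numeric", call. = FALSE)
  }
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have the same length", call. = FALSE)
  }
  if (length(wavenumbers) < 2L) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers))) {
    stop("wavenumbers must be finite", call. = FALSE)
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop("intensities must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (all(d < 0)) {
    wavenumbers <- rev(wavenumbers)
    intensities <- rev(intensities)
    d <- -rev(d)
  }
  if (any(d <= 0)) {
    stop("wavenumber axis must be strictly monotonic (duplicate or unordered values found)",
         call. = FALSE)
  }
  if (!is.list(meta)) stop("meta must be a list", call. = FALSE)
  validate_spectrum_meta(meta)
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 intensities = as.numeric(intensities),
                 meta = meta),
            class = "raman_spectrum")
}

#' Controlled vocabulary of cup materials
#'
#' @return Character vector of the four material group labels: standard
#'   UHMWPE, 50 and 75 kGy cross-linked PE, and vitamin E-blended UHMWPE.
#' @export
pe_materials <- function() c("STD", "XL-50", "XL-75", "VE")

pe_states <- function() c("unworn", "worn")
pe_polarizations <- function() c("unpolarized", "XYYX", "XZYX")

# Accept "XL50"/"xl-50" spellings etc.; return canonical token or NA.
normalize_material <- function(x) {
  key <- toupper(gsub("[-_ ]", "", x))
  canon <- pe_materials()
  names(canon) <- toupper(gsub("[-_ ]", "", canon))
  unname(canon[key])
}

validate_spectrum_meta <- function(meta) {
  if (!is.null(meta$material)) {
    if (is.na(normalize_material(meta$material))) {
      stop("unknown material '", meta$material, "'; expected one of ",
           paste(pe_materials(), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(meta$state) && !meta$state %in% pe_states()) {
    stop("unknown state '", meta$state, "'; expected unworn or worn", call. = FALSE)
  }
  if (!is.null(meta$polarization) && !meta$polarization %in% pe_polarizations()) {
    stop("unknown polarization '", meta$polarization, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  if (length(x$meta)) {
    flat <- vapply(x$meta, function(v) paste(format(v), collapse = ","), "")
    cat("  meta:", paste(names(flat), flat, sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Check that a spectrum covers a wavenumber interval
#'
#' Quantification needs the full 1040-1480 cm^-1 analysis range (fitted
#' 1040-1110 C-C stretching region through the 1416 cm^-1 crystallinity
#' marker); spectra that do not span it are rejected up front.
#'
#' @param s a `raman_spectrum`.
#' @param span numeric length-2, the required `[lo, hi]` interval in cm^-1.
#' @param what label used in the error message.
#' @return `s`, invisibly, if coverage holds; otherwise an error.
#' @export
require_coverage <- function(s, span = c(1040, 1480), what = "quantification") {
  stopifnot(inherits(s, "raman_spectrum"))
  lo <- min(s$wavenumbers); hi <- max(s$wavenumbers)
  if (lo > span[1] || hi < span[2]) {
    stop(sprintf("spectrum spans [%.1f, %.1f] cm^-1 but %s requires coverage of [%g, %g]",
                 lo, hi, what, span[1], span[2]), call. = FALSE)
  }
  invisible(s)
}

#' Read a spectrum from disk
#'
#' Supports two interchange dialects: two-column ASCII XY (whitespace- or
#' comma-separated, `#` comments, no header required) and JCAMP-DX with
#' `XYDATA=(X++(Y..Y))` or `XYPOINTS=(XY..XY)` tables in AFFN (plain
#' decimal) form. Descending axes are reversed to ascending storage order.
#'
#' @param path file path.
#' @param format `"ascii-xy"`, `"jcamp-dx"`, or `"auto"` (default: sniff by
#'   extension `.jdx`/`.dx`/`.jcamp`, else content).
#' @param meta metadata list attached to the returned spectrum (merged over
#'   anything recovered from the file header).
#' @param span required wavenumber coverage, `NULL` to skip the check.
#'   Defaults to `NULL`: coverage is enforced where quantification starts.
#' @return a `raman_spectrum`.
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, format = c("auto", "ascii-xy", "jcamp-dx"),
                          meta = list(), span = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jdx", "dx", "jcamp")) "jcamp-dx" else {
      first <- readLines(path, n = 1L, warn = FALSE)
      if (length(first) && startsWith(trimws(first), "##")) "jcamp-dx" else "ascii-xy"
    }
  }
  parsed <- switch(format,
    "ascii-xy" = parse_ascii_xy(path),
    "jcamp-dx" = parse_jcamp(path))
  s <- raman_spectrum(parsed$x, parsed$y, meta = utils::modifyList(parsed$meta, meta))
  if (!is.null(span)) require_coverage(s, span, what = "this analysis")
  s
}

parse_ascii_xy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  x <- numeric(0); y <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[[i]])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "[,;[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(vals) < 2L || anyNA(vals)) {
      stop(sprintf("%s: line %d is not a two-column numeric row: '%s'",
                   path, i, lines[[i]]), call. = FALSE)
    }
    x <- c(x, vals[1]); y <- c(y, vals[2])
  }
  if (length(x) < 2L) stop(path, ": fewer than 2 data rows", call. = FALSE)
  list(x = x, y = y, meta = list())
}

#' Write a spectrum to disk
#'
#' Inverse of [read_spectrum()]; both formats round-trip the axes to better
#' than 1e-9 (values are written with 15 significant digits).
#'
#' @param s a `raman_spectrum`.
#' @param path output file path.
#' @param format `"ascii-xy"` or `"jcamp-dx"` (written as an AFFN
#'   `XYPOINTS=(XY..XY)` table).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("ascii-xy", "jcamp-dx")) {
  stopifnot(inherits(s, "raman_spectrum"))
  format <- match.arg(format)
  num <- function(v) sprintf("%.15g", v)
  if (format == "ascii-xy") {
    hdr <- "# ramanpe spectrum: Raman shift (cm^-1)  intensity (counts)"
    writeLines(c(hdr, paste(num(s$wavenumbers), num(s$intensities))), path)
  } else {
    title <- if (!is.null(s$meta$cup_id)) as.character(s$meta$cup_id) else "ramanpe spectrum"
    lines <- c(
      paste0("##TITLE=", title),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=RAMAN SPECTRUM",
      "##XUNITS=1/CM",
      "##YUNITS=ARBITRARY UNITS",
      "##XFACTOR=1",
      "##YFACTOR=1",
      paste0("##FIRSTX=", num(s$wavenumbers[1])),
      paste0("##LASTX=", num(s$wavenumbers[length(s$wavenumbers)])),
      paste0("##NPOINTS=", length(s$wavenumbers)),
      "##XYPOINTS=(XY..XY)",
      paste0(num(s$wavenumbers), ", ", num(s$intensities)),
      "##END=")
    writeLines(lines, path)
  }
  invisible(path)
}

# Minimal JCAMP-DX reader: AFFN XYDATA=(X++(Y..Y)) and XYPOINTS=(XY..XY).
# Compressed ordinate forms (SQZ/DIF/DUP/PAC) are out of scope.
parse_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    pat <- paste0("^##\\s*", name, "\\s*=")
    hit <- grep(pat, toupper(lines))
    if (!length(hit)) return(NULL)
    trimws(sub(pat, "", lines[hit[1]], ignore.case = TRUE))
  }
  xf <- suppressWarnings(as.numeric(ldr("XFACTOR"))); if (!length(xf) || is.na(xf)) xf <- 1
  yf <- suppressWarnings(as.numeric(ldr("YFACTOR"))); if (!length(yf) || is.na(yf)) yf <- 1
  start <- grep("^##\\s*(XYDATA|XYPOINTS)\\s*=", toupper(lines))
  if (!length(start)) {
    stop(path, ": no ##XYDATA or ##XYPOINTS table found", call. = FALSE)
  }
  start <- start[1]
  mode <- if (grepl("XYPOINTS", toupper(lines[start]))) "xypoints" else "xydata"
  body_end <- grep("^##", lines)
  body_end <- body_end[body_end > start]
  body_end <- if (length(body_end)) body_end[1] - 1L else length(lines)
  body <- lines[seq(start + 1L, body_end)]
  body <- trimws(sub("\\$\\$.*$", "", body))  # strip inline comments
  body <- body[nzchar(body)]
  if (!length(body)) stop(path, ": empty JCAMP data table", call. = FALSE)

  if (mode == "xypoints") {
    x <- numeric(0); y <- numeric(0)
    for (i in seq_along(body)) {
      tok <- strsplit(body[[i]], "[,;[:space:]]+")[[1]]
      tok <- tok[nzchar(tok)]
      vals <- suppressWarnings(as.numeric(tok))
      if (anyNA(vals) || length(vals) %% 2L != 0L) {
        stop(sprintf("%s: malformed XYPOINTS line %d: '%s'", path,
                     start + i, body[[i]]), call. = FALSE)
      }
      idx <- seq(1L, length(vals), by = 2L)
      x <- c(x, vals[idx]); y <- c(y, vals[idx + 1L])
    }
  } else {
    # (X++(Y..Y)): each line starts with an abscissa, rest are ordinates at
    # uniform DELTAX increments.
    raw <- lapply(seq_along(body), function(i) {
      tok <- strsplit(body[[i]], "[,;[:space:]]+")[[1]]
      tok <- tok[nzchar(tok)]
      vals <- suppressWarnings(as.numeric(tok))
      if (anyNA(vals) || length(vals) < 2L) {
        stop(sprintf("%s: malformed XYDATA line %d: '%s'", path,
                     start + i, body[[i]]), call. = FALSE)
      }
      vals
    })
    firstx <- suppressWarnings(as.numeric(ldr("FIRSTX")))
    lastx <- suppressWarnings(as.numeric(ldr("LASTX")))
    npts <- suppressWarnings(as.integer(ldr("NPOINTS")))
    ny <- sum(vapply(raw, function(v) length(v) - 1L, 1L))
    dx <- suppressWarnings(as.numeric(ldr("DELTAX")))
    if (!length(dx) || is.na(dx)) {
      if (length(firstx) && length(lastx) && !is.na(firstx) && !is.na(lastx) && ny > 1L) {
        dx <- (lastx - firstx) / (ny - 1L) / xf
      } else if (length(raw) > 1L) {
        dx <- (raw[[2]][1] - raw[[1]][1]) / (length(raw[[1]]) - 1L)
      } else {
        stop(path, ": cannot infer DELTAX for XYDATA table", call. = FALSE)
      }
    }
    x <- numeric(0); y <- numeric(0)
    for (v in raw) {
      n <- length(v) - 1L
      x <- c(x, v[1] + dx * (seq_len(n) - 1L))
      y <- c(y, v[-1])
    }
    if (length(npts) && !is.na(npts) && npts != length(y)) {
      stop(sprintf("%s: NPOINTS=%d but %d ordinates read", path, npts, length(y)),
           call. = FALSE)
    }
  }
  meta <- list()
  ttl <- ldr("TITLE")
  if (length(ttl) && nzchar(ttl)) meta$title <- ttl
  list(x = x * xf, y = y * yf, meta = meta)
}

#' Read a cohort manifest
#'
#' One CSV describes a whole wear study: spectrum rows map files to cup,
#' material group, wear state, measurement point and polarization;
#' gravimetry rows (role `loaded` or `soak_control`) carry the measured mass
#' change of each cup. Soak-control cups are non-loaded reference cups
#' stored in serum to measure fluid-absorption mass gain; they may appear
#' with gravimetry only (no spectra).
#'
#' Columns: `role` (`spectrum`, `loaded`, `soak_control`), `path`, `cup_id`,
#' `material`, `state`, `point_index`, `polarization`,
#' `measured_mass_change_mg`. Spectrum rows need `path`..`point_index`;
#' gravimetry rows need `cup_id`, `material`, `measured_mass_change_mg`.
#'
#' @param path manifest CSV path; relative spectrum paths are resolved
#'   against the manifest's directory.
#' @return A `cohort_manifest`: list with data frames `records` (spectrum
#'   rows, with resolved absolute `path`) and `gravimetry`.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("role", "cup_id", "material")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("manifest missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(df$role), c("spectrum", "loaded", "soak_control"))
  if (length(bad_role)) {
    stop("unknown role value(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  mat <- normalize_material(df$material)
  if (anyNA(mat)) {
    stop("unknown material value(s): ",
         paste(unique(df$material[is.na(mat)]), collapse = ", "), call. = FALSE)
  }
  df$material <- mat

  rec <- df[df$role == "spectrum", , drop = FALSE]
  grav <- df[df$role != "spectrum", , drop = FALSE]

  if (nrow(rec)) {
    for (col in c("path", "state", "point_index")) {
      if (!col %in% names(rec) || any(is.na(rec[[col]]) | rec[[col]] == "")) {
        stop("spectrum rows must have non-empty '", col, "'", call. = FALSE)
      }
    }
    bad_state <- setdiff(unique(rec$state), pe_states())
    if (length(bad_state)) {
      stop("unknown state value(s): ", paste(bad_state, collapse = ", "), call. = FALSE)
    }
    rec$point_index <- as.integer(rec$point_index)
    if (any(is.na(rec$point_index) | rec$point_index < 1L)) {
      stop("point_index must be a positive integer", call. = FALSE)
    }
    if (!"polarization" %in% names(rec)) rec$polarization <- "unpolarized"
    rec$polarization[is.na(rec$polarization) | rec$polarization == ""] <- "unpolarized"
    bad_pol <- setdiff(unique(rec$polarization), pe_polarizations())
    if (length(bad_pol)) {
      stop("unknown polarization value(s): ", paste(bad_pol, collapse = ", "),
           call. = FALSE)
    }
    key <- paste(rec$cup_id, rec$state, rec$point_index, rec$polarization, sep = "\r")
    if (anyDuplicated(key)) {
      d <- rec[duplicated(key), c("cup_id", "state", "point_index")]
      stop("duplicate (cup_id, state, point_index) in manifest: ",
           paste(apply(d, 1, paste, collapse = "/"), collapse = "; "), call. = FALSE)
    }
    base <- dirname(normalizePath(path))
    abs <- ifelse(grepl("^(/|[A-Za-z]:)", rec$path), rec$path,
                  file.path(base, rec$path))
    missing_files <- abs[!file.exists(abs)]
    if (length(missing_files)) {
      stop("manifest references missing spectrum file(s): ",
           paste(utils::head(missing_files, 5), collapse = ", "), call. = FALSE)
    }
    rec$path <- abs
  }
  if (nrow(grav)) {
    if (!"measured_mass_change_mg" %in% names(grav) ||
        any(is.na(suppressWarnings(as.numeric(grav$measured_mass_change_mg))))) {
      stop("gravimetry rows must have numeric measured_mass_change_mg", call. = FALSE)
    }
    grav$measured_mass_change_mg <- as.numeric(grav$measured_mass_change_mg)
  }
  structure(list(records = rec, gravimetry = grav, path = normalizePath(path)),
            class = "cohort_manifest")
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("<cohort_manifest> %d spectra, %d gravimetry records\n",
              nrow(x$records), nrow(x$gravimetry)))
  invisible(x)
}
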