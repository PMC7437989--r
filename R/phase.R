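#' Calibration constants of the phase and conformer equations
#'
#' The Strobl-Hagedorn three-phase equations and the Lagaron/Naylor
#' conformer equations are ratios of integrated band areas scaled by fixed
#' calibration constants established against X-ray / DSC crystallinity:
#'
#' \deqn{\alpha_o = A_{1416} / (0.46\, A_{1295+1305})}
#' \deqn{\alpha_a = A_{1085} / (0.79\, A_{1295+1305})}
#' \deqn{\alpha_b = 1 - (\alpha_o + \alpha_a)}
#' \deqn{\mathrm{all\mbox{-}trans} = A_{1130} / (0.80\, A_{1295+1305})}
#' \deqn{\mathrm{ortho\mbox{-}trans} = 1.78\, A_{1416} / A_{1130}}
#'
#' The constants are stored exactly at their published precision and are
#' never re-derived; override only deliberately, e.g. to explore an
#' alternative calibration.
#'
#' @param c_o denominator constant of the orthorhombic fraction (1416 cm^-1
#'   band), default 0.46.
#' @param c_a denominator constant of the amorphous fraction (1085 cm^-1
#'   band), default 0.79.
#' @param c_t denominator constant of the all-trans fraction (1130 cm^-1
#'   band), default 0.80.
#' @param c_ot multiplier of the ortho-trans ratio, default 1.78.
#' @return list of class `pe_calibration`.
#' @export
pe_calibration <- function(c_o = 0.46, c_a = 0.79, c_t = 0.80, c_ot = 1.78) {
  vals <- c(c_o = c_o, c_a = c_a, c_t = c_t, c_ot = c_ot)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("calibration constants must be positive and finite", call. = FALSE)
  }
  structure(as.list(vals), class = "pe_calibration")
}

#' Band areas of a polyethylene Raman spectrum
#'
#' The five integrated areas every derived parameter is built from:
#' 1416 cm^-1 (orthorhombic CH2 bend), 1085 cm^-1 (amorphous C-C stretch),
#' the conformation-independent 1295+1305 cm^-1 CH2-twisting reference
#' group, 1130 cm^-1 (all-trans C-C stretch), and 1065 cm^-1 (the
#' orientation reference for the A1130/A1065 check).
#'
#' @param A_1416,A_1085,A_1295_1305,A_1130,A_1065 nonnegative areas
#'   (intensity x cm^-1).
#' @param flags character vector of quality flags attached during
#'   measurement (e.g. `"A_1130:clipped_negative"`).
#' @return list of class `band_areas`.
#' @export
band_areas <- function(A_1416, A_1085, A_1295_1305, A_1130, A_1065,
                       flags = character(0)) {
  v <- c(A_1416 = A_1416, A_1085 = A_1085, A_1295_1305 = A_1295_1305,
         A_1130 = A_1130, A_1065 = A_1065)
  if (any(!is.finite(v))) stop("band areas must be finite", call. = FALSE)
  if (any(v < 0)) stop("band areas must be nonnegative", call. = FALSE)
  structure(c(as.list(v), list(flags = flags)), class = "band_areas")
}

#' @export
print.band_areas <- function(x, ...) {
  cat(sprintf("<band_areas> A1416=%.4g A1085=%.4g A1295+1305=%.4g A1130=%.4g A1065=%.4g\n",
              x$A_1416, x$A_1085, x$A_1295_1305, x$A_1130, x$A_1065))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Three-phase composition from band areas
#'
#' Computes the orthorhombic (`alpha_o`), amorphous (`alpha_a`) and
#' intermediate "third-phase" (`alpha_b`) mass fractions. `alpha_b` is
#' obtained by difference and may come out negative for unsuitable band
#' choices; it is then flagged (`negative_alpha_b`), never silently
#' clipped, so the diagnostic information survives.
#'
#' @param areas a [band_areas()] object (requires `A_1295_1305 > 0`).
#' @param const a [pe_calibration()] object.
#' @return list of class `phase_composition` with `alpha_o`, `alpha_a`,
#'   `alpha_b`, `flags`.
#' @export
compute_phase_composition <- function(areas, const = pe_calibration()) {
  stopifnot(inherits(areas, "band_areas"), inherits(const, "pe_calibration"))
  if (areas$A_1295_1305 <= 0) {
    stop("A_1295_1305 must be positive to normalise band areas", call. = FALSE)
  }
  alpha_o <- areas$A_1416 / (const$c_o * areas$A_1295_1305)
  alpha_a <- areas$A_1085 / (const$c_a * areas$A_1295_1305)
  alpha_b <- 1 - (alpha_o + alpha_a)
  flags <- character(0)
  if (alpha_b < 0) flags <- "negative_alpha_b"
  structure(list(alpha_o = alpha_o, alpha_a = alpha_a, alpha_b = alpha_b,
                 flags = flags),
            class = "phase_composition")
}

#' Trans-conformer content from band areas
#'
#' `all_trans` is the fraction of extended planar-zigzag C-C sequences in
#' all phases (1130 cm^-1 band over the twisting reference); `ortho_trans`
#' is the fraction of those sequences sitting in an orthorhombic (crystal)
#' environment. The two move inversely when A1130 changes because it enters
#' the first ratio in the numerator and the second in the denominator.
#'
#' @inheritParams compute_phase_composition
#' @return list of class `conformer_content` with `all_trans`,
#'   `ortho_trans` (NA and flagged `undefined_ortho_trans` when
#'   `A_1130 = 0`), `flags`.
#' @export
compute_conformer_content <- function(areas, const = pe_calibration()) {
  stopifnot(inherits(areas, "band_areas"), inherits(const, "pe_calibration"))
  if (areas$A_1295_1305 <= 0) {
    stop("A_1295_1305 must be positive to normalise band areas", call. = FALSE)
  }
  all_trans <- areas$A_1130 / (const$c_t * areas$A_1295_1305)
  flags <- character(0)
  if (areas$A_1130 > 0) {
    ortho_trans <- const$c_ot * areas$A_1416 / areas$A_1130
  } else {
    ortho_trans <- NA_real_
    flags <- "undefined_ortho_trans"
  }
  structure(list(all_trans = all_trans, ortho_trans = ortho_trans, flags = flags),
            class = "conformer_content")
}

#' Molecular-orientation check ratio
#'
#' The 1130 and 1065 cm^-1 bands have different vibrational symmetries;
#' under preferred chain orientation the 1130 cm^-1 band strengthens
#' relative to 1065 cm^-1. A stable A1130/A1065 ratio across wear states
#' supports isotropy of the articulating surface, i.e. that changes in the
#' 1130 cm^-1 band reflect conformation, not orientation.
#'
#' @param areas a [band_areas()] object.
#' @return list of class `orientation_check` with `ratio_1130_1065` (NA and
#'   flagged when `A_1065 = 0`).
#' @export
orientation_ratio <- function(areas) {
  stopifnot(inherits(areas, "band_areas"))
  if (areas$A_1065 > 0) {
    structure(list(ratio_1130_1065 = areas$A_1130 / areas$A_1065,
                   flags = character(0)),
              class = "orientation_check")
  } else {
    structure(list(ratio_1130_1065 = NA_real_, flags = "undefined_orientation_ratio"),
              class = "orientation_check")
  }
}

#' Coincidence of spectra under different laser polarizations
#'
#' Compares parallel X(YY)X and crossed X(ZY)X polarization spectra from
#' the same point. Each spectrum is normalized to its 1295+1305 cm^-1
#' reference area (the standard internal normalization), linearly
#' interpolated onto the common wavenumber grid, and the root-mean-square
#' difference divided by the mean of the two normalized peak intensities is
#' returned. Identical spectra give 0; values below `threshold` are
#' reported as coincident, i.e. no detectable polarization dependence and
#' hence no chain orientation. The default threshold 0.05 is a documented
#' convention validated against noise-only simulations.
#'
#' @param s_yy,s_zy `raman_spectrum` objects for the two polarization
#'   geometries.
#' @param window wavenumber window of the twisting reference used for
#'   normalization.
#' @param threshold coincidence call threshold on the metric.
#' @return list of class `polarization_comparison`: `metric`, `coincident`,
#'   `n_common` grid points.
#' @export
compare_polarizations <- function(s_yy, s_zy, window = c(1270, 1330),
                                  threshold = 0.05) {
  stopifnot(inherits(s_yy, "raman_spectrum"), inherits(s_zy, "raman_spectrum"))
  lo <- max(min(s_yy$wavenumbers), min(s_zy$wavenumbers))
  hi <- min(max(s_yy$wavenumbers), max(s_zy$wavenumbers))
  if (lo >= hi) stop("spectra have no common wavenumber range", call. = FALSE)
  norm1 <- integrate_band(s_yy, window, local_baseline = "none")
  norm2 <- integrate_band(s_zy, window, local_baseline = "none")
  if (norm1$area <= 0 || norm2$area <= 0) {
    stop("reference 1295+1305 area must be positive in both spectra", call. = FALSE)
  }
  grid <- sort(unique(c(
    s_yy$wavenumbers[s_yy$wavenumbers >= lo & s_yy$wavenumbers <= hi],
    s_zy$wavenumbers[s_zy$wavenumbers >= lo & s_zy$wavenumbers <= hi])))
  y1 <- stats::approx(s_yy$wavenumbers, s_yy$intensities, xout = grid)$y / norm1$area
  y2 <- stats::approx(s_zy$wavenumbers, s_zy$intensities, xout = grid)$y / norm2$area
  peak <- mean(c(max(y1), max(y2)))
  if (peak <= 0) stop("degenerate (nonpositive) spectra", call. = FALSE)
  metric <- sqrt(mean((y1 - y2)^2)) / peak
  structure(list(metric = metric, coincident = metric < threshold,
                 threshold = threshold, n_common = length(grid)),
            class = "polarization_comparison")
}
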