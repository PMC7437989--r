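#' Default baseline specification
#'
#' A linear baseline through two band-free anchor windows flanking the
#' analysis range: 1020-1035 cm^-1 (below the 1065 cm^-1 C-C stretch) and
#' 1480-1495 cm^-1 (above the CH2 bending envelope). A degree-2 polynomial
#' over the same anchors is available for curved fluorescence backgrounds.
#'
#' @param method `"linear-anchors"` or `"polynomial"`.
#' @param anchors list of numeric length-2 anchor windows (cm^-1) the
#'   baseline is fitted through.
#' @param degree polynomial degree (polynomial method only), at most 5.
#' @return list of class `baseline_spec`.
#' @export
baseline_spec <- function(method = c("linear-anchors", "polynomial"),
                          anchors = list(c(1020, 1035), c(1480, 1495)),
                          degree = 2L) {
  method <- match.arg(method)
  if (!length(anchors) || !all(vapply(anchors, length, 1L) == 2L)) {
    stop("anchors must be a list of [lo, hi] windows", call. = FALSE)
  }
  if (method == "polynomial") {
    degree <- as.integer(degree)
    if (degree < 1L || degree > 5L) stop("degree must be in 1..5", call. = FALSE)
  } else {
    degree <- 1L
  }
  structure(list(method = method, anchors = anchors, degree = degree),
            class = "baseline_spec")
}

#' Baseline-correct a spectrum
#'
#' Fits the baseline model through the points falling inside the anchor
#' windows and subtracts it over the whole axis. Because the model is
#' re-fitted to already-corrected data, applying the correction twice with
#' the same anchors is idempotent up to numerical noise.
#'
#' @param s a `raman_spectrum`.
#' @param spec a [baseline_spec()].
#' @return list with `spectrum` (corrected `raman_spectrum`) and `model`
#'   (the fitted baseline: `spec` plus `coefficients` of the polynomial in
#'   centred wavenumber and the `baseline` evaluated on the axis).
#' @export
correct_baseline <- function(s, spec = baseline_spec()) {
  stopifnot(inherits(s, "raman_spectrum"), inherits(spec, "baseline_spec"))
  wn <- s$wavenumbers
  span <- range(wn)
  if (length(spec$anchors) < spec$degree + 1L) {
    stop(sprintf(paste0("a degree-%d baseline needs at least %d anchor windows ",
                        "to be determined; got %d"),
                 spec$degree, spec$degree + 1L, length(spec$anchors)),
         call. = FALSE)
  }
  idx <- logical(length(wn))
  for (w in spec$anchors) {
    w <- sort(w)
    if (w[1] < span[1] - 1e-9 || w[2] > span[2] + 1e-9) {
      stop(sprintf("anchor window [%g, %g] lies outside the spectrum span [%g, %g]",
                   w[1], w[2], span[1], span[2]), call. = FALSE)
    }
    inw <- wn >= w[1] & wn <= w[2]
    if (sum(inw) < 2L) {
      stop(sprintf("anchor window [%g, %g] contains fewer than 2 points", w[1], w[2]),
           call. = FALSE)
    }
    idx <- idx | inw
  }
  # centre the axis for a well-conditioned polynomial basis
  x0 <- mean(span)
  basis <- function(x) outer(x - x0, 0:spec$degree, `^`)
  fit <- stats::lm.fit(basis(wn[idx]), s$intensities[idx])
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  baseline <- drop(basis(wn) %*% coefs)
  corrected <- raman_spectrum(wn, s$intensities - baseline, meta = s$meta)
  model <- spec
  model$coefficients <- coefs
  model$center <- x0
  model$baseline <- baseline
  list(spectrum = corrected, model = model)
}

#' Extract a wavenumber region
#'
#' Returns the points with `lo <= wavenumber <= hi` (inclusive bounds, as
#' in the "1040-1110 cm^-1 range" convention), metadata preserved.
#'
#' @param s a `raman_spectrum`.
#' @param lo,hi region bounds in cm^-1, `lo < hi`, inside the spectrum span.
#' @return a `raman_spectrum` restricted to the region.
#' @export
extract_region <- function(s, lo, hi) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (!(lo < hi)) stop("lo must be < hi", call. = FALSE)
  keep <- s$wavenumbers >= lo & s$wavenumbers <= hi
  if (sum(keep) < 2L) {
    stop(sprintf("region [%g, %g] selects fewer than 2 points from span [%g, %g]",
                 lo, hi, min(s$wavenumbers), max(s$wavenumbers)), call. = FALSE)
  }
  raman_spectrum(s$wavenumbers[keep], s$intensities[keep], meta = s$meta)
}
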