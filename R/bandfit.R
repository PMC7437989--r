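#' Pseudo-Voigt profile
#'
#' Area-parameterized pseudo-Voigt line shape: a linear combination of a
#' unit-area Gaussian and a unit-area Lorentzian sharing one full width at
#' half maximum, mixed by `gaussian_fraction` and scaled to integrate
#' (over the whole real line) to `area`.
#'
#' @param x wavenumbers (cm^-1).
#' @param area integrated area (intensity x cm^-1).
#' @param center band position (cm^-1).
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param gaussian_fraction Gaussian mixing fraction in `[0, 1]`.
#' @return intensities at `x`.
#' @export
pseudo_voigt <- function(x, area, center, fwhm, gaussian_fraction = 0.5) {
  stopifnot(fwhm > 0)
  u <- (x - center) / fwhm
  g <- (2 / fwhm) * sqrt(log(2) / pi) * exp(-4 * log(2) * u^2)
  l <- (2 / (pi * fwhm)) / (1 + 4 * u^2)
  area * (gaussian_fraction * g + (1 - gaussian_fraction) * l)
}

#' Fraction of a pseudo-Voigt area captured by a finite window
#'
#' Closed-form integral of the unit-area pseudo-Voigt over `[lo, hi]`:
#' Gaussian part via the normal CDF, Lorentzian part via the arctangent
#' CDF. Used to correct finite-window trapezoidal band integrals for the
#' slowly decaying Lorentzian tails (a +-2 FWHM window loses ~8% of a pure
#' Lorentzian).
#'
#' @param window numeric length-2 `[lo, hi]` in cm^-1.
#' @inheritParams pseudo_voigt
#' @return captured area fraction in `(0, 1)`.
#' @export
pv_window_fraction <- function(window, center, fwhm, gaussian_fraction = 0.5) {
  stopifnot(fwhm > 0, length(window) == 2L)
  window <- sort(window)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  fg <- stats::pnorm(window[2], center, sigma) - stats::pnorm(window[1], center, sigma)
  fl <- (atan(2 * (window[2] - center) / fwhm) -
           atan(2 * (window[1] - center) / fwhm)) / pi
  gaussian_fraction * fg + (1 - gaussian_fraction) * fl
}

#' Define a peak component
#'
#' @param center band position in cm^-1.
#' @param fwhm full width at half maximum in cm^-1.
#' @param gaussian_fraction Gaussian mixing fraction.
#' @param area integrated area (used as initial guess when fitting; `NA` to
#'   initialize from the data).
#' @param label optional band label.
#' @return one-row data frame.
#' @export
peak_component <- function(center, fwhm = 10, gaussian_fraction = 0.5,
                           area = NA_real_, label = NULL) {
  data.frame(label = if (is.null(label)) sprintf("%.0f", center) else label,
             center = center, fwhm = fwhm,
             gaussian_fraction = gaussian_fraction, area = area,
             stringsAsFactors = FALSE)
}

#' Fit pseudo-Voigt components to a spectral region
#'
#' Bounded least-squares fit (Levenberg-Marquardt, [minpack.lm::nls.lm()])
#' of a sum of pseudo-Voigt components to a baseline-corrected region.
#' Free parameters per component: area (>= 0), center (within
#' `center_window` of its initial value), FWHM (in `fwhm_bounds`), and
#' Gaussian fraction (in `[0, 1]`). Intensities are normalized internally
#' to their maximum absolute value before fitting and areas rescaled
#' afterwards, so results are exactly invariant under global intensity
#' scaling.
#'
#' @param region a `raman_spectrum` restricted to the fit region (e.g. the
#'   1040-1110 cm^-1 C-C stretching range), baseline-corrected.
#' @param init data frame of initial components ([peak_component()] rows).
#' @param center_window half-width of the center box constraint (cm^-1).
#' @param fwhm_bounds numeric length-2 global FWHM bounds (cm^-1).
#' @param fwhm_rel optional length-2 relative FWHM bounds per component
#'   (multiples of the initial width, intersected with `fwhm_bounds`);
#'   polymer band widths are well characterized, so constraining them
#'   stabilizes overlapped fits at modest signal-to-noise.
#' @param include_baseline if `TRUE`, a free linear baseline is fitted
#'   together with the components (absorbs residual background and tails
#'   of distant bands).
#' @param max_iter,ftol optimizer controls.
#' @return object of class `region_fit`: `components` (data frame with
#'   fitted `center`, `fwhm`, `gaussian_fraction`, `area`), `baseline`
#'   (intercept/slope or NULL), `residual_rms`, `converged`,
#'   `n_iterations`, and the fit `scale`.
#' @export
fit_region <- function(region, init,
                       center_window = 8, fwhm_bounds = c(3, 40),
                       fwhm_rel = NULL, fix_mixing = FALSE,
                       include_baseline = FALSE,
                       max_iter = 500L, ftol = 1e-10) {
  stopifnot(inherits(region, "raman_spectrum"), is.data.frame(init), nrow(init) >= 1L)
  x <- region$wavenumbers
  y <- region$intensities
  ncomp <- nrow(init)
  npar <- 4L * ncomp + if (include_baseline) 2L else 0L
  if (length(x) < 3L * npar / 2L) {
    stop(sprintf("region has %d points for %d parameters: underdetermined",
                 length(x), npar), call. = FALSE)
  }
  scale <- max(abs(y))
  if (scale == 0) stop("all-zero region: nothing to fit", call. = FALSE)
  yn <- y / scale

  # initial areas from the local maxima: amplitude at the nearest grid point
  # converted through the pseudo-Voigt peak-height relation
  a0 <- init$area / scale
  for (i in seq_len(ncomp)) {
    if (is.na(a0[i])) {
      amp <- max(yn[which.min(abs(x - init$center[i]))], 1e-3)
      h1 <- init$gaussian_fraction[i] * 2 * sqrt(log(2) / pi) +
        (1 - init$gaussian_fraction[i]) * 2 / pi
      a0[i] <- amp * init$fwhm[i] / h1
    }
  }
  x0c <- mean(range(x))
  if (is.null(fwhm_rel)) {
    fw_lo <- rep(fwhm_bounds[1], ncomp)
    fw_hi <- rep(fwhm_bounds[2], ncomp)
  } else {
    fw_lo <- pmax(fwhm_bounds[1], init$fwhm * fwhm_rel[1])
    fw_hi <- pmin(fwhm_bounds[2], init$fwhm * fwhm_rel[2])
  }
  gf_lo <- if (fix_mixing) init$gaussian_fraction else rep(0, ncomp)
  gf_hi <- if (fix_mixing) init$gaussian_fraction else rep(1, ncomp)
  p0 <- c(rbind(a0, init$center, init$fwhm, init$gaussian_fraction))
  lower <- c(rbind(rep(0, ncomp), init$center - center_window, fw_lo, gf_lo))
  upper <- c(rbind(rep(Inf, ncomp), init$center + center_window, fw_hi, gf_hi))
  if (include_baseline) {
    p0 <- c(p0, 0, 0)
    lower <- c(lower, -Inf, -Inf)
    upper <- c(upper, Inf, Inf)
  }
  model <- function(p) {
    yhat <- numeric(length(x))
    for (i in seq_len(ncomp)) {
      j <- 4L * (i - 1L)
      yhat <- yhat + pseudo_voigt(x, p[j + 1L], p[j + 2L], p[j + 3L], p[j + 4L])
    }
    if (include_baseline) yhat <- yhat + p[npar - 1L] + p[npar] * (x - x0c)
    yhat
  }
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = function(p) model(p) - yn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = ftol, ptol = 1e-10))
  p <- fit$par
  comps <- init
  for (i in seq_len(ncomp)) {
    j <- 4L * (i - 1L)
    comps$area[i] <- p[j + 1L] * scale
    comps$center[i] <- p[j + 2L]
    comps$fwhm[i] <- p[j + 3L]
    comps$gaussian_fraction[i] <- p[j + 4L]
  }
  structure(list(
    components = comps,
    baseline = if (include_baseline) {
      list(intercept = p[npar - 1L] * scale, slope = p[npar] * scale, center = x0c)
    },
    residual_rms = sqrt(mean(fit$fvec^2)) * scale,
    converged = fit$info %in% 1:4,
    n_iterations = fit$niter,
    info = fit$info,
    scale = scale,
    region = range(x)), class = "region_fit")
}

#' @export
print.region_fit <- function(x, ...) {
  cat(sprintf("<region_fit> [%.0f, %.0f] cm^-1, %d components, rms %.3g, %s in %d iter\n",
              x$region[1], x$region[2], nrow(x$components), x$residual_rms,
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  print(x$components, digits = 4)
  invisible(x)
}

#' Evaluate a fitted region model on an arbitrary axis
#'
#' Sums the fitted pseudo-Voigt components (the analytic line shapes extend
#' beyond the fitted region; the optional linear baseline does not and is
#' evaluated only if `with_baseline`).
#'
#' @param object a `region_fit`.
#' @param wavenumbers axis to evaluate on.
#' @param with_baseline include the fitted linear baseline term.
#' @param ... unused.
#' @return numeric intensities.
#' @export
predict.region_fit <- function(object, wavenumbers, with_baseline = FALSE, ...) {
  yhat <- numeric(length(wavenumbers))
  for (i in seq_len(nrow(object$components))) {
    cc <- object$components[i, ]
    yhat <- yhat + pseudo_voigt(wavenumbers, cc$area, cc$center, cc$fwhm,
                                cc$gaussian_fraction)
  }
  if (with_baseline && !is.null(object$baseline)) {
    yhat <- yhat + object$baseline$intercept +
      object$baseline$slope * (wavenumbers - object$baseline$center)
  }
  yhat
}

#' Integrate a band over a wavenumber window
#'
#' Trapezoidal integral of the intensity over `[lo, hi]`, optionally after
#' subtracting a straight line through the window endpoints (robust to a
#' residual local background). Negative results are clipped to 0 and
#' flagged.
#'
#' @param s a `raman_spectrum` (or a baseline-corrected region).
#' @param window numeric length-2 `[lo, hi]` in cm^-1, inside the span,
#'   containing at least 3 points.
#' @param local_baseline `"none"` or `"endpoints-line"`.
#' @return list with `area` and `flags` (character, possibly
#'   `"clipped_negative"`).
#' @export
integrate_band <- function(s, window, local_baseline = c("none", "endpoints-line")) {
  stopifnot(inherits(s, "raman_spectrum"), length(window) == 2L)
  local_baseline <- match.arg(local_baseline)
  window <- sort(window)
  span <- range(s$wavenumbers)
  if (window[1] < span[1] - 1e-9 || window[2] > span[2] + 1e-9) {
    stop(sprintf("window [%g, %g] outside spectrum span [%g, %g]",
                 window[1], window[2], span[1], span[2]), call. = FALSE)
  }
  keep <- s$wavenumbers >= window[1] & s$wavenumbers <= window[2]
  if (sum(keep) < 3L) {
    stop(sprintf("window [%g, %g] contains fewer than 3 points",
                 window[1], window[2]), call. = FALSE)
  }
  x <- s$wavenumbers[keep]
  y <- s$intensities[keep]
  if (local_baseline == "endpoints-line") {
    n <- length(x)
    line <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
    y <- y - line
  }
  area <- pracma::trapz(x, y)
  flags <- character(0)
  if (area < 0) {
    area <- 0
    flags <- "clipped_negative"
  }
  list(area = area, flags = flags)
}

#' Default band-measurement configuration
#'
#' Band windows, fit initializations and shape assumptions for
#' [measure_band_areas()]. Defaults (all in cm^-1):
#' \itemize{
#'   \item stretch fit region 1040-1110 with components at 1065 (FWHM 10)
#'     and 1085 (FWHM 18) — these bands overlap and must be deconvolved;
#'   \item bend fit region 1395-1500 with components at 1416 (FWHM 10),
#'     1441 and 1461 (FWHM 18) — the crystallinity marker at 1416 sits on
#'     the flank of the strong bending doublet and cannot be separated by
#'     windowed integration;
#'   \item direct trapezoidal integration windows 1110-1150 (A1130) and
#'     1270-1330 (A1295+1305, the internal conventional twisting group),
#'     corrected for finite-window tail capture using the reference shapes
#'     below, after peeling off the fitted neighbouring-band models;
#'   \item reference shapes used for tail correction and peel-off: 1130
#'     (FWHM 10), twisting split 55/45 between 1295 and 1305 (FWHM 10),
#'     Gaussian fraction 0.5 throughout.
#' }
#'
#' @param stretch_region,bend_region fit region bounds.
#' @param stretch_init,bend_init initial [peak_component()] tables.
#' @param window_1130,window_1295_1305 integration windows.
#' @param shape_1130 reference shape for the 1130 cm^-1 band (list with
#'   `center`, `fwhm`, `gaussian_fraction`).
#' @param twist_components reference decomposition of the twisting group
#'   (data frame with `center`, `fwhm`, `gaussian_fraction`, `weight`).
#' @param local_baseline local baseline for the integration windows;
#'   `"endpoints-line"` (default) makes the integrals immune to residual
#'   linear background at the cost of a larger (but still closed-form)
#'   tail-capture correction.
#' @param tail_correction divide windowed integrals by the analytic
#'   captured-area fraction of the reference shape under the chosen local
#'   baseline protocol.
#' @param n_sweeps number of peel-off sweeps alternating the two fits and
#'   the two integrations, each on the data minus the current model of all
#'   other bands.
#' @param stretch_baseline,bend_baseline include a free linear baseline in
#'   the stretch / bend region fits (absorbs residual background and
#'   distant-band tails).
#' @param fwhm_rel relative FWHM bounds passed to [fit_region()].
#' @param fix_mixing freeze each component's Gaussian fraction at its
#'   configured value instead of fitting it. At the photon-noise levels
#'   typical of these acquisitions the Lorentzian tail weight is barely
#'   identifiable and freeing it roughly triples the variance of the
#'   overlapped-band areas, so the mixing is fixed by default; set `FALSE`
#'   to fit it.
#' @param center_window center box half-width passed to [fit_region()].
#' @return list of class `band_config`.
#' @export
band_config <- function(stretch_region = c(1040, 1110),
                        stretch_init = rbind(
                          peak_component(1065, fwhm = 10),
                          peak_component(1085, fwhm = 18)),
                        bend_region = c(1395, 1500),
                        bend_init = rbind(
                          peak_component(1416, fwhm = 10),
                          peak_component(1441, fwhm = 18),
                          peak_component(1461, fwhm = 18)),
                        window_1130 = c(1110, 1150),
                        window_1295_1305 = c(1270, 1330),
                        shape_1130 = list(center = 1130, fwhm = 10,
                                          gaussian_fraction = 0.5),
                        twist_components = data.frame(
                          center = c(1295, 1305), fwhm = c(10, 10),
                          gaussian_fraction = c(0.5, 0.5),
                          weight = c(0.55, 0.45)),
                        local_baseline = "endpoints-line",
                        tail_correction = TRUE,
                        n_sweeps = 2L,
                        stretch_baseline = TRUE,
                        bend_baseline = TRUE,
                        fwhm_rel = c(0.6, 1.6),
                        fix_mixing = TRUE,
                        center_window = 8) {
  structure(list(stretch_region = stretch_region, stretch_init = stretch_init,
                 bend_region = bend_region, bend_init = bend_init,
                 window_1130 = window_1130, window_1295_1305 = window_1295_1305,
                 shape_1130 = shape_1130, twist_components = twist_components,
                 local_baseline = local_baseline,
                 tail_correction = tail_correction,
                 n_sweeps = as.integer(n_sweeps),
                 stretch_baseline = isTRUE(stretch_baseline),
                 bend_baseline = isTRUE(bend_baseline),
                 fwhm_rel = fwhm_rel,
                 fix_mixing = isTRUE(fix_mixing),
                 center_window = center_window),
            class = "band_config")
}

# Effective captured-area fraction of a reference shape mixture under the
# chosen integration protocol. For endpoints-line integration the line
# through the shape's own endpoint ordinates is subtracted as well, so the
# capture is the window integral minus the trapezoid of the endpoint values
# (both closed-form); the correction is then exact for an isolated band of
# the reference shape.
effective_capture <- function(window, shapes, weights, local_baseline) {
  window <- sort(window)
  f <- 0
  for (i in seq_along(weights)) {
    fi <- pv_window_fraction(window, shapes$center[i], shapes$fwhm[i],
                             shapes$gaussian_fraction[i])
    if (local_baseline == "endpoints-line") {
      ends <- pseudo_voigt(window, 1, shapes$center[i], shapes$fwhm[i],
                           shapes$gaussian_fraction[i])
      fi <- fi - diff(window) * mean(ends)
    }
    f <- f + weights[i] * fi
  }
  f
}

# Tail-corrected trapezoidal integral of one marker band on a residual
# spectrum (data minus the model of every other band).
corrected_integral <- function(x, y, window, shapes, weights, config) {
  r <- integrate_band(raman_spectrum(x, y), window,
                      local_baseline = config$local_baseline)
  area <- r$area
  if (config$tail_correction && area > 0) {
    f <- effective_capture(window, shapes, weights, config$local_baseline)
    if (f < 0.2) {
      stop("effective window capture below 0.2; widen the window or narrow the reference shape",
           call. = FALSE)
    }
    area <- area / f
  }
  list(area = area, flags = r$flags)
}

#' Measure the five marker-band areas of a PE spectrum
#'
#' Implements the full measurement protocol on a baseline-corrected
#' spectrum covering 1040-1480 cm^-1: pseudo-Voigt deconvolution of the
#' overlapped 1040-1110 cm^-1 stretch region (A1065, A1085) and of the
#' 1395-1500 cm^-1 bending region (A1416, with the 1441/1461 bands fitted
#' alongside and discarded), and tail-corrected windowed integration of the
#' isolated 1130 cm^-1 band and 1295+1305 cm^-1 twisting reference group.
#' The steps alternate for `n_sweeps` rounds, each re-measuring one band on
#' the spectrum minus the current model of all the others, so that slowly
#' decaying Lorentzian tails of neighbouring bands do not bias the windowed
#' integrals (a single sweep leaves ~1-2% cross-talk; two are enough for
#' <0.5%).
#'
#' Intensities are normalized internally, which makes every returned area
#' exactly proportional to a global intensity factor and all downstream
#' fractions scale-invariant.
#'
#' @param s a baseline-corrected `raman_spectrum` covering 1040-1480 cm^-1.
#' @param config a [band_config()].
#' @return a [band_areas()] object; fit diagnostics are attached as
#'   attribute `fits` (list with `stretch` and `bend` `region_fit`s).
#' @export
measure_band_areas <- function(s, config = band_config()) {
  stopifnot(inherits(s, "raman_spectrum"), inherits(config, "band_config"))
  require_coverage(s, c(1040, 1480), what = "band-area measurement")
  x <- s$wavenumbers
  scale <- max(abs(s$intensities))
  if (scale == 0) stop("all-zero spectrum: nothing to measure", call. = FALSE)
  y <- s$intensities / scale

  twist <- config$twist_components
  model_1130 <- function(a) pseudo_voigt(x, a, config$shape_1130$center,
                                         config$shape_1130$fwhm,
                                         config$shape_1130$gaussian_fraction)
  model_twist <- function(a) {
    out <- numeric(length(x))
    for (i in seq_len(nrow(twist))) {
      out <- out + pseudo_voigt(x, a * twist$weight[i], twist$center[i],
                                twist$fwhm[i], twist$gaussian_fraction[i])
    }
    out
  }

  m_stretch <- numeric(length(x))
  m_bend <- numeric(length(x))
  a_1130 <- 0
  a_twist <- 0
  flags <- character(0)
  stretch_fit <- NULL
  bend_fit <- NULL

  for (sweep in seq_len(max(1L, config$n_sweeps))) {
    flags <- character(0)

    resid <- y - model_1130(a_1130) - model_twist(a_twist) - m_bend
    stretch_fit <- fit_region(
      extract_region(raman_spectrum(x, resid, meta = s$meta),
                     config$stretch_region[1], config$stretch_region[2]),
      init = config$stretch_init,
      fwhm_rel = config$fwhm_rel, fix_mixing = config$fix_mixing,
      center_window = config$center_window,
      include_baseline = config$stretch_baseline)
    if (!stretch_fit$converged) flags <- c(flags, "stretch_fit_not_converged")
    m_stretch <- predict(stretch_fit, x)

    r <- corrected_integral(x, y - m_stretch - model_twist(a_twist) - m_bend,
                            config$window_1130,
                            shapes = as.data.frame(config$shape_1130),
                            weights = 1, config = config)
    a_1130 <- r$area
    if (length(r$flags)) flags <- c(flags, paste0("A_1130:", r$flags))

    r <- corrected_integral(x, y - m_stretch - model_1130(a_1130) - m_bend,
                            config$window_1295_1305,
                            shapes = twist, weights = twist$weight,
                            config = config)
    a_twist <- r$area
    if (length(r$flags)) flags <- c(flags, paste0("A_1295_1305:", r$flags))

    resid <- y - m_stretch - model_1130(a_1130) - model_twist(a_twist)
    bend_fit <- fit_region(
      extract_region(raman_spectrum(x, resid, meta = s$meta),
                     config$bend_region[1], config$bend_region[2]),
      init = config$bend_init,
      fwhm_rel = config$fwhm_rel, fix_mixing = config$fix_mixing,
      center_window = config$center_window,
      include_baseline = config$bend_baseline)
    if (!bend_fit$converged) flags <- c(flags, "bend_fit_not_converged")
    m_bend <- predict(bend_fit, x)
  }

  pick <- function(fit, nominal) {
    i <- which.min(abs(fit$components$center - nominal))
    max(0, fit$components$area[i])
  }
  areas <- band_areas(
    A_1416 = pick(bend_fit, 1416) * scale,
    A_1085 = pick(stretch_fit, 1085) * scale,
    A_1295_1305 = a_twist * scale,
    A_1130 = a_1130 * scale,
    A_1065 = pick(stretch_fit, 1065) * scale,
    flags = unique(flags))
  attr(areas, "fits") <- list(stretch = stretch_fit, bend = bend_fit)
  areas
}
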