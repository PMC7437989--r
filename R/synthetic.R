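#' Ground-truth phase targets for synthesis
#'
#' The three independent quantities a synthetic PE spectrum is built from:
#' the orthorhombic fraction, the amorphous fraction (the third-phase
#' fraction is `1 - alpha_o - alpha_a` by construction) and the all-trans
#' conformer fraction. All-trans sequences exist at least throughout the
#' crystal, so `all_trans >= alpha_o` is required.
#'
#' @param alpha_o orthorhombic fraction, in `[0, 1]`.
#' @param alpha_a amorphous fraction, `alpha_o + alpha_a <= 1`.
#' @param all_trans all-trans fraction, in `[alpha_o, 1]`.
#' @return list of class `phase_targets`.
#' @export
phase_targets <- function(alpha_o, alpha_a, all_trans) {
  if (!valid_targets(alpha_o, alpha_a, all_trans)) {
    stop(sprintf(paste0("invalid phase targets (alpha_o=%.3f, alpha_a=%.3f, ",
                        "all_trans=%.3f): need alpha_o, alpha_a >= 0, ",
                        "alpha_o + alpha_a <= 1, all_trans in [alpha_o, 1]"),
                 alpha_o, alpha_a, all_trans), call. = FALSE)
  }
  structure(list(alpha_o = alpha_o, alpha_a = alpha_a, all_trans = all_trans),
            class = "phase_targets")
}

valid_targets <- function(alpha_o, alpha_a, all_trans) {
  is.finite(alpha_o) && is.finite(alpha_a) && is.finite(all_trans) &&
    alpha_o >= 0 && alpha_a >= 0 && alpha_o + alpha_a <= 1 &&
    all_trans >= alpha_o && all_trans <= 1
}

#' Invert the phase and conformer equations to band areas
#'
#' Produces the unique set of marker-band areas that the forward equations
#' map back onto the given targets, for a chosen area of the 1295+1305
#' cm^-1 internal reference group. The 1065 cm^-1 band is not constrained
#' by the equations; it is set to `k_1065` times the amorphous-band area so
#' the orientation ratio A1130/A1065 is well defined and responds to the
#' amorphous pool.
#'
#' @param targets a [phase_targets()] object.
#' @param a_ref area of the 1295+1305 reference group (> 0).
#' @param const a [pe_calibration()].
#' @param k_1065 ratio A1065 / A1085.
#' @return a [band_areas()] object.
#' @export
invert_composition <- function(targets, a_ref, const = pe_calibration(),
                               k_1065 = 0.6) {
  stopifnot(inherits(targets, "phase_targets"))
  if (!is.finite(a_ref) || a_ref <= 0) {
    stop("a_ref must be a positive reference area", call. = FALSE)
  }
  A_1085 <- targets$alpha_a * const$c_a * a_ref
  band_areas(
    A_1416 = targets$alpha_o * const$c_o * a_ref,
    A_1085 = A_1085,
    A_1295_1305 = a_ref,
    A_1130 = targets$all_trans * const$c_t * a_ref,
    A_1065 = k_1065 * A_1085)
}

#' Reference band shapes of the synthetic PE spectrum
#'
#' Default pseudo-Voigt shapes of the eight rendered bands. Sharp
#' crystalline / trans-sequence bands (1065, 1130, 1295, 1305, 1416 cm^-1)
#' get FWHM 10 cm^-1; broad amorphous-sensitive bands (1085, 1441, 1461
#' cm^-1) get 18 cm^-1; Gaussian fraction 0.5 throughout — typical polymer
#' Raman widths.
#'
#' @return data frame with columns `center`, `fwhm`, `gaussian_fraction`.
#' @export
band_shape_spec <- function() {
  data.frame(
    center = c(1065, 1085, 1130, 1295, 1305, 1416, 1441, 1461),
    fwhm = c(10, 18, 10, 10, 10, 10, 18, 18),
    gaussian_fraction = 0.5)
}

check_band_shapes <- function(shapes) {
  nominal <- band_shape_spec()$center
  stopifnot(is.data.frame(shapes),
            all(c("center", "fwhm", "gaussian_fraction") %in% names(shapes)),
            nrow(shapes) == length(nominal))
  if (any(abs(shapes$center - nominal) > 10)) {
    stop("band centers must lie within 10 cm^-1 of their nominal positions",
         call. = FALSE)
  }
  if (any(shapes$fwhm <= 0)) stop("band FWHM must be positive", call. = FALSE)
  if (any(shapes$gaussian_fraction < 0 | shapes$gaussian_fraction > 1)) {
    stop("gaussian_fraction must be in [0, 1]", call. = FALSE)
  }
  invisible(shapes)
}

#' Noise model for synthetic spectra
#'
#' Additive Gaussian noise with a photon-like intensity dependence:
#' standard deviation `scale * sqrt(pmax(signal, 0) + floor)`. A
#' `"poisson-like"` variant draws Poisson counts of the shifted signal
#' (then recentres), for strictly count-valued noise.
#'
#' @param type `"gaussian"` or `"poisson-like"`.
#' @param scale noise scale; 0 disables noise.
#' @param floor dark/readout variance floor (counts).
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(type = c("gaussian", "poisson-like"), scale = 1, floor = 100) {
  type <- match.arg(type)
  stopifnot(scale >= 0, floor >= 0)
  structure(list(type = type, scale = scale, floor = floor), class = "noise_spec")
}

apply_noise <- function(y, noise) {
  if (noise$scale == 0) return(y)
  if (noise$type == "gaussian") {
    y + stats::rnorm(length(y), 0, noise$scale * sqrt(pmax(y, 0) + noise$floor))
  } else {
    shifted <- pmax(y, 0) + noise$floor
    y + noise$scale * (stats::rpois(length(y), shifted) - shifted)
  }
}

#' Render a synthetic PE Raman spectrum
#'
#' Draws the eight marker bands as pseudo-Voigt profiles with prescribed
#' integrated areas, adds a polynomial baseline and optional noise. The
#' 1295+1305 cm^-1 twisting group area is split `twist_split` between its
#' two components (only the sum is ever consumed downstream); the 1441 and
#' 1461 cm^-1 bending bands, which strengthen with amorphous content, are
#' rendered with areas `k_bend * alpha_a * A_1295_1305` and never
#' quantified.
#'
#' @param areas a [band_areas()] object (the five quantified areas).
#' @param shapes band shape table, see [band_shape_spec()].
#' @param baseline polynomial baseline coefficients `c0, c1, ...` of
#'   `sum(c_k * ((x - 1250)/100)^k)` in counts; `0` for none.
#' @param noise a [noise_spec()].
#' @param seed integer seed for the noise draw; `NULL` uses (and advances)
#'   the current RNG stream.
#' @param span wavenumber range to render, cm^-1.
#' @param step grid step, cm^-1; must not exceed half the smallest FWHM.
#' @param const calibration used to infer the amorphous fraction for the
#'   bending-band areas.
#' @param twist_split fraction of the twisting-group area assigned to the
#'   1295 cm^-1 component.
#' @param k_bend length-2 multipliers for the 1441 and 1461 cm^-1 areas
#'   (times `alpha_a * A_1295_1305`).
#' @param meta metadata list for the returned spectrum.
#' @return a `raman_spectrum`.
#' @export
render_spectrum <- function(areas, shapes = band_shape_spec(),
                            baseline = 0, noise = noise_spec(scale = 0),
                            seed = NULL, span = c(1000, 1500), step = 1,
                            const = pe_calibration(), twist_split = 0.55,
                            k_bend = c(1.2, 0.9), meta = list()) {
  stopifnot(inherits(areas, "band_areas"), inherits(noise, "noise_spec"))
  check_band_shapes(shapes)
  if (step > min(shapes$fwhm) / 2) {
    stop(sprintf("step %.3g cm^-1 undersamples the narrowest band (FWHM %.3g)",
                 step, min(shapes$fwhm)), call. = FALSE)
  }
  alpha_a <- if (areas$A_1295_1305 > 0) {
    areas$A_1085 / (const$c_a * areas$A_1295_1305)
  } else 0
  amp <- c(areas$A_1065, areas$A_1085, areas$A_1130,
           twist_split * areas$A_1295_1305,
           (1 - twist_split) * areas$A_1295_1305,
           areas$A_1416,
           k_bend[1] * alpha_a * areas$A_1295_1305,
           k_bend[2] * alpha_a * areas$A_1295_1305)
  x <- seq(span[1], span[2], by = step)
  y <- numeric(length(x))
  for (i in seq_len(nrow(shapes))) {
    if (amp[i] > 0) {
      y <- y + pseudo_voigt(x, amp[i], shapes$center[i], shapes$fwhm[i],
                            shapes$gaussian_fraction[i])
    }
  }
  u <- (x - 1250) / 100
  for (k in seq_along(baseline)) y <- y + baseline[k] * u^(k - 1)
  if (noise$scale > 0) {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      }
      set.seed(as.integer(seed))
    }
    y <- apply_noise(y, noise)
  }
  raman_spectrum(x, y, meta = meta)
}

#' Define one material group of a simulated wear study
#'
#' @param unworn,worn [phase_targets()] group means for the two states
#'   (either may be `NULL` to skip that state).
#' @param cup_sd between-cup SD of each target (length 3:
#'   alpha_o, alpha_a, all_trans; recycled).
#' @param point_sd within-cup, between-point SD (same layout).
#' @param mass_loss length-2 `c(mean, sd)` of true mass loss of loaded
#'   cups, mg.
#' @return list of class `group_spec`.
#' @export
group_spec <- function(unworn = NULL, worn = NULL,
                       cup_sd = c(0.02, 0.02, 0.02),
                       point_sd = c(0.015, 0.015, 0.015),
                       mass_loss = c(100, 10)) {
  stopifnot(!is.null(unworn) || !is.null(worn),
            all(cup_sd >= 0), all(point_sd >= 0), mass_loss[2] >= 0)
  for (tg in list(unworn, worn)) {
    if (!is.null(tg)) stopifnot(inherits(tg, "phase_targets"))
  }
  structure(list(unworn = unworn, worn = worn,
                 cup_sd = rep_len(cup_sd, 3L), point_sd = rep_len(point_sd, 3L),
                 mass_loss = mass_loss),
            class = "group_spec")
}

#' Define a simulated wear study
#'
#' The scenario fixes every condition of a simulated cohort: per-group
#' target means and SDs, cohort structure (cups per group and measurement
#' points per cup), spectral rendering (reference area, band shapes,
#' baseline, noise), gravimetry (mass loss and soak-control fluid gain)
#' and the seed.
#'
#' @param groups named list of [group_spec()]s; names are material labels.
#' @param n_cups cups per (material, state) cell.
#' @param n_points measurement points per cup.
#' @param a_ref area of the 1295+1305 reference group in rendered units.
#' @param baseline polynomial baseline coefficients (see
#'   [render_spectrum()]).
#' @param noise a [noise_spec()].
#' @param soak length-2 `c(mean, sd)` of soak-control fluid-absorption mass
#'   gain, mg.
#' @param shapes band shape table.
#' @param k_1065,k_bend,twist_split rendering couplings, see
#'   [invert_composition()] and [render_spectrum()].
#' @param span,step rendered axis.
#' @param seed integer RNG seed for the whole study.
#' @return list of class `study_scenario`.
#' @export
study_scenario <- function(groups, n_cups = 3L, n_points = 12L,
                           a_ref = 20000, baseline = c(50, -10),
                           noise = noise_spec(scale = 1, floor = 100),
                           soak = c(5, 0.5), shapes = band_shape_spec(),
                           k_1065 = 0.6, k_bend = c(1.2, 0.9),
                           twist_split = 0.55,
                           span = c(1000, 1500), step = 1, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)),
            n_cups >= 1L, n_points >= 1L, a_ref > 0,
            inherits(noise, "noise_spec"), soak[2] >= 0)
  for (g in groups) stopifnot(inherits(g, "group_spec"))
  check_band_shapes(shapes)
  structure(list(groups = groups, n_cups = as.integer(n_cups),
                 n_points = as.integer(n_points), a_ref = a_ref,
                 baseline = baseline, noise = noise, soak = soak,
                 shapes = shapes, k_1065 = k_1065, k_bend = k_bend,
                 twist_split = twist_split, span = span, step = step,
                 seed = as.integer(seed)),
            class = "study_scenario")
}

#' Default four-group hip-simulator study scenario
#'
#' Calibrated to the published cohort: three loaded (worn) and three
#' non-loaded control (unworn) cups per material, twelve points per cup.
#' Group means encode the reported orderings — STD with higher
#' crystallinity than XL-75, XL-50 with the highest amorphous and all-trans
#' content and the lowest ortho-trans, XL-75 the reverse, VE
#' indistinguishable from STD when unworn — and the two wear mechanisms:
#' in STD the orthorhombic phase grows at the expense of the amorphous
#' phase, in the cross-linked cups the third phase does; the all-trans
#' content rises in every group. Mass losses are ~100 mg for STD/VE and
#' 30-40 mg for the cross-linked groups.
#'
#' @param noise a [noise_spec()]; default photon-like Gaussian noise.
#' @param cup_sd,point_sd SD triplets passed to every group.
#' @param seed study seed.
#' @return a [study_scenario()].
#' @export
default_study_scenario <- function(noise = noise_spec(scale = 1, floor = 100),
                                   cup_sd = c(0.02, 0.02, 0.02),
                                   point_sd = c(0.015, 0.015, 0.015),
                                   seed = 1L) {
  gs <- function(u, w, mass) {
    group_spec(unworn = do.call(phase_targets, as.list(u)),
               worn = do.call(phase_targets, as.list(w)),
               cup_sd = cup_sd, point_sd = point_sd, mass_loss = mass)
  }
  study_scenario(
    groups = list(
      "STD"   = gs(c(0.59, 0.250, 0.70), c(0.62, 0.225, 0.76), c(100, 12)),
      "XL-50" = gs(c(0.52, 0.300, 0.76), c(0.52, 0.270, 0.80), c(35, 5)),
      "XL-75" = gs(c(0.48, 0.260, 0.56), c(0.48, 0.240, 0.61), c(32, 5)),
      "VE"    = gs(c(0.58, 0.240, 0.69), c(0.585, 0.250, 0.74), c(95, 12))),
    noise = noise, seed = seed)
}

#' Wear-mechanism scenarios
#'
#' Noiseless, zero-SD single-material scenarios expressing the two wear
#' mechanisms as additive shifts on the phase targets:
#' `"ortho_from_amorphous"` (STD-like: the orthorhombic phase grows at the
#' expense of the amorphous phase) and `"third_from_amorphous"` (XL-like:
#' the third phase grows at the expense of the amorphous phase); in both,
#' the all-trans content rises.
#'
#' @param mechanism which mechanism to encode.
#' @param seed study seed.
#' @return a [study_scenario()] with one group, both states, SDs and noise
#'   zero.
#' @export
wear_mechanism_scenario <- function(mechanism = c("ortho_from_amorphous",
                                                  "third_from_amorphous"),
                                    seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "ortho_from_amorphous") {
    material <- "STD"
    unworn <- phase_targets(0.59, 0.25, 0.70)
    worn <- phase_targets(0.62, 0.22, 0.76)
    mass <- c(100, 0)
  } else {
    material <- "XL-50"
    unworn <- phase_targets(0.52, 0.30, 0.76)
    worn <- phase_targets(0.52, 0.27, 0.80)
    mass <- c(35, 0)
  }
  groups <- list(group_spec(unworn = unworn, worn = worn,
                            cup_sd = c(0, 0, 0), point_sd = c(0, 0, 0),
                            mass_loss = mass))
  names(groups) <- material
  study_scenario(groups = groups, noise = noise_spec(scale = 0),
                 soak = c(5, 0), seed = seed)
}

draw_targets <- function(mean_targets, sd, max_tries = 100L) {
  mu <- c(mean_targets$alpha_o, mean_targets$alpha_a, mean_targets$all_trans)
  if (all(sd == 0)) return(mean_targets)
  for (i in seq_len(max_tries)) {
    v <- stats::rnorm(3L, mu, sd)
    if (valid_targets(v[1], v[2], v[3])) {
      return(phase_targets(v[1], v[2], v[3]))
    }
  }
  stop("could not draw valid phase targets in ", max_tries,
       " tries; scenario means/SDs too close to the simplex boundary",
       call. = FALSE)
}

#' Simulate a whole wear study
#'
#' Draws cup-level targets from each group's mean/SD, point-level targets
#' within each cup, renders every spectrum, and produces gravimetry for the
#' loaded cups and their non-loaded soak controls (the control cups are
#' also the unworn Raman reference cups). Fully reproducible from the
#' scenario seed.
#'
#' Sign conventions: loaded-cup gravimetry rows carry the *measured mass
#' loss* in mg (true loss minus the cup's own fluid gain, positive =
#' lighter); soak-control rows carry the *measured mass gain* in mg.
#'
#' @param scenario a [study_scenario()].
#' @return object of class `simulated_study`: list with `spectra` (named
#'   list of `raman_spectrum`), `records` (manifest data frame with a
#'   `spectrum` key column), `gravimetry` (data frame), `truth` (data frame
#'   of cup- and point-level generating targets) and the `scenario`.
#' @export
simulate_study <- function(scenario) {
  stopifnot(inherits(scenario, "study_scenario"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(scenario$seed)

  spectra <- list()
  records <- list()
  grav <- list()
  truth <- list()
  for (material in names(scenario$groups)) {
    g <- scenario$groups[[material]]
    mat_tag <- gsub("[^A-Za-z0-9]", "", material)
    for (state in pe_states()) {
      tg_mean <- g[[state]]
      if (is.null(tg_mean)) next
      for (cup in seq_len(scenario$n_cups)) {
        cup_id <- sprintf("%s_%s%d", mat_tag, if (state == "worn") "L" else "C", cup)
        cup_targets <- draw_targets(tg_mean, g$cup_sd)
        truth[[length(truth) + 1L]] <- data.frame(
          level = "cup", material = material, state = state, cup_id = cup_id,
          point_index = NA_integer_,
          alpha_o = cup_targets$alpha_o, alpha_a = cup_targets$alpha_a,
          all_trans = cup_targets$all_trans)
        for (pt in seq_len(scenario$n_points)) {
          pt_targets <- draw_targets(cup_targets, g$point_sd)
          areas <- invert_composition(pt_targets, scenario$a_ref,
                                      k_1065 = scenario$k_1065)
          key <- sprintf("%s_%s_p%02d", cup_id, state, pt)
          meta <- list(cup_id = cup_id, material = material, state = state,
                       point_index = pt, polarization = "unpolarized",
                       accumulations = 4L)
          spectra[[key]] <- render_spectrum(
            areas, shapes = scenario$shapes, baseline = scenario$baseline,
            noise = scenario$noise, seed = NULL, span = scenario$span,
            step = scenario$step, twist_split = scenario$twist_split,
            k_bend = scenario$k_bend, meta = meta)
          records[[length(records) + 1L]] <- data.frame(
            role = "spectrum", spectrum = key, path = paste0(key, ".txt"),
            cup_id = cup_id, material = material, state = state,
            point_index = pt, polarization = "unpolarized")
          truth[[length(truth) + 1L]] <- data.frame(
            level = "point", material = material, state = state, cup_id = cup_id,
            point_index = pt,
            alpha_o = pt_targets$alpha_o, alpha_a = pt_targets$alpha_a,
            all_trans = pt_targets$all_trans)
        }
        gain <- stats::rnorm(1L, scenario$soak[1], scenario$soak[2])
        if (state == "worn") {
          loss_true <- stats::rnorm(1L, g$mass_loss[1], g$mass_loss[2])
          grav[[length(grav) + 1L]] <- data.frame(
            role = "loaded", cup_id = cup_id, material = material,
            measured_mass_change_mg = round(loss_true - gain, 2))
        } else {
          grav[[length(grav) + 1L]] <- data.frame(
            role = "soak_control", cup_id = cup_id, material = material,
            measured_mass_change_mg = round(gain, 2))
        }
      }
    }
    if (is.null(g$unworn) && !is.null(g$worn)) {
      # the non-loaded control cups exist physically even when their
      # spectra are not part of the scenario; their soak gravimetry is
      # still needed to correct the loaded cups
      for (cup in seq_len(scenario$n_cups)) {
        grav[[length(grav) + 1L]] <- data.frame(
          role = "soak_control",
          cup_id = sprintf("%s_C%d", mat_tag, cup), material = material,
          measured_mass_change_mg =
            round(stats::rnorm(1L, scenario$soak[1], scenario$soak[2]), 2))
      }
    }
  }
  structure(list(spectra = spectra,
                 records = do.call(rbind, records),
                 gravimetry = do.call(rbind, grav),
                 truth = do.call(rbind, truth),
                 scenario = scenario),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study> %d spectra, %d cups, %d gravimetry records\n",
              length(x$spectra), sum(x$truth$level == "cup"), nrow(x$gravimetry)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits one ascii-xy file per spectrum, a `manifest.csv` combining
#' spectrum and gravimetry rows, and a `truth.csv` ground-truth table for
#' recovery checks.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return path of the written manifest, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(study$spectra)) {
    write_spectrum(study$spectra[[key]], file.path(dir, paste0(key, ".txt")))
  }
  rec <- study$records
  rec$spectrum <- NULL
  rec$measured_mass_change_mg <- NA_real_
  grav <- study$gravimetry
  grav$path <- ""
  grav$state <- ""
  grav$point_index <- NA_integer_
  grav$polarization <- ""
  manifest <- rbind(rec[, c("role", "path", "cup_id", "material", "state",
                            "point_index", "polarization",
                            "measured_mass_change_mg")],
                    grav[, c("role", "path", "cup_id", "material", "state",
                             "point_index", "polarization",
                             "measured_mass_change_mg")])
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  utils::write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(path)
}

#' Read or write a study scenario as JSON
#'
#' Scenarios are fully serializable so a study's generating conditions can
#' be shipped as a plain-text fixture and reloaded bit-identically.
#'
#' @param scenario a [study_scenario()].
#' @param path JSON file path.
#' @return `write_scenario`: `path` invisibly; `read_scenario`: a
#'   [study_scenario()].
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "study_scenario"))
  x <- unclass(scenario)
  x$noise <- unclass(x$noise)
  x$groups <- lapply(x$groups, function(g) {
    g <- unclass(g)
    for (st in pe_states()) {
      if (is.null(g[[st]])) g[[st]] <- NULL else g[[st]] <- unclass(g[[st]])
    }
    g
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- lapply(x$groups, function(g) {
    tg <- function(v) {
      if (is.null(v) || !length(v)) NULL else do.call(phase_targets, as.list(v))
    }
    group_spec(unworn = tg(g$unworn), worn = tg(g$worn),
               cup_sd = g$cup_sd, point_sd = g$point_sd,
               mass_loss = g$mass_loss)
  })
  study_scenario(
    groups = groups, n_cups = x$n_cups, n_points = x$n_points, a_ref = x$a_ref,
    baseline = x$baseline,
    noise = noise_spec(x$noise$type, x$noise$scale, x$noise$floor),
    soak = x$soak, shapes = as.data.frame(x$shapes), k_1065 = x$k_1065,
    k_bend = x$k_bend, twist_split = x$twist_split, span = x$span,
    step = x$step, seed = x$seed)
}

#' Load a packaged scenario fixture
#'
#' Packaged synthetic scenarios under `inst/extdata/`, e.g.
#' `"fig7_std_unworn"` and `"fig7_std_worn"`: single-cup, zero-SD,
#' noiseless STD scenarios whose generating orthorhombic fractions (0.59
#' unworn, 0.62 worn) match the selected high-mass-loss standard-PE cup;
#' the remaining targets are synthetic choices consistent with the
#' reported directions of change.
#'
#' @param name fixture name (file `<name>.json`).
#' @return a [study_scenario()].
#' @export
scenario_fixture <- function(name) {
  path <- system.file("extdata", paste0(name, ".json"), package = "ramanpe")
  if (path == "") stop("no packaged scenario fixture named '", name, "'",
                       call. = FALSE)
  read_scenario(path)
}
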