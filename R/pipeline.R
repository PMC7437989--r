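#' Pipeline configuration
#'
#' Bundles every tunable of an end-to-end run: baseline model, band
#' measurement config, calibration constants, statistics options. A run is
#' fully determined by (manifest, config, seed), and the report records a
#' hash of the configuration for provenance.
#'
#' @param baseline a [baseline_spec()].
#' @param bands a [band_config()].
#' @param const a [pe_calibration()].
#' @param alpha significance level of the cohort tests.
#' @param kw_method `"auto"`, `"exact"` or `"asymptotic"` (see
#'   [kruskal_wallis()]).
#' @param parameters parameter columns carried through cup summaries and
#'   group statistics.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(baseline = baseline_spec(), bands = band_config(),
                            const = pe_calibration(), alpha = 0.05,
                            kw_method = "auto",
                            parameters = c("alpha_o", "alpha_a", "alpha_b",
                                           "all_trans", "ortho_trans",
                                           "ratio_1130_1065")) {
  stopifnot(inherits(baseline, "baseline_spec"), inherits(bands, "band_config"),
            inherits(const, "pe_calibration"), alpha > 0, alpha < 1)
  structure(list(baseline = baseline, bands = bands, const = const,
                 alpha = alpha, kw_method = kw_method, parameters = parameters),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Quantify one spectrum
#'
#' Baseline correction, band-area measurement and the derived parameters
#' for a single spectrum: the full single-spectrum protocol.
#'
#' @param s a `raman_spectrum` covering 1040-1480 cm^-1.
#' @param config a [pipeline_config()].
#' @return one-row data frame with the five band areas, `alpha_o`,
#'   `alpha_a`, `alpha_b`, `all_trans`, `ortho_trans`, `ratio_1130_1065`,
#'   a `flags` string and a `flagged` exclusion indicator.
#' @export
analyze_spectrum <- function(s, config = pipeline_config()) {
  stopifnot(inherits(s, "raman_spectrum"))
  corrected <- correct_baseline(s, config$baseline)$spectrum
  areas <- measure_band_areas(corrected, config$bands)
  phase <- compute_phase_composition(areas, config$const)
  conf <- compute_conformer_content(areas, config$const)
  orient <- orientation_ratio(areas)
  flags <- unique(c(areas$flags, phase$flags, conf$flags, orient$flags))
  # exclusion only for measurement-quality problems, not for legitimate
  # diagnostic values such as a negative third-phase content
  bad <- grepl("not_converged|clipped_negative", flags)
  data.frame(
    cup_id = s$meta$cup_id %||% NA_character_,
    material = s$meta$material %||% NA_character_,
    state = s$meta$state %||% NA_character_,
    point_index = s$meta$point_index %||% NA_integer_,
    A_1416 = areas$A_1416, A_1085 = areas$A_1085,
    A_1295_1305 = areas$A_1295_1305, A_1130 = areas$A_1130,
    A_1065 = areas$A_1065,
    alpha_o = phase$alpha_o, alpha_a = phase$alpha_a, alpha_b = phase$alpha_b,
    all_trans = conf$all_trans, ortho_trans = conf$ortho_trans,
    ratio_1130_1065 = orient$ratio_1130_1065,
    flags = paste(flags, collapse = ";"),
    flagged = any(bad),
    stringsAsFactors = FALSE)
}

get_study_spectrum <- function(input, record) {
  if (inherits(input, "simulated_study")) {
    s <- input$spectra[[record$spectrum]]
    s$meta <- utils::modifyList(s$meta, list(
      cup_id = record$cup_id, material = record$material,
      state = record$state, point_index = record$point_index))
    s
  } else {
    read_spectrum(record$path, meta = list(
      cup_id = record$cup_id, material = record$material,
      state = record$state, point_index = record$point_index,
      polarization = record$polarization))
  }
}

#' Run the full cohort analysis
#'
#' Manifest to report: every spectrum is baseline-corrected, its five band
#' areas measured and the phase / conformer / orientation parameters
#' computed; points are aggregated to cup means; materials are compared per
#' state with the Kruskal-Wallis test and Dunn-Bonferroni letters; wear
#' (worn vs unworn) is tested per material; group percent changes upon
#' wear and the all-trans vs ortho-trans trend are derived; and gravimetry
#' is soak-corrected and compared across materials. Spectra that fail are
#' recorded in the error ledger and the run continues.
#'
#' @param input a `cohort_manifest` (spectra read from disk) or a
#'   `simulated_study` (in-memory).
#' @param config a [pipeline_config()].
#' @return object of class `study_report`: list of data frames
#'   `per_spectrum`, `per_cup`, `group_summary`, `group_tests`,
#'   `group_letters`, `wear_tests`, `percent_change`, `trend`,
#'   `mass_loss`, `mass_loss_tests`, plus `errors`, `config_hash`,
#'   `n_errors`, and `log` (character).
#' @export
run_analysis <- function(input, config = pipeline_config()) {
  stopifnot(inherits(input, "cohort_manifest") || inherits(input, "simulated_study"))
  t0 <- Sys.time()
  hash <- config_hash(config)
  log_lines <- sprintf("[%s] run_analysis start, config %s",
                       format(t0, "%Y-%m-%d %H:%M:%S"), hash)
  records <- input$records
  errors <- list()
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    rows[[i]] <- tryCatch({
      analyze_spectrum(get_study_spectrum(input, rec), config)
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<- data.frame(
        cup_id = rec$cup_id, state = rec$state, point_index = rec$point_index,
        message = conditionMessage(e), stringsAsFactors = FALSE)
      NULL
    })
  }
  per_spectrum <- do.call(rbind, rows)
  if (is.null(per_spectrum) || !nrow(per_spectrum)) {
    stop("no spectrum could be analyzed", call. = FALSE)
  }
  params <- config$parameters

  # cup-level aggregation
  cup_rows <- list()
  for (key in unique(paste(per_spectrum$cup_id, per_spectrum$state, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    sub <- per_spectrum[per_spectrum$cup_id == parts[1] &
                          per_spectrum$state == parts[2], , drop = FALSE]
    cs <- tryCatch(summarize_cup(sub, parameters = params), error = function(e) {
      errors[[length(errors) + 1L]] <<- data.frame(
        cup_id = parts[1], state = parts[2], point_index = NA_integer_,
        message = conditionMessage(e), stringsAsFactors = FALSE)
      NULL
    })
    if (is.null(cs)) next
    row <- data.frame(cup_id = parts[1], material = sub$material[1],
                      state = parts[2], n_valid = cs$n_valid,
                      n_flagged = cs$n_flagged, stringsAsFactors = FALSE)
    for (p in params) {
      row[[p]] <- unname(cs$mean[p])
      row[[paste0(p, "_sd")]] <- unname(cs$sd[p])
    }
    cup_rows[[length(cup_rows) + 1L]] <- row
  }
  per_cup <- do.call(rbind, cup_rows)

  # group summaries (mean +- SD of cup means, the published reporting unit)
  group_summary <- do.call(rbind, lapply(
    split(per_cup, list(per_cup$material, per_cup$state), drop = TRUE),
    function(d) {
      out <- data.frame(material = d$material[1], state = d$state[1],
                        n_cups = nrow(d), stringsAsFactors = FALSE)
      for (p in params) {
        out[[paste0(p, "_mean")]] <- mean(d[[p]], na.rm = TRUE)
        out[[paste0(p, "_sd")]] <- stats::sd(d[[p]], na.rm = TRUE)
      }
      out
    }))
  rownames(group_summary) <- NULL

  # across-material tests per state, with letters
  group_tests <- list(); group_letters <- list()
  for (st in unique(per_cup$state)) {
    d <- per_cup[per_cup$state == st, , drop = FALSE]
    mats <- unique(d$material)
    if (length(mats) < 2L) next
    for (p in params) {
      groups <- lapply(mats, function(m) {
        v <- d[[p]][d$material == m]
        v[is.finite(v)]
      })
      names(groups) <- mats
      if (any(lengths(groups) < 1L)) next
      kw <- kruskal_wallis(groups, method = config$kw_method)
      dn <- dunn_bonferroni(groups, alpha = config$alpha, omnibus = kw,
                            method = config$kw_method)
      group_tests[[length(group_tests) + 1L]] <- data.frame(
        state = st, parameter = p, H = kw$H, df = kw$df, p = kw$p,
        method = kw$method, significant = kw$p < config$alpha,
        stringsAsFactors = FALSE)
      group_letters[[length(group_letters) + 1L]] <- data.frame(
        state = st, parameter = p, material = names(dn$letters),
        letters = unname(dn$letters),
        post_hoc_licensed = !length(dn$flags), stringsAsFactors = FALSE)
    }
  }
  group_tests <- do.call(rbind, group_tests)
  group_letters <- do.call(rbind, group_letters)

  # wear effect per material (worn vs unworn cup means)
  wear_tests <- list()
  for (m in unique(per_cup$material)) {
    d <- per_cup[per_cup$material == m, , drop = FALSE]
    if (length(unique(d$state)) < 2L) next
    for (p in params) {
      groups <- list(unworn = d[[p]][d$state == "unworn"],
                     worn = d[[p]][d$state == "worn"])
      groups <- lapply(groups, function(v) v[is.finite(v)])
      if (any(lengths(groups) < 1L)) next
      kw <- kruskal_wallis(groups, method = config$kw_method)
      wear_tests[[length(wear_tests) + 1L]] <- data.frame(
        material = m, parameter = p, H = kw$H, p = kw$p,
        significant = kw$p < config$alpha, stringsAsFactors = FALSE)
    }
  }
  wear_tests <- do.call(rbind, wear_tests)

  # percent change of group means upon wear, and the all-trans vs
  # ortho-trans trend across materials
  pc_rows <- list()
  for (m in unique(group_summary$material)) {
    gu <- group_summary[group_summary$material == m &
                          group_summary$state == "unworn", , drop = FALSE]
    gw <- group_summary[group_summary$material == m &
                          group_summary$state == "worn", , drop = FALSE]
    if (!nrow(gu) || !nrow(gw)) next
    row <- data.frame(material = m, stringsAsFactors = FALSE)
    for (p in params) {
      row[[p]] <- percent_change(gu[[paste0(p, "_mean")]], gw[[paste0(p, "_mean")]])
    }
    pc_rows[[length(pc_rows) + 1L]] <- row
  }
  pc <- do.call(rbind, pc_rows)
  trend <- NULL
  if (!is.null(pc) && nrow(pc) >= 2L &&
      all(c("all_trans", "ortho_trans") %in% names(pc))) {
    trend <- tryCatch(trend_fit(pc$ortho_trans, pc$all_trans),
                      error = function(e) NULL)
  }

  # gravimetry
  mass_loss <- NULL; mass_tests <- NULL
  grav <- input$gravimetry
  if (!is.null(grav) && nrow(grav) && any(grav$role == "loaded")) {
    mass_loss <- tryCatch(correct_mass_loss(grav), error = function(e) {
      errors[[length(errors) + 1L]] <<- data.frame(
        cup_id = NA_character_, state = NA_character_,
        point_index = NA_integer_, message = conditionMessage(e),
        stringsAsFactors = FALSE)
      NULL
    })
    if (!is.null(mass_loss) && length(unique(mass_loss$material)) >= 2L) {
      groups <- split(mass_loss$corrected_mass_loss_mg, mass_loss$material)
      kw <- kruskal_wallis(groups, method = config$kw_method)
      dn <- dunn_bonferroni(groups, alpha = config$alpha, omnibus = kw,
                            method = config$kw_method)
      mass_tests <- list(
        omnibus = data.frame(H = kw$H, df = kw$df, p = kw$p, method = kw$method),
        letters = data.frame(material = names(dn$letters),
                             letters = unname(dn$letters),
                             stringsAsFactors = FALSE))
    }
  }

  errors <- if (length(errors)) do.call(rbind, errors) else NULL
  t1 <- Sys.time()
  log_lines <- c(log_lines,
                 sprintf("[%s] analyzed %d/%d spectra, %d cups, %d error(s)",
                         format(t1, "%Y-%m-%d %H:%M:%S"),
                         nrow(per_spectrum), nrow(records),
                         if (is.null(per_cup)) 0L else nrow(per_cup),
                         if (is.null(errors)) 0L else nrow(errors)))
  structure(list(per_spectrum = per_spectrum, per_cup = per_cup,
                 group_summary = group_summary, group_tests = group_tests,
                 group_letters = group_letters, wear_tests = wear_tests,
                 percent_change = pc, trend = trend, mass_loss = mass_loss,
                 mass_loss_tests = mass_tests, errors = errors,
                 n_errors = if (is.null(errors)) 0L else nrow(errors),
                 config_hash = hash, log = log_lines),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d spectra, %d cup summaries, %d error(s), config %s\n",
              nrow(x$per_spectrum), if (is.null(x$per_cup)) 0L else nrow(x$per_cup),
              x$n_errors, substr(x$config_hash, 1, 8)))
  if (!is.null(x$group_summary)) {
    cat("group means (alpha_o):\n")
    print(x$group_summary[, c("material", "state", "alpha_o_mean", "alpha_o_sd")],
          digits = 3)
  }
  invisible(x)
}

#' Write the report tables of a run
#'
#' One delimited file per table plus the run log.
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("per_spectrum", "per_cup", "group_summary", "group_tests",
            "group_letters", "wear_tests", "percent_change", "mass_loss",
            "errors")
  for (nm in tabs) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(report$trend)) {
    utils::write.csv(data.frame(slope = report$trend$slope,
                                intercept = report$trend$intercept,
                                r = report$trend$r, n = report$trend$n),
                     file.path(dir, "trend.csv"), row.names = FALSE)
  }
  if (!is.null(report$mass_loss_tests)) {
    utils::write.csv(report$mass_loss_tests$letters,
                     file.path(dir, "mass_loss_letters.csv"), row.names = FALSE)
  }
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Simulate a study and write it to disk
#'
#' Convenience wrapper: [simulate_study()] then [write_study()], returning
#' the in-memory study (whose `truth` table supports recovery tests).
#'
#' @param scenario a [study_scenario()].
#' @param out output directory; `NULL` keeps the study in memory only.
#' @return the `simulated_study`, invisibly.
#' @export
run_simulate <- function(scenario, out = NULL) {
  study <- simulate_study(scenario)
  if (!is.null(out)) write_study(study, out)
  invisible(study)
}
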