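# Delimited-text readers/writers for the instrument-style CSV dialects, JSON
# result records, and the pipeline driver chaining the stages.

read_checked_csv <- function(path, numeric_cols, character_cols = character()) {
  if (!file.exists(path)) {
    ks_stop(paste0("input file not found: ", path), "missing_file")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c(numeric_cols, character_cols)
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    ks_stop(paste0("missing column(s) in ", basename(path), ": ",
                   paste(absent, collapse = ", ")), "schema_error")
  }
  if (nrow(df) == 0L) {
    ks_warn(paste0(basename(path), " has a header but no data rows"),
            "empty_file")
    return(df)
  }
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]) &
                   !(df[[col]] %in% c("NA", "")))
    if (length(bad)) {
      ks_stop(sprintf("unparseable value '%s' at row %d, column '%s' of %s",
                      df[[col]][bad[1L]], bad[1L], col, basename(path)),
              "parse_error")
    }
    df[[col]] <- parsed
  }
  df
}

#' Read and write equilibrium denaturation series CSV
#'
#' Long-format CSV with columns `denaturant_M`, `value`, `probe`,
#' `replicate_id`, `temperature_K`; one series per (probe, replicate_id)
#' combination. Decimal point is `.`; a header row is mandatory.
#'
#' @param path File path.
#'
#' @return `read_denaturation_csv()`: a list of [denaturation_series()].
#' @export
read_denaturation_csv <- function(path) {
  df <- read_checked_csv(path, c("denaturant_M", "value", "temperature_K"),
                         c("probe", "replicate_id"))
  if (nrow(df) == 0L) return(list())
  keys <- interaction(df$probe, df$replicate_id, drop = TRUE)
  lapply(split(df, keys), function(g) {
    denaturation_series(g$denaturant_M, g$value, probe = g$probe[1L],
                        temperature = g$temperature_K[1L],
                        replicate_id = g$replicate_id[1L])
  })
}

#' @rdname read_denaturation_csv
#' @param series A [denaturation_series()] or list of them.
#' @return `write_denaturation_csv()`: the path, invisibly.
#' @export
write_denaturation_csv <- function(series, path) {
  if (inherits(series, "kinstab_denaturation_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(denaturant_M = s$denaturant, value = s$observable,
               probe = s$probe, replicate_id = s$replicate_id,
               temperature_K = s$temperature)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write thermal melt CSV
#'
#' Columns `temperature_C`, `theta222`, `sample_id`; one melt per sample_id.
#'
#' @param path File path.
#'
#' @return `read_thermal_csv()`: a list of [thermal_melt()].
#' @export
read_thermal_csv <- function(path) {
  df <- read_checked_csv(path, c("temperature_C", "theta222"), "sample_id")
  if (nrow(df) == 0L) return(list())
  lapply(split(df, df$sample_id), function(g) {
    thermal_melt(g$temperature_C, g$theta222, sample_id = g$sample_id[1L])
  })
}

#' @rdname read_thermal_csv
#' @param melts A [thermal_melt()] or list of them.
#' @return `write_thermal_csv()`: the path, invisibly.
#' @export
write_thermal_csv <- function(melts, path) {
  if (inherits(melts, "kinstab_thermal_melt")) melts <- list(melts)
  df <- do.call(rbind, lapply(melts, function(m) {
    data.frame(temperature_C = m$temperatures, theta222 = m$ellipticity222,
               sample_id = m$sample_id)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write progress-curve CSV
#'
#' Columns `time_s`, `fluorescence_AU`, `substrate_uM`, `enzyme_nM`,
#' `temperature_C`, `calibration_AU_per_uM`; one curve per
#' (substrate_uM, temperature_C) combination.
#'
#' @param path File path.
#'
#' @return `read_progress_csv()`: a list of [progress_curve()].
#' @export
read_progress_csv <- function(path) {
  df <- read_checked_csv(path, c("time_s", "fluorescence_AU", "substrate_uM",
                                 "enzyme_nM", "temperature_C",
                                 "calibration_AU_per_uM"))
  if (nrow(df) == 0L) return(list())
  keys <- interaction(df$substrate_uM, df$temperature_C, drop = TRUE)
  lapply(split(df, keys), function(g) {
    progress_curve(g$time_s, g$fluorescence_AU,
                   substrate_conc = g$substrate_uM[1L],
                   enzyme_conc = g$enzyme_nM[1L],
                   temperature = g$temperature_C[1L],
                   calibration = g$calibration_AU_per_uM[1L])
  })
}

#' @rdname read_progress_csv
#' @param curves A [progress_curve()] or list of them.
#' @return `write_progress_csv()`: the path, invisibly.
#' @export
write_progress_csv <- function(curves, path) {
  if (inherits(curves, "kinstab_progress_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(time_s = cv$time, fluorescence_AU = cv$fluorescence,
               substrate_uM = cv$substrate_conc, enzyme_nM = cv$enzyme_conc,
               temperature_C = cv$temperature,
               calibration_AU_per_uM = cv$calibration)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write rate-point CSV
#'
#' Columns `substrate_uM`, `rate_uM_per_s`, `temperature_C`.
#'
#' @param path File path.
#'
#' @return `read_rates_csv()`: a data frame with columns `substrate_conc`,
#'   `rate`, `temperature` accepted by the kinetics fitters.
#' @export
read_rates_csv <- function(path) {
  df <- read_checked_csv(path, c("substrate_uM", "rate_uM_per_s",
                                 "temperature_C"))
  data.frame(substrate_conc = df$substrate_uM, rate = df$rate_uM_per_s,
             temperature = df$temperature_C)
}

#' @rdname read_rates_csv
#' @param points Rate observations (data frame or list of [rate_point()]).
#' @return `write_rates_csv()`: the path, invisibly.
#' @export
write_rates_csv <- function(points, path) {
  df <- rate_points_df(points)
  out <- data.frame(substrate_uM = df$substrate_conc,
                    rate_uM_per_s = df$rate, temperature_C = df$temperature)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write spectral series CSV
#'
#' Long-format CSV with columns `wavelength_nm`, `value`, `condition`,
#' `probe`, `sample_id`; all conditions must share one wavelength grid.
#'
#' @param path File path.
#'
#' @return `read_spectral_series_csv()`: a [spectral_series()].
#' @export
read_spectral_series_csv <- function(path) {
  df <- read_checked_csv(path, c("wavelength_nm", "value", "condition"),
                         c("probe", "sample_id"))
  conds <- sort(unique(df$condition))
  spectra <- lapply(conds, function(cv) {
    g <- df[df$condition == cv, ]
    g <- g[order(g$wavelength_nm), ]
    spectrum(g$wavelength_nm, g$value, probe = g$probe[1L],
             sample_id = g$sample_id[1L])
  })
  spectral_series(conds, spectra)
}

#' @rdname read_spectral_series_csv
#' @param series A [spectral_series()].
#' @return `write_spectral_series_csv()`: the path, invisibly.
#' @export
write_spectral_series_csv <- function(series, path) {
  df <- do.call(rbind, lapply(seq_along(series$spectra), function(i) {
    s <- series$spectra[[i]]
    data.frame(wavelength_nm = s$wavelengths, value = s$values,
               condition = series$condition_values[i], probe = s$probe,
               sample_id = s$sample_id)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fit_to_list <- function(x) {
  out <- unclass(x)
  out$covariance <- NULL
  lapply(out, function(v) if (is.matrix(v)) NULL else v)
}

#' Serialize fit results to JSON
#'
#' Writes any of the package's fit/result objects (or a named list of them)
#' as a JSON record including the model name and all scalar parameters,
#' standard errors and diagnostics. Covariance matrices are omitted from the
#' serialized form.
#'
#' @param x A fit object or named list of fit objects.
#' @param path Output path.
#'
#' @return The path, invisibly.
#' @export
write_fit_json <- function(x, path) {
  as_record <- function(obj) {
    if (is.list(obj) && !is.null(attr(obj, "class")) &&
        grepl("^kinstab_", class(obj)[1L])) {
      c(list(model = sub("^kinstab_", "", class(obj)[1L])), fit_to_list(obj))
    } else if (is.list(obj) && is.null(attr(obj, "class"))) {
      lapply(obj, as_record)
    } else {
      obj
    }
  }
  jsonlite::write_json(as_record(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

default_config <- function() {
  list(
    out_dir = ".",
    seed = 1L,
    unfolding = list(path = NULL, model = "auto", share_m = FALSE,
                     temperature_K = 283.15),
    thermal = list(path = NULL, smoothing_window = 5, prominence = 0.1),
    kinetics = list(rates_path = NULL, enzyme_nM = NULL,
                    temperature_rates_path = NULL),
    spectra = list(path = NULL, rank_policy = "singular_value",
                   threshold_factor = 5),
    report = list(enabled = FALSE, protein = "both")
  )
}

#' Build a validated pipeline configuration
#'
#' Merges user options into the documented defaults; unknown keys at either
#' level are rejected so typos fail loudly. Use `pipeline_config()` with no
#' arguments to inspect every default.
#'
#' @param ... Named top-level blocks (`out_dir`, `seed`, `unfolding`,
#'   `thermal`, `kinetics`, `spectra`, `report`), each a named list of the
#'   options shown by `pipeline_config()`.
#'
#' @return A `kinstab_config` list.
#' @export
pipeline_config <- function(...) {
  base <- default_config()
  user <- list(...)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    ks_stop(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
            "config_error")
  }
  for (key in names(user)) {
    if (is.list(base[[key]]) && is.list(user[[key]])) {
      bad <- setdiff(names(user[[key]]), names(base[[key]]))
      if (length(bad)) {
        ks_stop(paste0("unknown option(s) in '", key, "': ",
                       paste(bad, collapse = ", ")), "config_error")
      }
      base[[key]][names(user[[key]])] <- user[[key]]
    } else {
      base[[key]] <- user[[key]]
    }
  }
  structure(base, class = "kinstab_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    ks_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            "pipeline_error")
  })
}

#' Run the full analysis pipeline
#'
#' Executes every configured stage -- spectral SVD component counting,
#' equilibrium unfolding fits (with automatic two-/three-state model
#' selection informed by the SVD rank), thermal melt Tm extraction,
#' Michaelis-Menten and Arrhenius kinetics -- and, when enabled, the
#' variant-comparison report built from the packaged reference tables.
#' Inputs are validated before any stage runs: a missing file fails
#' immediately with no partial outputs. Results are written to
#' `<out_dir>/results.json`, the report (if enabled) to `report.csv` and
#' `report.txt`, and a run log capturing the package version, seed and every
#' configured threshold to `run_log.txt`. Reruns with identical config and
#' inputs are byte-identical.
#'
#' @param config A [pipeline_config()].
#'
#' @return (Invisibly) a named list of all stage results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "kinstab_config")) {
    ks_stop("`config` must come from pipeline_config()", "config_error")
  }
  paths <- c(config$unfolding$path, config$thermal$path,
             config$kinetics$rates_path, config$kinetics$temperature_rates_path,
             config$spectra$path)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing)) {
    ks_stop(paste0("configured input file(s) not found: ",
                   paste(missing, collapse = ", ")), "missing_file")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  svd_hint <- NULL
  if (!is.null(config$spectra$path)) {
    results$spectra <- stage("spectra", {
      ser <- read_spectral_series_csv(config$spectra$path)
      res <- svd_analyze(ser, policy = config$spectra$rank_policy,
                         threshold_factor = config$spectra$threshold_factor)
      list(estimated_rank = res$estimated_rank,
           singular_values = res$singular_values,
           policy = res$policy)
    })
    svd_hint <- results$spectra$estimated_rank
  }

  if (!is.null(config$unfolding$path)) {
    results$unfolding <- stage("unfolding", {
      ser_list <- read_denaturation_csv(config$unfolding$path)
      lapply(ser_list, function(s) {
        switch(config$unfolding$model,
          two = fit_two_state(s, temperature = config$unfolding$temperature_K),
          three = fit_three_state(s,
                                  temperature = config$unfolding$temperature_K),
          auto = {
            sel <- select_model(s, svd_hint = svd_hint,
                                temperature = config$unfolding$temperature_K)
            res <- if (sel$chosen == "two_state") sel$two_state else
              sel$three_state
            res$chosen_model <- sel$chosen
            res
          },
          ks_stop("unfolding model must be 'auto', 'two' or 'three'",
                  "config_error"))
      })
    })
  }

  if (!is.null(config$thermal$path)) {
    results$thermal <- stage("thermal", {
      melts <- read_thermal_csv(config$thermal$path)
      lapply(melts, melting_temperatures,
             smoothing_window = config$thermal$smoothing_window,
             prominence = config$thermal$prominence)
    })
  }

  if (!is.null(config$kinetics$rates_path)) {
    results$kinetics_mm <- stage("kinetics", {
      pts <- read_rates_csv(config$kinetics$rates_path)
      if (is.null(config$kinetics$enzyme_nM)) {
        ks_stop("kinetics$enzyme_nM is required with rates_path",
                "config_error")
      }
      fit_michaelis_menten(pts, config$kinetics$enzyme_nM)
    })
  }
  if (!is.null(config$kinetics$temperature_rates_path)) {
    results$kinetics_arrhenius <- stage("kinetics", {
      pts <- read_rates_csv(config$kinetics$temperature_rates_path)
      tmax <- suppressWarnings(find_tmax(pts))
      fit_arrhenius(pts, tmax)
    })
  }

  if (isTRUE(config$report$enabled)) {
    results$report <- stage("report", {
      rows <- build_comparison_table(config$report$protein)
      writeLines(render_report(rows, "csv"),
                 file.path(config$out_dir, "report.csv"))
      writeLines(render_report(rows, "text"),
                 file.path(config$out_dir, "report.txt"))
      rows
    })
  }

  write_fit_json(results, file.path(config$out_dir, "results.json"))
  log_lines <- c(
    paste0("kinstab version: ",
           as.character(utils::packageVersion("kinstab"))),
    paste0("seed: ", config$seed),
    paste0("unfolding: model=", config$unfolding$model,
           " share_m=", config$unfolding$share_m,
           " temperature_K=", config$unfolding$temperature_K),
    paste0("thermal: smoothing_window=", config$thermal$smoothing_window,
           " prominence=", config$thermal$prominence),
    paste0("spectra: rank_policy=", config$spectra$rank_policy,
           " threshold_factor=", config$spectra$threshold_factor),
    paste0("inputs: ", paste(paths, collapse = ", "))
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(results)
}
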