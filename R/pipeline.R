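# End-to-end pipeline: simulate (or load) -> derive -> reduce -> stationarity
# -> grid search -> summarize -> subgroup -> forecast. Every run writes a
# manifest recording the configuration hash and seed; re-running a manifest
# reproduces byte-identical data CSVs (wall-clock timings go to a separate
# timings.csv, which is exempt from the byte-identity contract).

#' Pipeline configuration
#'
#' @param mode `"simulate"` (default) or `"load"` (read per-patient minute
#'   CSVs from `input_dir`).
#' @param sim A [sim_config()] (simulate mode).
#' @param input_dir Directory of minute CSVs (load mode).
#' @param out_dir Output directory; stage outputs land in stage-named
#'   subdirectories.
#' @param resolutions Subset of [resolution_ladder()] to analyze.
#' @param signals Signal columns to model (default: all present).
#' @param p_range,d_grid,q_range Grid ranges (see [arima_grid()]).
#' @param criterion Selection criterion.
#' @param alpha Significance level for stationarity and subgroup tests.
#' @param min_n_test,min_n_fit Sufficiency thresholds (stationarity / grid).
#' @param train_fraction Forecast training fraction.
#' @param forecast_signal Signal used in the forecasting stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "load"), sim = sim_config(),
                            input_dir = NULL, out_dir = tempfile("cvr_run_"),
                            resolutions = c(1, 5, 10),
                            signals = NULL,
                            p_range = 1:3, d_grid = c(0L, 1L), q_range = 0:3,
                            criterion = "aic", alpha = 0.05,
                            min_n_test = 30L, min_n_fit = 50L,
                            train_fraction = 0.5,
                            forecast_signal = "ICP") {
  mode <- match.arg(mode)
  if (!all(resolutions %in% resolution_ladder())) {
    stop("resolutions must be drawn from resolution_ladder()", call. = FALSE)
  }
  structure(list(mode = mode, sim = sim, input_dir = input_dir,
                 out_dir = out_dir, resolutions = sort(resolutions),
                 signals = signals, p_range = p_range, d_grid = d_grid,
                 q_range = q_range, criterion = criterion, alpha = alpha,
                 min_n_test = min_n_test, min_n_fit = min_n_fit,
                 train_fraction = train_fraction,
                 forecast_signal = forecast_signal),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; keys mirror the arguments of [pipeline_config()] and
#' [sim_config()] (simulator keys live under a `sim:` block). Unknown keys
#' are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  raw$sim <- NULL
  ok_pipe <- names(formals(pipeline_config))
  ok_sim <- names(formals(sim_config))
  bad <- c(setdiff(names(raw), ok_pipe), setdiff(names(sim_args), ok_sim))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(sim_args$noise_sd)) sim_args$noise_sd <- unlist(sim_args$noise_sd)
  raw$sim <- do.call(sim_config, if (is.null(sim_args)) list() else sim_args)
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

csv_header <- function(stage, config) {
  sprintf("# cvrarima stage=%s config=%s seed=%d", stage,
          config_hash(config), config$sim$seed)
}

write_stage_csv <- function(df, path, stage, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csv_header(stage, config), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, na = "",
                     quote = FALSE)
  invisible(path)
}

#' Read a per-patient minute-resolution CSV
#'
#' Expects a `minute` (or `timestamp`) column plus signal columns; empty
#' cells are missing. A leading `#` comment line is skipped. Unknown columns
#' are preserved with a message; out-of-order timestamps are rejected.
#'
#' @param path File path.
#' @return A `minute_table` data.frame.
#' @export
read_minute_csv <- function(path) {
  first <- readLines(path, n = 1L)
  pid <- if (grepl("patient_id=", first)) {
    sub(".*patient_id=(\\S+).*", "\\1", first)
  } else NA_character_
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  tcol <- intersect(c("minute", "timestamp"), names(df))
  if (!length(tcol)) stop("no timestamp column", call. = FALSE)
  tcol <- tcol[1]
  if (is.unsorted(df[[tcol]], strictly = TRUE)) {
    stop("timestamps are not strictly increasing", call. = FALSE)
  }
  names(df)[names(df) == tcol] <- "minute"
  known <- c("minute", "MAP", "ICP", "CPP", "AMP", "PRx", "PAx", "RAC", "RAP",
             "COx_L", "COx_R", "COx-a_L", "COx-a_R", "rSO2_L", "rSO2_R",
             "PbtO2")
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    message("preserving unknown column(s): ", paste(extra, collapse = ", "))
  }
  attr(df, "patient_id") <- pid
  class(df) <- c("minute_table", "data.frame")
  df
}

#' Write a per-patient minute-resolution CSV
#'
#' Inverse of [read_minute_csv()]; write-read-write is byte-stable.
#' @param table A `minute_table`.
#' @param path Output path.
#' @export
write_minute_csv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pid <- attr(table, "patient_id")
  writeLines(sprintf("# cvrarima minute_table patient_id=%s",
                     if (is.null(pid) || is.na(pid)) "NA" else pid), con)
  utils::write.table(as.data.frame(table), con, sep = ",", row.names = FALSE,
                     na = "", quote = FALSE)
  invisible(path)
}

#' Run the full multi-resolution characterization pipeline
#'
#' Executes all stages in order: simulate (or load) minute tables, apply the
#' gap rule and resolution ladder, run stationarity tests on raw and
#' first-differenced series, grid-search ARIMA orders on the pre-differenced
#' series, summarize population median optima, compare criteria across
#' clinical subgroups, and evaluate one-step forecasts on the configured
#' signal at 1-min resolution. Failures in one patient x signal cell are
#' logged and skipped, never abort the run. A `manifest.json` capturing the
#' configuration hash and seed is written at the end.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results
#'   (`minute_tables, meta, stationarity, stationarity_table, optima,
#'   median_models, subgroup, forecasts, manifest`).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dirs <- file.path(out, c("minute", "reduced", "stationarity", "grid",
                           "summary", "subgroup", "forecast"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  log_lines <- character(0)
  note <- function(msg) {
    log_lines <<- c(log_lines, msg)
    say(msg)
  }

  # ---- stage 1: minute tables -------------------------------------------
  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$sim)
    meta <- cohort$meta
    minute_tables <- lapply(cohort$waveforms, derive_indices)
    names(minute_tables) <- meta$patient_id
  } else {
    files <- list.files(config$input_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    if (!length(files)) stop("no input CSVs found", call. = FALSE)
    minute_tables <- lapply(files, read_minute_csv)
    ids <- vapply(minute_tables, function(t) {
      pid <- attr(t, "patient_id")
      if (is.null(pid) || is.na(pid)) basename(tempfile("P")) else pid
    }, character(1))
    names(minute_tables) <- ids
    meta_path <- file.path(config$input_dir, "meta.csv")
    meta <- if (file.exists(meta_path)) {
      utils::read.csv(meta_path, comment.char = "#", check.names = FALSE)
    } else NULL
  }
  for (pid in names(minute_tables)) {
    write_minute_csv(minute_tables[[pid]],
                     file.path(out, "minute", paste0(pid, ".csv")))
  }
  if (!is.null(meta)) {
    write_stage_csv(meta, file.path(out, "minute", "meta.csv"), "minute",
                    config)
  }

  signals <- config$signals
  if (is.null(signals)) signals <- minute_signals(minute_tables[[1]])
  all_na_sig <- signals[vapply(signals, function(s) {
    all(vapply(minute_tables, function(t) all(is.na(t[[s]])), logical(1)))
  }, logical(1))]
  if (length(all_na_sig)) {
    note(paste("skipping channel-absent signal(s):",
               paste(all_na_sig, collapse = ", ")))
    signals <- setdiff(signals, all_na_sig)
  }

  # ---- stages 2-4: reduce, stationarity, grid ---------------------------
  stat_rows <- list(); optima_rows <- list(); timing_rows <- list()
  for (pid in names(minute_tables)) {
    tab <- minute_tables[[pid]]
    for (sig in signals) {
      filled <- fill_gaps(tab[[sig]])
      for (res in config$resolutions) {
        cell <- tryCatch({
          seg <- if (res == 1) longest_segment(filled) else {
            ds <- downsample(filled, res)
            if (!nrow(ds)) numeric(0) else {
              seg_tab <- table(ds$segment_id)
              v <- ds$value[ds$segment_id ==
                              as.integer(names(which.max(seg_tab)))]
              v[!is.na(v)]
            }
          }
          write_stage_csv(
            data.frame(value = seg),
            file.path(out, "reduced",
                      sprintf("%s_%s_%dmin.csv", pid, gsub("-", "", sig), res)),
            "reduced", config)

          usable_test <- sufficiency_check(seg, config$min_n_test)
          st_raw <- if (usable_test) {
            cbind(stage = "raw", stationarity_tests(seg, config$alpha,
                                                    config$min_n_test))
          } else {
            data.frame(stage = "raw", adf_stat = NA, adf_p = NA,
                       adf_reject = NA, kpss_stat = NA, kpss_p = NA,
                       kpss_reject = NA, label = NA_character_,
                       agreement_nonstationary = NA, n = length(seg))
          }
          st_dif <- if (usable_test && length(seg) > config$min_n_test) {
            cbind(stage = "differenced",
                  stationarity_tests(difference_series(seg, 1), config$alpha,
                                     config$min_n_test))
          } else NULL
          stat_rows[[length(stat_rows) + 1L]] <-
            cbind(patient_id = pid, signal = sig, resolution = res,
                  rbind(st_raw, st_dif))

          if (sufficiency_check(seg, max(config$min_n_fit + 1L, 2L))) {
            g <- arima_grid(seg, config$p_range, config$d_grid,
                            config$q_range, pre_diff = 1L,
                            criterion = config$criterion,
                            min_n = config$min_n_fit)
            grid_df <- cbind(signal = sig, g$records)
            write_stage_csv(
              grid_df[setdiff(names(grid_df), "fit_seconds")],
              file.path(out, "grid",
                        sprintf("%s_%s_%dmin.csv", pid, gsub("-", "", sig), res)),
              "grid", config)
            timing_rows[[length(timing_rows) + 1L]] <-
              cbind(patient_id = pid, resolution = res, grid_df[
                c("signal", "p", "d", "q", "fit_seconds")])
            best <- select_optimal(g$records, config$criterion)
            if (!is.null(best)) {
              optima_rows[[length(optima_rows) + 1L]] <- data.frame(
                patient_id = pid, signal = sig, resolution = res,
                p = best$p, total_d = best$total_d, q = best$q,
                aic = best$aic, bic = best$bic, ll = best$ll)
            }
          }
          TRUE
        }, error = function(e) {
          note(sprintf("cell %s/%s/%dmin failed: %s", pid, sig, res,
                       conditionMessage(e)))
          FALSE
        })
      }
    }
  }
  stationarity <- do.call(rbind, stat_rows)
  if (!is.null(stationarity)) {
    write_stage_csv(stationarity,
                    file.path(out, "stationarity", "stationarity.csv"),
                    "stationarity", config)
    st_table <- cohort_stationarity_table(
      stationarity[stationarity$stage == "raw", ])
    write_stage_csv(st_table,
                    file.path(out, "stationarity", "cohort_table.csv"),
                    "stationarity", config)
  } else st_table <- NULL
  optima <- do.call(rbind, optima_rows)
  if (length(timing_rows)) {
    write_stage_csv(do.call(rbind, timing_rows),
                    file.path(out, "grid", "timings.csv"), "grid", config)
  }

  # ---- stage 5: population medians --------------------------------------
  median_models <- NULL
  if (!is.null(optima)) {
    write_stage_csv(optima, file.path(out, "summary", "optima.csv"),
                    "summary", config)
    median_models <- population_median_models(optima, config$criterion)
    write_stage_csv(median_models,
                    file.path(out, "summary", "median_models.csv"),
                    "summary", config)
  }

  # ---- stage 6: subgroup comparisons ------------------------------------
  subgroup <- NULL
  if (!is.null(optima) && !is.null(meta)) {
    res1 <- optima[optima$resolution == min(config$resolutions), ]
    subgroup <- subgroup_analysis(res1, meta, alpha = config$alpha)
    if (!is.null(subgroup)) {
      write_stage_csv(subgroup, file.path(out, "subgroup", "subgroup.csv"),
                      "subgroup", config)
      write_stage_csv(significant_subgroups(subgroup),
                      file.path(out, "subgroup", "significant.csv"),
                      "subgroup", config)
    }
  }

  # ---- stage 7: forecasting ---------------------------------------------
  fc_rows <- list()
  if (!is.null(optima)) {
    fsig <- config$forecast_signal
    cand <- optima[optima$signal == fsig & optima$resolution == 1, ]
    for (i in seq_len(nrow(cand))) {
      pid <- cand$patient_id[i]
      x <- longest_segment(fill_gaps(minute_tables[[pid]][[fsig]]))
      fc_rows[[length(fc_rows) + 1L]] <- tryCatch(
        evaluate_forecast(x, c(cand$p[i], cand$total_d[i], cand$q[i]),
                          config$train_fraction, patient_id = pid,
                          signal = fsig),
        error = function(e) {
          note(sprintf("forecast %s/%s failed: %s", pid, fsig,
                       conditionMessage(e)))
          NULL
        })
    }
  }
  forecasts <- do.call(rbind, fc_rows)
  if (!is.null(forecasts)) {
    write_stage_csv(forecasts, file.path(out, "forecast", "forecasts.csv"),
                    "forecast", config)
    write_stage_csv(correlation_vs_spread(forecasts),
                    file.path(out, "forecast", "r_vs_spread.csv"),
                    "forecast", config)
  }

  manifest <- list(config_hash = config_hash(config), seed = config$sim$seed,
                   package_version = as.character(utils::packageVersion("cvrarima")),
                   stages = basename(dirs), log = log_lines)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(minute_tables = minute_tables, meta = meta,
                 stationarity = stationarity, stationarity_table = st_table,
                 optima = optima, median_models = median_models,
                 subgroup = subgroup, forecasts = forecasts,
                 manifest = manifest, out_dir = out))
}
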