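# File formats and pipeline orchestration.
#
# Image stacks are multi-page TIFFs (page order = time, or phase step for
# FLIM stacks) with a JSON sidecar `<path>.json` holding pixel size,
# modulation frequency and timestamps; CSV/JSON carry all tabular results.

# 31-bit code space for scaled-float TIFF pages; the top code marks NaN
.f32_vmax <- 2^31 - 2
.f32_nan <- 2^31 - 1

#' Write an image sequence as a multi-page TIFF with a JSON sidecar
#'
#' Two storage modes are offered. `bits = 16` stores unsigned 16-bit
#' integers and is exact for integer-valued data in 0..65535 (camera counts,
#' label masks). `bits = 32` stores real-valued images (lifetimes,
#' fluorescence) as affine-scaled 31-bit integer codes with a reserved
#' sentinel for non-finite pixels; the value range is recorded in the
#' sidecar, so reading restores values to within one part in 2^31 of the
#' image range and restores `NaN` positions exactly.
#'
#' @param images list of numeric matrices (one page each).
#' @param path output TIFF path; metadata goes to `<path>.json`.
#' @param bits 32 (scaled real data, `NaN`-safe, default) or 16 (unsigned
#'   integer; values are rounded and must fit in 0..65535).
#' @param metadata named list stored in the sidecar (e.g. `pixel_size_um`,
#'   `modulation_frequency_hz`, `timestamps_s`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(images, path, bits = 32, metadata = list()) {
  if (!is.list(images)) images <- list(images)
  if (!bits %in% c(16, 32)) stop("bits must be 16 or 32")
  if (bits == 16) {
    vals <- unlist(images)
    if (!all(is.finite(vals)))
      stop("16-bit output cannot store non-finite values; use bits = 32")
    if (min(vals) < 0 || max(vals) > 65535)
      stop("16-bit output requires values in 0..65535")
    coded <- lapply(images, function(m) round(m) / 65535)
  } else {
    vals <- unlist(images)
    fin <- vals[is.finite(vals)]
    lo <- if (length(fin)) min(fin) else 0
    hi <- if (length(fin)) max(fin) else 0
    scale <- if (hi > lo) .f32_vmax / (hi - lo) else 0
    coded <- lapply(images, function(m) {
      code <- round((m - lo) * scale)
      code[!is.finite(m)] <- .f32_nan
      code / (2^32 - 1)
    })
    metadata$value_min <- lo
    metadata$value_max <- hi
  }
  tiff::writeTIFF(coded, path, bits.per.sample = bits,
                  compression = "none", reduce = FALSE)
  metadata$n_pages <- length(images)
  metadata$bits <- bits
  jsonlite::write_json(metadata, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack and its metadata sidecar
#'
#' Inverts the [write_stack()] encoding (integer pages as-is; scaled 32-bit
#' pages back to their value range, sentinel codes back to `NaN`). A missing
#' sidecar yields raw integer pages and empty metadata with a warning;
#' timestamps default to the page index.
#'
#' @param path TIFF path written by [write_stack()] (or any multi-page TIFF).
#' @return list: `images` (list of matrices), `metadata` (list), and
#'   `timestamps_s` (from the sidecar, or 0, 1, 2, ... when absent).
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    metadata <- jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    warning("no metadata sidecar at ", side, "; returning raw integer pages")
    metadata <- list()
  }
  pages <- lapply(pages, function(m) {
    mode(m) <- "numeric"
    m
  })
  if (identical(metadata$bits, 32L) || identical(metadata$bits, 32)) {
    lo <- metadata$value_min
    hi <- metadata$value_max
    pages <- lapply(pages, function(code) {
      v <- if (hi > lo) lo + code * (hi - lo) / .f32_vmax else
        matrix(lo, nrow(code), ncol(code))
      v[code == .f32_nan] <- NaN
      v
    })
  }
  ts <- metadata$timestamps_s
  if (is.null(ts)) ts <- seq_along(pages) - 1
  list(images = pages, metadata = metadata, timestamps_s = as.numeric(ts))
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected
#' so typos cannot silently fall back to defaults; every tunable of the
#' analysis chain is reachable from here. The resolved configuration is
#' written beside the outputs of every run.
#'
#' @param preset experiment preset (see [make_experiment()]).
#' @param seed base RNG seed.
#' @param out output directory (`NULL`: nothing is written).
#' @param calibration named list: `tau0_ns`, `tau_ox_ns`, `o2_ox_fraction`,
#'   `temperature_c`.
#' @param schedule named list overriding [default_step_schedule()] fields.
#' @param analysis named list: `margin_um`, `min_iou`, `plateau_window_min`,
#'   `aerobic_window_h`, `pre_switch_window_h`, `post_switch_window_h`.
#' @param synthesis named list: `n_chambers`, `duration_h`, `division_cv`,
#'   `response_time_constant_min`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "aerobic", seed = 1, out = NULL,
                            calibration = list(), schedule = list(),
                            analysis = list(), synthesis = list()) {
  defaults <- list(
    calibration = list(tau0_ns = 526, tau_ox_ns = 144, o2_ox_fraction = 1.0,
                       temperature_c = 30),
    schedule = list(levels_percent = c(0, 2, 4, 6, 8, 10, 15, 21, 100),
                    initial_hold_h = 4, step_duration_h = 3,
                    sample_interval_min = 5),
    analysis = list(margin_um = 0.5, min_iou = 0.2, plateau_window_min = 60,
                    aerobic_window_h = c(0, 9),
                    pre_switch_window_h = c(0, 8 + 5 / 60),
                    post_switch_window_h = c(8 + 10 / 60, 9)),
    synthesis = list(n_chambers = 5, duration_h = 9, division_cv = 0.2,
                     response_time_constant_min = 37))
  merge_block <- function(name, user) {
    unknown <- setdiff(names(user), names(defaults[[name]]))
    if (length(unknown))
      stop("unknown key(s) in ", name, ": ", paste(unknown, collapse = ", "))
    utils::modifyList(defaults[[name]], user)
  }
  if (!preset %in% c("aerobic", "anaerobic_switch", "step_test"))
    stop("unknown preset: ", preset)
  structure(list(preset = preset, seed = seed, out = out,
                 calibration = merge_block("calibration", calibration),
                 schedule = merge_block("schedule", schedule),
                 analysis = merge_block("analysis", analysis),
                 synthesis = merge_block("synthesis", synthesis)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), c("preset", "seed", "out", "calibration",
                                 "schedule", "analysis", "synthesis"))
  if (length(unknown))
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Run the full synthetic pipeline for one preset
#'
#' Executes generation and analysis in dependency order and (optionally)
#' writes every artifact to `config$out`:
#' \itemize{
#'   \item `step_test`: oxygen trace CSV, plateau table, switching-time JSON.
#'   \item `aerobic` / `anaerobic_switch`: per-chamber cell and population
#'     CSVs, division lists, growth rates (mean +/- SD over chambers),
#'     intensity slopes, and for the switch preset a fold-change of the
#'     post-switch slope against an aerobic reference run with the same
#'     chamber seeds.
#' }
#' Re-running with an unchanged configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report` list with the headline numbers, per-stage
#'   parameters and collected warnings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))
  out <- config$out
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  calib <- withCallingHandlers(
    fit_stern_volmer(config$calibration$tau0_ns, config$calibration$tau_ox_ns,
                     config$calibration$o2_ox_fraction,
                     config$calibration$temperature_c),
    warning = function(w) { note(w); invokeRestart("muffleWarning") })
  model <- o2_response_model(config$synthesis$response_time_constant_min)

  report <- list(preset = config$preset, seed = config$seed,
                 kq = calib$kq, config = unclass(config))

  run_colony_preset <- function(preset, seed) {
    exp_ <- make_experiment(preset, seed = seed,
                            n_chambers = config$synthesis$n_chambers,
                            duration_h = config$synthesis$duration_h,
                            response_model = model,
                            division_cv = config$synthesis$division_cv)
    series <- lapply(exp_$colonies, function(cl) population_series(truth_records(cl)))
    list(exp = exp_, series = series)
  }

  if (config$preset == "step_test") {
    schedule <- do.call(step_schedule, config$schedule)
    trace <- simulate_o2_response(schedule, model)
    plat <- plateau_values(trace, schedule,
                           window_min = config$analysis$plateau_window_min)
    sw <- withCallingHandlers(
      switching_times(trace, schedule, plateaus = plat),
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
    report$plateaus <- plat
    report$switching <- sw
    if (!is.null(out)) {
      write_csv_plain(data.frame(time_s = trace$times_s,
                                 o2_percent = 100 * trace$o2_fraction,
                                 roi = trace$source_roi),
                      file.path(out, "o2_trace.csv"))
      write_csv_plain(as.data.frame(plat), file.path(out, "plateaus.csv"))
      jsonlite::write_json(as.data.frame(sw), file.path(out, "switching.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
    }
  } else {
    res <- run_colony_preset(config$preset, config$seed)
    win <- if (config$preset == "aerobic") config$analysis$aerobic_window_h
           else config$analysis$pre_switch_window_h
    fits <- lapply(res$series, growth_rate, window = win)
    mus <- vapply(fits, `[[`, numeric(1), "mu_per_h")
    report$growth <- list(mu_per_chamber = mus, mu_mean = mean(mus),
                          mu_sd = stats::sd(mus), window_h = win)
    slope_full <- vapply(res$series, function(s)
      as.numeric(intensity_slope(s, window = win)), numeric(1))
    report$intensity_slope <- list(per_chamber = slope_full,
                                   mean = mean(slope_full), window_h = win)
    if (config$preset == "anaerobic_switch") {
      post <- config$analysis$post_switch_window_h
      slope_post <- vapply(res$series, function(s)
        as.numeric(intensity_slope(s, window = post)), numeric(1))
      # aerobic reference with the same chamber seeds for the fold-change
      ref <- run_colony_preset("aerobic", config$seed)
      slope_ref <- vapply(ref$series, function(s)
        as.numeric(intensity_slope(s, window = config$analysis$aerobic_window_h)),
        numeric(1))
      fc <- fold_change(mean(slope_post), mean(slope_ref))
      report$switch <- list(slope_post_per_chamber = slope_post,
                            slope_post_mean = mean(slope_post),
                            slope_aerobic_ref = mean(slope_ref),
                            fold_change = fc, window_h = post)
    }
    if (!is.null(out)) {
      cells <- do.call(rbind, lapply(seq_along(res$exp$colonies), function(i) {
        r <- truth_records(res$exp$colonies[[i]]); r$chamber <- i; r
      }))
      pop <- do.call(rbind, lapply(seq_along(res$series), function(i) {
        s <- as.data.frame(res$series[[i]]); s$chamber <- i; s
      }))
      lin <- do.call(rbind, lapply(seq_along(res$exp$colonies), function(i) {
        d <- res$exp$colonies[[i]]$divisions; if (nrow(d)) d$chamber <- i; d
      }))
      write_csv_plain(cells, file.path(out, "cells.csv"))
      write_csv_plain(pop, file.path(out, "population.csv"))
      write_csv_plain(lin, file.path(out, "lineage.csv"))
      jsonlite::write_json(
        report[setdiff(names(report), "config")],
        file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA,
        na = "null")
    }
  }
  if (!is.null(out))
    yaml::write_yaml(unclass(config)[setdiff(names(unclass(config)), "out")],
                     file.path(out, "resolved_config.yaml"))
  report$warnings <- warnings_log
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> preset '%s', seed %s, Kq = %.4f\n",
              x$preset, format(x$seed), x$kq))
  if (!is.null(x$growth))
    cat(sprintf("  mu = %.3f +/- %.3f 1/h over %d chamber(s)\n",
                x$growth$mu_mean, x$growth$mu_sd, length(x$growth$mu_per_chamber)))
  if (!is.null(x$switch))
    cat(sprintf("  post-switch slope %.1f vs aerobic %.1f a.u./h -> %d-fold\n",
                x$switch$slope_post_mean, x$switch$slope_aerobic_ref,
                x$switch$fold_change$fold))
  if (!is.null(x$switching))
    cat(sprintf("  t90 median %.1f min over %d steps\n",
                stats::median(x$switching$t90_min, na.rm = TRUE),
                nrow(x$switching)))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
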