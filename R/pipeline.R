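#' Pipeline configuration
#'
#' Collects every stage parameter with its standard default: 3 Hz detection
#' cutoff, 5% sub-minimum rule, 50/15 ms smoothing kernels, 45 s z-score
#' window, 80 in-reach samples at 10 ms pre/post steps, +/-400 ms analysis
#' window, alpha = 0.01 (modulation, encoding) and 0.05 (tuning, windowed
#' regressions), 5-sample contiguity, 10,000 shuffles/shifts, +/-1 s lag
#' range in 1/120 s steps, 15 mm heatmap cells, Q3 + 1.5 IQR duration
#' curation with a 25-reach session minimum.
#'
#' @param ... named overrides of the defaults.
#' @return an object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    detect_cutoff_hz = 3,
    detect_peak_window_s = c(-0.5, 2.5),
    detect_min_frac = 0.05,
    kernel_modulation_ms = 50,
    kernel_regression_ms = 15,
    kernel_detection_ms = 0,
    zscore_window_s = 45,
    zscore_after_smoothing = TRUE,
    in_reach_n = 80L,
    grid_step_s = 0.01,
    endpoint_convention = "inclusive",
    analysis_window_s = 0.4,
    alpha_modulation = 0.01,
    alpha_tuning = 0.05,
    alpha_encoding = 0.01,
    alpha_windowed = 0.05,
    contiguity_min = 5L,
    n_shuffles = 10000L,
    n_shifts = 10000L,
    null_statistic = "max_lag",
    lag_range_s = 1,
    lag_step_s = 1 / 120,
    heatmap_cell_mm = 15,
    curation_iqr_mult = 1.5,
    min_valid_reaches = 25L,
    alignment_mode = "stretched",
    regression_pad_s = 0.25,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Validate a session bundle
#'
#' Checks file presence, column schemas, monotone time stamps, nominal
#' sampling rate, and unit-id referential integrity.
#'
#' @param dir bundle directory.
#' @return data.frame of findings (severity, file, message); zero rows when
#'   the bundle is clean.
#' @export
validate_bundle <- function(dir) {
  findings <- list()
  add <- function(severity, file, message) {
    findings[[length(findings) + 1]] <<-
      data.frame(severity = severity, file = file, message = message)
  }
  need <- c("events.csv", "kinematics.csv", "spikes.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) add("error", f, "missing file")
  }
  if (length(findings) == 0) {
    ev <- utils::read.csv(file.path(dir, "events.csv"))
    for (col in c("trial", "target_id", "cue_on_s", "target_on_s")) {
      if (!col %in% names(ev)) add("error", "events.csv",
                                   paste("missing column", col))
    }
    if (all(c("cue_on_s", "target_on_s") %in% names(ev))) {
      if (is.unsorted(ev$target_on_s, strictly = TRUE))
        add("error", "events.csv", "target_on_s not strictly increasing")
      if (any(ev$cue_on_s >= ev$target_on_s))
        add("error", "events.csv", "cue must precede target display")
    }
    kin <- utils::read.csv(file.path(dir, "kinematics.csv"))
    for (col in c("t_s", "x_mm", "y_mm", "z_mm", "valid")) {
      if (!col %in% names(kin)) add("error", "kinematics.csv",
                                    paste("missing column", col))
    }
    if ("t_s" %in% names(kin)) {
      if (is.unsorted(kin$t_s, strictly = TRUE))
        add("error", "kinematics.csv", "t_s not strictly increasing")
      fps <- 1 / stats::median(diff(kin$t_s))
      if (abs(fps - 120) > 1) {
        add("warning", "kinematics.csv",
            sprintf("sampling rate %.1f frames/s differs from nominal 120 (lag step assumes 1/120 s)",
                    fps))
      }
    }
    sp <- utils::read.csv(file.path(dir, "spikes.csv"))
    for (col in c("unit_id", "t_s")) {
      if (!col %in% names(sp)) add("error", "spikes.csv",
                                   paste("missing column", col))
    }
    if (all(c("unit_id", "t_s") %in% names(sp))) {
      bad_rows <- unlist(lapply(split(seq_len(nrow(sp)), sp$unit_id),
                                function(ix) {
        ix[c(FALSE, diff(sp$t_s[ix]) < 0)]
      }))
      if (length(bad_rows)) {
        add("error", "spikes.csv",
            paste("non-monotone spike times at row(s)",
                  paste(utils::head(sort(bad_rows), 5), collapse = ", ")))
      }
      if ("t_s" %in% names(kin) && nrow(sp) > 0 &&
          (min(sp$t_s) < min(kin$t_s) - 1 || max(sp$t_s) > max(kin$t_s) + 1)) {
        add("warning", "spikes.csv", "spike times extend beyond kinematics")
      }
    }
  }
  if (length(findings) == 0) {
    return(data.frame(severity = character(0), file = character(0),
                      message = character(0)))
  }
  do.call(rbind, findings)
}

#' Run the full analysis pipeline on a session bundle
#'
#' Executes kinematic feature extraction (50 and 15 ms kernels), reach
#' detection and curation, firing-rate estimation, peri-reach modulation and
#' directional-tuning testing, spatial heatmaps, lagged encoding regressions
#' with circular-shift significance and Shapley decomposition, and the
#' summary report. All stage outputs are written as CSV/JSON into `outdir`
#' together with a manifest; reruns with identical inputs, config and seed
#' produce byte-identical outputs.
#'
#' @param bundle_dir session bundle directory (see [write_session_bundle()]).
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return invisible list with all in-memory stage results.
#' @export
run_pipeline <- function(bundle_dir, config = pipeline_config(),
                         outdir = file.path(bundle_dir, "out")) {
  findings <- validate_bundle(bundle_dir)
  if (any(findings$severity == "error")) {
    stop("bundle validation failed:\n",
         paste(sprintf("  [%s] %s: %s", findings$severity, findings$file,
                       findings$message), collapse = "\n"))
  }
  bundle <- read_session_bundle(bundle_dir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  n_targets <- bundle$config$n_targets %||% 8L
  target_display_s <- bundle$config$target_display_s %||% 3
  task <- task_config(n_targets = n_targets,
                      radius = bundle$config$radius %||% 178,
                      target_display_s = target_display_s)

  feat50 <- compute_features(bundle$trajectory, config$kernel_modulation_ms)
  feat15 <- compute_features(bundle$trajectory, config$kernel_regression_ms)
  utils::write.csv(feat50, file.path(outdir, sprintf(
    "features_%dms.csv", as.integer(config$kernel_modulation_ms))),
    row.names = FALSE)
  utils::write.csv(feat15, file.path(outdir, sprintf(
    "features_%dms.csv", as.integer(config$kernel_regression_ms))),
    row.names = FALSE)

  feat_detect <- compute_features(bundle$trajectory,
                                  config$kernel_detection_ms)
  reaches <- detect_reaches(feat_detect, bundle$events, task,
                            cutoff_hz = config$detect_cutoff_hz,
                            peak_window = config$detect_peak_window_s,
                            min_frac = config$detect_min_frac)
  reaches <- curate_reaches(reaches, config$min_valid_reaches,
                            config$curation_iqr_mult)
  utils::write.csv(reaches, file.path(outdir, "reaches.csv"),
                   row.names = FALSE)
  session_excluded <- isTRUE(attr(reaches, "session_excluded"))

  span <- range(bundle$trajectory$t)
  lags <- seq(-config$lag_range_s, config$lag_range_s,
              by = config$lag_step_s)
  units <- names(bundle$spikes)
  modulation <- list(); tuning <- list(); encoding <- list()
  grid0 <- NULL
  mod_rows <- list(); tun_rows <- list(); enc_rows <- list(); shap_rows <- list()
  summary_units <- list()

  if (!session_excluded) {
    design <- build_design(feat15, reaches, "reach_window",
                           pad_s = config$regression_pad_s)
    for (u in units) {
      st <- bundle$spikes[[u]]
      fir <- fractional_interval_rate(st, span, unit_id = u)
      r50 <- smooth_rate(fir, config$kernel_modulation_ms)
      r15 <- sliding_zscore(smooth_rate(fir, config$kernel_regression_ms),
                            config$zscore_window_s)

      grid <- build_grid(r50, reaches, mode = config$alignment_mode,
                         step_s = config$grid_step_s,
                         in_reach_n = config$in_reach_n,
                         endpoint_convention = config$endpoint_convention,
                         features = feat50)
      if (is.null(grid0)) grid0 <- grid
      base <- shuffle_baseline(r50, nrow(grid$fr), config$n_shuffles,
                               seed = derive_seed(seed, 1000L + match(u, units)))
      mod <- test_modulation(grid, base, config$alpha_modulation,
                             config$contiguity_min)
      modulation[[u]] <- mod
      mod_rows[[u]] <- data.frame(
        unit = u, timepoint = seq_along(mod$mean_fr), phase = grid$phase,
        mean_fr = mod$mean_fr, p = mod$p, sign = mod$sign)

      tun <- tryCatch(
        test_directional_tuning(grid, alpha = config$alpha_tuning,
                                contiguity_min = config$contiguity_min),
        error = function(e) NULL)
      if (!is.null(tun)) {
        tuning[[u]] <- tun
        tun_rows[[u]] <- data.frame(
          unit = u, timepoint = seq_along(tun$p), p = tun$p,
          severity = tun$severity)
      }

      hm <- spatial_heatmap(feat50, r50, config$heatmap_cell_mm)
      utils::write.csv(hm, file.path(outdir, sprintf("heatmap_%s.csv", u)),
                       row.names = FALSE)

      enc_u <- list()
      for (set in c("kinematics_only", "kinematics_plus_error")) {
        res <- encode_unit(design, r15, set, lags,
                           n_shifts = config$n_shifts,
                           seed = derive_seed(seed, 2000L + match(u, units)),
                           alpha = config$alpha_encoding,
                           statistic = config$null_statistic)
        enc_u[[set]] <- res
        enc_rows[[paste(u, set)]] <- data.frame(
          unit = u, set = set, lag_ms = 1000 * res$fit$lags_s,
          r2 = res$fit$r2, adj_r2 = res$fit$adj_r2)
        shap_rows[[paste(u, set)]] <- data.frame(
          unit = u, set = set, column = names(res$shapley$values),
          group = unname(regressor_groups(set)[names(res$shapley$values)]),
          value = unname(res$shapley$values),
          proportion = unname(res$shapley$proportions))
        summary_units[[paste(u, set)]] <- list(
          unit = u, set = set, opt_lag_ms = 1000 * res$fit$opt_lag_s,
          r2 = res$fit$opt_r2, adj_r2 = res$fit$opt_adj_r2,
          null_p = res$null$p, null_crit = res$null$crit,
          significant = res$null$significant)
      }
      encoding[[u]] <- enc_u
    }
  }

  utils::write.csv(do.call(rbind, mod_rows) %||%
                     data.frame(), file.path(outdir, "modulation.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, tun_rows) %||% data.frame(),
                   file.path(outdir, "tuning.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, enc_rows) %||% data.frame(),
                   file.path(outdir, "encoding.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, shap_rows) %||% data.frame(),
                   file.path(outdir, "shapley.csv"), row.names = FALSE)
  jsonlite::write_json(summary_units, file.path(outdir,
                                                "encoding_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  report <- summarize_session(modulation, tuning, encoding, grid0)
  report$session_excluded <- session_excluded
  report$n_valid_reaches <- sum(reaches$valid)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_report_md(report, file.path(outdir, "report.md"))

  cfg_tmp <- file.path(outdir, "config_used.yaml")
  yaml::write_yaml(unclass(config), cfg_tmp, precision = 15)
  manifest <- list(
    package = "vimreach",
    version = as.character(utils::packageVersion("vimreach")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_tmp)),
    n_units = length(units),
    outputs = sort(setdiff(list.files(outdir), "manifest.json"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(features_50 = feat50, features_15 = feat15,
                 reaches = reaches, modulation = modulation, tuning = tuning,
                 encoding = encoding, report = report, outdir = outdir))
}

write_report_md <- function(report, path) {
  fmt <- function(x) if (is.numeric(x)) sprintf("%.3f", x) else as.character(x)
  lines <- c("# Session report", "")
  flat <- function(x, prefix = "") {
    out <- character(0)
    for (nm in names(x)) {
      v <- x[[nm]]
      if (is.list(v)) {
        out <- c(out, flat(v, paste0(prefix, nm, ".")))
      } else if (length(v) == 1) {
        out <- c(out, sprintf("- %s%s: %s", prefix, nm, fmt(v)))
      }
    }
    out
  }
  writeLines(c(lines, flat(report)), path)
}
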