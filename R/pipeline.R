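# 31-bit polynomial rolling hash over a string; stamped on every output
# table so results are traceable to the configuration that produced them
str_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Hash of a pipeline configuration
#'
#' @param config a [pipeline_config()] list.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(config) {
  str_hash(paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), ""), collapse = ";"))
}

#' Pipeline configuration
#'
#' Flat keyed list of every tunable the pipeline stages consume, with
#' the analysis defaults: 407 Hz sampling, 30-95 Hz slope band with
#' threshold 1.5 on 1-s windows, 200 ms spike pad, 1-s Hann spectra
#' normalized over 0-50 Hz, sigma band 10-15 Hz (detector sigma 9-15
#' Hz, theta 4-8 Hz), 0.5 s/0.1 s detector windowing with threshold
#' 0.95, 0.5 s minimum duration, 0.1 s merge gap, 2-s 9-taper coherence
#' at 12.5 Hz, FDR q = 0.05. Unknown override keys are rejected.
#'
#' @param ... overrides of default keys.
#' @param file optional YAML file of overrides (applied before `...`).
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- list(
    sampling_rate = 407, slope_band_lo = 30, slope_band_hi = 95,
    slope_threshold = 1.5, slope_window = 1, spike_pad = 0.2,
    psd_window = 1, norm_band_lo = 0, norm_band_hi = 50,
    sigma_band_lo = 10, sigma_band_hi = 15,
    det_theta_lo = 4, det_theta_hi = 8, det_sigma_lo = 9,
    det_sigma_hi = 15, det_window = 0.5, det_step = 0.1,
    det_threshold = 0.95, min_duration = 0.5, merge_gap = 0.1,
    taper_T = 2, taper_W = 2.5, coherence_freq = 12.5, fdr_q = 0.05,
    n_active = 8, n_resolved = 10, n_control = 8,
    rate_active = 0.65, rate_resolved = 1.09, rate_control = 1.84,
    rate_dispersion = 2, synchrony_target = 0.6,
    render_duration = 300, burst_snr = 3, spike_rate = 0, seed = 1)
  apply_over <- function(cfg, over) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    utils::modifyList(cfg, over)
  }
  if (!is.null(file)) cfg <- apply_over(cfg, yaml::read_yaml(file))
  cfg <- apply_over(cfg, list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a source-recording container
#'
#' Plain-text header (subject, fs, vertical axis, tab-delimited source
#' table with id/hemisphere/label/coordinates) followed by the payload
#' as little-endian 32-bit floats, sources by samples in row-major
#' order. Round trips are lossless at float32 precision.
#'
#' @param rec a [source_recording()].
#' @param path file path.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  src <- rec$sources
  coord <- function(cn) if (cn %in% names(src)) src[[cn]] else 0
  hdr <- c(
    "spindlesource-recording v1",
    paste("subject", rec$subject),
    paste("fs", format(rec$fs, digits = 15)),
    paste("vertical_axis", rec$vertical_axis),
    paste("n_sources", nrow(rec$data)),
    paste("n_samples", ncol(rec$data)),
    "sources:",
    sprintf("%s\t%s\t%s\t%g\t%g\t%g", src$id, src$hemisphere, src$label,
            coord("x"), coord("y"), coord("z")),
    "payload float32le")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(as.vector(t(rec$data)), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_recording
#' @return [read_recording()] returns the [source_recording()].
#' @export
read_recording <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  marker <- charToRaw("payload float32le\n")
  pos <- NULL
  limit <- length(raw) - length(marker) + 1L
  hits <- which(raw == marker[1])
  for (h in hits) {
    if (h <= limit &&
        identical(raw[h:(h + length(marker) - 1L)], marker)) {
      pos <- h
      break
    }
  }
  if (is.null(pos)) stop("malformed container: payload marker missing",
                         call. = FALSE)
  hdr <- strsplit(rawToChar(raw[1:(pos - 1L)]), "\n")[[1]]
  if (hdr[1] != "spindlesource-recording v1")
    stop("malformed container header (line 1)", call. = FALSE)
  field <- function(key) {
    ln <- grep(paste0("^", key, " "), hdr, value = TRUE)
    if (!length(ln)) stop("malformed container: missing '", key,
                          "' (header line)", call. = FALSE)
    sub(paste0("^", key, " "), "", ln[1])
  }
  fs <- as.numeric(field("fs"))
  if (!is.finite(fs) || fs <= 0) stop("invalid fs in header", call. = FALSE)
  ns <- as.integer(field("n_sources"))
  nt <- as.integer(field("n_samples"))
  i0 <- which(hdr == "sources:")
  rows <- hdr[(i0 + 1L):(i0 + ns)]
  parts <- strsplit(rows, "\t")
  if (any(lengths(parts) != 6L))
    stop("malformed source table at header line ", i0 + 1L, call. = FALSE)
  src <- data.frame(
    id = as.integer(vapply(parts, `[[`, "", 1)),
    hemisphere = vapply(parts, `[[`, "", 2),
    label = vapply(parts, `[[`, "", 3),
    x = as.numeric(vapply(parts, `[[`, "", 4)),
    y = as.numeric(vapply(parts, `[[`, "", 5)),
    z = as.numeric(vapply(parts, `[[`, "", 6)),
    stringsAsFactors = FALSE)
  payload <- readBin(raw[(pos + length(marker)):length(raw)], "numeric",
                     n = ns * nt, size = 4L, endian = "little")
  if (length(payload) != ns * nt)
    stop("payload size does not match header source/sample counts",
         call. = FALSE)
  source_recording(matrix(payload, nrow = ns, byrow = TRUE), fs,
                   sources = src, subject = field("subject"),
                   vertical_axis = field("vertical_axis"))
}

write_stamped_table <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Orchestrates the stages in fixed order: simulate (cohort table plus
#' rendered left/right inferior-Rolandic recordings), preprocess
#' (aperiodic-slope artifact flagging; spike masking when spike times
#' are supplied), detector training on a dedicated labelled simulation,
#' detection, per-subject spindle features, the group spindle-rate
#' model, and the spindle-rate to cognition models. Every table is
#' written tab-delimited under `out_dir` with the resolved
#' configuration's hash; given equal seeds, outputs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param spike_times optional named list (by subject) of per-hemisphere
#'   spike-time vectors, or a single numeric vector applied everywhere.
#' @return invisibly, a list with the cohort table, detections, feature
#'   table, group model and cognition results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         spike_times = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  spec <- cohort_spec(
    n_per_group = c(active = config$n_active, resolved = config$n_resolved,
                    control = config$n_control),
    group_rate_means = c(active = config$rate_active,
                         resolved = config$rate_resolved,
                         control = config$rate_control),
    rate_dispersion = config$rate_dispersion,
    synchrony_target = config$synchrony_target,
    render_duration = config$render_duration, seed = config$seed)
  sim <- simulate_cohort(spec, render = TRUE)
  tab <- sim$table

  # detector training on a separate labelled recording
  tcfg <- sim_config(duration = 600, burst_rate = 3,
                     burst_snr = config$burst_snr,
                     seed = config$seed + 90001L)
  trec <- simulate_recording(tcfg)
  tft <- compute_features(trec$data[1, ], trec$fs, config$det_window,
                          config$det_step,
                          c(config$det_theta_lo, config$det_theta_hi),
                          c(config$det_sigma_lo, config$det_sigma_hi))
  model <- train_detector(tft, label_windows(tft, trec$truth),
                          threshold = config$det_threshold,
                          min_duration = config$min_duration,
                          merge_gap = config$merge_gap)
  write_detector(model, file.path(out_dir, "detector_model.txt"))

  tapers <- dpss_tapers(2L * round(config$sampling_rate),
                        config$taper_T * config$taper_W)
  detections <- list()
  features <- list()
  for (i in seq_len(nrow(tab))) {
    subj <- tab$subject[i]
    pair <- sim$recordings[[subj]]
    pp <- lapply(pair, function(rec) {
      rec <- flag_artifacts(rec,
                            c(config$slope_band_lo, config$slope_band_hi),
                            config$slope_threshold, config$slope_window)
      st <- if (is.numeric(spike_times)) spike_times
            else spike_times[[subj]]
      if (!is.null(st)) rec <- mask_spikes(rec, st, config$spike_pad)
      rec
    })
    det <- lapply(pp, detect_recording, model = model,
                  window = config$det_window, step = config$det_step)
    detections[[subj]] <- do.call(rbind, Map(function(d, h) {
      if (nrow(d)) cbind(subject = subj, hemisphere = h, d)
    }, det, names(det)))
    features[[subj]] <- spindle_feature_table(pp$left, pp$right,
                                              det$left, det$right, tapers)
    # replace generator rates with detected rates for the models
    tab$rate_lh[i] <- features[[subj]]$rate_lh
    tab$rate_rh[i] <- features[[subj]]$rate_rh
  }
  det_tab <- do.call(rbind, detections)
  if (is.null(det_tab))
    det_tab <- data.frame(subject = character(0), hemisphere = character(0),
                          source = integer(0), onset = numeric(0),
                          offset = numeric(0), duration = numeric(0))
  feat_tab <- do.call(rbind, features)
  write_stamped_table(det_tab, file.path(out_dir, "detections.tsv"), hash)
  write_stamped_table(feat_tab, file.path(out_dir, "features.tsv"), hash)
  write_stamped_table(tab, file.path(out_dir, "cohort.tsv"), hash)

  long <- data.frame(
    subject = rep(tab$subject, 2L), group = rep(tab$group, 2L),
    age = rep(tab$age, 2L),
    rate = c(tab$rate_lh, tab$rate_rh))
  gm <- group_rate_model(long$rate, long$group, long$age, long$subject)
  gm_tab <- data.frame(term = names(gm$coefficients),
                       estimate = gm$coefficients, se = gm$se,
                       p = gm$p_values)
  gm_tab$percent_reduction <- ifelse(
    gm_tab$term %in% c("active", "resolved"),
    percent_reduction(gm_tab$estimate), NA)
  write_stamped_table(gm_tab, file.path(out_dir, "group_model.tsv"), hash)

  cog <- global_model_test(tab)
  cog_tab <- do.call(rbind, lapply(names(cog$fits), function(tk) {
    f <- cog$fits[[tk]]
    data.frame(task = tk, n = f$n_obs, beta1 = f$beta1,
               ci_lo = f$ci[1], ci_hi = f$ci[2], p = f$p,
               loglik = f$fit$loglik,
               r2_marginal = f$r_squared$marginal,
               r2_conditional = f$r_squared$conditional)
  }))
  write_stamped_table(cog_tab, file.path(out_dir, "cognition.tsv"), hash)
  global_tab <- data.frame(loglik = cog$loglik,
                           null_loglik = cog$null_loglik,
                           lrt_stat = cog$lrt$statistic, lrt_p = cog$lrt$p)
  write_stamped_table(global_tab, file.path(out_dir, "cognition_global.tsv"),
                      hash)
  invisible(list(cohort = tab, detections = det_tab, features = feat_tab,
                 group_model = gm, cognition = cog))
}
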