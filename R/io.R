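#' Write spike trains as a plain-text event table
#'
#' Tab-separated rows `(neuron_id, time_ms)` sorted by time then neuron,
#' preceded by `#`-prefixed header lines recording the population size,
#' duration and 1 ms resolution. The format round-trips losslessly through
#' [read_spike_events()].
#'
#' @param spikes a `spike_data` object.
#' @param path output file.
#' @export
write_spike_events <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_data"))
  idx <- which(spikes$trains == 1L, arr.ind = TRUE)
  ev <- data.frame(neuron_id = idx[, 2], time_ms = idx[, 1])
  ev <- ev[order(ev$time_ms, ev$neuron_id), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_neurons=%d", ncol(spikes$trains)),
    sprintf("# duration_ms=%d", spikes$total_ms),
    "# resolution_ms=1",
    "neuron_id\ttime_ms"
  ), con)
  if (nrow(ev)) {
    utils::write.table(ev, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a spike event table
#'
#' @param path file written by [write_spike_events()].
#' @param markers,on_ms,off_ms,grid optional stimulus metadata re-attached
#'   to the returned object.
#' @return a `spike_data` object.
#' @export
read_spike_events <- function(path, markers = NULL, on_ms = NULL,
                              off_ms = NULL, grid = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) stop(sprintf("missing header '%s' in %s", key, path),
                         call. = FALSE)
    as.integer(sub(".*=", "", m[1]))
  }
  n_neurons <- get_hdr("n_neurons")
  total_ms <- get_hdr("duration_ms")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) && grepl("^neuron_id", body[1])) body <- body[-1]
  if (!length(body)) {
    return(spike_data_from_events(
      data.frame(neuron_id = integer(0), time_ms = integer(0)),
      n_neurons, total_ms, markers, on_ms, off_ms, grid))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2 |
                 vapply(parts, function(p) anyNA(suppressWarnings(as.integer(p))),
                        logical(1)))
  if (length(bad)) {
    offset <- length(lines) - length(body)
    stop(sprintf("malformed event row(s) at line(s): %s",
                 paste(bad + offset, collapse = ", ")), call. = FALSE)
  }
  ev <- data.frame(
    neuron_id = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    time_ms = vapply(parts, function(p) as.integer(p[2]), integer(1))
  )
  if (is.unsorted(ev$time_ms)) {
    stop("event times must be sorted ascending", call. = FALSE)
  }
  if (anyDuplicated(ev)) {
    stop(sprintf("duplicate (neuron, time) rows: %s",
                 paste(which(duplicated(ev)), collapse = ", ")), call. = FALSE)
  }
  spike_data_from_events(ev, n_neurons, total_ms, markers, on_ms, off_ms, grid)
}

#' Write a stimulus sequence to JSON
#'
#' Stores the compact representation (distinct patterns, markers,
#' durations, grid) so the sequence round-trips exactly.
#' @param stim a [stim_sequence()].
#' @param path output `.json` file.
#' @export
write_stimulus <- function(stim, path) {
  stopifnot(inherits(stim, "stim_sequence"))
  jsonlite::write_json(
    list(grid = stim$grid, on_ms = stim$on_ms, off_ms = stim$off_ms,
         patterns = stim$patterns, pattern_ids = stim$markers$pattern),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stim_sequence(x$patterns, x$pattern_ids, x$grid, x$on_ms, x$off_ms)
}

#' Run the full simulate-characterize-train-evaluate pipeline
#'
#' Executes the configured stages on a synthetic population and writes the
#' evaluation report (JSON), the neuron profile table (TSV) and the spike
#' events (TSV) into `out_dir`. Every output embeds the config fingerprint
#' and seed; re-running with the same config reproduces the files.
#'
#' @param config list (or path to a JSON file) with fields:
#'   `n_neurons`, `n_patterns`, `trials`, `w_ms`, `variant`, `filter_len`,
#'   `epochs`, `scheme`, `folds`, `seed`, `snr_range`, `model`
#'   (`"cnn"`/`"glm"`). Missing fields take the demo-scale defaults.
#' @param out_dir output directory (created if missing).
#' @param verbose print stage timings.
#' @return the `eval_report`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("lgnrun"),
                         verbose = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  # 16 patterns x 8 pixels keeps each pixel in 4 patterns (as in the full
  # 32 x 4 protocol), so held-out patterns remain predictable from the rest
  defaults <- list(n_neurons = 6, n_patterns = 16, pixels_per_pattern = 8,
                   trials = 15, w_ms = 50, variant = "V-FH", filter_len = 5,
                   epochs = 30, scheme = "per_pattern", folds = 5, seed = 1,
                   snr_range = c(0.2, 1), model = "cnn", grid = c(4, 8))
  cfg <- utils::modifyList(defaults, config)
  if ((cfg$n_patterns * cfg$pixels_per_pattern) %% prod(cfg$grid) != 0) {
    stop("n_patterns * pixels_per_pattern must be divisible by the pixel count",
         call. = FALSE)
  }
  hash <- config_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- force(expr)
    if (verbose) message(sprintf("[%s] %.1fs", name, proc.time()[3] - t0))
    res
  }
  stim <- stage("simulate: stimulus", make_checkerboard(
    grid = cfg$grid, n_patterns = cfg$n_patterns,
    pixels_per_pattern = cfg$pixels_per_pattern, trials = cfg$trials,
    seed = derive_seed(cfg$seed, 1L)))
  specs <- lgn_population(cfg$n_neurons, grid = cfg$grid,
                          seed = derive_seed(cfg$seed, 2L),
                          snr_range = cfg$snr_range)
  spikes <- stage("simulate: population",
                  simulate_population(stim, specs,
                                      seed = derive_seed(cfg$seed, 3L)))
  write_spike_events(spikes, file.path(out_dir, "spikes.tsv"))
  write_stimulus(stim, file.path(out_dir, "stimulus.json"))
  profile <- stage("characterize", profile_population(spikes, stim,
                                                      w_ms = cfg$w_ms))
  utils::write.table(profile, file.path(out_dir, "neuron_profile.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  rates <- bin_rates(spikes, cfg$w_ms)
  ecfg <- encoder_config(variant = cfg$variant, w_ms = cfg$w_ms,
                         grid = cfg$grid, n_neurons = cfg$n_neurons,
                         filter_len = cfg$filter_len, epochs = cfg$epochs,
                         seed = derive_seed(cfg$seed, 4L))
  report <- stage("train+evaluate", evaluate_encoder(
    stim, rates, ecfg, scheme = cfg$scheme, k = cfg$folds,
    seed = derive_seed(cfg$seed, 5L), model = cfg$model))
  out <- list(
    config = cfg, config_hash = hash, seed = cfg$seed,
    per_neuron_corr = report$per_neuron_corr,
    mean_corr = mean(report$per_neuron_corr),
    corr_matrix = report$corr_matrix,
    peak_r2 = report$peak$r2,
    variability_r2 = report$variability$r2,
    beta_fit = if (!is.null(report$beta_fit)) {
      report$beta_fit[c("alpha", "beta")]
    },
    profile = profile
  )
  jsonlite::write_json(out, file.path(out_dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  jsonlite::write_json(
    list(config_hash = hash, seed = cfg$seed,
         files = c("spikes.tsv", "stimulus.json", "neuron_profile.tsv",
                   "eval_report.json")),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline; `--config`, `--out`, `--seed`),
#' `simulate` (stimulus + spikes only) and `evaluate` (alias of `run`).
#' Install target: `Rscript -e 'lgnencoder::lgn_cli()' run --out results`.
#'
#' @param args character vector (default: the command line).
#' @export
lgn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: lgn_cli <run|simulate> [--config file.json] [--out dir] [--seed n]")
    return(invisible(1L))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "lgn_out"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--verbose", action = "store_true", default = TRUE)
  ))
  opt <- optparse::parse_args(parser, args = args[-1])
  config <- if (!is.null(opt$config)) opt$config else list(seed = opt$seed)
  if (is.list(config)) config$seed <- opt$seed
  switch(cmd,
    run = ,
    evaluate = run_pipeline(config, out_dir = opt$out, verbose = opt$verbose),
    simulate = {
      cfgl <- if (is.character(config)) {
        jsonlite::read_json(config, simplifyVector = TRUE)
      } else config
      stim <- make_checkerboard(seed = opt$seed,
                                n_patterns = cfgl$n_patterns %||% 32,
                                trials = cfgl$trials %||% 10)
      specs <- lgn_population(cfgl$n_neurons %||% 12, seed = opt$seed)
      spikes <- simulate_population(stim, specs, seed = opt$seed)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      write_spike_events(spikes, file.path(opt$out, "spikes.tsv"))
      write_stimulus(stim, file.path(opt$out, "stimulus.json"))
      message("wrote ", opt$out)
    },
    stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
  )
  invisible(0L)
}
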