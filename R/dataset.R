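#' Configuration for the synthetic dataset generator
#'
#' The stated world of the generator: current-clamped cells held at
#' -85 mV, stimulated with 10 mock PSPs at 100 Hz of configurable
#' quantal content, imaged as two-channel line-scans with leading
#' laser-off lines. Conditions are labels mapped onto channel blocks
#' (`"control"` keeps the default channel set, `"4AP"` zeroes the
#' A-type conductance, `"CdNi"` zeroes the Ca conductance).
#'
#' @param n_cells number of cells.
#' @param conditions character vector recycled across cells.
#' @param Q quantal content of the train stimulus per trial.
#' @param trials_per_cell trials per cell.
#' @param response_min_dff true-dF/F level above which a trial's ground
#'   truth flag is "responder".
#' @param geom an [imaging_geometry()].
#' @return A named list.
#' @export
dataset_config <- function(n_cells = 2, conditions = c("control", "4AP"),
                           Q = 600, trials_per_cell = 1,
                           response_min_dff = 0.05,
                           geom = imaging_geometry()) {
  list(n_cells = n_cells, conditions = conditions, Q = Q,
       trials_per_cell = trials_per_cell,
       response_min_dff = response_min_dff, geom = geom)
}

condition_channels <- function(condition) {
  switch(condition,
         control = default_channels(),
         `4AP` = default_channels(gbar_A = 0),
         CdNi = default_channels(gbar_Ca = 0),
         stop(sprintf("unknown condition '%s'", condition), call. = FALSE))
}

#' Generate a synthetic dataset with a ground-truth manifest
#'
#' Runs the full forward model (stimulus -> membrane -> calcium ->
#' fluorescence -> noisy line-scan) for every cell and trial, writes
#' the stimulus and voltage traces as two-column CSV, the green and red
#' scan channels as 16-bit TIFF, and a single versioned `manifest.json`
#' pairing every file with its generating parameters (seed, condition,
#' stimulus, true onset, true decay constant, true dF/F, responder
#' flag). The same seed reproduces the manifest byte for byte.
#'
#' @param config a [dataset_config()].
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @param force overwrite a non-empty existing directory.
#' @return The manifest (invisibly), as written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
generate_dataset <- function(config, seed, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("output directory exists and is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- config$geom
  camod <- calcium_model()
  kin <- quantal_kinetics()
  entries <- list()
  for (ci in seq_len(config$n_cells)) {
    condition <- config$conditions[(ci - 1L) %% length(config$conditions) + 1L]
    cell <- cell_params(conductances = condition_channels(condition))
    for (tr_i in seq_len(config$trials_per_cell)) {
      trial_seed <- seed + 1000L * ci + tr_i
      set.seed(trial_seed)
      stim_onset <- 0.5 # s of pre-stimulus baseline in the scan
      pre <- as.integer(round(stim_onset / (1 / 20000)))
      inj <- build_psp_train(kin, n = 10, rate = 100, Q = config$Q,
                             duration = 3.5)
      inj <- trace(c(numeric(pre), inj$values), dt = inj$dt, units = "pA")
      sim <- simulate_membrane(cell, inj)
      fl <- simulate_calcium_fluorescence(camod, sim$i_ca)
      true_dff <- max(fl$F$values) / fl$F$values[1L] - 1
      scans <- render_linescan(
        list(list(profile = fl$F, columns = 20:40)),
        geom, seed = trial_seed
      )
      stem <- sprintf("cell%02d_trial%02d", ci, tr_i)
      files <- list(
        injection = paste0(stem, "_inj.csv"),
        voltage = paste0(stem, "_vm.csv"),
        green = paste0(stem, "_green.tif"),
        red = paste0(stem, "_red.tif")
      )
      write_trace(inj, file.path(out_dir, files$injection))
      write_trace(sim$V, file.path(out_dir, files$voltage))
      write_tiff16(scans$green$pixels, file.path(out_dir, files$green))
      write_tiff16(scans$red$pixels, file.path(out_dir, files$red))
      entries[[length(entries) + 1L]] <- list(
        cell = ci, trial = tr_i, seed = trial_seed,
        condition = condition,
        stimulus = list(type = "psp_train", n = 10, rate_hz = 100,
                        Q = config$Q, onset_s = stim_onset),
        true_onset_s = stim_onset,
        true_tau_decay_s = camod$tau_extrusion,
        true_dff = round(true_dff, 6),
        is_response = true_dff >= config$response_min_dff,
        files = files
      )
    }
  }
  manifest <- list(schema = "ng2ca-manifest-1", master_seed = seed,
                   n_entries = length(entries), entries = entries)
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = 8)
  writeLines(json, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
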