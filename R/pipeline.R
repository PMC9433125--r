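# End-to-end orchestration: simulate/load -> preprocess -> spectral +
# synchrony -> topography -> group statistics, with a run manifest.

#' Run the full seizure-EEG analysis
#'
#' Orchestrates the pipeline on a recording (or a simulation
#' configuration): zero-phase band-pass and notch filtering, 1-s epoching
#' around the annotated seizure onset, amplitude-based artifact rejection,
#' per-epoch Welch band powers, broadband and per-band PLV tables, mean
#' PSD / PLV time courses, per-epoch topography values with the
#' diffusion-extent time course, and Kruskal--Wallis state comparisons.
#' All tabular outputs are written as CSV, the statistics additionally as
#' JSON, plus a JSON run manifest listing every artifact.
#'
#' When the recording carries no `"ictal"` annotation, the statistics
#' stage is skipped with a warning and the remaining outputs are still
#' produced.
#'
#' @param x An [eeg_recording()] or a [sim_config()] (which is simulated
#'   first).
#' @param out_dir Output directory, created if needed. `NULL` computes
#'   everything and writes nothing.
#' @param low_hz,high_hz,notch_hz Filter settings, defaults 1, 70, 50 Hz.
#' @param amp_limit_uv Artifact rejection threshold, default 200 uV
#'   (disabled with `Inf`). Applied to non-ictal epochs only: spike-wave
#'   discharges legitimately exceed background-artifact amplitudes.
#' @param plv_bands Bands for the PLV tables, default broadband plus the
#'   five rhythms.
#' @param diffusion_level Threshold (log10 power units) for
#'   [diffusion_extent()]; the default — midway between the median and
#'   the maximum per-channel total log power — separates background from
#'   discharge-level power so the extent time course resolves the spatial
#'   spread and retreat of the discharge.
#' @param alpha Significance level for [compare_states()], default 0.05.
#' @return A `swd_run`: list with `epochs`, `band_power`, `plv`,
#'   `psd_timecourse`, `plv_timecourse`, `diffusion`, `stats`
#'   (`NULL` when skipped), `recording` (preprocessed), and `manifest`.
#' @examples
#' \donttest{
#' run <- run_analysis(sim_config(duration_s = 60, seizure_onset_s = 40,
#'   seizure_offset_s = 50, background_interval_s = c(2, 32)))
#' run$stats
#' }
#' @export
run_analysis <- function(x, out_dir = NULL, low_hz = 1, high_hz = 70,
                         notch_hz = 50, amp_limit_uv = 200,
                         plv_bands = c("broadband",
                                       as.character(eeg_bands()$band)),
                         diffusion_level = NULL, alpha = 0.05) {
  cfg <- NULL
  if (inherits(x, "sim_config")) {
    cfg <- x
    rec <- simulate_recording(cfg)
  } else if (inherits(x, "eeg_recording")) {
    rec <- x
  } else {
    stop("x must be an eeg_recording or a sim_config", call. = FALSE)
  }

  stage <- "preprocess"
  res <- tryCatch({
    rec_f <- notch_filter(bandpass_filter(rec, low_hz, high_hz), notch_hz)
    stage <- "epoching"
    epochs <- make_epochs(rec_f)
    # amplitude rejection targets background artifacts; ictal discharges
    # legitimately exceed any background threshold and are kept
    non_ictal <- as_epoch_series(epochs[epochs$state != "ictal", ], epochs)
    kept <- reject_artifact_epochs(non_ictal, amp_limit_uv)
    epochs <- as_epoch_series(
      dplyr::arrange(dplyr::bind_rows(
        epochs[epochs$state == "ictal", ], kept), .data$start_s),
      epochs)
    if (nrow(epochs) == 0) stop("all epochs rejected", call. = FALSE)

    stage <- "spectral"
    bp <- band_power_table(epochs)
    psd_tc <- mean_psd_timecourse(epochs)

    stage <- "synchrony"
    plv <- plv_table(epochs, rec = rec_f, bands = plv_bands)
    plv_tc <- mean_plv_timecourse(plv[plv$band == plv_bands[1], ])

    stage <- "topography"
    totals <- bp |>
      dplyr::group_by(.data$epoch, .data$t_rel, .data$state,
                      .data$channel) |>
      dplyr::summarise(value = log10(sum(10^.data$power)),
                       .groups = "drop")
    lev <- diffusion_level %||%
      ((stats::median(totals$value) + max(totals$value)) / 2)
    diffusion <- totals |>
      dplyr::group_by(.data$epoch, .data$t_rel, .data$state) |>
      dplyr::summarise(extent = diffusion_extent(.data$value, lev),
                       .groups = "drop")

    stage <- "stats"
    has_ictal <- any(epochs$state == "ictal") &&
      any(epochs$state == "pre_ictal") && any(epochs$state == "inter_ictal")
    stats_tbl <- NULL
    if (has_ictal) {
      stats_tbl <- dplyr::bind_rows(
        compare_states(bp, alpha = alpha),
        compare_states(plv[plv$band != "broadband", ], alpha = alpha)
      )
    } else {
      warning("statistics stage skipped: need epochs in all three states",
              call. = FALSE)
    }
    list(epochs = epochs, band_power = bp, plv = plv,
         psd_timecourse = psd_tc, plv_timecourse = plv_tc,
         channel_totals = totals, diffusion = diffusion,
         diffusion_level = lev, stats = stats_tbl, recording = rec_f)
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("swdeeg")),
    recording_id = rec$id,
    config = if (is.null(cfg)) NULL else unclass(cfg),
    filter = list(low_hz = low_hz, high_hz = high_hz, notch_hz = notch_hz),
    amp_limit_uv = amp_limit_uv,
    plv_bands = plv_bands,
    diffusion_level = res$diffusion_level,
    alpha = alpha,
    n_epochs = nrow(res$epochs),
    outputs = character()
  )
  class(res) <- "swd_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    emit <- function(obj, name) {
      p <- file.path(out_dir, name)
      readr::write_csv(obj, p)
      p
    }
    outs <- c(
      emit(res$band_power, "band_power.csv"),
      emit(res$plv, "plv.csv"),
      emit(res$psd_timecourse, "psd_timecourse.csv"),
      emit(res$plv_timecourse, "plv_timecourse.csv"),
      emit(res$diffusion, "diffusion_extent.csv")
    )
    if (!is.null(res$stats)) {
      p <- file.path(out_dir, "group_stats.json")
      jsonlite::write_json(
        res$stats |> dplyr::mutate(n_groups = purrr::map(.data$n_groups,
                                                         as.list)),
        p, auto_unbox = TRUE, digits = NA)
      outs <- c(outs, p, emit(dplyr::select(res$stats, -"n_groups"),
                              "group_stats.csv"))
    }
    res$manifest$outputs <- basename(outs)
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    res$manifest$outputs <- c(res$manifest$outputs, "manifest.json")
  }
  res
}

#' @export
print.swd_run <- function(x, ...) {
  cat(sprintf("<swd_run>  %d epochs | %d band-power rows | %d PLV rows | stats: %s\n",
              nrow(x$epochs), nrow(x$band_power), nrow(x$plv),
              if (is.null(x$stats)) "skipped" else
                sprintf("%d comparisons", nrow(x$stats))))
  invisible(x)
}
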