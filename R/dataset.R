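#' Serial-dilution sampling plan
#'
#' Replicated serial-dilution design: distinct non-negative concentrations,
#' an optional blank (0), `replicates_per_run` repeats within a run and
#' `n_runs` independent runs (the measured assays used three).
#'
#' @param concentrations Distinct concentrations (> 0), any order.
#' @param unit Concentration unit tag (`"mg/L"`, `"mg/mL"`, `"M"`).
#' @param include_blank Add a 0-concentration blank level.
#' @param replicates_per_run Repeats of each level within a run.
#' @param n_runs Independent experimental runs.
#' @param seed Integer seed from which every trace's child seed derives.
#' @return A `ggp_sample_plan` object.
#' @export
sample_plan <- function(concentrations, unit = "mg/L", include_blank = TRUE,
                        replicates_per_run = 1, n_runs = 3, seed = 1) {
  if (any(concentrations <= 0) || anyDuplicated(concentrations))
    stop_ggp("concentrations must be positive and distinct",
             "ggpgmr_validation_error")
  assert_scalar_num(n_runs, "n_runs", lower = 1)
  assert_scalar_num(replicates_per_run, "replicates_per_run", lower = 1)
  levels <- sort(concentrations, decreasing = TRUE)
  if (include_blank) levels <- c(levels, 0)
  structure(list(concentrations = levels, unit = unit,
                 include_blank = include_blank,
                 replicates_per_run = as.integer(replicates_per_run),
                 n_runs = as.integer(n_runs), seed = seed),
            class = "ggp_sample_plan")
}

assay_true_spectra <- function(assay, concentration, grid) {
  if (assay$type == "fluorescent") {
    list(t0 = fluorescence_spectrum(assay$model, concentration, grid))
  } else if (is.null(assay$kinetics)) {
    list(t0 = transmitted_spectrum(assay$model, concentration, grid))
  } else {
    kinetic_pair(assay$model, assay$kinetics, concentration, grid)
  }
}

#' Generate a replicated synthetic assay dataset
#'
#' For every run x concentration (x kinetic read time) the true spectrum is
#' built from the assay model, pushed through the transmission matrix to
#' give the GGP-GMR CCD trace (with seeded instrument noise), and recorded
#' in parallel through the reference spectrometer channel (seeded additive
#' per-bin noise plus a run-level multiplicative gain jitter). All ground
#' truth and every child seed are retained so any single measurement can be
#' regenerated bit-for-bit.
#'
#' @param plan A [sample_plan()].
#' @param assay An [assay_preset()] (or an equivalent hand-built list).
#' @param tm A [build_transmission_matrix()] for the GGP-GMR channel.
#' @param noise [noise_params()] for the CCD channel; its `seed` field is
#'   ignored in favour of per-measurement child seeds derived from the
#'   plan's seed. `NULL` for noiseless traces.
#' @param spectrometer_noise_sd Additive per-bin noise SD of the
#'   spectrometer channel (intensity units; 0 disables).
#' @param spectrometer_gain_jitter_sd SD of the run-level multiplicative
#'   gain jitter of the spectrometer channel (0 disables).
#' @return A `ggp_assay_dataset`: `index` data.frame (one row per
#'   measurement: id, run, replicate, concentration, timepoint, seeds),
#'   lists `traces` and `spectra` keyed by id, `truth` data.frame, plus the
#'   plan and assay.
#' @export
generate_dataset <- function(plan, assay, tm, noise = NULL,
                             spectrometer_noise_sd = 0,
                             spectrometer_gain_jitter_sd = 0) {
  stopifnot(inherits(plan, "ggp_sample_plan"), inherits(assay, "ggp_assay"),
            inherits(tm, "ggp_transmission_matrix"))
  grid <- tm$wavelengths
  idx <- list(); traces <- list(); spectra <- list(); truth <- list()
  id <- 0L
  for (run in seq_len(plan$n_runs)) {
    gain <- if (spectrometer_gain_jitter_sd > 0)
      with_seed(child_seed(plan$seed, run, stream = 3L),
                1 + rnorm(1, 0, spectrometer_gain_jitter_sd)) else 1
    for (conc in plan$concentrations) {
      for (rep in seq_len(plan$replicates_per_run)) {
        sps <- assay_true_spectra(assay, conc, grid)
        for (tp in names(sps)) {
          id <- id + 1L
          sp <- sps[[tp]]
          tseed <- child_seed(plan$seed, id, stream = 1L)
          sseed <- child_seed(plan$seed, id, stream = 2L)
          ns <- if (is.null(noise)) NULL else
            noise_params(noise$read_noise_sd, noise$shot_noise_scale,
                         noise$dark_offset, seed = tseed)
          traces[[id]] <- forward_readout(tm, sp, ns)
          spectra[[id]] <- if (spectrometer_noise_sd > 0 || gain != 1) {
            y <- with_seed(sseed, gain * sp$intensity +
                             rnorm(length(grid), 0, spectrometer_noise_sd))
            spectrum_sample(grid, pmax(y, 0))
          } else sp
          tr <- attr(sp, "truth")
          idx[[id]] <- data.frame(id = id, run = run, replicate = rep,
                                  concentration = conc, timepoint = tp,
                                  trace_seed = tseed, spectrum_seed = sseed)
          truth[[id]] <- data.frame(
            id = id,
            peak_nm = if (is.null(tr)) grid[which.max(sp$intensity)]
                      else tr$peak_nm,
            amplitude = if (is.null(tr)) max(sp$intensity) else tr$amplitude)
        }
      }
    }
  }
  structure(list(index = do.call(rbind, idx), traces = traces,
                 spectra = spectra, truth = do.call(rbind, truth),
                 plan = plan, assay = assay,
                 noise = noise,
                 spectrometer_noise_sd = spectrometer_noise_sd,
                 spectrometer_gain_jitter_sd = spectrometer_gain_jitter_sd),
            class = "ggp_assay_dataset")
}

#' @export
print.ggp_assay_dataset <- function(x, ...) {
  cat(sprintf("assay dataset '%s': %d measurements (%d runs x %d levels%s)\n",
              x$assay$name, nrow(x$index), x$plan$n_runs,
              length(x$plan$concentrations),
              if (any(x$index$timepoint != "t0")) " x kinetic timepoints" else ""))
  invisible(x)
}

#' Regenerate one measurement from the seed ledger
#'
#' Rebuilds the GGP-GMR trace of measurement `id` from its recorded child
#' seed and the dataset's plan; used to verify ledger completeness.
#'
#' @param dataset A [generate_dataset()] result.
#' @param id Measurement id.
#' @param tm The transmission matrix the dataset was generated with.
#' @return A [ccd_trace()], bit-identical to `dataset$traces[[id]]`.
#' @export
regenerate_trace <- function(dataset, id, tm) {
  row <- dataset$index[dataset$index$id == id, ]
  if (nrow(row) != 1L)
    stop_ggp("unknown measurement id", "ggpgmr_validation_error")
  sps <- assay_true_spectra(dataset$assay, row$concentration, tm$wavelengths)
  sp <- sps[[row$timepoint]]
  ns <- if (is.null(dataset$noise)) NULL else
    noise_params(dataset$noise$read_noise_sd, dataset$noise$shot_noise_scale,
                 dataset$noise$dark_offset, seed = row$trace_seed)
  forward_readout(tm, sp, ns)
}
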