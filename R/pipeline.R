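#' Pipeline configuration
#'
#' Validated bundle of all stage parameters for [run_pipeline()]. Binarization
#' thresholds are restricted to the two values used throughout the analysis
#' (0 and 1 z-units).
#'
#' @param bands band layout tibble (`band`, `low`, `high`).
#' @param montage `"referential"`, `"global"` or `"local"`.
#' @param threshold binarization threshold, 0 or 1.
#' @param downsample state decimation factor.
#' @param window_s wavelet segment length (s).
#' @param fit a [fit_config()].
#' @param n_null number of geometric nulls for permutation testing.
#' @param fc_segment_s segment length for segmented FC estimators (s).
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(bands = default_bands(), montage = "referential",
                            threshold = 0, downsample = 10, window_s = 100,
                            fit = fit_config(), n_null = 200,
                            fc_segment_s = 3600, seed = 1L) {
  if (!all(c("band", "low", "high") %in% names(bands)))
    abort_invalid("bands must have columns band, low, high")
  if (any(bands$low >= bands$high)) abort_invalid("band low must be < high")
  if (!montage %in% c("referential", "global", "local"))
    abort_invalid("montage must be referential, global or local")
  if (!threshold %in% c(0, 1))
    abort_invalid("threshold must be 0 or 1")
  if (downsample < 1) abort_invalid("downsample must be >= 1")
  if (!inherits(fit, "fit_config")) abort_invalid("fit must be a fit_config()")
  if (n_null < 1) abort_invalid("n_null must be >= 1")
  structure(list(bands = bands, montage = montage, threshold = threshold,
                 downsample = as.integer(downsample), window_s = window_s,
                 fit = fit, n_null = as.integer(n_null),
                 fc_segment_s = fc_segment_s, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_entry <- function(name, obj) {
  tibble::tibble(stage = name, checksum = rlang::hash(obj))
}

#' Run the full structure-function coupling pipeline
#'
#' Executes the stages in order: montage re-referencing, wavelet band power,
#' binarization into power-amplitude states, one-electrode-per-region
#' selection, empirical moments, pseudo-likelihood model fit, the comparison
#' functional connectivity suite (co-activation, Pearson and partial
#' correlation of band power, PLV/PLI/WPLI of the band-passed signal),
#' geometric structural nulls, coupling statistics (structure-function
#' correlation and ROC AUC with one-sided permutation p against the nulls and
#' FDR correction across bands), and the goodness-of-fit divergence. A
#' manifest of per-stage content hashes makes reruns verifiable.
#'
#' @param rec a [recording()] with electrode coordinates.
#' @param con a [connectome()] over the full atlas.
#' @param electrode_to_region integer map electrode -> atlas region.
#' @param config a [pipeline_config()].
#' @return a list of class `mem_pipeline` with elements `states`, `fits`,
#'   `fc`, `nulls`, `coupling` (tibble of per-band, per-method results),
#'   `gof`, `selected`, `manifest` and `config`.
#' @export
run_pipeline <- function(rec, con, electrode_to_region, config = pipeline_config()) {
  stopifnot(inherits(rec, "recording"), inherits(con, "connectome"),
            inherits(config, "pipeline_config"))
  manifest <- list()

  rec_m <- apply_montage(rec, config$montage)
  manifest[[1]] <- stage_entry("montage", rec_m$montage)

  bp <- wavelet_band_power(rec_m, bands = config$bands,
                           window_s = config$window_s)
  manifest[[2]] <- stage_entry("band_power", lapply(bp, function(b) b$power))

  states <- lapply(bp, binarize_power, threshold = config$threshold,
                   downsample = config$downsample)
  manifest[[3]] <- stage_entry("states", lapply(states, function(s) s$states))

  sel <- select_roi_electrodes(rec$coords, con$centroids, electrode_to_region)
  regions <- electrode_to_region[sel]
  states <- lapply(states, function(s) {
    binary_states(s$states[sel, , drop = FALSE], band = s$band,
                  threshold = s$threshold, downsample = s$downsample,
                  montage = s$montage, labels = s$labels[sel])
  })
  manifest[[4]] <- stage_entry("electrode_selection", sel)

  moments <- lapply(states, compute_moments)
  manifest[[5]] <- stage_entry("moments", moments)

  fits <- lapply(states, fit_pseudolikelihood, cfg = config$fit)
  manifest[[6]] <- stage_entry("mem_fit", lapply(fits, function(f) f$J))

  band_names <- config$bands$band
  fc <- list()
  for (b in seq_along(band_names)) {
    bn <- band_names[b]
    edges <- c(config$bands$low[b], config$bands$high[b])
    pw_sel <- bp[[b]]$power[sel, , drop = FALSE]
    fc[[bn]] <- list(
      mem = fc_matrix(fits[[b]]$J, "mem", band = bn, montage = rec_m$montage),
      coactivation = coactivation_fc(states[[b]], mode = "rate"),
      pearson = pearson_fc(pw_sel, band = bn, montage = rec_m$montage),
      partial_correlation = partial_correlation_fc(
        pw_sel, fs = rec$fs, segment_s = config$fc_segment_s,
        band = bn, montage = rec_m$montage),
      plv = phase_fc(recording(rec_m$signal[sel, , drop = FALSE], rec$fs,
                               coords = rec$coords[sel, , drop = FALSE],
                               montage = rec_m$montage),
                     edges, "plv", segment_s = config$fc_segment_s,
                     band_name = bn),
      pli = phase_fc(recording(rec_m$signal[sel, , drop = FALSE], rec$fs,
                               coords = rec$coords[sel, , drop = FALSE],
                               montage = rec_m$montage),
                     edges, "pli", segment_s = config$fc_segment_s,
                     band_name = bn),
      wpli = phase_fc(recording(rec_m$signal[sel, , drop = FALSE], rec$fs,
                                coords = rec$coords[sel, , drop = FALSE],
                                montage = rec_m$montage),
                      edges, "wpli", segment_s = config$fc_segment_s,
                      band_name = bn)
    )
  }
  manifest[[7]] <- stage_entry("fc_suite", lapply(fc, function(l)
    lapply(l, unclass)))

  nulls <- lapply(seq_len(config$n_null), function(k)
    geometric_null(con, regions, seed = derive_seed(config$seed, 1000 + k)))
  manifest[[8]] <- stage_entry("geometric_nulls",
                               lapply(nulls, function(x) x$null_idx))

  sc_emp <- con$counts[regions, regions]
  sc_emp_log <- normalize_streamlines(sc_emp)
  rows <- list()
  for (bn in band_names) {
    for (meth in names(fc[[bn]])) {
      f <- fc[[bn]][[meth]]
      r_obs <- structure_function_correlation(f, sc_emp_log)
      auc_obs <- roc_auc(f, sc_emp)$auc
      # nulls with an empty or constant streamline submatrix give NA and are
      # excluded from the permutation distribution
      r_null <- vapply(nulls, function(nu) suppressWarnings(
        structure_function_correlation(f, normalize_streamlines(nu$null_counts))),
        numeric(1))
      auc_null <- vapply(nulls, function(nu) {
        adj <- nu$null_counts > 0
        if (all(adj[upper.tri(adj)]) || !any(adj[upper.tri(adj)])) NA_real_
        else roc_auc(f, nu$null_counts)$auc
      }, numeric(1))
      rows[[length(rows) + 1]] <- tibble::tibble(
        band = bn, method = meth,
        r_structure_function = r_obs, auc = auc_obs,
        p_perm_r = permutation_test(r_obs, stats::na.omit(r_null)),
        p_perm_auc = permutation_test(auc_obs, auc_null[!is.na(auc_null)]),
        n_null = config$n_null)
    }
  }
  coupling <- dplyr::bind_rows(rows)
  coupling <- coupling |>
    dplyr::group_by(.data$method) |>
    dplyr::mutate(q_fdr_r = fdr_correct(.data$p_perm_r),
                  q_fdr_auc = fdr_correct(.data$p_perm_auc)) |>
    dplyr::ungroup()
  manifest[[9]] <- stage_entry("coupling", coupling)

  gof <- purrr::map_dfr(band_names, function(bn) {
    tab <- tryCatch(estimate_state_probabilities(fits[[bn]], states[[bn]]),
                    memfc_error_silent_state = function(e) NULL)
    if (is.null(tab))
      tibble::tibble(band = bn, divergence = NA_real_, n_states = NA_integer_,
                     z_hat = NA_real_, silent_observed = FALSE)
    else
      tibble::tibble(band = bn,
                     divergence = modified_kl_divergence(tab$p_empirical,
                                                         tab$p_model),
                     n_states = nrow(tab), z_hat = attr(tab, "z_hat"),
                     silent_observed = TRUE)
  })
  manifest[[10]] <- stage_entry("goodness_of_fit", gof)

  structure(list(states = states, fits = fits, fc = fc, nulls = nulls,
                 coupling = coupling, gof = gof,
                 selected = tibble::tibble(electrode = sel, region = regions),
                 manifest = dplyr::bind_rows(manifest), config = config),
            class = "mem_pipeline")
}

#' @export
print.mem_pipeline <- function(x, ...) {
  cat(sprintf("<mem_pipeline> %d bands x %d methods, %d channels, %d nulls\n",
              length(x$fits), length(x$fc[[1]]), nrow(x$selected),
              x$config$n_null))
  print(x$coupling)
  invisible(x)
}

#' End-to-end demonstration on a synthetic patient
#'
#' Generates a synthetic patient (atlas, clustered electrodes, distance-
#' decaying structural connectome, a planted pairwise model whose interactions
#' track the log-normalized streamline counts), samples states from the
#' planted model, synthesizes a band-limited recording modulated by those
#' states, and runs [run_pipeline()]. Returns the results bundle with the
#' planted ground truth attached for recovery checks.
#'
#' @param seed integer master seed.
#' @param n_atlas,n_electrodes synthetic brain size.
#' @param hours recording duration in hours.
#' @param bands band layout (defaults to theta and alpha).
#' @param coupling_scale planted structure-coupling strength (0 plants an
#'   independent model).
#' @param target_rate planted mean activation rate.
#' @param fs sampling rate of the synthesized recording.
#' @param state_dt planted state duration (s).
#' @param n_null geometric nulls for the permutation tests.
#' @param threshold binarization threshold (0 or 1).
#' @param montage montage to analyse under.
#' @param noise forward-model noise amplitudes (see
#'   [synthesize_recording()]).
#' @param fit a [fit_config()].
#' @return a `mem_pipeline` bundle with attribute `ground_truth`.
#' @export
demo_synthetic <- function(seed = 1, n_atlas = 200, n_electrodes = 20,
                           hours = 2, bands = default_bands()[1:2, ],
                           coupling_scale = 0.5, target_rate = 0.3,
                           fs = 64, state_dt = 0.5, n_null = 200,
                           threshold = 1, montage = "referential",
                           noise = list(reference_amp = 0.25,
                                        local_shared_amp = 0.25,
                                        pink_amp = 0.25),
                           fit = fit_config(max_iter = 20000)) {
  brain <- generate_geometry(n_atlas, n_electrodes, seed = derive_seed(seed, 1))
  con <- generate_structural_connectome(brain, seed = derive_seed(seed, 2))
  truth <- derive_ground_truth_mem(con, brain$electrode_to_region,
                                   coupling_scale = coupling_scale,
                                   target_rate = target_rate,
                                   seed = derive_seed(seed, 3))
  Tst <- round(hours * 3600 / state_dt)
  st <- sample_states(truth, Tst, method = "metropolis",
                      seed = derive_seed(seed, 4), burn_in = 500, thin = 5)

  sig <- 0
  for (b in seq_len(nrow(bands))) {
    r <- synthesize_recording(st, band = c(bands$low[b], bands$high[b]),
                              fs = fs, state_dt = state_dt, noise = noise,
                              seed = derive_seed(seed, 10 + b),
                              coords = brain$electrode_coords)
    sig <- sig + r$signal
  }
  rec <- recording(sig, fs, coords = brain$electrode_coords)

  cfg <- pipeline_config(bands = bands, montage = montage,
                         threshold = threshold, fit = fit, n_null = n_null,
                         seed = derive_seed(seed, 20))
  out <- run_pipeline(rec, con, brain$electrode_to_region, cfg)
  attr(out, "ground_truth") <- list(brain = brain, connectome = con,
                                    mem = truth, states = st)
  out
}
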