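#' Default pipeline configuration
#'
#' Returns the full nested configuration list used throughout the pipeline.
#' Every tunable constant lives here so that preprocessing, detection,
#' feature extraction, model training and the bradycardia rule can be
#' re-parameterized without touching code.  Values fall into two groups:
#' decision constants taken from the published method (alarm-at-300-s
#' convention, 2-s flat line, 46-bpm bradycardia threshold, 301 trees,
#' the 1.2x feature-count rule, FN-cost grid covering 1-1.4) and
#' engineering defaults chosen here (envelope bands, SSF window, plateau
#' tolerance) that the method names but does not print.
#'
#' @return A nested list with sections `preprocess`, `detect`, `features`,
#'   `model`, `brady`, and `synth`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$brady$threshold_bpm
default_config <- function() {
  list(
    alarm_time_s = 300,
    preprocess = list(
      flat_min_duration_s = 2.0,   # constant value for at least 2 s => probe disconnection
      flat_tol = 0,                # exact sample repetition in raw units
      baseline_order = 5L,
      bp = list(
        systolic_max_mmHg = 300,
        diastolic_min_mmHg = 20,
        map_min_mmHg = 30,
        map_max_mmHg = 200,
        pulse_pressure_min_mmHg = 20,
        neg_slope_max_mmHg_per_s = -400,  # mean negative slope steeper than -40 mmHg/100 ms
        delta_sys_max_mmHg = 20,
        delta_dia_max_mmHg = 20,
        # implemented but disabled: heart-rate range and beat-period change
        use_hr_criterion = FALSE,
        hr_range_bpm = c(20, 200),
        use_period_criterion = FALSE,
        delta_period_max_s = 0.5
      )
    ),
    detect = list(
      ssf_window_s = 0.128,
      pulse_delay_s = NULL,        # NULL => one SSF window (group-delay correction)
      refractory_s = 0.2,          # 300 bpm physiological ceiling
      qrs_scale = 2L,              # dyadic wavelet scale used for QRS candidate search
      pulse_scale = 3L,            # wider scale for SSF-of-SSF bumps
      threshold_rms_factor = 2.0,
      searchback_factor = 1.66,
      pair_window_s = 0.12,
      bands = list(low = c(0.5, 6), qrs = c(5, 25), high = c(40, 110)),
      envelope_smooth_s = 0.05,
      kappa_pacing = 1.2,          # high-band / QRS-band envelope ratio for pacing spikes
      kappa_twave = 0.3,           # QRS-band envelope vs median of accepted beats
      vt_width_s = 0.14,           # QRS-band envelope above half local max for > 140 ms
      vt_high_ratio = 0.8
    ),
    features = list(
      windows = list(              # analysis window per alarm type, seconds from record start
        ASYSTOLE    = c(284, 300),
        BRADYCARDIA = c(280, 300),
        TACHYCARDIA = c(280, 300),
        VFIB        = c(293, 300),   # matches the earliest augmented start
        VTACH       = c(290, 300)
      ),
      vf_augment_starts_s = c(293, 294, 295, 296),  # true-VF training windows, each to 300 s
      template_half_window_s = 0.25,
      sharpness_half_window_s = 0.06,
      stability_band = 0.30,
      periodicity_lag_s = c(0.24, 2.4),   # 25-250 bpm
      swing_sub_window_s = 1.0,
      spectral_band_hz = c(0.5, 15),
      rate_resolution_bpm = 0.1    # measured rates quantized before threshold comparisons
    ),
    model = list(
      n_trees = 301L,
      cost_fp = 1.0,
      cost_fn_grid = seq(1.0, 2.0, by = 0.1),
      selection_repeats = 5L,
      plateau_tol = 0.5,           # score units on the median curve
      max_k = 10L,                 # forward-selection curve length cap
      expand_factor = 1.2          # final feature count = ceil(1.2 * x)
    ),
    brady = list(
      threshold_bpm = 46,
      run_beats = 4L
    ),
    synth = list(
      fs = 250,
      duration_s = 300,
      base_hr_bpm = 75
    )
  )
}

#' Load configuration from a YAML file
#'
#' Reads a YAML file and merges it over [default_config()]; keys absent from
#' the file keep their defaults.  Merging is recursive, so a file may override
#' a single leaf (e.g. `brady: {threshold_bpm: 50}`).
#'
#' @param path Path to a YAML configuration file, or `NULL` for defaults.
#' @return The merged configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  modify_list_deep(cfg, user)
}

modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]   # unnamed lists (e.g. burst specs) replace
    }
  }
  base
}

# Derive a component seed from a master seed; keeps results < 2^31 and makes
# each pipeline stage draw from an independent stream.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + offset) %% .Machine$integer.max)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
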