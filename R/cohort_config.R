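#' Default clinical distribution parameters
#'
#' Per-variable location/spread targets for the clinical block of the synthetic
#' cohort, given separately for the COPD and control arms. Each entry is a list
#' with `median`, `q1`, `q3` (interquartile targets) and `lo`, `hi` (truncation
#' limits, taken from the observed ranges of the emulated study population),
#' plus a `dist` tag: `"tnorm"` (truncated normal moment-matched to the
#' median/IQR), `"lnorm"` (log-normal, for right-skewed variables) or
#' `"nbinom"` (over-dispersed count; `q1`/`q3` reinterpreted as `mu`/`size`).
#'
#' Spirometry medians/IQRs mirror a typical severe-COPD clinic population:
#' e.g. FEV1 29% predicted (IQR 22-39) in patients vs 92% (87-102) in healthy
#' never-smoker controls.
#'
#' @return Named list with elements `copd` and `control`, each a named list of
#'   per-variable parameter lists.
#' @export
default_clinical_params <- function() {
  v <- function(median, q1, q3, lo, hi, dist = "tnorm") {
    list(median = median, q1 = q1, q3 = q3, lo = lo, hi = hi, dist = dist)
  }
  list(
    copd = list(
      age        = v(67, 58, 72, 42, 78),
      bmi        = v(26, 23, 31, 19, 46),
      fvc_l      = v(2.0, 1.5, 2.5, 1.0, 5.1),
      fvc_pct    = v(47, 39, 57, 29, 83),
      fev1_l     = v(1.0, 0.8, 1.2, 0.5, 2.7),
      fev1_pct   = v(29, 22, 39, 14, 81),
      pef        = v(149, 125, 229, 85, 466),
      pef_pct    = v(27, 23, 39, 14, 80),
      # truncated strictly below the diagnostic 0.7 cut-off
      fev1_fvc   = v(0.49, 0.42, 0.65, 0.35, 0.699),
      dlco       = v(4.9, 2.6, 5.8, 1.9, 8.4),
      pack_years = v(40, 27, 53, 5, 84, dist = "lnorm"),
      mmrc       = v(2, 2, 3, 1, 4),
      # mu / size of a negative binomial; exacerbations in last 12 months
      exacerbations = v(2, 1.9, 8, 0, Inf, dist = "nbinom")
    ),
    control = list(
      age        = v(37, 27, 62, 23, 74),
      bmi        = v(24, 23, 26, 22, 37),
      fvc_l      = v(3.6, 3.1, 4.5, 2.6, 6.7),
      fvc_pct    = v(89, 86, 109, 84, 129),
      fev1_l     = v(3.3, 2.5, 3.6, 2.1, 5.4),
      fev1_pct   = v(92, 87, 102, 83, 122),
      pef        = v(403, 347, 535, 296, 701),
      pef_pct    = v(94, 81, 102, 75, 108),
      fev1_fvc   = v(0.81, 0.80, 0.83, 0.77, 0.93),
      dlco       = v(7.4, 6.1, 7.7, 4.7, 11.2)
      # pack_years, mmrc, exacerbations: structurally 0 for never-smoker controls
    )
  )
}

#' Default comorbidity/medication flag prevalences (COPD arm)
#'
#' Bernoulli prevalences for the dichotomous patient characteristics; controls
#' carry `FALSE` for all of them. Smoking status is handled separately as a
#' three-level categorical (current/ex/never with probabilities 0.40/0.56/0.04).
#'
#' @return Named numeric vector of prevalences in \[0,1\].
#' @export
default_flag_prevalence <- function() {
  c(
    emphysema              = 0.52,
    laba                   = 0.96,
    lama                   = 0.80,
    ics                    = 0.80,
    theophylline           = 0.68,
    oxygen                 = 0.40,
    heart_failure          = 0.48,
    coronary_heart_disease = 0.28,
    hypertension           = 0.44,
    asthma                 = 0.28,
    pulmonary_hypertension = 0.16,
    sleep_apnea            = 0.04,
    diabetes               = 0.08,
    osteoporosis           = 0.08,
    depression             = 0.16
  )
}

#' Default planted-effect table
#'
#' Each row plants one standardized log-scale effect in the synthetic cohort.
#' `target` is an analyte name (e.g. `"Kynurenine"`), an analyte class
#' (`"class:SM"`, `"class:SM(OH)"`, `"class:PUFA-PC"`, `"class:lysoPC"`) or an
#' untargeted spectral signal (`"mz:serum:neg:327"`). `contrast` is `"COPD"`
#' (patients vs controls) or `"GOLD:X"` (stratum X vs the other COPD strata).
#' `effect` is the shift in units of the analyte's log-scale SD; positive means
#' elevated in the contrast group.
#'
#' Defaults encode the disease signatures the package is designed to recover:
#' sphingomyelins and hydroxylated sphingomyelins decreased in COPD, PUFA-rich
#' phosphatidylcholines (total acyl C36-C40, >= 2 double bonds) decreased,
#' lysoPCs elevated; lysoPCs additionally high in GOLD A, kynurenine high in
#' GOLD B, putrescine up / ornithine down in GOLD C (so the putrescine/Orn
#' ratio is high and Orn/Ser low in C); serum-negative m/z 327/367/368 shifted
#' between COPD and controls, m/z 1069/1317 high in GOLD B and serum-positive
#' m/z 259 high in GOLD A.
#'
#' @return `data.frame` with columns `target`, `contrast`, `effect`.
#' @export
default_effect_table <- function() {
  data.frame(
    target = c(
      "class:SM", "class:SM(OH)", "class:PUFA-PC", "class:lysoPC",
      "class:lysoPC", "Kynurenine", "Putrescine", "Orn",
      "mz:serum:neg:327", "mz:serum:neg:367", "mz:serum:neg:368",
      "mz:serum:neg:1069", "mz:serum:neg:1317", "mz:serum:pos:259"
    ),
    contrast = c(
      "COPD", "COPD", "COPD", "COPD",
      "GOLD:A", "GOLD:B", "GOLD:C", "GOLD:C",
      "COPD", "COPD", "COPD",
      "GOLD:B", "GOLD:B", "GOLD:A"
    ),
    effect = c(
      -1.2, -1.2, -0.9, 0.8,
      1.0, 1.0, 1.0, -0.8,
      1.2, 1.2, 1.2,
      1.3, 1.3, 1.3
    ),
    stringsAsFactors = FALSE
  )
}

#' Configure a synthetic cohort
#'
#' Bundles every tunable of the synthetic-cohort generator. The defaults are
#' the study conditions the package emulates: 25 COPD patients (all male,
#' GOLD A-D split 2/2/4/17) and 21 healthy never-smoker controls (9 M / 12 F),
#' clinical variables matched to the published medians/IQRs, a targeted
#' metabolite panel with the planted COPD and GOLD-stratum signatures of
#' [default_effect_table()], and untargeted serum/EBC peak lists with
#' multiplicative spectrum-level batch noise that TIC normalization removes.
#'
#' @param n_copd,n_control Arm sizes (non-negative integers).
#' @param gold_counts Named counts for GOLD categories A-D; must sum to
#'   `n_copd`.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   `(config, seed)`.
#' @param effect_table Planted effects, see [default_effect_table()]. An empty
#'   `data.frame` yields a null cohort (groups identical in law).
#' @param clinical_params See [default_clinical_params()].
#' @param flag_prevalence See [default_flag_prevalence()].
#' @param batch_scale_sd SD of the spectrum-level log-normal scale factor
#'   (multiplies every peak of a spectrum; emulates batch/injection variation).
#' @param noise_sd SD of per-peak log-intensity noise; planted spectral effects
#'   are expressed in units of this SD.
#' @param targeted_sdlog Log-scale SD of targeted analyte concentrations.
#' @param n_peaks Peaks per (matrix, mode) channel before planted signals.
#' @param subtype_k Number of latent COPD subtypes to plant (0 = none). When
#'   `>= 2`, COPD subjects are split into `subtype_k` balanced latent classes
#'   and each class gets its own marker set (a slice of the targeted panel plus
#'   dedicated serum-negative m/z markers) shifted up by `subtype_effect`.
#' @param subtype_effect Standardized log-scale shift of subtype markers.
#' @param smoking_probs Probabilities of current/ex/never smoking status in
#'   the COPD arm (controls are never-smokers by inclusion).
#' @param control_male_fraction Fraction of males among controls (the COPD arm
#'   is all male).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_copd = 25, n_control = 21,
                          gold_counts = c(A = 2, B = 2, C = 4, D = 17),
                          seed = 1L,
                          effect_table = default_effect_table(),
                          clinical_params = default_clinical_params(),
                          flag_prevalence = default_flag_prevalence(),
                          batch_scale_sd = 0.5,
                          noise_sd = 0.4,
                          targeted_sdlog = 0.3,
                          n_peaks = 400,
                          subtype_k = 0,
                          subtype_effect = 0,
                          smoking_probs = c(current = 0.40, ex = 0.56,
                                            never = 0.04),
                          control_male_fraction = 9 / 21) {
  cfg <- list(
    n_copd = as.integer(n_copd), n_control = as.integer(n_control),
    gold_counts = gold_counts, seed = as.integer(seed),
    effect_table = effect_table, clinical_params = clinical_params,
    flag_prevalence = flag_prevalence,
    batch_scale_sd = batch_scale_sd, noise_sd = noise_sd,
    targeted_sdlog = targeted_sdlog, n_peaks = as.integer(n_peaks),
    subtype_k = as.integer(subtype_k), subtype_effect = subtype_effect,
    smoking_probs = smoking_probs,
    control_male_fraction = control_male_fraction
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid cohort_config field '%s': %s", field, why),
         call. = FALSE)
  }
  if (is.na(cfg$n_copd) || cfg$n_copd < 0) bad("n_copd", "must be >= 0")
  if (is.na(cfg$n_control) || cfg$n_control < 0) bad("n_control", "must be >= 0")
  if (!identical(sort(names(cfg$gold_counts)), c("A", "B", "C", "D")))
    bad("gold_counts", "must be named A, B, C, D")
  if (any(cfg$gold_counts < 0)) bad("gold_counts", "must be non-negative")
  if (sum(cfg$gold_counts) != cfg$n_copd)
    bad("gold_counts", sprintf("must sum to n_copd (%d)", cfg$n_copd))
  if (!is.finite(cfg$batch_scale_sd) || cfg$batch_scale_sd < 0)
    bad("batch_scale_sd", "must be a non-negative real")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd < 0)
    bad("noise_sd", "must be a non-negative real")
  if (!is.finite(cfg$targeted_sdlog) || cfg$targeted_sdlog <= 0)
    bad("targeted_sdlog", "must be > 0")
  if (cfg$n_peaks < 1) bad("n_peaks", "must be >= 1")
  if (cfg$subtype_k < 0 || cfg$subtype_k == 1)
    bad("subtype_k", "must be 0 or >= 2")
  for (arm in names(cfg$clinical_params)) {
    for (vn in names(cfg$clinical_params[[arm]])) {
      p <- cfg$clinical_params[[arm]][[vn]]
      if (p$dist == "tnorm" && p$q3 <= p$q1)
        bad(paste0("clinical_params$", arm, "$", vn), "spread (q3 - q1) must be > 0")
    }
  }
  if (any(cfg$flag_prevalence < 0 | cfg$flag_prevalence > 1))
    bad("flag_prevalence", "prevalences must lie in [0, 1]")
  if (length(cfg$smoking_probs) != 3 || any(cfg$smoking_probs < 0) ||
      abs(sum(cfg$smoking_probs) - 1) > 1e-8)
    bad("smoking_probs", "must be three probabilities summing to 1")
  if (cfg$control_male_fraction < 0 || cfg$control_male_fraction > 1)
    bad("control_male_fraction", "must lie in [0, 1]")
  if (nrow(cfg$effect_table) > 0 &&
      !all(c("target", "contrast", "effect") %in% names(cfg$effect_table)))
    bad("effect_table", "needs columns target, contrast, effect")
  invisible(cfg)
}

#' Configure a structureless (null) cohort
#'
#' A cohort in which the COPD/control and GOLD labels carry no information:
#' both arms share the control clinical distributions, every subject is a male
#' never-smoker without comorbidity/medication flags, and the effect table is
#' empty. Group and GOLD labels are still assigned, so the full workflow runs;
#' they are simply unrelated to the data. Used to calibrate the acceptance rule
#' (a sound rule accepts nothing here) and the type-I error of the univariate
#' tests.
#'
#' @param seed Integer seed.
#' @param ... Further arguments passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(seed = 1L, ...) {
  cp <- default_clinical_params()
  shared <- cp$control
  const0 <- list(median = 0, q1 = 0, q3 = 0, lo = 0, hi = 0, dist = "const")
  copd <- shared
  copd$pack_years <- const0
  copd$mmrc <- const0
  copd$exacerbations <- const0
  cohort_config(
    seed = seed,
    effect_table = default_effect_table()[0, ],
    clinical_params = list(copd = copd, control = shared),
    flag_prevalence = 0 * default_flag_prevalence(),
    smoking_probs = c(current = 0, ex = 0, never = 1),
    control_male_fraction = 1,
    ...
  )
}
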