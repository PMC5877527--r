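#' The targeted metabolite panel
#'
#' Panel of serum analytes quantified absolutely (concentrations in micromolar)
#' by the targeted assay the generator emulates: amino acids, biogenic amines,
#' acylcarnitines, lyso-, diacyl- and acyl-alkyl-phosphatidylcholines,
#' sphingomyelins and hydroxylated sphingomyelins, and total hexose. `location`
#' is the analyte's typical serum concentration (geometric mean, in micromolar);
#' published studies report significance rather than analyte-level means, so
#' locations are conventional values for adult serum.
#'
#' @return `data.frame` with columns `analyte`, `class`, `location`.
#' @export
targeted_panel <- function() {
  p <- function(class, ...) {
    x <- c(...)
    data.frame(analyte = names(x), class = class, location = unname(x),
               stringsAsFactors = FALSE)
  }
  rbind(
    p("amino_acid",
      Ala = 400, Arg = 100, Asn = 40, Asp = 10, Cit = 30, Gln = 600, Glu = 60,
      Gly = 250, His = 80, Ile = 60, Leu = 120, Lys = 180, Met = 25, Orn = 60,
      Phe = 60, Pro = 180, Ser = 110, Thr = 130, Trp = 60, Tyr = 70, Val = 230),
    p("biogenic_amine",
      Kynurenine = 2.5, Putrescine = 0.15, Serotonin = 0.6, Taurine = 60,
      ADMA = 0.5, Spermidine = 0.15),
    p("acylcarnitine",
      `Carnitine C0` = 35, `Carnitine C2` = 8, `Carnitine C16` = 0.1,
      `Carnitine C18:1` = 0.12, `Carnitine C18:2` = 0.05),
    p("lysoPC",
      `lysoPC a C16:0` = 90, `lysoPC a C17:0` = 2, `lysoPC a C18:0` = 25,
      `lysoPC a C18:1` = 20, `lysoPC a C18:2` = 25, `lysoPC a C26:1` = 0.2),
    p("PC_aa",
      `PC aa C32:0` = 15, `PC aa C34:1` = 230, `PC aa C34:2` = 380,
      `PC aa C36:2` = 220, `PC aa C36:3` = 150, `PC aa C36:4` = 200,
      `PC aa C38:4` = 110, `PC aa C38:6` = 80, `PC aa C40:6` = 25,
      `PC aa C42:0` = 0.5, `PC aa C42:2` = 0.2),
    p("PC_ae",
      `PC ae C34:3` = 8, `PC ae C36:3` = 7, `PC ae C38:3` = 4,
      `PC ae C40:6` = 4),
    p("SM",
      `SM C16:0` = 110, `SM C16:1` = 15, `SM C18:0` = 25, `SM C18:1` = 10,
      `SM C20:2` = 0.4, `SM C22:3` = 0.3, `SM C24:0` = 20, `SM C24:1` = 50),
    p("SM_OH",
      `SM (OH) C14:1` = 6, `SM (OH) C16:1` = 4, `SM (OH) C22:1` = 10,
      `SM (OH) C22:2` = 12, `SM (OH) C24:1` = 1.5),
    p("hexose", Hexose = 4500)
  )
}

#' @keywords internal
#' @noRd
acyl_spec <- function(analyte) {
  # parse "... C<len>:<db>" into total acyl length and double bonds
  m <- regmatches(analyte, regexec("C([0-9]+):([0-9]+)$", analyte))[[1]]
  if (length(m) == 0) return(c(NA_real_, NA_real_))
  as.numeric(m[2:3])
}

# analyte indices matched by an effect-table target (no "mz:" targets here)
resolve_targets <- function(targets, panel) {
  idx <- lapply(targets, function(tg) {
    if (tg == "class:SM") which(panel$class == "SM")
    else if (tg == "class:SM(OH)") which(panel$class == "SM_OH")
    else if (tg == "class:lysoPC") which(panel$class == "lysoPC")
    else if (tg == "class:PUFA-PC") {
      which(panel$class %in% c("PC_aa", "PC_ae") &
              vapply(panel$analyte, function(a) {
                s <- acyl_spec(a)
                !is.na(s[1]) && s[1] >= 36 && s[1] <= 40 && s[2] >= 2
              }, logical(1)))
    } else which(panel$analyte == tg)
  })
  unknown <- targets[lengths(idx) == 0]
  if (length(unknown) > 0)
    stop("effect_table names unknown analytes/classes: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  idx
}

# truncated-normal sampler by quantile inversion (fixed RNG draw count)
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

rtlnorm <- function(n, meanlog, sdlog, lo, hi) {
  u <- stats::runif(n, stats::plnorm(lo, meanlog, sdlog),
                    stats::plnorm(hi, meanlog, sdlog))
  stats::qlnorm(u, meanlog, sdlog)
}

sample_clinical_var <- function(n, p) {
  if (p$dist == "const") {
    rep(p$median, n)
  } else if (p$dist == "lnorm") {
    sdlog <- (log(p$q3) - log(p$q1)) / (2 * stats::qnorm(0.75))
    rtlnorm(n, log(p$median), sdlog, p$lo, p$hi)
  } else if (p$dist == "nbinom") {
    stats::rnbinom(n, mu = p$q1, size = p$q3)
  } else {
    sd <- (p$q3 - p$q1) / (2 * stats::qnorm(0.75))
    rtnorm(n, p$median, sd, p$lo, p$hi)
  }
}

#' Generate the clinical/demographic block of a synthetic cohort
#'
#' Draws one record per subject. COPD subjects are all male (as in the emulated
#' study population, which also drives the sex-sensitivity analysis), carry a
#' GOLD A-D label per `config$gold_counts`, a post-bronchodilator FEV1/FVC
#' strictly below 0.7, smoking history (40% current / 56% ex / 4% never
#' smokers) and Bernoulli comorbidity/medication flags. Controls are healthy
#' never-smokers (pack-years 0, no flags, `gold = "none"`) with roughly 43%
#' males. Continuous variables are truncated-normal (log-normal for pack-years,
#' negative-binomial for exacerbation counts) moment-matched to the configured
#' median/IQR targets.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; `NULL` continues the current RNG stream.
#' @return `data.frame` with one row per subject. Includes the latent `subtype`
#'   column (0 = none) when `config$subtype_k >= 2`; this is ground truth, not
#'   a clinical variable, and is never used as an analysis feature.
#' @export
generate_clinical <- function(config, seed = NULL) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  n_copd <- config$n_copd
  n_ctrl <- config$n_control
  n <- n_copd + n_ctrl

  cp <- config$clinical_params
  draw_arm <- function(n_arm, params) {
    out <- lapply(params, function(p) sample_clinical_var(n_arm, p))
    as.data.frame(out)
  }

  vars <- c("age", "bmi", "fvc_l", "fvc_pct", "fev1_l", "fev1_pct", "pef",
            "pef_pct", "fev1_fvc", "dlco", "pack_years", "mmrc",
            "exacerbations")
  copd <- if (n_copd > 0) draw_arm(n_copd, cp$copd) else NULL
  ctrl <- if (n_ctrl > 0) draw_arm(n_ctrl, cp$control) else NULL
  if (!is.null(ctrl)) {
    ctrl$pack_years <- 0
    ctrl$mmrc <- 0
    ctrl$exacerbations <- 0
    ctrl <- ctrl[, vars]
  }
  if (!is.null(copd)) {
    copd$mmrc <- round(copd$mmrc)
    copd <- copd[, vars]
  }
  rec <- rbind(copd, ctrl)
  rec$exacerbations <- as.integer(rec$exacerbations)

  rec <- cbind(
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = rep(c("COPD", "control"), c(n_copd, n_ctrl)),
      stringsAsFactors = FALSE
    ),
    rec
  )

  # GOLD labels: random allocation of the configured A-D counts
  gold <- rep("none", n)
  if (n_copd > 0) {
    lab <- rep(names(config$gold_counts), config$gold_counts)
    gold[seq_len(n_copd)] <- sample(lab)
  }
  rec$gold <- gold

  # sex: patients all male; controls get a deterministic male count
  sex <- rep("M", n)
  if (n_ctrl > 0) {
    n_male <- round(n_ctrl * config$control_male_fraction)
    s <- c(rep("M", n_male), rep("F", n_ctrl - n_male))
    sex[n_copd + seq_len(n_ctrl)] <- sample(s)
  }
  rec$sex <- sex

  # smoking status (COPD only; controls are never-smokers by inclusion)
  status <- rep("never", n)
  if (n_copd > 0) {
    status[seq_len(n_copd)] <- sample(c("current", "ex", "never"), n_copd,
                                      replace = TRUE,
                                      prob = unname(config$smoking_probs))
  }
  rec$current_smoker <- as.integer(status == "current")
  rec$ex_smoker <- as.integer(status == "ex")
  rec$pack_years[status == "never"] <- 0

  for (fl in names(config$flag_prevalence)) {
    x <- integer(n)
    if (n_copd > 0)
      x[seq_len(n_copd)] <- stats::rbinom(n_copd, 1, config$flag_prevalence[[fl]])
    rec[[fl]] <- x
  }

  # latent subtype labels (ground truth for recovery experiments)
  if (config$subtype_k >= 2) {
    st <- integer(n)
    if (n_copd > 0) {
      base <- rep(seq_len(config$subtype_k), length.out = n_copd)
      st[seq_len(n_copd)] <- sample(base)
    }
    rec$subtype <- st
  }

  rownames(rec) <- NULL
  rec
}

#' Generate the targeted metabolite panel of a synthetic cohort
#'
#' Concentrations are log-normal around each analyte's panel location with
#' log-scale SD `config$targeted_sdlog`; planted effects from
#' `config$effect_table` (and latent subtype markers, if configured) shift the
#' log-mean of the targeted subjects by `effect * targeted_sdlog`. Derived
#' ratios (Glu/Gln, Kynurenine/Trp, Putrescine/Orn, Orn/Ser, Thr/Ser) and
#' sphingomyelin totals (tSM, tSM-nonOH, tSM-OH, tSM-OH/tSM-nonOH) are
#' recomputed from the final concentrations, so they always equal their
#' quotients/sums exactly.
#'
#' @inheritParams generate_clinical
#' @param subjects Output of [generate_clinical()].
#' @return `data.frame`: `subject_id` plus one column per analyte and ratio.
#' @export
generate_targeted <- function(subjects, config, seed = NULL) {
  if (nrow(subjects) == 0) stop("subjects must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  panel <- targeted_panel()
  nsub <- nrow(subjects)
  np <- nrow(panel)
  sdlog <- config$targeted_sdlog

  shift <- matrix(0, nsub, np)
  et <- config$effect_table
  if (nrow(et) > 0) {
    tgt <- et[!startsWith(et$target, "mz:"), , drop = FALSE]
    if (nrow(tgt) > 0) {
      cols <- resolve_targets(tgt$target, panel)
      for (i in seq_len(nrow(tgt))) {
        rows <- contrast_subjects(tgt$contrast[i], subjects)
        shift[rows, cols[[i]]] <- shift[rows, cols[[i]]] + tgt$effect[i] * sdlog
      }
    }
  }
  if (config$subtype_k >= 2 && !is.null(subjects$subtype)) {
    for (s in seq_len(config$subtype_k)) {
      cols <- which((seq_len(np) - 1) %% config$subtype_k == (s - 1))
      rows <- which(subjects$subtype == s)
      shift[rows, cols] <- shift[rows, cols] + config$subtype_effect * sdlog
    }
  }

  noise <- matrix(stats::rnorm(nsub * np, 0, sdlog), nsub, np)
  conc <- exp(matrix(log(panel$location), nsub, np, byrow = TRUE) + shift + noise)
  colnames(conc) <- panel$analyte
  out <- data.frame(subject_id = subjects$subject_id, conc,
                    check.names = FALSE, stringsAsFactors = FALSE)
  add_derived_ratios(out, panel)
}

contrast_subjects <- function(contrast, subjects) {
  if (contrast == "COPD") which(subjects$group == "COPD")
  else if (startsWith(contrast, "GOLD:"))
    which(subjects$gold == sub("^GOLD:", "", contrast))
  else stop("unknown contrast: ", contrast, call. = FALSE)
}

add_derived_ratios <- function(tab, panel = targeted_panel()) {
  sm <- panel$analyte[panel$class == "SM"]
  smoh <- panel$analyte[panel$class == "SM_OH"]
  tab[["Glu/Gln"]] <- tab$Glu / tab$Gln
  tab[["Kynurenine/Trp"]] <- tab$Kynurenine / tab$Trp
  tab[["Putrescine/Orn"]] <- tab$Putrescine / tab$Orn
  tab[["Orn/Ser"]] <- tab$Orn / tab$Ser
  tab[["Thr/Ser"]] <- tab$Thr / tab$Ser
  tab[["tSM-nonOH"]] <- rowSums(tab[, sm, drop = FALSE])
  tab[["tSM-OH"]] <- rowSums(tab[, smoh, drop = FALSE])
  tab[["tSM"]] <- tab[["tSM-nonOH"]] + tab[["tSM-OH"]]
  tab[["tSM-OH/tSM-nonOH"]] <- tab[["tSM-OH"]] / tab[["tSM-nonOH"]]
  tab
}

#' Names of the derived ratio/total columns of the targeted panel
#' @return Character vector.
#' @export
targeted_ratio_names <- function() {
  c("Glu/Gln", "Kynurenine/Trp", "Putrescine/Orn", "Orn/Ser", "Thr/Ser",
    "tSM-nonOH", "tSM-OH", "tSM", "tSM-OH/tSM-nonOH")
}

# fixed m/z positions of planted spectral signals; offset 0.3 keeps them inside
# their nominal 1 Da bin under round-half-up binning
planted_mz <- function(bin) bin + 0.3

subtype_marker_mz <- function(k) {
  lapply(seq_len(k), function(s) 600 + 40 * (s - 1) + 2 * (0:19) + 0.3)
}

#' Generate untargeted peak lists for a synthetic cohort
#'
#' For each of the four channels (serum/EBC x positive/negative ionization) a
#' common peak grid of `config$n_peaks` random m/z values in the 90-1400 Da
#' acquisition range is drawn, with heavy-tailed (log-normal across peaks) base
#' intensities, so that spectra are comparable across subjects. Planted `mz:`
#' effects from `config$effect_table` add dedicated peaks whose log-intensity
#' is shifted by `effect * noise_sd` in the contrast group; latent subtype
#' markers (serum, negative mode) are added the same way. Every spectrum is
#' multiplied by a subject-by-spectrum batch factor `exp(N(0, batch_scale_sd^2))`
#' that total-ion-count normalization is designed to remove. EBC channels carry
#' no group signal under the default effect table.
#'
#' @inheritParams generate_targeted
#' @return Long-format `data.frame`: `subject_id`, `matrix` (`"serum"`/`"ebc"`),
#'   `mode` (`"pos"`/`"neg"`), `mz` (Da), `intensity` (arbitrary counts).
#' @export
generate_spectra <- function(subjects, config, seed = NULL) {
  if (nrow(subjects) == 0) stop("subjects must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nsub <- nrow(subjects)
  et <- config$effect_table
  mzfx <- if (nrow(et) > 0) et[startsWith(et$target, "mz:"), , drop = FALSE]
          else et[0, ]

  channels <- expand.grid(matrix = c("serum", "ebc"), mode = c("pos", "neg"),
                          stringsAsFactors = FALSE)
  out <- vector("list", nrow(channels))
  for (ci in seq_len(nrow(channels))) {
    mat <- channels$matrix[ci]
    mode <- channels$mode[ci]

    grid_mz <- stats::runif(config$n_peaks, 90, 1399.49)
    base_log <- stats::rnorm(config$n_peaks, log(5e3), 1.2)

    # planted signal peaks for this channel
    fx <- mzfx[grepl(sprintf("^mz:%s:%s:", mat, mode), mzfx$target), , drop = FALSE]
    fx_bin <- as.numeric(sub("^mz:[a-z]+:[a-z]+:", "", fx$target))
    add_mz <- planted_mz(fx_bin)
    add_log <- rep(log(2e4), length(add_mz))

    st_mz <- numeric(0)
    if (config$subtype_k >= 2 && mat == "serum" && mode == "neg") {
      st_mz <- unlist(subtype_marker_mz(config$subtype_k))
      add_mz <- c(add_mz, st_mz)
      add_log <- c(add_log, rep(log(2e4), length(st_mz)))
    }

    mz <- c(grid_mz, add_mz)
    mlog <- c(base_log, add_log)
    npk <- length(mz)

    shift <- matrix(0, nsub, npk)
    if (nrow(fx) > 0) {
      for (i in seq_len(nrow(fx))) {
        rows <- contrast_subjects(fx$contrast[i], subjects)
        col <- config$n_peaks + i
        shift[rows, col] <- shift[rows, col] + fx$effect[i] * config$noise_sd
      }
    }
    if (length(st_mz) > 0 && !is.null(subjects$subtype)) {
      per <- subtype_marker_mz(config$subtype_k)
      for (s in seq_len(config$subtype_k)) {
        cols <- config$n_peaks + nrow(fx) + (s - 1) * 20 + 1:20
        rows <- which(subjects$subtype == s)
        shift[rows, cols] <- shift[rows, cols] +
          config$subtype_effect * config$noise_sd
      }
    }

    noise <- matrix(stats::rnorm(nsub * npk, 0, config$noise_sd), nsub, npk)
    batch <- stats::rnorm(nsub, 0, config$batch_scale_sd)
    logI <- matrix(mlog, nsub, npk, byrow = TRUE) + shift + noise + batch

    out[[ci]] <- data.frame(
      subject_id = rep(subjects$subject_id, each = npk),
      matrix = mat, mode = mode,
      mz = rep(mz, nsub),
      intensity = as.vector(t(exp(logI))),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates [generate_clinical()], [generate_targeted()] and
#' [generate_spectra()] under the single seed in `config`, and attaches the
#' ground-truth record of every planted effect for parameter-recovery tests.
#' Identical `(config, seed)` yields an identical cohort.
#'
#' @param config A [cohort_config()].
#' @return Object of class `cohort_dataset`: list with `subjects`, `targeted`,
#'   `peaks`, `truth` (planted effect table, subtype labels and subtype marker
#'   m/z), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  subjects <- generate_clinical(config)
  targeted <- generate_targeted(subjects, config)
  peaks <- generate_spectra(subjects, config)
  truth <- list(
    effect_table = config$effect_table,
    subtype = if (!is.null(subjects$subtype))
      stats::setNames(subjects$subtype, subjects$subject_id) else NULL,
    subtype_marker_mz = if (config$subtype_k >= 2)
      subtype_marker_mz(config$subtype_k) else NULL
  )
  structure(list(subjects = subjects, targeted = targeted, peaks = peaks,
                 truth = truth, config = config),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d COPD / %d control subjects\n",
              sum(x$subjects$group == "COPD"),
              sum(x$subjects$group == "control")))
  cat(sprintf("  targeted analytes+ratios: %d; peak rows: %d\n",
              ncol(x$targeted) - 1L, nrow(x$peaks)))
  invisible(x)
}

#' Write / read a cohort to plain-text files
#'
#' `write_cohort()` writes `subjects.tsv`, `targeted.csv`, `peaks.csv` and
#' `truth.json` into `dir`; `read_cohort()` reads them back.
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Directory (created if missing).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `cohort_dataset` (without `config`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$targeted, file.path(dir, "targeted.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$peaks, file.path(dir, "peaks.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.delim(file.path(dir, "subjects.tsv"),
                                stringsAsFactors = FALSE)
  targeted <- utils::read.csv(file.path(dir, "targeted.csv"),
                              check.names = FALSE, stringsAsFactors = FALSE)
  peaks <- utils::read.csv(file.path(dir, "peaks.csv"),
                           stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(subjects = subjects, targeted = targeted, peaks = peaks,
                 truth = truth, config = NULL),
            class = "cohort_dataset")
}
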