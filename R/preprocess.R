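#' Integer m/z bin grid
#'
#' The untargeted acquisition window is 90-1400 Da; 1 Da binning therefore
#' yields 1311 integer bins.
#' @return Integer vector `90:1400`.
#' @export
mz_bins <- function() 90:1400

#' Bin a peak list to the 1 Da grid
#'
#' Each peak is assigned to its nearest-integer bin (round half up, i.e.
#' `floor(mz + 0.5)`) and intensities within a bin are summed, so binning
#' conserves total intensity. Peaks must lie in `[89.5, 1400.5)`; in `"strict"`
#' mode (default) an out-of-range peak is an error naming the offender, in
#' `"lenient"` mode it is dropped with a warning.
#'
#' @param peaks `data.frame` with columns `mz` and `intensity` (one peak list,
#'   i.e. one subject/matrix/mode combination).
#' @param mode `"strict"` or `"lenient"`.
#' @return Named numeric vector of length 1311 (names = integer m/z).
#' @export
bin_peaks <- function(peaks, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  mz <- peaks$mz
  intensity <- peaks$intensity
  if (any(!is.finite(mz)) || any(!is.finite(intensity)) || any(intensity < 0))
    stop("peaks must have finite m/z and finite non-negative intensities",
         call. = FALSE)
  out_of_range <- mz < 89.5 | mz >= 1400.5
  if (any(out_of_range)) {
    if (mode == "strict")
      stop(sprintf("peak at m/z %.4f outside the 90-1400 Da acquisition range",
                   mz[which(out_of_range)[1]]), call. = FALSE)
    warning(sprintf("dropping %d peak(s) outside the 90-1400 Da range",
                    sum(out_of_range)), call. = FALSE)
    mz <- mz[!out_of_range]
    intensity <- intensity[!out_of_range]
  }
  bin <- floor(mz + 0.5)
  bins <- mz_bins()
  out <- numeric(length(bins))
  names(out) <- bins
  if (length(bin) > 0) {
    s <- vapply(split(intensity, bin), sum, numeric(1))
    out[names(s)] <- s
  }
  out
}

#' Total-ion-count normalization
#'
#' Divides every bin by the profile's total so the result sums to 1. This
#' removes multiplicative spectrum-level (batch/injection) scale variation;
#' the operation is idempotent and invariant to rescaling of the input.
#'
#' @param profile Non-negative numeric vector (binned intensities).
#' @return Numeric vector summing to 1.
#' @export
tic_normalize <- function(profile) {
  if (any(profile < 0)) stop("profile has negative intensities", call. = FALSE)
  total <- sum(profile)
  if (total <= 0)
    stop("empty spectrum: total ion count is zero", call. = FALSE)
  profile / total
}

#' Log transform with pseudocount
#'
#' `x -> ln(x + pseudocount)`, applied to TIC-normalized bin fractions. The
#' pseudocount (default 1e-6) makes empty bins finite while preserving the
#' ordering of intensities.
#'
#' @param x Non-negative numeric vector.
#' @param pseudocount Positive offset added before taking the natural log.
#' @return Numeric vector.
#' @export
log_transform <- function(x, pseudocount = 1e-6) {
  if (any(x < 0)) stop("log_transform requires non-negative input", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  log(x + pseudocount)
}

#' Logistic transform onto (0, 1)
#'
#' `1 / ((0.5 + exp(-x)) * 2)`, equivalently `1 / (1 + 2 exp(-x))`: a strictly
#' increasing map of the real line onto (0, 1) with `f(0) = 1/3` and
#' `f(ln 2) = 1/2`. Used to place log-scale spectral intensities on the unit
#' interval for block integration.
#'
#' @param x Finite numeric vector.
#' @return Numeric vector in (0, 1).
#' @export
logistic_transform <- function(x) {
  if (any(!is.finite(x))) stop("logistic_transform requires finite input",
                               call. = FALSE)
  1 / (1 + 2 * exp(-x))
}

#' Scale each variable by its maximum
#'
#' Divides every column by its column maximum, so the maximum maps to exactly 1
#' and zeros stay 0. Applied to clinical/demographic and targeted-metabolite
#' variables (0/1 indicator variables are left unchanged since their maximum is
#' 1). Errors on a column with no positive value or with negative entries,
#' naming the variable.
#'
#' @param values Numeric matrix or data frame (subjects x variables).
#' @return Matrix of the same shape with entries in \[0, 1\].
#' @export
max_scale <- function(values) {
  m <- as.matrix(values)
  if (any(m < 0))
    stop("max_scale requires non-negative values (offending variable: ",
         colnames(m)[which(colSums(m < 0) > 0)[1]], ")", call. = FALSE)
  mx <- apply(m, 2, max)
  bad <- which(mx <= 0)
  if (length(bad) > 0)
    stop("max_scale: variable(s) with no positive value: ",
         paste(colnames(m)[bad], collapse = ", "), call. = FALSE)
  sweep(m, 2, mx, "/")
}

# clinical feature columns used for integration (labels and ground truth
# excluded)
clinical_feature_frame <- function(subjects) {
  drop <- c("subject_id", "group", "gold", "subtype", "sex")
  keep <- setdiff(names(subjects), drop)
  out <- subjects[, keep, drop = FALSE]
  out <- cbind(sex_male = as.integer(subjects$sex == "M"), out)
  for (j in seq_along(out)) out[[j]] <- as.numeric(out[[j]])
  rownames(out) <- subjects$subject_id
  out
}

#' Integrate the five data blocks into one unit-interval matrix
#'
#' Implements the integration recipe: untargeted peak lists are binned to the
#' 1 Da grid, TIC-normalized, log-transformed and mapped to (0,1) with
#' [logistic_transform()]; clinical/demographic and targeted variables are
#' divided by their per-variable maximum ([max_scale()]), with dichotomous
#' variables encoded as 0/1 indicators beforehand. The four spectral channels
#' (serum/EBC x pos/neg) plus the clinical and targeted blocks give six feature
#' blocks, recorded in a feature-to-block map.
#'
#' @param subjects,targeted,peaks The three blocks of a cohort (see
#'   [generate_cohort()] for their layout).
#' @param exclude_smoking Drop the smoking-history variables (`pack_years`,
#'   `current_smoker`, `ex_smoker`) before output, for sensitivity re-runs.
#' @param exclude_features Character vector of feature names (e.g.
#'   `"serum_neg_327"`) dropped before output, e.g. suspected drug-derived
#'   signals.
#' @param binning `"strict"` or `"lenient"`, passed to [bin_peaks()].
#' @param pseudocount Passed to [log_transform()].
#' @return Object of class `integrated_matrix`: list with `values` (subjects x
#'   features, all in \[0,1\]), `block` (named character vector mapping each
#'   feature to one of `clinical`, `targeted`, `serum-pos`, `serum-neg`,
#'   `ebc-pos`, `ebc-neg`) and `subjects`. All-zero clinical indicator columns
#'   (flags absent from the cohort) are dropped with a warning.
#' @export
integrate_blocks <- function(subjects, targeted, peaks,
                             exclude_smoking = FALSE,
                             exclude_features = character(0),
                             binning = "strict",
                             pseudocount = 1e-6) {
  ids <- subjects$subject_id
  if (anyDuplicated(ids)) stop("duplicate subject ids", call. = FALSE)
  miss_t <- setdiff(ids, targeted$subject_id)
  extra_t <- setdiff(targeted$subject_id, ids)
  miss_p <- setdiff(ids, unique(peaks$subject_id))
  extra_p <- setdiff(unique(peaks$subject_id), ids)
  if (length(c(miss_t, extra_t, miss_p, extra_p)) > 0)
    stop("subject sets differ across blocks: ",
         paste(unique(c(miss_t, extra_t, miss_p, extra_p)), collapse = ", "),
         call. = FALSE)

  # clinical block
  clin <- clinical_feature_frame(subjects)
  zero <- vapply(clin, function(x) all(x == 0), logical(1))
  if (any(zero)) {
    warning("dropping all-zero clinical variable(s): ",
            paste(names(clin)[zero], collapse = ", "), call. = FALSE)
    clin <- clin[, !zero, drop = FALSE]
  }
  clin_m <- max_scale(clin)

  # targeted block
  tg <- as.matrix(targeted[match(ids, targeted$subject_id),
                           setdiff(names(targeted), "subject_id"),
                           drop = FALSE])
  rownames(tg) <- ids
  tg_m <- max_scale(tg)

  # spectral blocks: bin -> TIC -> log -> logistic per (subject, channel)
  spec_blocks <- list()
  for (mat in c("serum", "ebc")) {
    for (md in c("pos", "neg")) {
      sel <- peaks$matrix == mat & peaks$mode == md
      sub_pk <- peaks[sel, , drop = FALSE]
      block <- matrix(NA_real_, length(ids), length(mz_bins()),
                      dimnames = list(ids, NULL))
      by_subj <- split(seq_len(nrow(sub_pk)), sub_pk$subject_id)
      for (id in ids) {
        rows <- by_subj[[id]]
        if (is.null(rows))
          stop(sprintf("subject %s has no %s/%s spectrum", id, mat, md),
               call. = FALSE)
        b <- bin_peaks(sub_pk[rows, ], mode = binning)
        block[id, ] <- logistic_transform(
          log_transform(tic_normalize(b), pseudocount))
      }
      bname <- paste0(ifelse(mat == "ebc", "ebc", "serum"), "-", md)
      colnames(block) <- paste0(sub("-", "_", bname), "_", mz_bins())
      spec_blocks[[bname]] <- block
    }
  }

  values <- cbind(clin_m, tg_m,
                  spec_blocks[["serum-pos"]], spec_blocks[["serum-neg"]],
                  spec_blocks[["ebc-pos"]], spec_blocks[["ebc-neg"]])
  block <- c(rep("clinical", ncol(clin_m)), rep("targeted", ncol(tg_m)),
             rep("serum-pos", ncol(spec_blocks[["serum-pos"]])),
             rep("serum-neg", ncol(spec_blocks[["serum-neg"]])),
             rep("ebc-pos", ncol(spec_blocks[["ebc-pos"]])),
             rep("ebc-neg", ncol(spec_blocks[["ebc-neg"]])))
  names(block) <- colnames(values)

  drop <- character(0)
  if (exclude_smoking)
    drop <- c(drop, intersect(c("pack_years", "current_smoker", "ex_smoker"),
                              colnames(values)))
  if (length(exclude_features) > 0) {
    unknown <- setdiff(exclude_features, colnames(values))
    if (length(unknown) > 0)
      stop("exclude_features not present: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    drop <- c(drop, exclude_features)
  }
  if (length(drop) > 0) {
    keep <- setdiff(colnames(values), drop)
    values <- values[, keep, drop = FALSE]
    block <- block[keep]
  }

  structure(list(values = values, block = block, subjects = subjects),
            class = "integrated_matrix")
}

#' @export
print.integrated_matrix <- function(x, ...) {
  cat(sprintf("integrated matrix: %d subjects x %d features\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$block))
  invisible(x)
}

#' Write an integrated matrix to disk
#'
#' Writes `integrated.csv` (subjects x features) and `blocks.json`
#' (feature-to-block map) into `dir`.
#'
#' @param im An `integrated_matrix`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_integrated <- function(im, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(subject_id = rownames(im$values), im$values,
                              check.names = FALSE),
                   file.path(dir, "integrated.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(im$block), file.path(dir, "blocks.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
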