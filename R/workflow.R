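#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement between two labelings of the same
#' subjects; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Two label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == maxi, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

# named block subsets of the six-block integrated matrix
block_subsets <- function() {
  list(
    all = c("clinical", "targeted", "serum-pos", "serum-neg",
            "ebc-pos", "ebc-neg"),
    clinical = "clinical",
    targeted = "targeted",
    serum_profiles = c("serum-pos", "serum-neg"),
    ebc_profiles = c("ebc-pos", "ebc-neg"),
    metabolomic = c("targeted", "serum-pos", "serum-neg",
                    "ebc-pos", "ebc-neg")
  )
}

#' Enumerate the candidate datasets of the de novo phenotyping workflow
#'
#' Builds the full cross-product of cohort scope (all subjects / COPD only) x
#' representation (original features / retained principal components) x six
#' named block subsets (all blocks; clinical only; targeted only; serum
#' profiles; EBC profiles; all metabolomic blocks without clinical), i.e.
#' 2 x 2 x 6 = 24 candidate datasets from a complete cohort. The PC
#' representation keeps, per subset and scope, only the components explaining
#' at least `variance_threshold` of the total variance (default 5%), recomputed
#' on that subset.
#'
#' @param im An `integrated_matrix` (see [integrate_blocks()]).
#' @param variance_threshold Minimal explained-variance fraction for a
#'   retained component.
#' @return List of 24 `candidate_dataset` objects, each with `dataset_id`,
#'   `cohort_scope`, `representation`, `source_subset`, `matrix`, and the row
#'   indices of its subjects in the cohort.
#' @export
enumerate_datasets <- function(im, variance_threshold = 0.05) {
  missing_blocks <- setdiff(unlist(block_subsets()), unique(im$block))
  if (length(missing_blocks) > 0)
    stop("integrated matrix lacks block(s): ",
         paste(unique(missing_blocks), collapse = ", "), call. = FALSE)
  scopes <- c("all_subjects", "copd_only")
  reps <- c("original_features", "retained_pcs")
  subsets <- block_subsets()

  out <- list()
  for (scope in scopes) {
    rows <- if (scope == "copd_only") which(im$subjects$group == "COPD")
            else seq_len(nrow(im$values))
    for (ss in names(subsets)) {
      cols <- which(im$block %in% subsets[[ss]])
      base <- im$values[rows, cols, drop = FALSE]
      for (rep_ in reps) {
        if (rep_ == "original_features") {
          m <- base
        } else {
          fit <- pca_fit(base)
          keep <- which(fit$explained >= variance_threshold)
          if (length(keep) == 0)
            stop(sprintf(
              "no component reaches the %.0f%% variance threshold for %s/%s",
              100 * variance_threshold, scope, ss), call. = FALSE)
          m <- fit$scores[, keep, drop = FALSE]
        }
        id <- paste(scope, rep_, ss, sep = ".")
        out[[id]] <- structure(
          list(dataset_id = id, cohort_scope = scope, representation = rep_,
               source_subset = ss, matrix = m, control_matrix = base,
               rows = rows),
          class = "candidate_dataset")
      }
    }
  }
  out
}

#' Evaluate the GOLD-based positive control for a candidate dataset
#'
#' Fits an sPLS-DA model on the dataset with the GOLD strata as class labels
#' (controls form a fifth class when in scope; strata absent from the cohort
#' are dropped with a warning) and evaluates the label partition as a
#' clustering of the subjects in the resulting score space with the full
#' validity battery. This is the quality bar that any de novo clustering of
#' the same dataset is asked to approach. The control model is always fit on
#' the dataset's source-subset features in their original representation
#' (`control_matrix`): the principal-component representation is a property of
#' the de novo clustering arm, whereas the supervised control selects its own
#' variables from the source data. `space = "raw"` instead evaluates the label
#' partition directly in that feature space, without the sPLS-DA projection.
#'
#' @param dataset A `candidate_dataset`.
#' @param subjects The cohort subject table.
#' @param n_components,keepX sPLS-DA settings for the control model (defaults:
#'   the 2-component / 60-variables-kept protocol, split 30 + 30, capped at
#'   the feature count).
#' @param space `"splsda"` (default) or `"raw"`.
#' @return A `validity_report` with attribute `labels` (the control partition).
#' @export
positive_control <- function(dataset, subjects, n_components = 2,
                             keepX = NULL, space = c("splsda", "raw")) {
  space <- match.arg(space)
  sub <- subjects[dataset$rows, , drop = FALSE]
  labels <- ifelse(sub$group == "control", "control", sub$gold)
  cnt <- table(labels)
  small <- names(cnt)[cnt < 2]
  if (length(small) > 0) {
    warning("dropping stratum/strata with n < 2: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(labels %in% small)
  } else keep <- rep(TRUE, length(labels))
  base <- if (!is.null(dataset$control_matrix)) dataset$control_matrix
          else dataset$matrix
  m <- base[keep, , drop = FALSE]
  lab <- labels[keep]
  p <- ncol(m)
  n_components <- min(n_components, p, length(unique(lab)))
  if (is.null(keepX)) keepX <- min(30, p)
  if (space == "splsda") {
    fit <- splsda_fit(m, lab, n_components = n_components, keepX = keepX)
    eval_space <- fit$x_scores
  } else {
    eval_space <- m
  }
  rep_ <- validity_report(eval_space, match(lab, unique(lab)),
                          apn = FALSE)
  attr(rep_, "labels") <- lab
  rep_
}

#' Hierarchically cluster a candidate dataset over a range of k
#'
#' Clusters the dataset once (euclidean, complete linkage), cuts the tree at
#' each `k`, and computes the validity battery per cut. The per-index best k
#' (respecting each index's orientation) is recorded. APN is computed when the
#' dataset has at most `apn_max_features` columns (leave-one-feature-out
#' re-clustering is quadratic in width otherwise).
#'
#' @param dataset A `candidate_dataset`.
#' @param k_range Candidate cluster counts (clipped to `[2, n - 1]`).
#' @param apn_max_features Width limit for computing APN.
#' @return List with `dendrogram`, `partitions` (list by k), `reports` (list
#'   of `validity_report` by k), `validity` (long `data.frame`: k, index,
#'   value), `best_k` (named vector per oriented index).
#' @export
run_denovo <- function(dataset, k_range = 2:8, apn_max_features = 50) {
  m <- dataset$matrix
  n <- nrow(m)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) stop("k_range empty after clipping", call. = FALSE)
  dend <- hclust_complete(m)
  do_apn <- ncol(m) >= 2 && ncol(m) <= apn_max_features
  partitions <- list()
  reports <- list()
  for (k in k_range) {
    part <- cut_k(dend, k)
    partitions[[as.character(k)]] <- part
    reports[[as.character(k)]] <- validity_report(m, part, apn = do_apn)
  }
  validity <- do.call(rbind, lapply(names(reports), function(kk) {
    v <- unlist(reports[[kk]])
    data.frame(k = as.integer(kk), index = names(v), value = unname(v),
               stringsAsFactors = FALSE)
  }))
  ori <- index_orientation()
  oriented <- names(ori)[!is.na(ori)]
  best_k <- vapply(oriented, function(idx) {
    v <- validity$value[validity$index == idx]
    kk <- validity$k[validity$index == idx]
    v[!is.finite(v)] <- NA
    if (all(is.na(v))) return(NA_integer_)
    if (ori[idx] == "max") kk[which.max(v)] else kk[which.min(v)]
  }, integer(1))
  list(dendrogram = dend, partitions = partitions, reports = reports,
       validity = validity, best_k = best_k)
}

# minimal misclassification count of a 2-cluster partition against binary
# group labels (best of the two cluster->group assignments)
misclassification_k2 <- function(partition, group_labels) {
  tab <- table(partition, group_labels)
  if (nrow(tab) == 1) return(min(colSums(tab)))
  min(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1])
}

#' Acceptance decision for a candidate dataset
#'
#' A de novo clustering is accepted when three conditions hold.
#'
#' (a) Quality: for at least one candidate k, the oriented scale-free validity
#' indices of the cut (Calinski-Harabasz, Davies-Bouldin, Baker-Hubert gamma,
#' C-index, silhouette, Dunn) are all within a relative `tolerance` (default
#' 10%) of the positive control or better. Scale-dependent summaries
#' (membership entropy, raw distance averages, APN) are reported but not
#' compared: the control partition lives in a different (supervised score)
#' space, where only scale-free geometry indices are commensurable.
#'
#' (b) Branch separation: when controls are in scope, cutting the dendrogram
#' at k = 2 misclassifies at most `max_misclassified` (default 2) subjects
#' against the COPD/control labels.
#'
#' (c) Non-chance structure: the partition passing (a) must show cluster
#' structure beyond what the clusterer extracts from structureless data. The
#' reference is obtained by independently permuting each feature column
#' (destroying multivariate structure while keeping every marginal) and
#' re-clustering; the observed Calinski-Harabasz statistic must exceed the
#' permutation mean by at least `null_z` reference SDs. Without this guard a
#' weak positive control (e.g. a supervised model that cannot overfit a
#' low-dimensional dataset) would let chance clusterings through. Note the
#' column permutation is uninformative for single-feature datasets (it
#' preserves the marginal, hence the clustering); such datasets fail (c) by
#' construction. (c) is only evaluated when (a) and (b) already hold, since
#' the decision is otherwise negative regardless.
#'
#' @param dataset A `candidate_dataset`.
#' @param denovo_result Output of [run_denovo()] on that dataset.
#' @param control_report Output of [positive_control()] on that dataset.
#' @param group_labels COPD/control label per cohort row (ignored for
#'   COPD-only datasets).
#' @param tolerance Relative tolerance band around each control index.
#' @param max_misclassified Branch-separation allowance at k = 2.
#' @param null_draws Number of column-permutation reference draws.
#' @param null_z Required CH excess over the reference, in reference SDs.
#' @return List with `accepted`, `reasons` (character), `best_k` (the smallest
#'   k meeting conditions (a) and (c), or NA), `misclassified` (count or NA),
#'   `ch_null_z` (CH z-score of `best_k` against the permutation reference).
#' @export
accept_dataset <- function(dataset, denovo_result, control_report,
                           group_labels = NULL, tolerance = 0.10,
                           max_misclassified = 2, null_draws = 100,
                           null_z = 3) {
  ori <- index_orientation()
  compare <- c("calinski_harabasz", "davies_bouldin", "bh_gamma",
               "c_index", "silhouette", "dunn")
  reasons <- character(0)

  within_band <- function(value, control, direction) {
    if (!is.finite(control) || !is.finite(value)) return(NA)
    band <- tolerance * abs(control)
    if (band == 0) band <- tolerance
    if (direction == "max") value >= control - band else value <= control + band
  }

  # (b) branch separation, checked first: it is cheap and, when violated,
  # makes the permutation reference of (c) unnecessary
  mis <- NA_integer_
  mis_ok <- TRUE
  if (dataset$cohort_scope == "all_subjects") {
    if (is.null(group_labels))
      stop("group_labels required for all-subject datasets", call. = FALSE)
    part2 <- cut_k(denovo_result$dendrogram, 2)
    mis <- misclassification_k2(part2, group_labels[dataset$rows])
    mis_ok <- mis <= max_misclassified
    if (!mis_ok)
      reasons <- c(reasons, sprintf("misclassification > %d (got %d) at k = 2",
                                    max_misclassified, mis))
  }

  m <- dataset$matrix
  ks <- as.integer(names(denovo_result$reports))
  ref_ch <- NULL   # null_draws x |ks| CH values, computed lazily once
  perm_reference <- function() {
    n <- nrow(m); p <- ncol(m)
    out <- base::matrix(NA_real_, null_draws, length(ks))
    for (b in seq_len(null_draws)) {
      # column permutation: destroys multivariate structure, keeps marginals
      mp <- base::matrix(m[order(rep(seq_len(p), each = n),
                                 stats::runif(n * p))], n, p)
      hc <- hclust_complete(mp)
      for (j in seq_along(ks))
        out[b, j] <- ch_stat(mp, cut_k(hc, ks[j]))
    }
    out
  }

  best_k <- NA_integer_
  ch_z <- NA_real_
  per_k_fail <- list()
  quality_seen <- FALSE
  for (kk in names(denovo_result$reports)) {
    rep_ <- denovo_result$reports[[kk]]
    ok <- vapply(compare, function(idx)
      isTRUE(within_band(rep_[[idx]], control_report[[idx]], ori[idx])),
      logical(1))
    if (!all(ok)) {
      per_k_fail[[kk]] <- compare[!ok]
      next
    }
    quality_seen <- TRUE
    if (!mis_ok) {      # decision already negative; (c) not evaluated
      best_k <- as.integer(kk)
      break
    }
    if (is.null(ref_ch)) ref_ch <- perm_reference()
    ref <- ref_ch[, match(as.integer(kk), ks)]
    z <- (rep_$calinski_harabasz - mean(ref)) / stats::sd(ref)
    if (is.finite(z) && z >= null_z) {
      best_k <- as.integer(kk)
      ch_z <- z
      break
    }
  }
  if (is.na(best_k)) {
    if (!quality_seen) {
      worst <- sort(table(unlist(per_k_fail)), decreasing = TRUE)
      reasons <- c(reasons, sprintf(
        "no k within %.0f%% of the positive control (most violated: %s)",
        100 * tolerance, paste(utils::head(names(worst), 3), collapse = ", ")))
    } else {
      reasons <- c(reasons, sprintf(
        "cluster structure indistinguishable from chance (CH z < %g against the column-permutation reference)",
        null_z))
    }
  }

  accepted <- !is.na(best_k) && mis_ok && is.finite(ch_z) && ch_z >= null_z
  list(accepted = accepted, reasons = reasons, best_k = best_k,
       misclassified = mis, ch_null_z = ch_z)
}

#' Run the complete de novo phenotyping workflow
#'
#' End-to-end procedure on an integrated cohort: enumerate the 24 candidate
#' datasets, hierarchically cluster each over `k_range`, score every cut with
#' the validity battery, evaluate the GOLD-based positive control on the same
#' dataset, and apply the acceptance rule. Datasets are ranked by their mean
#' relative oriented gap to the positive control (smaller = closer).
#'
#' @param im An `integrated_matrix` of the full cohort.
#' @param k_range Candidate cluster counts.
#' @param tolerance,max_misclassified,null_draws,null_z See [accept_dataset()].
#' @param variance_threshold See [enumerate_datasets()].
#' @param control_space See `space` in [positive_control()].
#' @param seed Optional seed for the permutation references of
#'   [accept_dataset()]; with a fixed seed the whole result is reproducible.
#' @return Object of class `workflow_result`: `datasets`, `denovo`, `controls`,
#'   `decisions` (per dataset), and `summary` (`data.frame` ranked by
#'   closeness: dataset_id, scope, representation, subset, accepted,
#'   mean_rel_gap, ch_best_k, misclassified).
#' @export
run_workflow <- function(im, k_range = 2:8, tolerance = 0.10,
                         max_misclassified = 2, variance_threshold = 0.05,
                         control_space = "splsda", null_draws = 100,
                         null_z = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  datasets <- enumerate_datasets(im, variance_threshold)
  group <- im$subjects$group
  ori <- index_orientation()
  compare <- c("calinski_harabasz", "davies_bouldin", "bh_gamma",
               "c_index", "silhouette", "dunn")

  denovo <- list(); controls <- list(); decisions <- list()
  rows <- list()
  for (id in names(datasets)) {
    ds <- datasets[[id]]
    dn <- run_denovo(ds, k_range)
    ctrl <- suppressWarnings(
      positive_control(ds, im$subjects, space = control_space))
    dec <- accept_dataset(ds, dn, ctrl, group, tolerance, max_misclassified,
                          null_draws, null_z)
    denovo[[id]] <- dn
    controls[[id]] <- ctrl
    decisions[[id]] <- dec

    # mean relative oriented gap of the dataset's best try per index
    gaps <- vapply(compare, function(idx) {
      ctl <- ctrl[[idx]]
      if (!is.finite(ctl)) return(NA_real_)
      v <- dn$validity$value[dn$validity$index == idx]
      v <- v[is.finite(v)]
      if (length(v) == 0) return(NA_real_)
      denom <- max(abs(ctl), .Machine$double.eps)
      if (ori[idx] == "max") max(0, (ctl - max(v)) / denom)
      else max(0, (min(v) - ctl) / denom)
    }, numeric(1))
    rows[[id]] <- data.frame(
      dataset_id = id, scope = ds$cohort_scope,
      representation = ds$representation, subset = ds$source_subset,
      accepted = dec$accepted,
      mean_rel_gap = mean(gaps, na.rm = TRUE),
      ch_best_k = unname(dn$best_k["calinski_harabasz"]),
      misclassified = dec$misclassified,
      stringsAsFactors = FALSE
    )
  }
  summary <- do.call(rbind, rows)
  summary <- summary[order(summary$mean_rel_gap), ]
  rownames(summary) <- NULL
  structure(list(datasets = datasets, denovo = denovo, controls = controls,
                 decisions = decisions, summary = summary),
            class = "workflow_result")
}

#' Write workflow outputs to disk
#'
#' Writes `workflow_summary.tsv` (the ranked dataset summary), `validity.tsv`
#' (dataset x k x index long table), one Newick dendrogram per dataset under
#' `dendrograms/`, and `acceptance.md` (human-readable decisions with reasons).
#'
#' @param wf A `workflow_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_workflow <- function(wf, dir) {
  dir.create(file.path(dir, "dendrograms"), showWarnings = FALSE,
             recursive = TRUE)
  utils::write.table(wf$summary, file.path(dir, "workflow_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  validity <- do.call(rbind, lapply(names(wf$denovo), function(id)
    cbind(dataset_id = id, wf$denovo[[id]]$validity)))
  utils::write.table(validity, file.path(dir, "validity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (id in names(wf$denovo))
    dendrogram_newick(wf$denovo[[id]]$dendrogram,
                      file.path(dir, "dendrograms", paste0(id, ".nwk")))
  lines <- c("# De novo phenotyping acceptance report", "")
  for (i in seq_len(nrow(wf$summary))) {
    id <- wf$summary$dataset_id[i]
    dec <- wf$decisions[[id]]
    lines <- c(lines, sprintf("## %s", id),
               sprintf("- accepted: %s", dec$accepted),
               if (!is.na(dec$best_k))
                 sprintf("- best k: %d", dec$best_k),
               if (!is.na(dec$misclassified))
                 sprintf("- misclassified at k = 2: %d", dec$misclassified),
               if (length(dec$reasons) > 0)
                 paste0("- ", dec$reasons),
               "")
  }
  writeLines(lines, file.path(dir, "acceptance.md"))
  invisible(dir)
}

#' @export
print.workflow_result <- function(x, ...) {
  cat(sprintf("de novo phenotyping workflow: %d candidate datasets, %d accepted\n",
              nrow(x$summary), sum(x$summary$accepted)))
  print(utils::head(x$summary, 8))
  invisible(x)
}
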