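# vectorized pooled two-sample Student's t over the columns of x
pooled_t_cols <- function(x, g, welch = FALSE) {
  lev <- unique(g)
  stopifnot(length(lev) == 2)
  x1 <- x[g == lev[1], , drop = FALSE]
  x2 <- x[g == lev[2], , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2, stats::var); v2 <- apply(x2, 2, stats::var)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 <= 0 | !is.finite(se2)
  p[degenerate] <- NA_real_
  list(effect = m1 - m2, t = tstat, p = p, degenerate = degenerate,
       level_order = lev)
}

#' Volcano-style two-group comparison
#'
#' Runs a per-feature two-sample Student's t-test (pooled variance; Welch
#' available behind a flag) between two groups on the integrated \[0,1\] scale.
#' The effect reported is the difference of group means on that scale (the
#' fold-change axis of a volcano display); ratios are unstable near zero, so no
#' ratio-type fold change is computed. No multiple-testing correction is
#' applied by default, matching the raw-p reporting convention of the analyses
#' this package reproduces; a Benjamini-Hochberg column can be requested.
#'
#' @param matrix Numeric subjects x features matrix.
#' @param group_labels Vector with exactly two levels, aligned with rows. The
#'   effect sign is `mean(first level) - mean(second level)`, where the first
#'   level is `"COPD"` if present, otherwise the first level encountered.
#' @param alpha Significance level for the `significant` flag.
#' @param welch Use the Welch (unequal-variance) t-test instead of pooled.
#' @param fdr Add a `p_bh` column of Benjamini-Hochberg adjusted p-values.
#' @return `data.frame` with columns `feature`, `effect`, `p`, `significant`,
#'   `degenerate`. Features with zero variance in both groups are flagged
#'   degenerate (`p = NA`) and excluded from significance counts. The number
#'   of significant features is attached as attribute `n_significant`.
#' @export
volcano <- function(matrix, group_labels, alpha = 0.05, welch = FALSE,
                    fdr = FALSE) {
  if (is.null(colnames(matrix)))
    colnames(matrix) <- paste0("V", seq_len(ncol(matrix)))
  g <- as.character(group_labels)
  lev <- unique(g)
  if (length(lev) != 2)
    stop("volcano requires exactly two groups", call. = FALSE)
  if (min(table(g)) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  # report effects as first-level minus second-level, with COPD first if present
  if ("COPD" %in% lev) lev <- c("COPD", setdiff(lev, "COPD"))
  res <- {
    x1 <- matrix[g == lev[1], , drop = FALSE]
    x2 <- matrix[g == lev[2], , drop = FALSE]
    pooled_t_cols(rbind(x1, x2),
                  rep(lev, c(nrow(x1), nrow(x2))), welch)
  }
  out <- data.frame(
    feature = colnames(matrix),
    effect = unname(res$effect),
    p = unname(res$p),
    degenerate = unname(res$degenerate),
    stringsAsFactors = FALSE
  )
  out$significant <- !out$degenerate & !is.na(out$p) & out$p < alpha
  if (fdr) out$p_bh <- stats::p.adjust(out$p, "BH")
  attr(out, "n_significant") <- sum(out$significant)
  attr(out, "level_order") <- lev
  out
}

#' One-way ANOVA with Tukey HSD across strata
#'
#' Per feature: one-way ANOVA F-test across the given strata (e.g. GOLD A-D),
#' followed by Tukey HSD pairwise comparisons using the studentized-range
#' distribution with the Tukey-Kramer unequal-n standard error. Features are
#' bucketed into significance tiers: `"high"` for p < 0.0001, `"moderate"` for
#' 0.0001 <= p < 0.05, `"ns"` otherwise.
#'
#' @param matrix Numeric subjects x features matrix.
#' @param gold_labels Stratum label per row; strata with fewer than 2 subjects
#'   are dropped with a warning (or an error when `strict = TRUE`).
#' @param alpha Significance level used in the returned Tukey flags.
#' @param strict Error instead of dropping undersized strata.
#' @return List with `anova` (`data.frame`: feature, F, p, tier) and `tukey`
#'   (`data.frame`: feature, pair, diff, p, significant).
#' @export
anova_tukey <- function(matrix, gold_labels, alpha = 0.05, strict = FALSE) {
  if (is.null(colnames(matrix)))
    colnames(matrix) <- paste0("V", seq_len(ncol(matrix)))
  g <- as.character(gold_labels)
  cnt <- table(g)
  small <- names(cnt)[cnt < 2]
  if (length(small) > 0) {
    if (strict)
      stop("strata with n < 2: ", paste(small, collapse = ", "), call. = FALSE)
    warning("dropping strata with n < 2: ", paste(small, collapse = ", "),
            call. = FALSE)
    keep <- !(g %in% small)
    matrix <- matrix[keep, , drop = FALSE]
    g <- g[keep]
  }
  lev <- sort(unique(g))
  k <- length(lev)
  if (k < 2) stop("need >= 2 strata with n >= 2", call. = FALSE)
  n <- nrow(matrix)
  gi <- lapply(lev, function(l) which(g == l))
  ni <- lengths(gi)

  means <- vapply(gi, function(idx) colMeans(matrix[idx, , drop = FALSE]),
                  numeric(ncol(matrix)))       # features x k
  if (ncol(matrix) == 1) means <- base::matrix(means, nrow = 1)
  grand <- colMeans(matrix)
  ssb <- rowSums(sweep(means, 1, grand)^2 %*% diag(ni, k, k))
  sst <- colSums(sweep(matrix, 2, grand)^2)
  ssw <- sst - ssb
  dfb <- k - 1
  dfw <- n - k
  msw <- ssw / dfw
  f <- (ssb / dfb) / msw
  p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  degenerate <- msw <= 0 | !is.finite(msw)
  p[degenerate] <- NA_real_
  tier <- ifelse(is.na(p), "degenerate",
                 ifelse(p < 1e-4, "high", ifelse(p < alpha, "moderate", "ns")))
  anova_tab <- data.frame(feature = colnames(matrix), F = unname(f),
                          p = unname(p), tier = tier,
                          stringsAsFactors = FALSE)

  # Tukey-Kramer pairwise comparisons
  pairs <- utils::combn(k, 2)
  tk <- vector("list", ncol(pairs))
  for (pi in seq_len(ncol(pairs))) {
    a <- pairs[1, pi]; b <- pairs[2, pi]
    diffs <- means[, b] - means[, a]
    se <- sqrt(msw / 2 * (1 / ni[a] + 1 / ni[b]))
    q <- abs(diffs) / se
    pt <- stats::ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
    pt[degenerate] <- NA_real_
    tk[[pi]] <- data.frame(
      feature = colnames(matrix),
      pair = paste0(lev[b], "-", lev[a]),
      diff = unname(diffs),
      p = unname(pt),
      stringsAsFactors = FALSE
    )
  }
  tukey <- do.call(rbind, tk)
  tukey$significant <- !is.na(tukey$p) & tukey$p < alpha
  rownames(tukey) <- NULL
  list(anova = anova_tab, tukey = tukey)
}

#' Clinical-metabolite association table
#'
#' For the patient arm only: Pearson correlation between each metabolite and
#' each continuous clinical variable, a two-sample pooled t-test p-value for
#' each dichotomous variable, and a one-way ANOVA p-value for multi-level
#' variables (exacerbation counts are treated as a factor). A cell is flagged
#' `notable` when `|r| >= 0.49` or `p < 0.05`.
#'
#' @param panel `data.frame` of metabolite columns (plus `subject_id`,
#'   ignored), rows aligned with `subjects`.
#' @param subjects Subject table (patients only; rows aligned with `panel`).
#' @param continuous_vars,categorical_vars Names of clinical columns to use.
#'   Multi-level variables are detected as categorical columns with more than
#'   two distinct values.
#' @param metabolites Metabolite column names (default: all non-id columns of
#'   `panel`).
#' @return `data.frame` with columns `metabolite`, `clinical_variable`, `kind`
#'   (`"pearson_r"` or `"test_p"`), `value`, `notable`, `degenerate`.
#' @export
association_table <- function(panel, subjects,
                              continuous_vars = c("pack_years", "fev1_l", "pef"),
                              categorical_vars = c("current_smoker", "ics",
                                                   "lama", "theophylline",
                                                   "pulmonary_hypertension",
                                                   "heart_failure", "emphysema",
                                                   "exacerbations"),
                              metabolites = NULL) {
  if (is.null(metabolites))
    metabolites <- setdiff(names(panel), "subject_id")
  rows <- list()
  for (m in metabolites) {
    y <- panel[[m]]
    degener_m <- stats::sd(y) == 0
    for (v in continuous_vars) {
      x <- subjects[[v]]
      deg <- degener_m || stats::sd(x) == 0
      r <- if (deg) NA_real_ else stats::cor(x, y)
      rows[[length(rows) + 1]] <- data.frame(
        metabolite = m, clinical_variable = v, kind = "pearson_r",
        value = r, notable = !deg && abs(r) >= 0.49, degenerate = deg,
        stringsAsFactors = FALSE)
    }
    for (v in categorical_vars) {
      x <- subjects[[v]]
      nlev <- length(unique(x))
      deg <- degener_m || nlev < 2 || min(table(x)) < 2
      pval <- NA_real_
      if (!deg) {
        if (nlev == 2) {
          res <- pooled_t_cols(base::matrix(y, ncol = 1), as.character(x))
          pval <- res$p[1]
        } else {
          at <- suppressWarnings(
            anova_tukey(base::matrix(y, ncol = 1,
                                     dimnames = list(NULL, m)),
                        as.character(x)))
          pval <- at$anova$p[1]
        }
      }
      deg <- deg || is.na(pval)
      rows[[length(rows) + 1]] <- data.frame(
        metabolite = m, clinical_variable = v, kind = "test_p",
        value = pval, notable = !deg && pval < 0.05, degenerate = deg,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity re-run of the volcano comparison
#'
#' Re-runs [volcano()] after excluding the masked subjects and reports how many
#' of the originally significant features remain significant (e.g. excluding
#' all female subjects to probe sex confounding).
#'
#' @param matrix Numeric subjects x features matrix.
#' @param labels Two-level group labels aligned with rows.
#' @param exclusion_mask Logical vector, `TRUE` = exclude that subject.
#' @param alpha Significance level.
#' @return List with `n_before`, `n_after` (significant among the originally
#'   significant set), `fraction_retained`, and the two volcano tables.
#' @export
sensitivity_rerun <- function(matrix, labels, exclusion_mask, alpha = 0.05) {
  stopifnot(length(exclusion_mask) == nrow(matrix))
  before <- volcano(matrix, labels, alpha)
  keep <- !exclusion_mask
  g2 <- labels[keep]
  if (length(unique(g2)) < 2 || min(table(g2)) < 2)
    stop("exclusion leaves fewer than 2 subjects in a group", call. = FALSE)
  after <- volcano(matrix[keep, , drop = FALSE], g2, alpha)
  sig_before <- before$feature[before$significant]
  sig_after <- after$feature[after$significant]
  n_before <- length(sig_before)
  n_after <- length(intersect(sig_before, sig_after))
  list(
    n_before = n_before,
    n_after = n_after,
    fraction_retained = if (n_before == 0) 1 else n_after / n_before,
    volcano_before = before,
    volcano_after = after
  )
}
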