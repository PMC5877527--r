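#' Principal component analysis with a fixed sign convention
#'
#' Column-centered (unscaled: the integrated features already live on \[0,1\])
#' singular value decomposition. Signs are fixed so that the largest-magnitude
#' entry of each loading vector is positive, making runs reproducible.
#'
#' @param matrix Numeric subjects x features matrix.
#' @param n_components Number of components (default: all,
#'   `min(n_subjects - 1, n_features)`).
#' @return Object of class `pca_model`: `loadings` (features x components,
#'   orthonormal columns), `scores` (subjects x components), `explained`
#'   (fraction of total variance per component, non-increasing), `center`.
#' @export
pca_fit <- function(matrix, n_components = NULL) {
  x <- as.matrix(matrix)
  n <- nrow(x); p <- ncol(x)
  if (n < 2 || p < 1) stop("need >= 2 subjects and >= 1 feature", call. = FALSE)
  maxc <- min(n - 1, p)
  if (is.null(n_components)) n_components <- maxc
  if (n_components > maxc)
    stop(sprintf("n_components (%d) exceeds min(n-1, p) = %d",
                 n_components, maxc), call. = FALSE)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = n_components, nv = n_components)
  d <- sv$d
  expl <- d^2 / sum(d^2)
  loadings <- sv$v
  scores <- sv$u %*% diag(d[seq_len(n_components)], n_components, n_components)
  # sign convention: largest-|.| loading entry positive
  for (c_ in seq_len(n_components)) {
    j <- which.max(abs(loadings[, c_]))
    if (loadings[j, c_] < 0) {
      loadings[, c_] <- -loadings[, c_]
      scores[, c_] <- -scores[, c_]
    }
  }
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(n_components)))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(n_components)))
  structure(list(loadings = loadings, scores = scores,
                 explained = expl[seq_len(n_components)],
                 explained_all = expl, center = ctr),
            class = "pca_model")
}

#' Per-block contribution to a principal component
#'
#' Contribution of block B to component c is `100 * sum over features of B of
#' loading[f, c]^2`; since loading vectors are unit-norm the contributions over
#' all blocks sum to 100 percent. This is the accounting used to report the
#' relative importance of input sources (clinical, targeted, spectral channels)
#' for each component.
#'
#' @param pca_model A [pca_fit()] result.
#' @param block_map Named character vector mapping every feature to its block.
#' @param component Component index (or vector of indices).
#' @return Matrix: blocks x selected components, percentages.
#' @export
block_contribution <- function(pca_model, block_map, component = 1) {
  feats <- rownames(pca_model$loadings)
  unmapped <- setdiff(feats, names(block_map))
  if (length(unmapped) > 0)
    stop("features without a block: ", paste(utils::head(unmapped, 5),
                                             collapse = ", "), call. = FALSE)
  blocks <- block_map[feats]
  out <- vapply(component, function(c_) {
    l2 <- pca_model$loadings[, c_]^2
    100 * vapply(split(l2, blocks), sum, numeric(1))
  }, numeric(length(unique(blocks))))
  out <- base::matrix(out, ncol = length(component),
                      dimnames = list(sort(unique(blocks)),
                                      paste0("PC", component)))
  out
}

# dummy-code a factor into a centered indicator matrix
class_dummy <- function(y) {
  f <- factor(y)
  m <- stats::model.matrix(~ f - 1)
  colnames(m) <- levels(f)
  attr(m, "assign") <- NULL
  attr(m, "contrasts") <- NULL
  m
}

#' Fit a sparse PLS discriminant analysis model
#'
#' Classes are dummy-coded (one centered indicator column per class). Per
#' component, the first singular-vector pair of the cross-covariance between
#' the deflated data and the class matrix is computed; the data-side loading is
#' hard-thresholded to retain exactly `keepX[h]` largest-magnitude entries
#' (ties broken toward the lower feature index) and renormalized to unit norm.
#' Scores are the deflated data projected on the sparse loading; both data and
#' class matrices are then deflated on the score.
#'
#' @param matrix Numeric subjects x features matrix.
#' @param class_labels Class label per row (>= 2 classes, each n >= 2).
#' @param n_components Number of components.
#' @param keepX Number of variables retained per component; a scalar is
#'   recycled. Must satisfy `1 <= keepX <= n_features`.
#' @return Object of class `splsda_model`: `x_loadings` (sparse, features x
#'   components), `x_scores`, `p_loadings` (regression loadings used for
#'   deflation/projection), `keepX`, `selected` (list of selected feature names
#'   per component), `classes`, `center`.
#' @export
splsda_fit <- function(matrix, class_labels, n_components = 2, keepX = NULL) {
  x <- as.matrix(matrix)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- factor(class_labels)
  if (nlevels(y) < 2) stop("need >= 2 classes", call. = FALSE)
  if (min(table(y)) < 2) stop("each class needs n >= 2", call. = FALSE)
  p <- ncol(x)
  if (is.null(keepX)) keepX <- p
  keepX <- rep(as.integer(keepX), length.out = n_components)
  if (any(keepX < 1) || any(keepX > p))
    stop(sprintf("keepX must lie in [1, %d]", p), call. = FALSE)

  ctr <- colMeans(x)
  xh <- sweep(x, 2, ctr)
  ym <- class_dummy(y)
  yh <- sweep(ym, 2, colMeans(ym))

  u_all <- base::matrix(0, p, n_components,
                        dimnames = list(colnames(x), NULL))
  p_all <- base::matrix(0, p, n_components)
  scores <- base::matrix(0, nrow(x), n_components,
                         dimnames = list(rownames(x), NULL))
  selected <- vector("list", n_components)
  for (h in seq_len(n_components)) {
    M <- crossprod(xh, yh)                      # p x K
    sv <- svd(M, nu = 1, nv = 1)
    u <- sv$u[, 1]
    # retain exactly keepX[h] largest-|.| entries, ties to lower index
    ord <- order(-abs(u), seq_along(u))
    keep <- ord[seq_len(keepX[h])]
    us <- numeric(p)
    us[keep] <- u[keep]
    nrm <- sqrt(sum(us^2))
    if (nrm == 0) stop("degenerate loading (zero cross-covariance)",
                       call. = FALSE)
    us <- us / nrm
    t_ <- drop(xh %*% us)
    tt <- sum(t_^2)
    ph <- drop(crossprod(xh, t_)) / tt
    qh <- drop(crossprod(yh, t_)) / tt
    xh <- xh - tcrossprod(t_, ph)
    yh <- yh - tcrossprod(t_, qh)
    u_all[, h] <- us
    p_all[, h] <- ph
    scores[, h] <- t_
    selected[[h]] <- colnames(x)[sort(keep)]
  }
  structure(list(x_loadings = u_all, x_scores = scores, p_loadings = p_all,
                 keepX = keepX, selected = selected, classes = levels(y),
                 class_labels = y, center = ctr),
            class = "splsda_model")
}

#' Project new observations into an sPLS-DA score space
#'
#' Applies the training centering and the stored sequential deflation to new
#' rows, returning their component scores.
#'
#' @param model An [splsda_fit()] result.
#' @param newdata Numeric matrix with the training feature columns.
#' @return Scores matrix (rows x components).
#' @export
splsda_project <- function(model, newdata) {
  xh <- sweep(as.matrix(newdata), 2, model$center)
  H <- ncol(model$x_loadings)
  out <- base::matrix(0, nrow(xh), H)
  for (h in seq_len(H)) {
    t_ <- drop(xh %*% model$x_loadings[, h])
    out[, h] <- t_
    xh <- xh - tcrossprod(t_, model$p_loadings[, h])
  }
  out
}

# balanced error rate of nearest-class-centroid assignment in score space
ber_centroid <- function(train_scores, train_y, test_scores, test_y, ncomp) {
  tr <- train_scores[, seq_len(ncomp), drop = FALSE]
  te <- test_scores[, seq_len(ncomp), drop = FALSE]
  lev <- levels(train_y)
  centroids <- base::matrix(0, length(lev), ncomp)
  for (i in seq_along(lev))
    centroids[i, ] <- colMeans(tr[train_y == lev[i], , drop = FALSE])
  d2 <- outer(rowSums(te^2), rowSums(centroids^2), "+") -
    2 * te %*% t(centroids)
  pred <- lev[max.col(-d2, ties.method = "first")]
  per_class <- vapply(lev, function(l) {
    idx <- test_y == l
    if (!any(idx)) return(NA_real_)
    mean(pred[idx] != l)
  }, numeric(1))
  mean(per_class, na.rm = TRUE)
}

# stratified fold assignment; classes smaller than `folds` get each member its
# own recycled fold index (effectively leave-one-out within that class)
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (l in levels(y)) {
    idx <- which(y == l)
    fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold
}

#' Tune an sPLS-DA model by repeated stratified cross-validation
#'
#' Grid search over component counts and per-component `keepX` values using
#' repeated stratified k-fold cross-validation (defaults: 10 repeats of
#' 5-fold). Model quality is the balanced error rate (BER) of
#' nearest-class-centroid assignment in the cross-validated score space.
#' Selection is by minimal mean BER; ties break toward fewer components, then
#' toward smaller total `keepX`.
#'
#' @param matrix Numeric subjects x features matrix.
#' @param class_labels Class label per row.
#' @param component_grid Candidate component counts.
#' @param keepX_grid Candidate `keepX` values (scalar per component).
#' @param repeats,folds Cross-validation protocol (default 10 x 5-fold).
#' @param seed Integer seed making folds and the whole tuning reproducible.
#' @return List with `n_components`, `keepX`, and `cv_table` (`data.frame`:
#'   n_components, keepX, mean_ber, sd_ber).
#' @export
splsda_tune <- function(matrix, class_labels, component_grid = 1:3,
                        keepX_grid = c(10, 20, 30, 60),
                        repeats = 10, folds = 5, seed = 1L) {
  x <- as.matrix(matrix)
  y <- factor(class_labels)
  keepX_grid <- pmin(as.integer(keepX_grid), ncol(x))
  keepX_grid <- sort(unique(keepX_grid))
  maxc <- max(component_grid)
  set.seed(seed)
  small <- levels(y)[table(y) < folds]
  if (length(small) > 0)
    message("classes smaller than the fold count use leave-one-out folds: ",
            paste(small, collapse = ", "))

  ber <- array(NA_real_,
               c(length(keepX_grid), length(component_grid), repeats * folds))
  slot <- 0L
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      slot <- slot + 1L
      test <- fold == f
      if (!any(test) || length(unique(y[!test])) < nlevels(y)) next
      ytr <- droplevels(y[!test])
      if (min(table(ytr)) < 2) next
      for (ki in seq_along(keepX_grid)) {
        fit <- splsda_fit(x[!test, , drop = FALSE], ytr,
                          n_components = maxc, keepX = keepX_grid[ki])
        sc_te <- splsda_project(fit, x[test, , drop = FALSE])
        for (ci in seq_along(component_grid)) {
          ber[ki, ci, slot] <- ber_centroid(
            fit$x_scores, ytr, sc_te, factor(y[test], levels = levels(ytr)),
            component_grid[ci])
        }
      }
    }
  }
  cv <- expand.grid(keepX = keepX_grid, n_components = component_grid)
  cv$mean_ber <- NA_real_
  cv$sd_ber <- NA_real_
  for (i in seq_len(nrow(cv))) {
    ki <- match(cv$keepX[i], keepX_grid)
    ci <- match(cv$n_components[i], component_grid)
    v <- ber[ki, ci, ]
    cv$mean_ber[i] <- mean(v, na.rm = TRUE)
    cv$sd_ber[i] <- stats::sd(v, na.rm = TRUE)
  }
  cv <- cv[, c("n_components", "keepX", "mean_ber", "sd_ber")]
  ord <- order(cv$mean_ber, cv$n_components, cv$keepX)
  best <- cv[ord[1], ]
  list(n_components = best$n_components, keepX = best$keepX, cv_table = cv)
}
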