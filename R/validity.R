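#' Hierarchical clustering with euclidean distance and complete linkage
#'
#' Agglomerative clustering of subjects (rows) using euclidean distances and
#' the complete-linkage merge rule, under which merge heights are guaranteed
#' non-decreasing. Tie-breaking follows the deterministic lowest-index
#' convention of [stats::hclust()], so identical inputs give identical trees.
#'
#' @param matrix Numeric subjects x features matrix with unique row names.
#' @return An object of class `hclust`.
#' @export
hclust_complete <- function(matrix) {
  x <- as.matrix(matrix)
  if (nrow(x) < 2) stop("need >= 2 subjects", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  if (anyDuplicated(rownames(x)))
    stop("duplicate subject ids", call. = FALSE)
  stats::hclust(stats::dist(x), method = "complete")
}

#' Cut a dendrogram into k clusters
#'
#' Cuts the merge tree into `k` clusters; cluster ids are relabelled to be
#' contiguous 1..k in order of first appearance, so partitions are invariant
#' to the internal labelling of [stats::cutree()].
#'
#' @param dendrogram An `hclust` object.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector (subject -> cluster id) with attribute `k`.
#' @export
cut_k <- function(dendrogram, k) {
  n <- length(dendrogram$order)
  if (k < 1 || k > n) stop(sprintf("k must lie in [1, %d]", n), call. = FALSE)
  cl <- stats::cutree(dendrogram, k = k)
  out <- match(cl, unique(cl))
  names(out) <- names(cl)
  attr(out, "k") <- k
  out
}

#' Export a dendrogram as Newick text
#'
#' @param dendrogram An `hclust` object.
#' @param file Optional path; when given the tree is written there.
#' @return Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(dendrogram, file = NULL) {
  phy <- ape::as.phylo(dendrogram)
  txt <- ape::write.tree(phy, file = "")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# Calinski-Harabasz pseudo-F: [trace(B)/(k-1)] / [trace(W)/(n-k)]
ch_stat <- function(x, cl) {
  n <- nrow(x)
  k <- length(unique(cl))
  if (k < 2 || k > n - 1) return(NA_real_)
  grand <- colMeans(x)
  trW <- 0; trB <- 0
  for (c_ in unique(cl)) {
    xi <- x[cl == c_, , drop = FALSE]
    ci <- colMeans(xi)
    trW <- trW + sum(sweep(xi, 2, ci)^2)
    trB <- trB + nrow(xi) * sum((ci - grand)^2)
  }
  (trB / (k - 1)) / (trW / (n - k))
}

# orientation of each validity index: "max" = larger is better, "min" = smaller
# is better, NA = descriptive only (not compared in acceptance decisions)
index_orientation <- function() {
  c(calinski_harabasz = "max", davies_bouldin = "min", bh_gamma = "max",
    c_index = "min", silhouette = "max", dunn = "max",
    apn = NA, membership_entropy = NA,
    avg_within = NA, max_within = NA, avg_between = NA, max_between = NA)
}

#' Cluster-validity index battery
#'
#' Computes, from their definitions, the validity indices used to judge a
#' partition of subjects: Calinski-Harabasz pseudo-F, Davies-Bouldin index,
#' the Baker-Hubert adaptation of Goodman-Kruskal's gamma, the Hubert-Levine
#' C-index, Rousseeuw's mean silhouette width, the Dunn index (single-linkage
#' separation over maximal diameter), the entropy of the cluster-membership
#' distribution (natural log), and the average/maximal within- and
#' between-cluster euclidean distances. The leave-one-feature-out stability
#' index APN ([stability_apn()]) is included when `apn = TRUE`.
#'
#' Indices that need both within- and between-cluster structure are reported
#' `NA` with a reason when `k = 1` or `k = n`; a partition whose clusters all
#' have zero diameter reports `dunn = Inf`.
#'
#' @param matrix Numeric subjects x features matrix.
#' @param partition Cluster id per row (any labels; relabelled internally).
#' @param apn Also compute APN (re-clusters once per feature; costly for wide
#'   matrices).
#' @return Object of class `validity_report`: named list of index values with
#'   attributes `orientation` (see above) and `notes` (reasons for `NA`s).
#' @export
validity_report <- function(matrix, partition, apn = FALSE) {
  x <- as.matrix(matrix)
  cl <- match(partition, unique(partition))
  n <- nrow(x)
  stopifnot(length(cl) == n)
  k <- length(unique(cl))
  notes <- character(0)

  sizes <- tabulate(cl, k)
  prop <- sizes / n
  entropy <- -sum(prop * log(prop))

  out <- list(
    calinski_harabasz = NA_real_, davies_bouldin = NA_real_,
    bh_gamma = NA_real_, c_index = NA_real_, silhouette = NA_real_,
    dunn = NA_real_, apn = NA_real_, membership_entropy = entropy,
    avg_within = NA_real_, max_within = NA_real_,
    avg_between = NA_real_, max_between = NA_real_
  )

  d <- as.matrix(stats::dist(x))
  same <- outer(cl, cl, "==")
  ut <- upper.tri(d)
  dw <- d[ut & same]     # within-cluster pairwise distances
  db <- d[ut & !same]    # between-cluster pairwise distances

  if (length(dw) > 0) {
    out$avg_within <- mean(dw)
    out$max_within <- max(dw)
  } else notes <- c(notes, "no within-cluster pairs (k = n)")
  if (length(db) > 0) {
    out$avg_between <- mean(db)
    out$max_between <- max(db)
  } else notes <- c(notes, "no between-cluster pairs (k = 1)")

  if (k >= 2 && k <= n - 1) {
    centroids <- base::matrix(0, k, ncol(x))
    for (c_ in seq_len(k))
      centroids[c_, ] <- colMeans(x[cl == c_, , drop = FALSE])
    out$calinski_harabasz <- ch_stat(x, cl)

    # Davies-Bouldin: s_i = mean distance to own centroid
    s <- vapply(seq_len(k), function(c_) {
      mean(sqrt(rowSums(sweep(x[cl == c_, , drop = FALSE], 2,
                              centroids[c_, ])^2)))
    }, numeric(1))
    dcent <- as.matrix(stats::dist(centroids))
    rij <- outer(s, s, "+") / dcent
    rij[is.nan(rij)] <- Inf      # coincident zero-spread centroids
    diag(rij) <- -Inf
    out$davies_bouldin <- mean(apply(rij, 1, max))

    # Baker-Hubert gamma over (within, between) distance comparisons
    if (length(dw) > 0 && length(db) > 0) {
      sw <- sort(dw)
      # concordant: within < between; discordant: within > between; ties skip
      splus <- sum(findInterval(db, sw, left.open = TRUE))
      sminus <- sum(length(sw) - findInterval(db, sw))
      out$bh_gamma <- if (splus + sminus == 0) 0
                      else (splus - sminus) / (splus + sminus)

      # Hubert-Levine C-index
      l <- length(dw)
      all_sorted <- sort(d[ut])
      smin <- sum(all_sorted[seq_len(l)])
      smax <- sum(all_sorted[seq(length(all_sorted) - l + 1, length(all_sorted))])
      S <- sum(dw)
      out$c_index <- if (smax > smin) (S - smin) / (smax - smin) else 0
    }

    # silhouette (singletons get width 0 by convention)
    sil <- vapply(seq_len(n), function(i) {
      own <- cl[i]
      if (sizes[own] == 1) return(0)
      a <- sum(d[i, cl == own]) / (sizes[own] - 1)
      b <- min(vapply(setdiff(seq_len(k), own), function(c_)
        mean(d[i, cl == c_]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    out$silhouette <- mean(sil)

    # Dunn: min single-linkage separation / max diameter
    diam <- max(c(0, dw))
    sep <- min(db)
    out$dunn <- if (diam == 0) Inf else sep / diam
    if (diam == 0) notes <- c(notes, "zero max diameter: dunn = Inf")
  } else {
    notes <- c(notes, sprintf(
      "indices needing 2 <= k <= n-1 undefined for k = %d, n = %d", k, n))
  }

  if (apn) out$apn <- stability_apn(x, k, partition = cl)

  structure(out, class = "validity_report",
            orientation = index_orientation(), k = k, notes = notes)
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("validity report (k = %d)\n", attr(x, "k")))
  v <- unlist(x)
  ori <- attr(x, "orientation")[names(v)]
  for (nm in names(v))
    cat(sprintf("  %-20s %10.4f  %s\n", nm, v[[nm]],
                ifelse(is.na(ori[nm]), "", paste0("(", ori[nm], ")"))))
  if (length(attr(x, "notes")) > 0)
    cat("  notes:", paste(attr(x, "notes"), collapse = "; "), "\n")
  invisible(x)
}

#' Average proportion of non-overlap (APN)
#'
#' Leave-one-feature-out cluster stability: for each feature column, the
#' subjects are re-clustered with that column removed (same clusterer, same
#' k), and for each subject the proportion of its original co-cluster members
#' not shared with its new cluster is recorded. APN is the average of these
#' non-overlap proportions over subjects and deleted columns; 0 means
#' perfectly stable cluster assignments, values near `1 - 1/k` indicate
#' cluster labels unrelated to the data.
#'
#' @param matrix Numeric subjects x features matrix with >= 2 features.
#' @param k Number of clusters.
#' @param clusterer Function `(matrix, k) -> partition`; the default is
#'   complete-linkage hierarchical clustering cut at `k`.
#' @param partition Optional original partition; computed with `clusterer`
#'   when missing.
#' @return APN in \[0, 1\].
#' @export
stability_apn <- function(matrix, k,
                          clusterer = function(m, k) cut_k(hclust_complete(m), k),
                          partition = NULL) {
  x <- as.matrix(matrix)
  if (ncol(x) < 2)
    stop("APN needs >= 2 features (one is deleted at a time)", call. = FALSE)
  if (is.null(partition)) partition <- clusterer(x, k)
  orig <- match(partition, unique(partition))
  n <- nrow(x)
  total <- 0
  for (j in seq_len(ncol(x))) {
    newp <- clusterer(x[, -j, drop = FALSE], k)
    newp <- match(newp, unique(newp))
    tab <- table(orig, newp)
    osz <- rowSums(tab)
    overlap <- vapply(seq_len(n), function(i)
      tab[orig[i], newp[i]] / osz[orig[i]], numeric(1))
    total <- total + sum(1 - overlap)
  }
  total / (n * ncol(x))
}
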