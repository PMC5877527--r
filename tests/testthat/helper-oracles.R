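# Independent brute-force oracles used across tests. These deliberately use
# plain double loops over pairs and the definitional formulas, sharing no code
# with the package implementations.

oracle_dist <- function(x) as.matrix(dist(x))

oracle_validity <- function(x, cl) {
  x <- as.matrix(x)
  cl <- as.integer(factor(cl))
  n <- nrow(x)
  k <- max(cl)
  d <- oracle_dist(x)

  within <- c(); between <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (cl[i] == cl[j]) within <- c(within, d[i, j])
    else between <- c(between, d[i, j])
  }

  # Calinski-Harabasz
  grand <- colMeans(x)
  trW <- 0; trB <- 0
  for (c_ in 1:k) {
    xi <- x[cl == c_, , drop = FALSE]
    ci <- colMeans(xi)
    for (r in seq_len(nrow(xi))) trW <- trW + sum((xi[r, ] - ci)^2)
    trB <- trB + nrow(xi) * sum((ci - grand)^2)
  }
  ch <- (trB / (k - 1)) / (trW / (n - k))

  # Davies-Bouldin
  s <- numeric(k); cent <- matrix(0, k, ncol(x))
  for (c_ in 1:k) {
    xi <- x[cl == c_, , drop = FALSE]
    cent[c_, ] <- colMeans(xi)
    s[c_] <- mean(apply(xi, 1, function(r) sqrt(sum((r - cent[c_, ])^2))))
  }
  db_terms <- numeric(k)
  for (i in 1:k) {
    best <- -Inf
    for (j in 1:k) if (j != i) {
      dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      v <- (s[i] + s[j]) / dij
      if (is.nan(v)) v <- Inf
      if (v > best) best <- v
    }
    db_terms[i] <- best
  }
  db <- mean(db_terms)

  # Baker-Hubert gamma
  splus <- 0; sminus <- 0
  for (w in within) for (b in between) {
    if (w < b) splus <- splus + 1
    else if (w > b) sminus <- sminus + 1
  }
  gam <- if (splus + sminus == 0) 0 else (splus - sminus) / (splus + sminus)

  # C-index
  l <- length(within)
  alls <- sort(c(within, between))
  smin <- sum(alls[1:l])
  smax <- sum(rev(alls)[1:l])
  cind <- if (smax > smin) (sum(within) - smin) / (smax - smin) else 0

  # silhouette
  sil <- numeric(n)
  for (i in 1:n) {
    own <- cl[i]
    nown <- sum(cl == own)
    if (nown == 1) { sil[i] <- 0; next }
    a <- mean(d[i, cl == own & seq_len(n) != i])
    b <- Inf
    for (c_ in setdiff(1:k, own)) b <- min(b, mean(d[i, cl == c_]))
    sil[i] <- (b - a) / max(a, b)
  }

  # Dunn
  diam <- if (length(within) > 0) max(within) else 0
  sep <- min(between)
  dunn <- if (diam == 0) Inf else sep / diam

  ent <- 0
  for (c_ in 1:k) {
    p <- sum(cl == c_) / n
    ent <- ent - p * log(p)
  }

  list(calinski_harabasz = ch, davies_bouldin = db, bh_gamma = gam,
       c_index = cind, silhouette = mean(sil), dunn = dunn,
       membership_entropy = ent,
       avg_within = mean(within), max_within = max(within),
       avg_between = mean(between), max_between = max(between))
}

oracle_apn <- function(x, k, orig = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  clusterer <- function(m) cutree(hclust(dist(m), "complete"), k)
  if (is.null(orig)) orig <- clusterer(x)
  orig <- as.integer(factor(orig))
  acc <- 0
  for (j in seq_len(ncol(x))) {
    newp <- clusterer(x[, -j, drop = FALSE])
    for (i in 1:n) {
      members <- which(orig == orig[i])
      shared <- sum(newp[members] == newp[i])
      acc <- acc + (1 - shared / length(members))
    }
  }
  acc / (n * ncol(x))
}

oracle_pca <- function(x, ncomp) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(cov(xc), symmetric = TRUE)
  list(loadings = ev$vectors[, 1:ncomp, drop = FALSE],
       explained = ev$values / sum(ev$values),
       scores = xc %*% ev$vectors[, 1:ncomp, drop = FALSE])
}

# first PLS-DA direction: leading left singular vector of t(Xc) %*% Yc
oracle_pls_direction <- function(x, y) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  ym <- sapply(levels(factor(y)), function(l) as.numeric(y == l))
  yc <- scale(ym, center = TRUE, scale = FALSE)
  svd(t(xc) %*% yc)$u[, 1]
}

cosine_sim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# small random clustering fixture: n points, p dims, k clusters
random_fixture <- function(n, p = 2, k = NULL) {
  if (is.null(k)) k <- sample(2:(n - 1), 1)
  x <- matrix(rnorm(n * p), n, p)
  cl <- sample(rep(1:k, length.out = n))
  list(x = x, cl = cl, k = k)
}
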