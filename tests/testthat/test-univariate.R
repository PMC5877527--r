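test_that("volcano matches the pooled two-sample t-test feature by feature", {
  set.seed(10)
  x <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  g <- rep(c("COPD", "control"), c(14, 16))
  x[g == "COPD", 1:3] <- x[g == "COPD", 1:3] + 1
  v <- volcano(x, g)
  for (j in 1:12) {
    tt <- t.test(x[g == "COPD", j], x[g == "control", j], var.equal = TRUE)
    expect_equal(v$p[j], tt$p.value, tolerance = 1e-12)
    expect_equal(v$effect[j], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
  vw <- volcano(x, g, welch = TRUE)
  tw <- t.test(x[g == "COPD", 5], x[g == "control", 5])
  expect_equal(vw$p[5], tw$p.value, tolerance = 1e-12)
})

test_that("a feature identical in both groups is degenerate, not significant", {
  x <- cbind(flat = rep(1, 10), ok = rnorm(10))
  g <- rep(c("a", "b"), each = 5)
  v <- volcano(x, g)
  expect_true(v$degenerate[1])
  expect_false(v$significant[1])
  expect_true(is.na(v$p[1]))
  expect_equal(attr(v, "n_significant"), sum(v$significant))
})

test_that("volcano p-values agree in rank with a permutation oracle", {
  set.seed(33)
  n <- 20
  x <- matrix(rnorm(n * 20), n, 20)
  g <- rep(c("A", "B"), each = 10)
  x[g == "A", 1:6] <- x[g == "A", 1:6] + seq(0.5, 3, length.out = 6)
  v <- volcano(x, g)
  # permutation null of |mean difference| per feature
  B <- 20000
  ga <- g == "A"
  obs <- abs(colMeans(x[ga, ]) - colMeans(x[!ga, ]))
  perm_p <- numeric(ncol(x))
  ind <- replicate(B, sample(ga))
  pa <- crossprod(ind, x) / sum(ga)            # B x p means of "A" draw
  pb <- crossprod(1 - ind, x) / sum(!ga)
  absdiff <- abs(pa - pb)
  for (j in seq_len(ncol(x)))
    perm_p[j] <- (sum(absdiff[, j] >= obs[j]) + 1) / (B + 1)
  expect_gt(cor(rank(v$p), rank(perm_p), method = "spearman"), 0.95)
})

test_that("planted sphingomyelin decreases surface with negative effects", {
  cfg <- cohort_config(seed = 21)
  sub <- generate_clinical(cfg, seed = 21)
  tg <- generate_targeted(sub, cfg, seed = 22)
  sm_cols <- targeted_panel()$analyte[targeted_panel()$class %in%
                                        c("SM", "SM_OH")]
  v <- volcano(max_scale(as.matrix(tg[, sm_cols])), sub$group)
  expect_true(all(v$effect < 0))
  expect_gt(mean(v$significant), 0.5)
})

test_that("ANOVA and Tukey HSD match the base-R oracle", {
  set.seed(5)
  g <- rep(c("A", "B", "C", "D"), c(4, 5, 6, 10))
  x <- matrix(rnorm(25 * 6), 25, 6, dimnames = list(NULL, paste0("f", 1:6)))
  x[g == "C", 2] <- x[g == "C", 2] + 2
  res <- anova_tukey(x, g)
  for (j in 1:6) {
    fit <- aov(x[, j] ~ factor(g))
    expect_equal(res$anova$p[j], summary(fit)[[1]][["Pr(>F)"]][1],
                 tolerance = 1e-10)
    th <- TukeyHSD(fit)[[1]]
    ours <- res$tukey[res$tukey$feature == paste0("f", j), ]
    expect_equal(ours$p[match(rownames(th), ours$pair)],
                 unname(th[, "p adj"]), tolerance = 1e-8)
    expect_equal(ours$diff[match(rownames(th), ours$pair)],
                 unname(th[, "diff"]), tolerance = 1e-10)
  }
})

test_that("a stratum shifted by three SDs is flagged against every other", {
  set.seed(6)
  g <- rep(c("A", "B", "C"), each = 8)
  x <- matrix(rnorm(24), 24, 1, dimnames = list(NULL, "f"))
  x[g == "B", 1] <- x[g == "B", 1] + 3
  res <- anova_tukey(x, g)
  b_pairs <- res$tukey[grepl("B", res$tukey$pair), ]
  expect_true(all(b_pairs$p < 0.05))
  expect_true(res$anova$tier %in% c("high", "moderate"))
})

test_that("Tukey p-values never undercut the pooled pairwise t-test", {
  set.seed(8)
  n <- 18; k <- 4
  for (rep_ in 1:10) {
    g <- rep(c("A", "B", "C", "D"), c(3, 4, 5, 6))
    x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "f"))
    res <- anova_tukey(x, g)
    # unadjusted pairwise t sharing the ANOVA mean-square error
    ni <- table(g)
    means <- tapply(x[, 1], g, mean)
    msw <- sum((x[, 1] - means[g])^2) / (n - k)
    for (pr in seq_len(nrow(res$tukey))) {
      ab <- strsplit(res$tukey$pair[pr], "-")[[1]]
      se <- sqrt(msw * (1 / ni[[ab[1]]] + 1 / ni[[ab[2]]]))
      p_t <- 2 * pt(abs(res$tukey$diff[pr]) / se, n - k, lower.tail = FALSE)
      expect_gte(res$tukey$p[pr] + 1e-12, p_t)
    }
  }
  # with exactly two strata the Tukey comparison is the pooled t-test
  g2 <- rep(c("A", "B"), c(6, 6))
  x2 <- matrix(rnorm(12), ncol = 1, dimnames = list(NULL, "f"))
  res2 <- anova_tukey(x2, g2)
  tt <- t.test(x2[g2 == "A", 1], x2[g2 == "B", 1], var.equal = TRUE)
  expect_equal(res2$tukey$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA null p-values are uniform across strata", {
  set.seed(9)
  ps <- unlist(lapply(1:20, function(i) {
    g <- rep(c("A", "B", "C", "D"), c(5, 5, 5, 10))
    x <- matrix(rnorm(25 * 20), 25, 20, dimnames = list(NULL, paste0("f", 1:20)))
    anova_tukey(x, g)$anova$p
  }))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the planted GOLD-C polyamine shift is localized by Tukey HSD", {
  hits <- vapply(1:10, function(s) {
    cfg <- cohort_config(seed = s, effect_table = data.frame(
      target = c("Putrescine", "Orn"), contrast = "GOLD:C",
      effect = c(3, -2.5)))
    sub <- generate_clinical(cfg, seed = s)
    tg <- generate_targeted(sub, cfg, seed = s + 40)
    copd <- sub$group == "COPD"
    m <- matrix(tg[["Putrescine/Orn"]][copd], ncol = 1,
                dimnames = list(NULL, "Putrescine/Orn"))
    suppressWarnings({
      res <- anova_tukey(m, sub$gold[copd])
    })
    cb <- res$tukey$significant[res$tukey$pair %in% c("C-B", "B-C")]
    cd <- res$tukey$significant[res$tukey$pair %in% c("D-C", "C-D")]
    isTRUE(cb) && isTRUE(cd)
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("association cells reproduce exact and brute-force correlations", {
  cfg <- small_cohort_config(seed = 4)
  sub <- generate_clinical(cfg, seed = 4)
  sub <- sub[sub$group == "COPD", ]
  tg <- generate_targeted(sub, cfg, seed = 5)
  tg$Constructed <- 2 * sub$pack_years
  tab <- association_table(tg, sub, metabolites = c("Glu", "Constructed"))
  cell <- tab[tab$metabolite == "Constructed" &
                tab$clinical_variable == "pack_years", ]
  expect_equal(cell$value, 1, tolerance = 1e-12)
  expect_true(cell$notable)
  # brute-force covariance-formula oracle
  r_oracle <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  glu <- tab[tab$metabolite == "Glu" & tab$kind == "pearson_r", ]
  for (i in seq_len(nrow(glu)))
    expect_equal(glu$value[i],
                 r_oracle(sub[[glu$clinical_variable[i]]], tg$Glu),
                 tolerance = 1e-12)
  # correlation is symmetric and affine-invariant
  x <- sub$pack_years; y <- tg$Glu
  expect_equal(r_oracle(x, y), r_oracle(y, x), tolerance = 1e-14)
  expect_equal(r_oracle(3 * x + 7, y), r_oracle(x, y), tolerance = 1e-12)
})

test_that("association p-values are uniform when metabolite and flag are independent", {
  set.seed(11)
  ps <- unlist(lapply(1:40, function(i) {
    sub <- data.frame(ics = rbinom(25, 1, 0.5))
    panel <- data.frame(subject_id = 1:25, M = rlnorm(25))
    tab <- association_table(panel, sub, continuous_vars = character(0),
                             categorical_vars = "ics", metabolites = "M")
    tab$value
  }))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a constant metabolite yields a degenerate association cell", {
  sub <- data.frame(pack_years = rnorm(10), ics = rbinom(10, 1, 0.5))
  panel <- data.frame(subject_id = 1:10, M = rep(2, 10))
  tab <- association_table(panel, sub, continuous_vars = "pack_years",
                           categorical_vars = "ics", metabolites = "M")
  expect_true(all(tab$degenerate))
  expect_true(all(is.na(tab$value)))
})

test_that("sensitivity re-runs report retention over the original hits", {
  res <- small_integrated(small_cohort_config(seed = 9))
  im <- res$im
  g <- im$subjects$group
  # empty exclusion is the identity
  s0 <- sensitivity_rerun(im$values, g, rep(FALSE, nrow(im$values)))
  expect_equal(s0$fraction_retained, 1)
  expect_equal(s0$n_after, s0$n_before)
  # excluding all females runs: females exist only among controls
  excl <- im$subjects$sex == "F"
  s1 <- sensitivity_rerun(im$values, g, excl)
  expect_true(s1$fraction_retained >= 0 && s1$fraction_retained <= 1)
  # emptying a group errors
  expect_error(sensitivity_rerun(im$values, g, g == "control"),
               "fewer than 2")
})

test_that("strong effects survive unstructured subject exclusion", {
  fr <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 40
    g <- rep(c("COPD", "control"), each = 20)
    x <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("f", 1:30)))
    x[g == "COPD", 1:15] <- x[g == "COPD", 1:15] + 1.8
    excl <- seq_len(n) %in% sample(n, 8)
    sensitivity_rerun(x, g, excl)$fraction_retained
  }, numeric(1))
  expect_gt(median(fr), 0.8)
})
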