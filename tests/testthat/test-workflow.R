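test_that("dataset enumeration spans the full 2 x 2 x 6 cross-product", {
  res <- small_integrated()
  ds <- enumerate_datasets(res$im)
  expect_length(ds, 24)
  grid <- expand.grid(scope = c("all_subjects", "copd_only"),
                      rep = c("original_features", "retained_pcs"),
                      subset = c("all", "clinical", "targeted",
                                 "serum_profiles", "ebc_profiles",
                                 "metabolomic"))
  expect_setequal(names(ds),
                  paste(grid$scope, grid$rep, grid$subset, sep = "."))
  copd_only <- Filter(function(d) d$cohort_scope == "copd_only", ds)
  expect_length(copd_only, 12)
  n_copd <- sum(res$im$subjects$group == "COPD")
  for (d in copd_only) expect_equal(nrow(d$matrix), n_copd)
})

test_that("every dataset's features come only from its declared blocks", {
  res <- small_integrated()
  ds <- enumerate_datasets(res$im)
  subsets <- list(
    all = c("clinical", "targeted", "serum-pos", "serum-neg",
            "ebc-pos", "ebc-neg"),
    clinical = "clinical", targeted = "targeted",
    serum_profiles = c("serum-pos", "serum-neg"),
    ebc_profiles = c("ebc-pos", "ebc-neg"),
    metabolomic = c("targeted", "serum-pos", "serum-neg",
                    "ebc-pos", "ebc-neg"))
  for (d in Filter(function(d) d$representation == "original_features", ds)) {
    used <- unique(unname(res$im$block[colnames(d$matrix)]))
    expect_setequal(used, subsets[[d$source_subset]])
  }
  # PC representations keep only components above the variance threshold
  for (d in Filter(function(d) d$representation == "retained_pcs", ds)) {
    fit <- pca_fit(d$control_matrix)
    expect_equal(ncol(d$matrix), sum(fit$explained >= 0.05))
  }
  expect_error(enumerate_datasets(
    structure(list(values = res$im$values[, res$im$block == "clinical"],
                   block = res$im$block[res$im$block == "clinical"],
                   subjects = res$im$subjects),
              class = "integrated_matrix")),
    "lacks block")
})

test_that("the positive control reports a four-group partition for patients", {
  res <- small_integrated()
  ds <- enumerate_datasets(res$im)
  ctrl <- positive_control(ds[["copd_only.original_features.targeted"]],
                           res$im$subjects)
  expect_s3_class(ctrl, "validity_report")
  expect_equal(attr(ctrl, "k"), 4)
  expect_setequal(unique(attr(ctrl, "labels")), c("A", "B", "C", "D"))
  ctrl_all <- positive_control(ds[["all_subjects.original_features.targeted"]],
                               res$im$subjects)
  expect_equal(attr(ctrl_all, "k"), 5)   # controls form a fifth group
})

test_that("GOLD-aligned structure beats equal-size random partitions", {
  # scenario with strong GOLD-stratum markers in the targeted panel
  gold_fx <- data.frame(
    target = c("class:lysoPC", "Kynurenine", "Putrescine", "Orn"),
    contrast = c("GOLD:A", "GOLD:B", "GOLD:C", "GOLD:C"),
    effect = c(3, 3, 3, -3))
  cfg <- cohort_config(seed = 31, n_peaks = 60, effect_table = gold_fx)
  co <- generate_cohort(cfg)
  im <- suppressWarnings(integrate_blocks(co$subjects, co$targeted, co$peaks))
  ds <- enumerate_datasets(im)
  d <- ds[["copd_only.original_features.targeted"]]
  ctrl <- positive_control(d, im$subjects)
  labels <- attr(ctrl, "labels")
  # permutation baseline in the same (raw targeted) space
  set.seed(32)
  raw_ctrl <- positive_control(d, im$subjects, space = "raw")
  base_ch <- vapply(1:1000, function(i) {
    perm <- sample(labels)
    validity_report(d$matrix, match(perm, unique(perm)))$calinski_harabasz
  }, numeric(1))
  p <- (sum(base_ch >= raw_ctrl$calinski_harabasz) + 1) / 1001
  expect_lt(p, 0.01)
})

test_that("a permuted-label positive control has near-zero silhouette", {
  set.seed(33)
  sils <- vapply(1:5, function(s) {
    res <- small_integrated(small_cohort_config(
      seed = s, effect_table = default_effect_table()[0, ]))
    ds <- enumerate_datasets(res$im)
    d <- ds[["copd_only.original_features.targeted"]]
    ctrl <- positive_control(d, res$im$subjects, space = "raw")
    ctrl$silhouette
  }, numeric(1))
  expect_lt(abs(mean(sils)), 0.1)
})

test_that("de novo clustering finds the planted subtype count", {
  hits <- vapply(1:8, function(s) {
    res <- small_integrated(small_cohort_config(seed = s, subtype_k = 2,
                                                subtype_effect = 4))
    ds <- enumerate_datasets(res$im)
    dn <- run_denovo(ds[["copd_only.original_features.targeted"]], 2:6)
    unname(dn$best_k["calinski_harabasz"]) == 2
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("structureless data scatter the per-index optima", {
  disagreement <- vapply(1:8, function(s) {
    res <- small_integrated(small_cohort_config(
      seed = s, effect_table = default_effect_table()[0, ]))
    ds <- enumerate_datasets(res$im)
    dn <- run_denovo(ds[["copd_only.original_features.serum_profiles"]], 2:8)
    length(unique(na.omit(dn$best_k)))
  }, numeric(1))
  expect_gte(median(disagreement), 3)
})

test_that("the acceptance rule rejects on misclassification and quality", {
  res <- small_integrated(small_cohort_config(seed = 41, subtype_k = 2,
                                              subtype_effect = 4))
  im <- res$im
  ds <- enumerate_datasets(im)
  d <- ds[["copd_only.original_features.targeted"]]
  dn <- run_denovo(d, 2:6)
  ctrl <- positive_control(d, im$subjects)
  set.seed(42)
  dec <- accept_dataset(d, dn, ctrl, im$subjects$group)
  expect_true(dec$accepted)
  expect_equal(dec$best_k, 2)
  expect_gte(dec$ch_null_z, 3)

  # an artificially unbeatable control is rejected on quality grounds
  harsh <- ctrl
  harsh$calinski_harabasz <- ctrl$calinski_harabasz * 100
  harsh$silhouette <- 0.999
  harsh$dunn <- 100
  harsh$davies_bouldin <- 1e-4
  harsh$c_index <- 1e-6
  harsh$bh_gamma <- 0.9999
  set.seed(42)
  dec2 <- accept_dataset(d, dn, harsh, im$subjects$group)
  expect_false(dec2$accepted)
  expect_true(any(grepl("positive control", dec2$reasons)))

  # misclassification above the allowance is rejected with that reason
  d_all <- ds[["all_subjects.original_features.ebc_profiles"]]
  dn_all <- run_denovo(d_all, 2:6)
  ctrl_all <- suppressWarnings(positive_control(d_all, im$subjects))
  weak <- ctrl_all
  for (nm in c("calinski_harabasz", "bh_gamma", "silhouette", "dunn"))
    weak[[nm]] <- -1e6
  for (nm in c("davies_bouldin", "c_index")) weak[[nm]] <- 1e6
  set.seed(43)
  dec3 <- accept_dataset(d_all, dn_all, weak, im$subjects$group)
  mis <- dec3$misclassified
  if (mis > 2) {
    expect_false(dec3$accepted)
    expect_true(any(grepl("misclassification", dec3$reasons)))
  } else succeed("EBC cut happened to split by group")
})

test_that("improving every index never flips acceptance to rejection", {
  res <- small_integrated(small_cohort_config(seed = 44, subtype_k = 2,
                                              subtype_effect = 4))
  im <- res$im
  ds <- enumerate_datasets(im)
  d <- ds[["copd_only.original_features.targeted"]]
  dn <- run_denovo(d, 2:6)
  ctrl <- positive_control(d, im$subjects)
  set.seed(45)
  base <- accept_dataset(d, dn, ctrl, im$subjects$group)
  # a uniformly easier control can only keep or gain acceptance
  easier <- ctrl
  easier$calinski_harabasz <- ctrl$calinski_harabasz / 2
  easier$silhouette <- ctrl$silhouette - 0.2
  easier$dunn <- ctrl$dunn / 2
  easier$bh_gamma <- ctrl$bh_gamma - 0.2
  easier$davies_bouldin <- ctrl$davies_bouldin * 2
  easier$c_index <- min(1, ctrl$c_index * 2 + 0.05)
  set.seed(45)
  eased <- accept_dataset(d, dn, easier, im$subjects$group)
  expect_gte(eased$accepted, base$accepted)
})

test_that("adjusted Rand agrees with the mclust reference", {
  suppressMessages(requireNamespace("mclust", quietly = TRUE))
  set.seed(46)
  for (i in 1:20) {
    a <- sample(1:3, 15, replace = TRUE)
    b <- sample(1:4, 15, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand(1:5, c(2, 3, 4, 5, 1)), 1)
})

test_that("the workflow is reproducible and writes its report", {
  res <- small_integrated(small_cohort_config(seed = 47))
  wf1 <- run_workflow(res$im, k_range = 2:5, null_draws = 30, seed = 48)
  wf2 <- run_workflow(res$im, k_range = 2:5, null_draws = 30, seed = 48)
  expect_identical(wf1$summary, wf2$summary)
  expect_identical(wf1$decisions, wf2$decisions)
  expect_equal(nrow(wf1$summary), 24)
  dir <- withr::local_tempdir()
  write_workflow(wf1, dir)
  expect_true(file.exists(file.path(dir, "workflow_summary.tsv")))
  expect_true(file.exists(file.path(dir, "validity.tsv")))
  expect_true(file.exists(file.path(dir, "acceptance.md")))
  expect_length(list.files(file.path(dir, "dendrograms")), 24)
})
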