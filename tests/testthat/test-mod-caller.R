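sep_features <- function(n_per_class, seed) {
  # well-separated synthetic feature build: positives mismatch ~ Beta around
  # 0.5, negatives around 0.01; everything else mildly informative noise
  set.seed(seed)
  n <- 2 * n_per_class
  rows <- lapply(seq_len(n), function(i) {
    pos_class <- i <= n_per_class
    mm <- if (pos_class) stats::rbeta(1, 20, 20) else stats::rbeta(1, 1, 99)
    cov <- 500L
    nm <- round(cov * mm)
    profile_row("f", i, "A", cov, prebase = "C", mismatch = mm,
                A = cov - nm, T = nm,
                arrest = if (pos_class) stats::runif(1, 0.2, 0.8)
                else stats::runif(1, 0, 0.05))
  })
  prof <- do.call(rbind, rows)
  class(prof) <- c("rt_profile", "data.frame")
  labels <- data.frame(ref_seg = "f", pos = seq_len(n_per_class))
  build_features(prof, labels)
}

test_that("the default feature schema has 15 features per row", {
  prof <- candidates_profile()
  feats <- build_features(prof)
  expect_equal(ncol(feats), 15L)
  expect_equal(nrow(feats), nrow(prof))
})

test_that("rate features are all zero on unmodified simulated data", {
  ref <- simulate_reference(1, 50, seed = 201)
  sim <- simulate_pileup(ref, NULL, depth = 200, seed = 202)
  feats <- build_features(compute_profile(sim$pileup, ref))
  for (col in c("mismatch", "arrest", "single_jump_direct",
                "single_jump_delayed", "double_jump",
                "fraction_as_G", "fraction_as_T", "fraction_as_C")) {
    vals <- feats[[col]]
    rb <- compute_profile(sim$pileup, ref)$refbase
    if (col %in% c("fraction_as_G", "fraction_as_T", "fraction_as_C")) {
      # the fraction matching the reference base is 1, all others 0
      target <- sub("fraction_as_", "", col)
      expect_equal(vals[rb != target], rep(0, sum(rb != target)))
    } else {
      expect_equal(vals, rep(0, length(vals)))
    }
  }
})

test_that("labelled builds restrict negatives to the positives' modal base", {
  ds <- make_labeled_dataset(n_refs = 2, ref_length = 60, depth = 300,
                             seed = 210)
  feats <- build_features(ds$profile, ds$positives)
  lab <- attr(feats, "label")
  expect_equal(sum(lab == "modified"), nrow(ds$positives))
  # all retained rows are adenosines (the planted base)
  key <- paste(attr(feats, "ref_seg"), attr(feats, "pos"))
  prof_key <- paste(ds$profile$ref_seg, ds$profile$pos)
  expect_true(all(ds$profile$refbase[match(key, prof_key)] == "A"))
})

test_that("labels for absent positions are dropped with a warning", {
  prof <- candidates_profile()
  labels <- data.frame(ref_seg = c(prof$ref_seg[1], "nonexistent"),
                       pos = c(prof$pos[1], 999L))
  expect_warning(feats <- build_features(prof, labels), "1 label")
  expect_equal(sum(attr(feats, "label") == "modified"), 1L)
})

test_that("training balances classes 1:1 exactly before cross-validation", {
  feats <- sep_features(30, seed = 301)
  # add extra negatives to unbalance
  caller <- train_caller(feats, n_trees = 100, cv_repeats = 2, seed = 7)
  expect_equal(caller$n_balanced, 2L * 30L)

  unbal <- sep_features(25, seed = 302)
  lab <- attr(unbal, "label")
  lab[1:10] <- "unmodified"   # 15 positives vs 35 negatives
  caller2 <- train_caller(unbal, labels = lab, n_trees = 100,
                          cv_repeats = 2, seed = 7)
  expect_equal(caller2$n_balanced, 30L)
})

test_that("well-separated classes reach near-perfect cross-validated AUROC
           and shuffled labels stay at chance", {
  feats <- sep_features(100, seed = 310)
  caller <- train_caller(feats, n_trees = 200, cv_folds = 5, cv_repeats = 3,
                         seed = 11)
  expect_gt(caller$cv_report$auroc_mean, 0.99)

  set.seed(12)
  shuffled <- sample(attr(feats, "label"))
  chance <- train_caller(feats, labels = shuffled, n_trees = 200,
                         cv_folds = 5, cv_repeats = 3, seed = 11)
  expect_gt(chance$cv_report$auroc_mean, 0.4)
  expect_lt(chance$cv_report$auroc_mean, 0.6)
})

test_that("training is deterministic for a fixed seed", {
  feats <- sep_features(30, seed = 320)
  c1 <- train_caller(feats, n_trees = 100, cv_repeats = 2, seed = 42)
  c2 <- train_caller(feats, n_trees = 100, cv_repeats = 2, seed = 42)
  expect_identical(c1$cv_report, c2$cv_report)
  expect_identical(predict(c1, feats)$probability,
                   predict(c2, feats)$probability)
  # on label-noise data the forest is forced to fit bootstrap noise, so a
  # different seed produces measurably different vote fractions (separable
  # data would vote unanimously under any seed)
  set.seed(99)
  noisy <- sample(attr(feats, "label"))
  c3 <- train_caller(feats, labels = noisy, n_trees = 100, cv_repeats = 2,
                     seed = 43)
  c4 <- train_caller(feats, labels = noisy, n_trees = 100, cv_repeats = 2,
                     seed = 44)
  expect_false(identical(predict(c3, feats)$probability,
                         predict(c4, feats)$probability))
})

test_that("too few minority instances is a hard error", {
  feats <- sep_features(30, seed = 330)
  lab <- attr(feats, "label")
  lab[lab == "modified"][seq_len(sum(lab == "modified") - 3L)] <- "unmodified"
  expect_error(train_caller(feats, labels = lab, cv_folds = 5),
               "not compatible")
})

test_that("prediction scores separable training data nearly perfectly and
           respects contracts", {
  feats <- sep_features(60, seed = 340)
  caller <- train_caller(feats, n_trees = 200, cv_repeats = 2, seed = 5)
  calls <- predict(caller, feats)
  expect_true(all(calls$probability >= 0 & calls$probability <= 1))
  truth <- attr(feats, "label") == "modified"
  expect_gte(mean(calls$call == truth), 0.95)

  empty <- candidates_profile()[0, ]
  expect_equal(nrow(predict(caller, empty)), 0L)

  broken <- feats[, setdiff(names(feats), "arrest")]
  expect_error(predict(caller, broken), "arrest")
})

test_that("saved models reload and predict bit-identically", {
  feats <- sep_features(30, seed = 350)
  caller <- train_caller(feats, n_trees = 100, cv_repeats = 2, seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  save_caller(caller, f)
  back <- load_caller(f)
  expect_identical(predict(back, feats)$probability,
                   predict(caller, feats)$probability)
  expect_identical(back$config, caller$config)
})

test_that("corrupted or foreign model files are refused", {
  f <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", f)
  expect_error(load_caller(f))
  saveRDS(list(a = 1), f)
  expect_error(load_caller(f), "not a saved rtsig caller")
})

test_that("the rank-based AUROC agrees with an independent ROC implementation", {
  set.seed(360)
  for (i in 1:5) {
    scores <- c(stats::rnorm(40, 1), stats::rnorm(60, 0))
    labels <- rep(c(TRUE, FALSE), c(40, 60))
    scores <- round(scores, 1)  # force ties
    ours <- auroc(scores, labels)
    theirs <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                             predictor = scores,
                                             quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})
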