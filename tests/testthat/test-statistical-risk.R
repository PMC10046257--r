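test_that("Min-Max age normalization matches its formula and clips out-of-range", {
  p <- normalization_params(30, 80)
  expect_equal(normalize_age(30, p), 0)
  expect_equal(normalize_age(80, p), 1)
  expect_equal(normalize_age(55, p), 0.5)
  expect_warning(t <- normalize_age(95, p), "clipped")
  expect_equal(t, 1)
  expect_error(normalization_params(50, 50), "degenerate")
})

test_that("feature encoding drops BI-RADS and keeps a fixed schema", {
  co <- generate_cohort(n = 40, n_cancer = 8, seed = 3)
  ft <- encode_features(co)
  expect_false("birads" %in% names(ft))
  expect_false("patient_id" %in% names(ft))
  expect_equal(nrow(ft), 40)
  expect_equal(levels(attr(ft, "labels")), c("cancer", "non-cancer"))

  ft2 <- encode_features(generate_cohort(n = 25, n_cancer = 6, seed = 4))
  expect_identical(names(ft), names(ft2))  # schema-constant column set

  # encoding is injective up to the dropped columns: decode and compare
  decoded <- data.frame(lapply(ft[attr(ft, "categorical")], as.character),
                        check.names = FALSE)
  orig <- co$records[names(decoded)]
  for (f in names(decoded)) {
    if (is.logical(orig[[f]])) {
      expect_identical(decoded[[f]] == "present", orig[[f]], label = f)
    } else {
      expect_identical(decoded[[f]], orig[[f]], label = f)
    }
  }
})

test_that("unlabeled records cannot enter the feature table", {
  co <- generate_cohort(n = 20, n_cancer = 5, seed = 8)
  co$records$label[3] <- NA
  expect_error(encode_features(co), "unlabeled")
})

test_that("SMOTE-NC hits the per-class target exactly and preserves originals", {
  co <- generate_cohort(n = 130, n_cancer = 21, seed = 13)
  ft <- encode_features(co)
  aug <- augment_smote_nc(ft, target_per_class = 200, k_neighbors = 5, seed = 13)
  counts <- table(attr(aug, "labels"))
  expect_equal(unname(counts[["cancer"]]), 200)
  expect_equal(unname(counts[["non-cancer"]]), 200)
  expect_equal(nrow(aug), 400)
  # original rows come first, bit-identical
  expect_identical(plain_df(aug)[seq_len(nrow(ft)), ], plain_df(ft))
  expect_identical(attr(aug, "synthetic")[seq_len(nrow(ft))], rep(FALSE, nrow(ft)))
})

test_that("SMOTE-NC is a no-op at target and errors on tiny classes", {
  co <- generate_cohort(n = 40, n_cancer = 20, seed = 21)
  ft <- encode_features(co)
  aug <- augment_smote_nc(ft, target_per_class = 20, k_neighbors = 5, seed = 1)
  expect_equal(nrow(aug), 40)
  expect_identical(plain_df(aug), plain_df(ft))

  co2 <- generate_cohort(n = 30, n_cancer = 4, seed = 22)
  expect_error(augment_smote_nc(encode_features(co2), 50, k_neighbors = 5),
               "more than k")
  w <- capture_warnings(augment_smote_nc(ft, target_per_class = 10, k_neighbors = 3))
  expect_match(w, "exceeds target", all = TRUE)
})

test_that("synthetic ages stay within the convex hull of their class", {
  for (s in c(31, 32, 33)) {
    co <- generate_cohort(n = 80, n_cancer = 15, seed = s)
    ft <- encode_features(co)
    aug <- augment_smote_nc(ft, target_per_class = 120, k_neighbors = 5, seed = s)
    labs <- attr(aug, "labels")
    syn <- attr(aug, "synthetic")
    for (cls in levels(labs)) {
      rng <- range(aug$age_norm[!syn & labs == cls])
      a <- aug$age_norm[syn & labs == cls]
      expect_true(all(a >= rng[1] - 1e-12 & a <= rng[2] + 1e-12))
    }
  }
})

test_that("training recovers a planted signal and seeded refits reproduce it", {
  co <- generate_cohort(n = 130, n_cancer = 21, seed = 41, effect_size = 2.5)
  ft <- encode_features(co)
  m1 <- train_classifier(ft, seed = 41)
  expect_gt(m1$cv_auc, 0.7)  # out-of-fold, leakage-free estimate
  m2 <- train_classifier(ft, seed = 41)
  expect_identical(m1$cv_auc, m2$cv_auc)
  expect_identical(predict_statistical_risk(m1, case_study_patient()),
                   predict_statistical_risk(m2, case_study_patient()))
})

test_that("label-permuted training data yields a chance-level AUC", {
  aucs <- vapply(c(51, 52, 53), function(s) {
    co <- generate_cohort(n = 130, n_cancer = 21, seed = s)
    set.seed(s + 500)
    co$records$label <- sample(co$records$label)
    train_classifier(encode_features(co), seed = s)$cv_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("a single-class table cannot be fit", {
  co <- generate_cohort(n = 30, n_cancer = 8, seed = 6)
  co$records$label <- "non-cancer"
  expect_error(train_classifier(encode_features(co), seed = 1), "single class")
})

test_that("Statistical Risk is bounded and invariant to the BI-RADS category", {
  co <- generate_cohort(n = 130, n_cancer = 21, seed = 61)
  model <- train_classifier(encode_features(co), seed = 61)
  probe <- generate_cohort(n = 15, n_cancer = 5, seed = 62)
  for (i in seq_len(15)) {
    rec <- cohort_record(probe, i)
    rs <- predict_statistical_risk(model, rec)
    expect_gte(rs, 0); expect_lte(rs, 100)
    mutated <- rec
    mutated$birads <- sample(setdiff(c("1", "2", "3", "4A", "4B", "4C", "5"),
                                     rec$birads), 1)
    expect_identical(predict_statistical_risk(model, mutated), rs)
  }
})

test_that("model archives round-trip through save/load", {
  co <- generate_cohort(n = 60, n_cancer = 12, seed = 71)
  model <- train_classifier(encode_features(co), seed = 71,
                            target_per_class = 80)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$cv_auc, model$cv_auc)
  rec <- cohort_record(co, 1)
  expect_identical(predict_statistical_risk(back, rec),
                   predict_statistical_risk(model, rec))
})
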