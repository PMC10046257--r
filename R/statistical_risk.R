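#' Min-Max normalization parameters for age
#'
#' @param min_t,max_t Minimum and maximum age (years) observed in the
#'   training data; `max_t` must exceed `min_t`.
#' @return A `normalization_params` object.
#' @export
normalization_params <- function(min_t, max_t) {
  min_t <- as.numeric(min_t); max_t <- as.numeric(max_t)
  if (!is.finite(min_t) || !is.finite(max_t) || max_t <= min_t) {
    stop("degenerate age range: max_t must be strictly greater than min_t",
         call. = FALSE)
  }
  structure(list(min_t = min_t, max_t = max_t), class = "normalization_params")
}

#' Min-Max normalize an age
#'
#' Computes `(age - min_t) / (max_t - min_t)`. Ages outside the training
#' range (possible at scoring time) are clipped to \[0, 1\] with a warning.
#'
#' @param age Age in years.
#' @param params A [normalization_params()] object.
#' @return Normalized age in \[0, 1\].
#' @export
normalize_age <- function(age, params) {
  stopifnot(inherits(params, "normalization_params"))
  t <- (age - params$min_t) / (params$max_t - params$min_t)
  if (any(t < 0 | t > 1)) {
    warning("age outside the training range; clipped to [0, 1]", call. = FALSE)
    t <- pmin(pmax(t, 0), 1)
  }
  t
}

.feature_fields <- function() {
  # every Table 2-3 descriptor except the expert's BI-RADS category
  setdiff(.record_fields, c("patient_id", "age", "birads", "label"))
}

#' Encode a labeled cohort into a classifier feature table
#'
#' Builds the statistical-arm design matrix: Min-Max normalized age plus
#' every categorical descriptor of the record schema, deliberately
#' excluding the radiologist's BI-RADS category (the statistical risk
#' must be independent of it). Present/absent flags become two-level
#' factors; all factor levels come from the controlled vocabularies so
#' the encoding is stable across cohorts.
#'
#' @param cohort A labeled `cohort` (every record must carry a label).
#' @param params Optional [normalization_params()]; computed from the
#'   cohort's age range when `NULL`.
#' @return A `feature_table`: a data frame with numeric `age_norm` and
#'   factor descriptor columns, plus attributes `labels` (factor with
#'   levels cancer/non-cancer), `categorical` (names of the categorical
#'   columns) and `norm_params`.
#' @export
encode_features <- function(cohort, params = NULL) {
  df <- cohort$records
  if (nrow(df) == 0) stop("empty cohort", call. = FALSE)
  if (anyNA(df$label)) {
    stop("all records must be labeled to build a feature table (",
         sum(is.na(df$label)), " unlabeled)", call. = FALSE)
  }
  if (is.null(params)) params <- normalization_params(min(df$age), max(df$age))
  voc <- record_vocabulary()
  out <- data.frame(age_norm = normalize_age(df$age, params))
  for (f in .feature_fields()) {
    out[[f]] <- if (f %in% .flag_fields) {
      factor(ifelse(df[[f]], "present", "absent"),
             levels = c("absent", "present"))
    } else {
      factor(df[[f]], levels = voc[[f]])
    }
  }
  structure(out,
            labels = factor(df$label, levels = c("cancer", "non-cancer")),
            categorical = .feature_fields(),
            norm_params = params,
            class = c("feature_table", "data.frame"))
}

# squared SMOTE-NC distance between row i and all rows of tab (same class):
# Euclidean on numeric features plus, per categorical mismatch, the square
# of the median of the numeric features' standard deviations (Chawla's rule)
.smotenc_dist2 <- function(tab, i, num_cols, cat_cols, med) {
  d2 <- rep(0, nrow(tab))
  for (cn in num_cols) d2 <- d2 + (tab[[cn]] - tab[[cn]][i])^2
  for (cn in cat_cols) d2 <- d2 + med^2 * (tab[[cn]] != tab[[cn]][i])
  d2
}

#' SMOTE-NC augmentation to a fixed per-class size
#'
#' Oversamples each class up to `target_per_class` rows using the
#' mixed-type SMOTE variant: a synthetic row interpolates the numeric
#' features between a randomly chosen seed row and one of its
#' `k_neighbors` nearest same-class neighbours, while each categorical
#' feature takes the majority value among those neighbours (ties prefer
#' the seed row's value, then vocabulary order). Original rows are
#' preserved unchanged, first, in their input order.
#'
#' @param table A `feature_table` from [encode_features()].
#' @param target_per_class Desired rows per class (default 200).
#' @param k_neighbors Number of nearest neighbours (default 5); each
#'   class must have more than `k_neighbors` members.
#' @param seed Optional integer seed for reproducibility.
#' @return An augmented `feature_table`; attribute `synthetic` is a
#'   logical vector flagging the generated rows.
#' @export
augment_smote_nc <- function(table, target_per_class = 200, k_neighbors = 5,
                             seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.null(seed)) set.seed(seed)
  labels <- attr(table, "labels")
  num_cols <- "age_norm"
  cat_cols <- attr(table, "categorical")
  voc_order <- lapply(table[cat_cols], levels)

  new_rows <- list()
  new_labels <- character(0)
  for (cls in levels(labels)) {
    idx <- which(labels == cls)
    n_c <- length(idx)
    if (n_c > target_per_class) {
      warning(sprintf("class '%s' already exceeds target (%d > %d); left as is",
                      cls, n_c, target_per_class), call. = FALSE)
      next
    }
    n_new <- target_per_class - n_c
    if (n_new == 0) next
    if (n_c <= k_neighbors) {
      stop(sprintf("class '%s' has %d members; need more than k = %d to augment",
                   cls, n_c, k_neighbors), call. = FALSE)
    }
    sub <- table[idx, , drop = FALSE]
    med <- stats::median(vapply(num_cols, function(cn) stats::sd(sub[[cn]]),
                                numeric(1)))
    if (!is.finite(med) || med == 0) med <- 1e-6  # degenerate numeric spread
    nn <- lapply(seq_len(n_c), function(i) {
      d2 <- .smotenc_dist2(sub, i, num_cols, cat_cols, med)
      d2[i] <- Inf
      order(d2)[seq_len(k_neighbors)]
    })
    seeds <- sample.int(n_c, n_new, replace = TRUE)
    for (j in seq_len(n_new)) {
      i <- seeds[j]
      neigh <- nn[[i]]
      pick <- neigh[sample.int(k_neighbors, 1)]
      row <- sub[i, , drop = FALSE]
      gap <- stats::runif(1)
      for (cn in num_cols) {
        row[[cn]] <- sub[[cn]][i] + gap * (sub[[cn]][pick] - sub[[cn]][i])
      }
      for (cn in cat_cols) {
        vals <- as.character(sub[[cn]][neigh])
        tabv <- table(vals)
        winners <- names(tabv)[tabv == max(tabv)]
        seed_val <- as.character(sub[[cn]][i])
        chosen <- if (seed_val %in% winners) seed_val
                  else winners[order(match(winners, voc_order[[cn]]))][1]
        row[[cn]] <- factor(chosen, levels = voc_order[[cn]])
      }
      new_rows[[length(new_rows) + 1]] <- row
      new_labels <- c(new_labels, cls)
    }
  }

  out <- if (length(new_rows) > 0) {
    rbind(as.data.frame(table), do.call(rbind, new_rows))
  } else {
    as.data.frame(table)
  }
  rownames(out) <- NULL
  structure(out,
            labels = factor(c(as.character(labels), new_labels),
                            levels = levels(labels)),
            categorical = cat_cols,
            norm_params = attr(table, "norm_params"),
            synthetic = c(rep(FALSE, nrow(table)),
                          rep(TRUE, length(new_rows))),
            class = c("feature_table", "data.frame"))
}

# stratified fold assignment: within each class, shuffle and deal round-robin
.stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cls in levels(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Train the bagged-trees Statistical Risk classifier
#'
#' Fits a bootstrap-aggregated decision-tree ensemble (a random forest
#' with `mtry` equal to the number of features, i.e. plain bagging) on
#' the SMOTE-NC-augmented feature table, and estimates out-of-fold
#' performance by stratified k-fold cross-validation. Augmentation runs
#' inside each training fold only, so held-out patients never influence
#' the synthetic rows they are scored against (leakage-free ordering);
#' the reported AUC is therefore an honest estimate and will sit below a
#' resubstitution-style figure.
#'
#' @param table A `feature_table` of the original (pre-augmentation)
#'   labeled cohort.
#' @param folds Number of cross-validation folds (default 5).
#' @param trees Number of trees in the ensemble (default 100).
#' @param seed Integer seed; all randomness (folds, SMOTE-NC, bootstrap)
#'   flows from it, so refits are bit-reproducible.
#' @param target_per_class,k_neighbors SMOTE-NC settings (defaults 200, 5).
#' @return A `risk_classifier`: the fitted ensemble plus the
#'   normalization parameters, factor-level encoding map, training
#'   metadata, cross-validated AUC and pooled out-of-fold ROC points.
#' @importFrom randomForest randomForest
#' @export
train_classifier <- function(table, folds = 5, trees = 100, seed = 1,
                             target_per_class = 200, k_neighbors = 5) {
  stopifnot(inherits(table, "feature_table"))
  labels <- attr(table, "labels")
  if (length(unique(labels)) < 2) {
    stop("training table contains a single class; cannot fit a classifier",
         call. = FALSE)
  }
  set.seed(seed)
  fold <- .stratified_folds(labels, folds)

  fit_bag <- function(x, y, ntree) {
    randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = ncol(x))
  }

  cv_scores <- rep(NA_real_, nrow(table))
  for (f in seq_len(folds)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    tr <- structure(as.data.frame(table)[tr_idx, , drop = FALSE],
                    labels = factor(as.character(labels[tr_idx]),
                                    levels = levels(labels)),
                    categorical = attr(table, "categorical"),
                    norm_params = attr(table, "norm_params"),
                    class = c("feature_table", "data.frame"))
    aug <- augment_smote_nc(tr, target_per_class, k_neighbors)
    forest <- fit_bag(as.data.frame(aug), attr(aug, "labels"), trees)
    pr <- stats::predict(forest, as.data.frame(table)[te_idx, , drop = FALSE],
                         type = "prob")
    cv_scores[te_idx] <- pr[, "cancer"]
  }
  truth <- as.character(labels)
  cv_auc <- auc(cv_scores * 100, truth)
  roc <- .roc_points(cv_scores * 100, truth)

  aug_full <- augment_smote_nc(table, target_per_class, k_neighbors)
  forest <- fit_bag(as.data.frame(aug_full), attr(aug_full, "labels"), trees)

  structure(list(
    forest = forest,
    norm_params = attr(table, "norm_params"),
    encoding = lapply(as.data.frame(table)[attr(table, "categorical")], levels),
    metadata = list(seed = seed, folds = folds, trees = trees,
                    target_per_class = target_per_class,
                    k_neighbors = k_neighbors,
                    n_train = nrow(table),
                    class_counts = table(labels)),
    cv_auc = cv_auc,
    roc = roc),
    class = "risk_classifier")
}

#' @export
print.risk_classifier <- function(x, ...) {
  cat(sprintf("<risk_classifier> bagged trees (%d trees), trained on %d patients\n",
              x$metadata$trees, x$metadata$n_train))
  cat(sprintf("  %d-fold cross-validated AUC: %.3f\n", x$metadata$folds, x$cv_auc))
  invisible(x)
}

# encode a single validated record against a trained model's feature map
.encode_record <- function(model, record) {
  voc_levels <- model$encoding
  out <- data.frame(age_norm = suppressWarnings(
    normalize_age(record$age, model$norm_params)))
  for (f in names(voc_levels)) {
    raw <- if (f %in% .flag_fields) {
      if (isTRUE(record[[f]])) "present" else "absent"
    } else {
      record[[f]]
    }
    if (is.null(raw) || !raw %in% voc_levels[[f]]) {
      stop(sprintf("record does not match the model's feature schema (field '%s')",
                   f), call. = FALSE)
    }
    out[[f]] <- factor(raw, levels = voc_levels[[f]])
  }
  out
}

#' Statistical Risk for one patient
#'
#' The ensemble's cancer-class probability (fraction of trees voting
#' cancer) scaled to \[0, 100\]. Invariant to the record's BI-RADS
#' category, which is not part of the feature set.
#'
#' @param model A trained `risk_classifier`.
#' @param record A validated `patient_record`.
#' @return Statistical Risk Rs in \[0, 100\].
#' @export
predict_statistical_risk <- function(model, record) {
  stopifnot(inherits(model, "risk_classifier"))
  x <- .encode_record(model, record)
  pr <- stats::predict(model$forest, x, type = "prob")
  as.numeric(pr[, "cancer"]) * 100
}

#' Save / load a trained Statistical Risk model
#'
#' The archive is a single self-describing RDS file holding the
#' serialized ensemble together with its normalization bounds, encoding
#' map and training metadata.
#'
#' @param model A `risk_classifier`.
#' @param path Archive path.
#' @return `save_model`: the path, invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "risk_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path, call. = FALSE)
  model <- readRDS(path)
  if (!inherits(model, "risk_classifier")) {
    stop("file is not a risk_classifier archive: ", path, call. = FALSE)
  }
  model
}
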