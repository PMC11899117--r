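#' Accumulative-tolerance outcome labels at a target visit
#'
#' A patient is *tolerant* at the target visit if they tolerated milk
#' at or before it (accumulative tolerance: once tolerant, tolerant at
#' every later time point, even after leaving follow-up). A patient is
#' *allergic* if still allergic and attending at the target visit.
#' Patients lost before the target without a tolerance event have no
#' outcome and are excluded (`NA`).
#'
#' Targets 5 and 6 are refused by default: too few patients remain
#' allergic that late for a meaningful model.
#'
#' @param cohort cohort table with one row per patient and columns
#'   `patient_id`, `first_tolerant_visit` (`NA` if never tolerant) and
#'   `last_visit` (last attended visit).
#' @param targetVisit 2, 3 or 4 (5 or 6 only with `allowLate = TRUE`).
#' @param allowLate permit targets 5 and 6.
#' @return factor (`allergic`/`tolerant`) named by patient id, `NA`
#'   where the outcome is undefined.
#' @export
assignOutcome <- function(cohort, targetVisit, allowLate = FALSE) {
  targetVisit <- as.integer(targetVisit)
  if (!targetVisit %in% 2:6) stop("unknown visit: ", targetVisit)
  if (targetVisit %in% 5:6 && !allowLate) {
    stop("models for visits 5-6 are refused by default ",
         "(too few remaining allergic patients); set allowLate = TRUE to override")
  }
  ft <- cohort$first_tolerant_visit
  tolerant <- !is.na(ft) & ft <= targetVisit
  allergic <- (is.na(ft) | ft > targetVisit) & cohort$last_visit >= targetVisit
  out <- rep(NA_character_, nrow(cohort))
  out[tolerant] <- "tolerant"
  out[allergic] <- "allergic"
  factor(stats::setNames(out, cohort$patient_id),
         levels = c("allergic", "tolerant"))
}

#' Per-visit status labels from a cohort table
#'
#' Expands the per-patient cohort table into the long
#' patient × visit × status table used by the epitope analysis. At
#' visit 1 every enrolled patient is allergic. From visit 2 on, a
#' patient is tolerant once tolerant (accumulative), allergic while
#' still attending allergic, and absent (no row) after withdrawing.
#'
#' @inheritParams assignOutcome
#' @return data.frame: `patient_id`, `visit`, `status`.
#' @export
visitLabels <- function(cohort) {
  out <- do.call(rbind, lapply(1:6, function(v) {
    if (v == 1L) {
      status <- rep("allergic", nrow(cohort))
      keep <- rep(TRUE, nrow(cohort))
    } else {
      ft <- cohort$first_tolerant_visit
      tolerant <- !is.na(ft) & ft <= v
      allergic <- (is.na(ft) | ft > v) & cohort$last_visit >= v
      status <- ifelse(tolerant, "tolerant", ifelse(allergic, "allergic", NA))
      keep <- !is.na(status)
    }
    data.frame(patient_id = cohort$patient_id[keep], visit = v,
               status = status[keep], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.SEROLOGY_COLS <- c("milk_sige", "alac_sige", "blg_sige", "casein_sige",
                    "total_ige", "casein_sigg4", "blg_sigg4", "alac_sigg4")

#' Baseline feature table for tolerance prediction
#'
#' Assembles the model inputs: the eight baseline serology
#' determinations (sIgE to whole milk, α-lactalbumin, β-lactoglobulin
#' and casein plus total IgE, in kU/L; sIgG4 to casein,
#' β-lactoglobulin and α-lactalbumin, in mg/L) together with the
#' baseline (visit 1) IgE and IgG4 peptide Z-scores, and the
#' accumulative-tolerance outcome at the target visit. Only baseline
#' measurements enter: nothing after visit 1 can leak into the
#' features.
#'
#' @param cohort cohort table (see [assignOutcome()]) carrying the
#'   serology columns.
#' @param baseline named list of visit-1 [BindingMatrix-class] objects,
#'   e.g. `list(IgE = ..., IgG4 = ...)`.
#' @param targetVisit outcome visit (2, 3 or 4).
#' @param allowLate passed to [assignOutcome()].
#' @param peptideSubset optional character vector of peptide keys; when
#'   given, only these peptides enter as features (e.g. the keys of the
#'   baseline-informative peptides). Default uses the whole library —
#'   importance rankings may legitimately surface peptides outside the
#'   informative set.
#' @return data.frame with one row per patient with a defined outcome:
#'   an `outcome` factor column plus all feature columns (peptide
#'   features named `<isotype>_<key>`).
#' @export
buildFeatureTable <- function(cohort, baseline, targetVisit, allowLate = FALSE,
                              peptideSubset = NULL) {
  y <- assignOutcome(cohort, targetVisit, allowLate = allowLate)
  sero <- cohort[intersect(.SEROLOGY_COLS, colnames(cohort))]
  rownames(sero) <- cohort$patient_id
  blocks <- lapply(names(baseline), function(iso) {
    bm <- baseline[[iso]]
    stopifnot(arrayVisit(bm) == 1L)
    m <- t(zscores(bm))
    if (!is.null(peptideSubset)) {
      bad <- setdiff(peptideSubset, colnames(m))
      if (length(bad)) stop("unknown peptide key(s): ", paste(bad, collapse = ", "))
      m <- m[, peptideSubset, drop = FALSE]
    }
    colnames(m) <- paste0(arrayIsotype(bm), "_", colnames(m))
    m
  })
  keep <- names(y)[!is.na(y)]
  x <- cbind(sero[keep, , drop = FALSE],
             do.call(cbind, lapply(blocks, function(m) m[keep, , drop = FALSE])))
  data.frame(outcome = y[keep], x, check.names = FALSE)
}

#' Default hyperparameter grid for the boosted-tree search
#'
#' Shallow trees, three learning rates, two minimum-child-weight
#' settings and three ensemble sizes — a small search space suited to a
#' cohort of ~100 patients with a few hundred features.
#'
#' @return data.frame grid with columns `max_depth`, `eta`,
#'   `min_child_weight`, `nrounds`.
#' @export
defaultGrid <- function() {
  expand.grid(max_depth = c(2L, 3L, 4L), eta = c(0.05, 0.1, 0.3),
              min_child_weight = c(1, 5), nrounds = c(50L, 150L, 300L))
}

#' Confusion-matrix metrics
#'
#' @param tp,fp,fn,tn confusion-matrix counts (positive class =
#'   tolerant).
#' @return named numeric: `precision`, `recall`, `f1`, `accuracy`.
#'   Precision/recall/F1 are 0 when their denominator is 0.
#' @examples
#' confusionMetrics(8, 2, 2, 18)
#' @export
confusionMetrics <- function(tp, fp, fn, tn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1,
    accuracy = (tp + tn) / (tp + fp + fn + tn))
}

.aucOf <- function(y, p) {
  if (length(unique(y[!is.na(p)])) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = p,
                                 levels = c("allergic", "tolerant"),
                                 direction = "<", quiet = TRUE)))
}

.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.xgbFit <- function(x, y, params, nrounds, spw) {
  dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y == "tolerant"))
  xgboost::xgb.train(
    params = c(params, list(objective = "binary:logistic",
                            eval_metric = "logloss",
                            scale_pos_weight = spw, nthread = 1)),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
}

#' Train and evaluate a gradient-boosted tolerance model
#'
#' Implements the full modelling protocol: a stratified 70/30
#' train/test split, a grid search over boosted-tree hyperparameters
#' by stratified 10-fold cross-validation on the training set
#' maximizing F1 (at the 0.5 probability threshold, positive class =
#' tolerant), a final refit on the whole training set with the winning
#' configuration, and evaluation on the held-out test set: ROC AUC on
#' train and test plus confusion-matrix metrics (precision, recall,
#' F1, accuracy) at threshold 0.5. Class imbalance is handled through
#' `scale_pos_weight` set to the training-class ratio; missing feature
#' values are imputed with training-split medians. Ties in the grid
#' search resolve to the first configuration in grid order. The seed
#' drives split, folds and fits, making the whole pipeline
#' reproducible.
#'
#' @param features feature table from [buildFeatureTable()] (an
#'   `outcome` factor column plus numeric features).
#' @param targetVisit the visit the outcome refers to (metadata only).
#' @param seed integer random seed.
#' @param grid hyperparameter grid, see [defaultGrid()].
#' @param nfold cross-validation folds (default 10).
#' @param trainFrac training fraction of the stratified split.
#' @return a [ModelReport-class]
#' @export
trainEvaluate <- function(features, targetVisit = NA_integer_, seed = 1L,
                          grid = defaultGrid(), nfold = 10L, trainFrac = 0.7) {
  stopifnot("outcome" %in% colnames(features))
  y <- factor(features$outcome, levels = c("allergic", "tolerant"))
  if (length(unique(stats::na.omit(y))) < 2L) {
    stop("degenerate outcome: a single class in the data")
  }
  x <- as.matrix(features[setdiff(colnames(features), "outcome")])
  storage.mode(x) <- "double"

  set.seed(as.integer(seed))
  train_idx <- sort(unlist(lapply(levels(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, round(trainFrac * length(idx)))
  })))
  test_idx <- setdiff(seq_along(y), train_idx)
  ytr <- y[train_idx]; yte <- y[test_idx]
  if (length(unique(ytr)) < 2L) stop("degenerate outcome: a single class in training")
  if (min(table(ytr)) < 10L) {
    warning("fewer than 10 training patients in a class (",
            paste(table(ytr), collapse = "/"), ")")
  }

  # training-median imputation, applied to both splits
  med <- apply(x[train_idx, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in which(colSums(is.na(x)) > 0L)) x[is.na(x[, j]), j] <- med[j]
  xtr <- x[train_idx, , drop = FALSE]
  xte <- x[test_idx, , drop = FALSE]

  spw <- sum(ytr == "allergic") / sum(ytr == "tolerant")
  fold <- .stratifiedFolds(ytr, nfold)
  cv_f1 <- vapply(seq_len(nrow(grid)), function(g) {
    params <- list(max_depth = grid$max_depth[g], eta = grid$eta[g],
                   min_child_weight = grid$min_child_weight[g])
    mean(vapply(seq_len(nfold), function(k) {
      tr <- fold != k
      if (length(unique(ytr[tr])) < 2L) return(NA_real_)
      fit <- .xgbFit(xtr[tr, , drop = FALSE], ytr[tr], params, grid$nrounds[g], spw)
      p <- stats::predict(fit, xgboost::xgb.DMatrix(xtr[!tr, , drop = FALSE]))
      pred <- p > 0.5
      pos <- ytr[!tr] == "tolerant"
      unname(confusionMetrics(sum(pred & pos), sum(pred & !pos),
                              sum(!pred & pos), sum(!pred & !pos))["f1"])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- which.max(cv_f1)

  params <- list(max_depth = grid$max_depth[best], eta = grid$eta[best],
                 min_child_weight = grid$min_child_weight[best])
  fit <- .xgbFit(xtr, ytr, params, grid$nrounds[best], spw)
  ptr <- stats::predict(fit, xgboost::xgb.DMatrix(xtr))
  pte <- stats::predict(fit, xgboost::xgb.DMatrix(xte))
  pred <- pte > 0.5
  pos <- yte == "tolerant"
  cm <- confusionMetrics(sum(pred & pos), sum(pred & !pos),
                         sum(!pred & pos), sum(!pred & !pos))

  imp_raw <- xgboost::xgb.importance(model = fit)
  gain <- stats::setNames(rep(0, ncol(x)), colnames(x))
  if (!is.null(imp_raw) && nrow(imp_raw)) {
    gain[imp_raw$Feature] <- imp_raw$Gain
  }
  importance <- data.frame(feature = names(gain), gain = unname(gain),
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$gain), ]
  rownames(importance) <- NULL

  methods::new("ModelReport",
    targetVisit = as.integer(targetVisit),
    metrics = c(train_auc = .aucOf(ytr, ptr), test_auc = .aucOf(yte, pte),
                f1 = unname(cm["f1"]), precision = unname(cm["precision"]),
                recall = unname(cm["recall"]), accuracy = unname(cm["accuracy"]),
                cv_f1 = unname(cv_f1[best])),
    importance = importance,
    params = c(params, list(nrounds = grid$nrounds[best],
                            scale_pos_weight = spw, nfold = nfold)),
    seed = as.integer(seed),
    model = fit,
    n = c(train = length(train_idx), test = length(test_idx))
  )
}

#' @describeIn ModelReport-class evaluation metrics as a named numeric
#' @param object,x a `ModelReport`
#' @export
setGeneric("modelMetrics", function(x) standardGeneric("modelMetrics"))

#' @rdname ModelReport-class
#' @export
setMethod("modelMetrics", "ModelReport", function(x) x@metrics)

setMethod("show", "ModelReport", function(object) {
  cat(sprintf("ModelReport: tolerance at visit %s (n train %d / test %d, seed %d)\n",
              object@targetVisit, object@n["train"], object@n["test"], object@seed))
  m <- object@metrics
  cat(sprintf("  AUC train %.3f / test %.3f; F1 %.3f, precision %.3f, recall %.3f, accuracy %.3f\n",
              m["train_auc"], m["test_auc"], m["f1"], m["precision"],
              m["recall"], m["accuracy"]))
  top <- utils::head(object@importance, 5L)
  cat("  top variables:", paste(sprintf("%s (%.2f)", top$feature, top$gain),
                                collapse = ", "), "\n")
})

#' Top variables of a tolerance model by gain share
#'
#' @param report a [ModelReport-class].
#' @param topK number of variables to report (all if larger than the
#'   variable count).
#' @return data.frame: `rank`, `feature`, `gain` (share over the full
#'   model) and `share_of_reported` (renormalized over the reported
#'   rows — flagged as such by its name).
#' @export
importanceReport <- function(report, topK = 10L) {
  imp <- report@importance
  topK <- min(as.integer(topK), nrow(imp))
  out <- imp[seq_len(topK), , drop = FALSE]
  out <- data.frame(rank = seq_len(topK), out,
                    share_of_reported = if (sum(out$gain) > 0)
                      out$gain / sum(out$gain) else 0)
  rownames(out) <- NULL
  out
}
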