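#' Stratified train/test split of a truth set
#'
#' Samples the training fraction within each label so the split preserves
#' the positive:negative ratio.
#'
#' @param truth data.frame `variant_id`, `label` (positive/negative).
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed integer seed.
#' @return the truth table with a `split` column (train/test).
#' @export
split_truth_set <- function(truth, train_fraction = 0.8, seed = 1L) {
  stopifnot(all(truth$label %in% c("positive", "negative")))
  set.seed(seed)
  truth$split <- "test"
  for (lab in unique(truth$label)) {
    idx <- which(truth$label == lab)
    n_train <- round(train_fraction * length(idx))
    truth$split[sample(idx, n_train)] <- "train"
  }
  truth
}

#' Train the supervised classifier of disease-relevant functional abnormality
#'
#' A random forest (500 trees, default mtry, unlimited depth) on combined
#' log2 fold-changes at Days 7, 11 and 15; the predicted class is the one
#' with the highest mean probability across trees. Training is
#' seed-deterministic.
#'
#' @param features data.frame `variant_id` plus feature columns.
#' @param truth truth table with `split` column from [split_truth_set()];
#'   only `split == "train"` rows are used.
#' @param feature_cols feature column names (default cLFC at Days 7/11/15).
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @return object of class `sge_ndd_model` wrapping the forest and the
#'   feature set.
#' @export
train_ndd_classifier <- function(features, truth,
                                 feature_cols = c("lfc_day7", "lfc_day11",
                                                  "lfc_day15"),
                                 n_trees = 500, seed = 1L) {
  check_columns(features, c("variant_id", feature_cols), "feature table")
  tr <- truth[truth$split == "train", ]
  if (length(unique(tr$label)) < 2)
    stop("training set must contain both labels")
  if (min(table(tr$label)) < 2)
    stop("need at least 2 training examples per label")
  x <- features[match(tr$variant_id, features$variant_id), feature_cols,
                drop = FALSE]
  ok <- complete.cases(x)
  if (!all(ok)) {
    tr <- tr[ok, ]
    x <- x[ok, , drop = FALSE]
  }
  y <- factor(tr$label, levels = c("negative", "positive"))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
  structure(list(forest = rf, feature_cols = feature_cols, seed = seed),
            class = "sge_ndd_model")
}

#' Posterior probabilities, binary calls and clinical confidence tiers
#'
#' The posterior is the mean across trees of the probability of the
#' positive (functionally abnormal) class. A variant is predicted abnormal
#' at posterior >= 0.5; tiers are `high` (> 0.9), `intermediate`
#' (0.5-0.9, inclusive of both ends) and `normal` (< 0.5).
#'
#' @param model an `sge_ndd_model`.
#' @param features feature table (`variant_id` + feature columns).
#' @return data.frame `variant_id`, `posterior`, `predicted` (logical),
#'   `tier`.
#' @export
predict_ndd <- function(model, features) {
  stopifnot(inherits(model, "sge_ndd_model"))
  x <- features[, model$feature_cols, drop = FALSE]
  ok <- complete.cases(x)
  post <- rep(NA_real_, nrow(x))
  if (any(ok))
    post[ok] <- predict(model$forest, x[ok, , drop = FALSE],
                        type = "prob")[, "positive"]
  tier <- ifelse(post > 0.9, "high",
                 ifelse(post >= 0.5, "intermediate", "normal"))
  data.frame(variant_id = features$variant_id, posterior = post,
             predicted = post >= 0.5, tier = tier)
}

#' ROC AUC by the rank (Mann-Whitney) statistic
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical or "positive"/"negative" labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics
#'
#' Sensitivity, specificity, positive and negative predictive value in
#' percent (one decimal), from the four confusion counts. A metric whose
#' denominator is empty is reported as `NA` (undefined), not 0.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @param roc_auc optional AUC to attach.
#' @return list of class `sge_confusion`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn, roc_auc = NA_real_) {
  pct <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 1)
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    ppv = pct(tp, tp + fp),
    npv = pct(tn, tn + fn),
    roc_auc = roc_auc
  ), class = "sge_confusion")
}

#' @export
print.sge_confusion <- function(x, ...) {
  cat(sprintf("TP %d TN %d FP %d FN %d | sens %.1f%% spec %.1f%% ppv %.1f%% npv %.1f%%",
              x$tp, x$tn, x$fp, x$fn, x$sensitivity, x$specificity,
              x$ppv, x$npv))
  if (!is.na(x$roc_auc)) cat(sprintf(" | AUC %.3f", x$roc_auc))
  cat("\n")
  invisible(x)
}

#' Evaluate predictions against truth labels
#'
#' Positives are truth-set disease variants; a true positive is a variant
#' predicted abnormal that is labelled positive. Metrics are invariant to
#' row order.
#'
#' @param predictions data.frame `variant_id`, `predicted` (logical) and
#'   optionally `posterior` (used for the AUC).
#' @param truth truth rows to evaluate on (`variant_id`, `label`).
#' @return an `sge_confusion`.
#' @export
evaluate_classifier <- function(predictions, truth) {
  m <- merge(truth, predictions, by = "variant_id")
  m <- m[!is.na(m$predicted), ]
  pos <- m$label == "positive"
  auc <- if ("posterior" %in% names(m)) roc_auc(m$posterior, pos) else NA_real_
  confusion_metrics(tp = sum(m$predicted & pos),
                    tn = sum(!m$predicted & !pos),
                    fp = sum(m$predicted & !pos),
                    fn = sum(!m$predicted & pos),
                    roc_auc = auc)
}

INSILICO_THRESHOLDS <- list(
  pejaver = list(
    sift = list(positive_below = 1e-4, negative_at_or_above = 1e-3),
    polyphen2 = list(positive_above = 0.978),
    revel = list(positive_above = 0.773),
    cadd = list(positive_above = 25.3)
  ),
  default = list(
    sift = list(positive_below = 0.05, negative_at_or_above = 0.05),
    polyphen2 = list(positive_above = 0.902),
    revel = list(positive_above = 0.5),
    cadd = list(positive_above = 20)
  )
)

#' Benchmark thresholded in-silico predictors against the truth set
#'
#' Applies per-tool thresholds (published supporting-evidence thresholds or
#' the developer defaults) to score columns and evaluates the resulting
#' binary calls. SIFT is oriented low = damaging; the other tools high =
#' damaging. Scores in the undefined SIFT band (between the test-positive
#' and test-negative cut-offs of the published set) are treated as
#' test-negative. Missing scores are excluded per tool, with counts
#' reported.
#'
#' @param scores score table (`variant_id` + tool columns).
#' @param truth truth rows to evaluate on.
#' @param threshold_set `"pejaver"` (published supporting-evidence
#'   thresholds) or `"default"` (developer-recommended).
#' @param tools which tools to benchmark.
#' @return named list of `sge_confusion`, one per tool, each with an
#'   `n_missing` attribute.
#' @export
insilico_compare <- function(scores, truth, threshold_set = c("pejaver", "default"),
                             tools = c("sift", "polyphen2", "revel", "cadd")) {
  threshold_set <- match.arg(threshold_set)
  th <- INSILICO_THRESHOLDS[[threshold_set]]
  unknown <- setdiff(tools, names(th))
  if (length(unknown)) stop("unknown tool(s): ", paste(unknown, collapse = ", "))
  out <- list()
  for (tool in tools) {
    s <- scores[[tool]][match(truth$variant_id, scores$variant_id)]
    ok <- !is.na(s)
    rule <- th[[tool]]
    call <- if (tool == "sift") s[ok] < rule$positive_below
            else s[ok] > rule$positive_above
    preds <- data.frame(variant_id = truth$variant_id[ok],
                        predicted = call, posterior = if (tool == "sift")
                          -s[ok] else s[ok])
    cm <- evaluate_classifier(preds, truth[ok, ])
    attr(cm, "n_missing") <- sum(!ok)
    out[[tool]] <- cm
  }
  out
}

#' Feature / guide ablation of the supervised classifier
#'
#' Re-runs guide combination, training and evaluation for subsets of
#' timepoint features and subsets of guides, reporting the test AUC per
#' configuration.
#'
#' @param effects centred per-guide effect table covering all kinds used.
#' @param library library table for PAM-codon exclusion.
#' @param truth truth table with split column.
#' @param feature_sets list of character vectors of kinds (e.g.
#'   `c("lfc_day7", "lfc_day15")`).
#' @param guide_sets list of character vectors of guides.
#' @param seed integer seed for training.
#' @return data.frame `features`, `guides`, `auc`.
#' @export
ndd_ablation <- function(effects, library, truth,
                         feature_sets = list(c("lfc_day7", "lfc_day11", "lfc_day15")),
                         guide_sets = list(c("g1", "g2"), "g1"),
                         seed = 1L) {
  rows <- list()
  for (gs in guide_sets) {
    eff <- merge_pam_codon(effects[effects$guide %in% gs, ], library)
    comb <- combine_guides(eff)
    wide <- effects_to_features(comb)
    for (fs in feature_sets) {
      model <- train_ndd_classifier(wide, truth, feature_cols = fs, seed = seed)
      preds <- predict_ndd(model, wide)
      cm <- evaluate_classifier(preds, truth[truth$split == "test", ])
      rows[[length(rows) + 1L]] <- data.frame(
        features = paste(fs, collapse = "+"),
        guides = paste(gs, collapse = "+"),
        auc = cm$roc_auc)
    }
  }
  do.call(rbind, rows)
}

#' Pivot a combined effect table to one feature column per kind
#'
#' @param combined combined effect table (several kinds stacked).
#' @return data.frame `variant_id` + one estimate column per kind.
#' @export
effects_to_features <- function(combined) {
  kinds <- unique(combined$kind)
  ids <- unique(combined$variant_id)
  out <- data.frame(variant_id = ids)
  for (k in kinds) {
    sub <- combined[combined$kind == k, ]
    out[[k]] <- sub$estimate[match(ids, sub$variant_id)]
  }
  out
}
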