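#' Default pipeline configuration
#'
#' All thresholds and tunables of the pipeline in one declarative list:
#' FDR threshold for functional calling, posterior tiers of the supervised
#' classifier, the low-abundance count filter, the burial threshold, the
#' frequency threshold and NMD windows of the interpretation engine, and
#' the truncation threshold of the loss-of-function criterion.
#'
#' @return named list of defaults.
#' @export
sge_config <- function() {
  list(
    fdr_alpha = 0.01,
    posterior_predict = 0.5,
    posterior_high = 0.9,
    low_count_threshold = 10,
    burial_threshold = 0.25,
    af_threshold = 3.25e-7,
    nmd_start_bp = 200,
    nmd_last_window = 55,
    truncation_threshold = 0.10,
    train_fraction = 0.8,
    boundary_window = 10,
    feature_kinds = c("lfc_day7", "lfc_day11", "lfc_day15"),
    bh_stratum = "global"
  )
}

#' Run the full synthetic-screen analysis pipeline
#'
#' Chains the stages end to end on a synthetic screen: gene and library
#' generation, true-class assignment, count simulation, low-abundance
#' filtering, size factors, per-guide LFC estimation at Days 7/11/15 (plus
#' the LFC-trend when requested), control centering, PAM-codon merging,
#' guide combination, functional-class assignment, truth-table simulation
#' and supervised classifier training/evaluation. Deterministic given
#' `seed`.
#'
#' @param scenario an [sge_scenario()].
#' @param gene optionally a pre-built `sge_gene`; by default a four-exon
#'   toy gene of 480 coding nt (giving roughly two thousand designed
#'   variants).
#' @param config pipeline configuration from [sge_config()].
#' @param seed master seed; per-stage seeds are derived from it.
#' @param with_trend also fit the LFC-trend.
#' @param with_classifier simulate truth tables and train/evaluate the
#'   supervised classifier.
#' @return list with the artefacts of every stage: `gene`, `variants`,
#'   `library`, `assignment`, `counts`, `factors`, `effects` (per-guide,
#'   centred), `combined` (per kind), `calls`, `gmm`, `truth`,
#'   `features`, `model`, `predictions`, `metrics`.
#' @export
run_sge_pipeline <- function(scenario = NULL, gene = NULL,
                             config = sge_config(), seed = 1L,
                             with_trend = FALSE, with_classifier = TRUE) {
  seed <- as.integer(seed) %% 100000L
  if (is.null(scenario)) scenario <- sge_scenario(seed = seed)
  if (is.null(gene))
    gene <- make_gene(4, rep(120, 4), seed = seed + 11L)
  variants <- enumerate_variants(gene)
  library <- variant_library(gene, variants)
  assignment <- assign_true_classes(variants, seed = seed + 23L)
  counts <- simulate_counts(library, assignment, scenario)
  counts <- filter_low_abundance(counts, config$low_count_threshold)
  factors <- size_factors(counts)

  kinds <- config$feature_kinds
  eff <- list()
  for (k in kinds) {
    day <- as.integer(sub("lfc_day", "", k))
    eff[[k]] <- fit_lfc(counts, factors, day = day)
  }
  if (with_trend) eff$lfc_trend <- fit_lfc_trend(counts, factors)
  effects <- do.call(rbind, eff)
  rownames(effects) <- NULL
  effects <- median_center(effects, variants)
  effects <- merge_pam_codon(effects, library)
  combined <- combine_guides(effects)

  cls <- assign_classes(combined[combined$kind == "lfc_day15", ],
                        combined[combined$kind == "lfc_day7", ],
                        alpha = config$fdr_alpha, seed = seed + 31L)

  out <- list(gene = gene, variants = variants, library = library,
              assignment = assignment, counts = counts, factors = factors,
              effects = effects, combined = combined, calls = cls$calls,
              gmm = cls$model, config = config, scenario = scenario)

  if (with_classifier) {
    tt <- simulate_truth_tables(variants, assignment, seed = seed + 47L)
    truth <- split_truth_set(tt$labels, config$train_fraction,
                             seed = seed + 53L)
    features <- effects_to_features(combined)
    model <- train_ndd_classifier(features, truth,
                                  feature_cols = kinds, seed = seed + 61L)
    preds <- predict_ndd(model, features)
    metrics <- evaluate_classifier(preds, truth[truth$split == "test", ])
    out$truth <- truth
    out$truth_tables <- tt
    out$features <- features
    out$model <- model
    out$predictions <- preds
    out$metrics <- metrics
  }
  out
}

#' Four-way class recovery of a pipeline run
#'
#' Fraction of called variants whose assigned SGE class equals their
#' generative class.
#'
#' @param result output of [run_sge_pipeline()].
#' @return list: `accuracy`, `n`, `confusion` (true x called table).
#' @export
class_recovery <- function(result) {
  truth <- result$assignment$true_class[
    match(result$calls$variant_id, result$assignment$variant_id)]
  called <- result$calls$sge_class
  ok <- !is.na(called) & !is.na(truth)
  list(accuracy = mean(called[ok] == truth[ok]), n = sum(ok),
       confusion = table(true = truth[ok], called = called[ok]))
}
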