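STRENGTH_POINTS <- c(supporting = 1, moderate = 2, strong = 4, very_strong = 8)

#' Gene configuration for the interpretation engine
#'
#' Houses the gene-level constants the rule set needs, so the engine is not
#' hard-coded to one gene: coding length, the CDS coordinate of the last
#' coding splice junction, the CDS intervals encoding the helicase (or
#' other critical) domains, exon phases, the NMD-escape windows, and the
#' frequency threshold.
#'
#' @param coding_length CDS length in nucleotides.
#' @param last_junction_cds CDS coordinate (1-based nt) of the last coding
#'   splice junction.
#' @param domain_cds_intervals list of `c(start, end)` CDS nt intervals of
#'   the critical domains; positions beyond every interval are "distal".
#' @param exon_phases integer vector of exon phases.
#' @param nmd_start_bp variants within the first this-many coding bp escape
#'   NMD (default 200).
#' @param nmd_last_window variants within this many bp 5' of the last
#'   coding junction, or downstream of it, escape NMD (default 55).
#' @param af_threshold maximum credible population allele frequency; above
#'   it the frequency evidence is benign-strong.
#' @param truncation_threshold fraction of protein removed above which a
#'   non-NMD loss-of-function variant gets strong (vs moderate) weight.
#' @return list of class `acmg_gene_config`.
#' @export
acmg_gene_config <- function(coding_length, last_junction_cds,
                             domain_cds_intervals = list(),
                             exon_phases = NULL,
                             nmd_start_bp = 200, nmd_last_window = 55,
                             af_threshold = 3.25e-7,
                             truncation_threshold = 0.10) {
  stopifnot(coding_length > 0, last_junction_cds <= coding_length)
  structure(list(coding_length = coding_length,
                 last_junction_cds = last_junction_cds,
                 domain_cds_intervals = domain_cds_intervals,
                 exon_phases = exon_phases,
                 nmd_start_bp = nmd_start_bp,
                 nmd_last_window = nmd_last_window,
                 af_threshold = af_threshold,
                 truncation_threshold = truncation_threshold),
            class = "acmg_gene_config")
}

#' Predict escape from nonsense-mediated decay
#'
#' A premature stop escapes NMD when it lies within the first
#' `nmd_start_bp` coding bases, or distal to `nmd_last_window` bp 5' of
#' the last coding splice junction (positions at or beyond
#' `last_junction_cds - nmd_last_window + 1`... implemented as strictly
#' greater than `last_junction_cds - nmd_last_window`); a position at the
#' junction itself escapes.
#'
#' @param cds_position 1-based CDS nucleotide position.
#' @param config an `acmg_gene_config`.
#' @return logical: TRUE if the variant is predicted to escape NMD.
#' @export
predict_nmd_escape <- function(cds_position, config) {
  if (any(is.na(cds_position)))
    stop("cds_position is required for NMD prediction")
  cds_position <= config$nmd_start_bp |
    cds_position > (config$last_junction_cds - config$nmd_last_window)
}

evidence_item <- function(code, direction = c("pathogenic", "benign"),
                          strength = c("supporting", "moderate", "strong",
                                       "very_strong"),
                          note = NA_character_) {
  direction <- match.arg(direction)
  strength <- match.arg(strength)
  pts <- unname(STRENGTH_POINTS[strength])
  if (direction == "benign") pts <- -pts
  data.frame(code = code, direction = direction, strength = strength,
             points = pts, note = note)
}

no_evidence <- function() {
  data.frame(code = character(0), direction = character(0),
             strength = character(0), points = integer(0),
             note = character(0))
}

is_distal_to_domains <- function(cds_position, config) {
  if (!length(config$domain_cds_intervals)) return(TRUE)
  ends <- vapply(config$domain_cds_intervals, function(iv) iv[2], 0)
  cds_position > max(ends)
}

#' Population-frequency evidence
#'
#' Absence from the population databases is pathogenic-moderate evidence
#' (reported with code `PM2_like`; clinical guidance for this gene labels
#' the criterion under BS1); a maximum population allele frequency above
#' the gene's maximum credible frequency is benign-strong (`BS1`). The
#' threshold comparison is a strict inequality.
#'
#' @param af_max maximum allele frequency across populations; 0 means
#'   unobserved.
#' @param config an `acmg_gene_config`.
#' @return evidence data.frame (possibly empty).
#' @export
assign_frequency_evidence <- function(af_max, config) {
  if (is.na(af_max)) return(no_evidence())
  if (af_max == 0)
    return(evidence_item("PM2_like", "pathogenic", "moderate",
                         note = "unobserved in population databases (labelled BS1-moderate in the source guidance)"))
  if (af_max > config$af_threshold)
    return(evidence_item("BS1", "benign", "strong"))
  no_evidence()
}

#' Computational (in-silico) evidence: PP3 / BP4
#'
#' PP3 (supporting pathogenic) when the splice-impact delta score exceeds
#' 0.7 or REVEL exceeds 0.7, or, with REVEL unavailable, CADD PHRED
#' exceeds 25. BP4 (supporting benign) when the splice delta is below 0.2
#' and REVEL below 0.2 (CADD below 10 substituting for missing REVEL).
#' Not applied to canonical splice acceptor/donor variants, where the
#' loss-of-function criterion already encodes the splice prediction. A
#' missing splice delta is treated as no predicted splice impact.
#'
#' @param consequence variant consequence.
#' @param spliceai,revel,cadd scores (NA when unavailable).
#' @return evidence data.frame (possibly empty).
#' @export
assign_insilico_evidence <- function(consequence, spliceai = NA, revel = NA,
                                     cadd = NA) {
  if (consequence == "splice_acceptor_donor") return(no_evidence())
  sp <- if (is.na(spliceai)) 0 else spliceai
  pp3 <- (sp > 0.7) ||
    (!is.na(revel) && revel > 0.7) ||
    (is.na(revel) && !is.na(cadd) && cadd > 25)
  if (pp3) return(evidence_item("PP3", "pathogenic", "supporting"))
  bp4 <- (sp < 0.2) &&
    ((!is.na(revel) && revel < 0.2) ||
       (is.na(revel) && !is.na(cadd) && cadd < 10))
  if (bp4) return(evidence_item("BP4", "benign", "supporting"))
  no_evidence()
}

#' Loss-of-function evidence: the PVS1 decision tree
#'
#' Nonsense / frameshift: very strong when NMD is predicted; otherwise,
#' when distal to the critical domains, strong if more than the truncation
#' threshold of the protein is removed, moderate if less. Canonical splice
#' acceptor/donor: for a non-phase-0 exon (skipping frameshifts), very
#' strong when NMD is predicted, else strong/moderate by the truncation
#' fraction of the skipping-induced frameshift; for a phase-0 exon outside
#' the critical domains, moderate.
#'
#' @param consequence one of nonsense, frameshift, splice_acceptor_donor.
#' @param cds_position 1-based CDS position (for splice variants, the
#'   nearest coding position of the affected exon boundary).
#' @param exon_phase phase of the affected exon (required for splice
#'   variants).
#' @param truncation_fraction fraction of protein removed; derived from
#'   `cds_position` when NA.
#' @param distal_to_domains whether the variant lies distal to the critical
#'   domains; derived from the config when NA.
#' @param config an `acmg_gene_config`.
#' @return evidence data.frame (possibly empty).
#' @export
assign_lof_evidence <- function(consequence, cds_position, exon_phase = NA,
                                truncation_fraction = NA,
                                distal_to_domains = NA, config) {
  if (!consequence %in% c("nonsense", "frameshift", "splice_acceptor_donor"))
    return(no_evidence())
  nmd_escape <- predict_nmd_escape(cds_position, config)
  if (is.na(truncation_fraction))
    truncation_fraction <- 1 - cds_position / config$coding_length
  if (is.na(distal_to_domains))
    distal_to_domains <- is_distal_to_domains(cds_position, config)

  if (consequence %in% c("nonsense", "frameshift")) {
    if (!nmd_escape)
      return(evidence_item("PVS1", "pathogenic", "very_strong"))
    if (distal_to_domains) {
      strength <- if (truncation_fraction > config$truncation_threshold)
        "strong" else "moderate"
      return(evidence_item("PVS1", "pathogenic", strength))
    }
    return(no_evidence())
  }

  ## canonical splice acceptor / donor
  if (is.na(exon_phase))
    stop("exon_phase is required for splice acceptor/donor variants")
  if (exon_phase != 0) {
    if (!nmd_escape)
      return(evidence_item("PVS1", "pathogenic", "very_strong"))
    strength <- if (truncation_fraction > config$truncation_threshold)
      "strong" else "moderate"
    return(evidence_item("PVS1", "pathogenic", strength))
  }
  if (distal_to_domains)
    return(evidence_item("PVS1", "pathogenic", "moderate"))
  no_evidence()
}

#' Missense-specific evidence: PP2, PS1, PM5, PP5
#'
#' PP2 (supporting) applies to every missense variant in a
#' missense-constrained disease gene. PS1 (strong) when the same
#' amino-acid change was previously reported de novo
#' pathogenic/likely-pathogenic; otherwise PM5 (moderate) when a different
#' amino acid at the same residue was. PP5 (supporting) independently when
#' a non-de-novo pathogenic report exists at the residue.
#'
#' @param consequence variant consequence.
#' @param same_aa_change_dn_plp,same_residue_dn_plp,non_dn_plp_at_residue
#'   prior-report flags.
#' @return evidence data.frame.
#' @export
assign_missense_evidence <- function(consequence,
                                     same_aa_change_dn_plp = FALSE,
                                     same_residue_dn_plp = FALSE,
                                     non_dn_plp_at_residue = FALSE) {
  if (consequence != "missense") return(no_evidence())
  ev <- evidence_item("PP2", "pathogenic", "supporting")
  if (isTRUE(same_aa_change_dn_plp)) {
    ev <- rbind(ev, evidence_item("PS1", "pathogenic", "strong"))
  } else if (isTRUE(same_residue_dn_plp)) {
    ev <- rbind(ev, evidence_item("PM5", "pathogenic", "moderate"))
  }
  if (isTRUE(non_dn_plp_at_residue))
    ev <- rbind(ev, evidence_item("PP5", "pathogenic", "supporting"))
  ev
}

#' De novo and functional-assay evidence: PS2, PS3 / BS3
#'
#' PS2 is moderate when the variant is de novo and the same variant was
#' previously reported de novo pathogenic/likely-pathogenic, supporting
#' when the variant is not known de novo but such a report exists. A
#' functional-assay call of abnormal merits PS3 (strong pathogenic),
#' normal merits BS3 (strong benign); an unavailable call contributes
#' nothing.
#'
#' @param de_novo_status one of de_novo, unknown, inherited.
#' @param same_variant_dn_plp prior-report flag for this exact variant.
#' @param sge_call one of abnormal, normal, unavailable.
#' @return evidence data.frame.
#' @export
assign_denovo_and_functional <- function(de_novo_status = "unknown",
                                         same_variant_dn_plp = FALSE,
                                         sge_call = "unavailable") {
  ev <- no_evidence()
  if (isTRUE(same_variant_dn_plp)) {
    strength <- if (de_novo_status == "de_novo") "moderate" else "supporting"
    ev <- rbind(ev, evidence_item("PS2", "pathogenic", strength))
  }
  if (sge_call == "abnormal")
    ev <- rbind(ev, evidence_item("PS3", "pathogenic", "strong"))
  else if (sge_call == "normal")
    ev <- rbind(ev, evidence_item("BS3", "benign", "strong"))
  ev
}

#' Combine evidence points into the five-tier classification
#'
#' Point values follow the published quantitative framework (supporting 1,
#' moderate 2, strong 4, very strong 8; benign evidence negative). Tier
#' cut-points: total >= 10 pathogenic, 6-9 likely pathogenic, 0-5 VUS,
#' -6..-1 likely benign, <= -7 benign.
#'
#' @param evidence evidence data.frame (rows from the assign_* functions).
#' @return list of class `acmg_result`: `evidence`, `total_points`,
#'   `tier`.
#' @export
combine_points <- function(evidence) {
  total <- if (nrow(evidence)) sum(evidence$points) else 0L
  tier <- if (total >= 10) "pathogenic"
          else if (total >= 6) "likely_pathogenic"
          else if (total >= 0) "VUS"
          else if (total >= -6) "likely_benign"
          else "benign"
  structure(list(evidence = evidence, total_points = total, tier = tier),
            class = "acmg_result")
}

#' @export
print.acmg_result <- function(x, ...) {
  cat("ACMG:", x$tier, sprintf("(%+d points)", x$total_points), "\n")
  if (nrow(x$evidence))
    cat(" ", paste(sprintf("%s[%s %+d]", x$evidence$code,
                           x$evidence$strength, x$evidence$points),
                   collapse = " "), "\n")
  invisible(x)
}

#' Interpret a single variant
#'
#' Assembles the applicable evidence for one interpretation context and
#' combines points. With `use_sge = FALSE` the functional-assay call is
#' ignored (the "without SGE" counterfactual).
#'
#' @param context a list or one-row data.frame with fields: `consequence`,
#'   `cds_position`, `exon_phase`, `truncation_fraction`,
#'   `distal_to_domains`, `af_max`, `de_novo_status`,
#'   `same_variant_dn_plp`, `same_aa_change_dn_plp`,
#'   `same_residue_dn_plp`, `non_dn_plp_at_residue`, `spliceai`, `revel`,
#'   `cadd`, `sge_call`. Missing optional fields default to
#'   NA/FALSE/"unknown"/"unavailable".
#' @param config an `acmg_gene_config`.
#' @param use_sge whether PS3/BS3 from the functional assay are applied.
#' @return an `acmg_result`.
#' @export
interpret_variant <- function(context, config, use_sge = TRUE) {
  g <- function(field, default) {
    v <- context[[field]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) default else v
  }
  csq <- context$consequence
  ev <- no_evidence()
  ev <- rbind(ev, assign_frequency_evidence(g("af_max", NA), config))
  if (csq %in% c("nonsense", "frameshift", "splice_acceptor_donor")) {
    ev <- rbind(ev, assign_lof_evidence(
      csq, context$cds_position, g("exon_phase", NA),
      g("truncation_fraction", NA), g("distal_to_domains", NA), config))
  }
  ev <- rbind(ev, assign_missense_evidence(
    csq, g("same_aa_change_dn_plp", FALSE), g("same_residue_dn_plp", FALSE),
    g("non_dn_plp_at_residue", FALSE)))
  ev <- rbind(ev, assign_insilico_evidence(
    csq, g("spliceai", NA), g("revel", NA), g("cadd", NA)))
  ev <- rbind(ev, assign_denovo_and_functional(
    g("de_novo_status", "unknown"), g("same_variant_dn_plp", FALSE),
    if (use_sge) g("sge_call", "unavailable") else "unavailable"))
  combine_points(ev)
}

#' Interpret a cohort with and without the functional assay
#'
#' Applies [interpret_variant()] to every row of a context table twice
#' (with and without PS3/BS3) and summarises tier counts by consequence.
#' Per-row failures are collected, not fatal.
#'
#' @param contexts data.frame of interpretation contexts (one row per
#'   variant; columns as in [interpret_variant()], plus `variant_id`).
#' @param config an `acmg_gene_config`.
#' @return list: `tiers` (per-variant tiers with and without SGE and the
#'   point totals), `summary` (counts by consequence x tier x mode),
#'   `errors` (per-row failure messages).
#' @export
interpret_cohort <- function(contexts, config) {
  n <- nrow(contexts)
  tier_with <- tier_without <- rep(NA_character_, n)
  pts_with <- pts_without <- rep(NA_integer_, n)
  errors <- character(0)
  for (i in seq_len(n)) {
    ctx <- as.list(contexts[i, ])
    res <- tryCatch({
      w <- interpret_variant(ctx, config, use_sge = TRUE)
      wo <- interpret_variant(ctx, config, use_sge = FALSE)
      list(w = w, wo = wo)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("%s: %s", contexts$variant_id[i],
                                  conditionMessage(res)))
      next
    }
    tier_with[i] <- res$w$tier; pts_with[i] <- res$w$total_points
    tier_without[i] <- res$wo$tier; pts_without[i] <- res$wo$total_points
  }
  tiers <- data.frame(variant_id = contexts$variant_id,
                      consequence = contexts$consequence,
                      tier_with_sge = tier_with, points_with_sge = pts_with,
                      tier_without_sge = tier_without,
                      points_without_sge = pts_without)
  ok <- !is.na(tiers$tier_with_sge)
  summary <- rbind(
    data.frame(mode = "with_sge",
               as.data.frame(table(consequence = tiers$consequence[ok],
                                   tier = tiers$tier_with_sge[ok]))),
    data.frame(mode = "without_sge",
               as.data.frame(table(consequence = tiers$consequence[ok],
                                   tier = tiers$tier_without_sge[ok]))))
  list(tiers = tiers, summary = summary, errors = errors)
}

#' Derivation of the gene's frequency threshold constants
#'
#' Reconstructs the disease-prevalence constant used for the
#' maximum-credible-allele-frequency threshold: prevalence = population
#' prevalence of the phenotype times the fraction of cohort families
#' explained by de novo variants in the gene. Also reports the value the
#' standard maximum-credible-AF formula (prevalence x allelic
#' heterogeneity x genetic heterogeneity / (2 x penetrance)) would give,
#' which differs in magnitude from the published threshold shipped as the
#' default - the discrepancy is surfaced rather than resolved.
#'
#' @param phenotype_prevalence population prevalence of the phenotype
#'   (default 0.01 for intellectual disability).
#' @param gene_dn_count de novo variants in the gene in the reference
#'   cohort (default 112).
#' @param cohort_families families in the reference cohort (default
#'   31058).
#' @param allelic_heterogeneity maximum allelic contribution (default
#'   0.09).
#' @param genetic_heterogeneity gene's share of the phenotype (default 1).
#' @param penetrance assumed penetrance (default 0.5).
#' @param published_threshold the threshold the engine actually uses.
#' @return list: `prevalence`, `prevalence_denominator` (the "1 in N"),
#'   `standard_formula_af`, `published_threshold`.
#' @export
af_threshold_derivation <- function(phenotype_prevalence = 0.01,
                                    gene_dn_count = 112,
                                    cohort_families = 31058,
                                    allelic_heterogeneity = 0.09,
                                    genetic_heterogeneity = 1,
                                    penetrance = 0.5,
                                    published_threshold = 3.25e-7) {
  prevalence <- phenotype_prevalence * gene_dn_count / cohort_families
  list(prevalence = prevalence,
       prevalence_denominator = 1 / prevalence,
       standard_formula_af = prevalence * allelic_heterogeneity *
         genetic_heterogeneity / (2 * penetrance),
       published_threshold = published_threshold)
}
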