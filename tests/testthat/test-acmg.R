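# a toy gene configuration: 1989 nt CDS (662 aa), last coding junction at
# nt 1836, helicase-like domains spanning CDS nt 397-1700
toy_config <- function(...) {
  acmg_gene_config(coding_length = 1989, last_junction_cds = 1836,
                   domain_cds_intervals = list(c(397, 1700)), ...)
}

test_that("NMD escape follows the start-proximal and last-junction rules", {
  cfg <- toy_config()
  expect_true(predict_nmd_escape(150, cfg))    # within first 200 bp
  expect_true(predict_nmd_escape(200, cfg))    # boundary inclusive
  expect_false(predict_nmd_escape(201, cfg))   # just beyond
  ## 55 bp rule: escape iff pos > 1836 - 55 = 1781
  expect_false(predict_nmd_escape(1781, cfg))  # exactly 55 bp 5' of junction
  expect_true(predict_nmd_escape(1782, cfg))
  expect_true(predict_nmd_escape(1836, cfg))   # at the junction
  expect_error(predict_nmd_escape(NA, cfg), "required")
})

test_that("frequency evidence: unobserved is moderate, above threshold benign strong", {
  cfg <- toy_config()
  ev <- assign_frequency_evidence(0, cfg)
  expect_equal(ev$points, 2)
  expect_equal(ev$direction, "pathogenic")
  ev <- assign_frequency_evidence(1e-6, cfg)
  expect_equal(ev$code, "BS1")
  expect_equal(ev$points, -4)
  ## strict inequality at the threshold itself
  expect_equal(nrow(assign_frequency_evidence(3.25e-7, cfg)), 0)
  expect_equal(nrow(assign_frequency_evidence(NA, cfg)), 0)
})

test_that("in-silico evidence follows the PP3/BP4 score bands", {
  expect_equal(assign_insilico_evidence("missense", spliceai = 0.8)$code, "PP3")
  expect_equal(assign_insilico_evidence("missense", revel = 0.75)$code, "PP3")
  ev <- assign_insilico_evidence("missense", spliceai = 0.1, revel = NA,
                                 cadd = 5)
  expect_equal(ev$code, "BP4")
  expect_equal(ev$points, -1)
  ## between the bands: nothing
  expect_equal(nrow(assign_insilico_evidence("missense", spliceai = 0.4,
                                             revel = 0.4)), 0)
  ## REVEL present but CADD-like missing path: REVEL rules
  expect_equal(assign_insilico_evidence("missense", revel = 0.1,
                                        spliceai = NA)$code, "BP4")
  ## CADD backs up only a missing REVEL
  expect_equal(nrow(assign_insilico_evidence("missense", revel = 0.4,
                                             cadd = 30)), 0)
  ## canonical splice variants are excluded (no double counting with PVS1)
  expect_equal(nrow(assign_insilico_evidence("splice_acceptor_donor",
                                             spliceai = 0.99)), 0)
})

test_that("PVS1 for premature stops follows the NMD and truncation branches", {
  cfg <- toy_config()
  ## NMD-predicted -> very strong
  ev <- assign_lof_evidence("nonsense", cds_position = 600, config = cfg)
  expect_equal(ev$points, 8)
  ## escapes NMD, distal to domains, truncates > 10%: 1782/1989 -> 10.4%
  ev <- assign_lof_evidence("nonsense", cds_position = 1782, config = cfg)
  expect_equal(ev$strength, "strong")
  ## escapes NMD, distal, truncates < 10%
  ev <- assign_lof_evidence("nonsense", cds_position = 1900, config = cfg)
  expect_equal(ev$strength, "moderate")
  ## escapes NMD within the domains (start-proximal): no branch
  expect_equal(nrow(assign_lof_evidence("nonsense", cds_position = 150,
                                        config = cfg)), 0)
})

test_that("PVS1 for canonical splice variants uses exon phase", {
  cfg <- toy_config()
  ## non-phase-0, NMD-predicted -> very strong
  ev <- assign_lof_evidence("splice_acceptor_donor", cds_position = 600,
                            exon_phase = 1, config = cfg)
  expect_equal(ev$points, 8)
  ## non-phase-0, escapes NMD, truncation > 10% -> strong
  ev <- assign_lof_evidence("splice_acceptor_donor", cds_position = 1782,
                            exon_phase = 2, config = cfg)
  expect_equal(ev$strength, "strong")
  ## phase-0 exon outside the domains -> moderate
  ev <- assign_lof_evidence("splice_acceptor_donor", cds_position = 1900,
                            exon_phase = 0, config = cfg)
  expect_equal(ev$strength, "moderate")
  ## phase-0 exon inside the domains -> nothing
  expect_equal(nrow(assign_lof_evidence("splice_acceptor_donor",
                                        cds_position = 600, exon_phase = 0,
                                        config = cfg)), 0)
  expect_error(assign_lof_evidence("splice_acceptor_donor",
                                   cds_position = 600, config = cfg),
               "exon_phase")
})

test_that("missense evidence composes PP2, PS1 xor PM5, and PP5", {
  ev <- assign_missense_evidence("missense")
  expect_equal(ev$code, "PP2")
  ev <- assign_missense_evidence("missense", same_aa_change_dn_plp = TRUE,
                                 same_residue_dn_plp = TRUE)
  expect_setequal(ev$code, c("PP2", "PS1"))  # PS1 pre-empts PM5
  ev <- assign_missense_evidence("missense", same_residue_dn_plp = TRUE)
  expect_setequal(ev$code, c("PP2", "PM5"))
  ev <- assign_missense_evidence("missense", non_dn_plp_at_residue = TRUE)
  expect_setequal(ev$code, c("PP2", "PP5"))
  expect_equal(nrow(assign_missense_evidence("synonymous")), 0)
})

test_that("de novo and functional-assay evidence follow the quoted rules", {
  ev <- assign_denovo_and_functional("de_novo", same_variant_dn_plp = TRUE)
  expect_equal(ev$code, "PS2")
  expect_equal(ev$strength, "moderate")
  ev <- assign_denovo_and_functional("unknown", same_variant_dn_plp = TRUE)
  expect_equal(ev$strength, "supporting")
  expect_equal(nrow(assign_denovo_and_functional("unknown", FALSE)), 0)
  ev <- assign_denovo_and_functional(sge_call = "abnormal")
  expect_equal(ev$code, "PS3"); expect_equal(ev$points, 4)
  ev <- assign_denovo_and_functional(sge_call = "normal")
  expect_equal(ev$code, "BS3"); expect_equal(ev$points, -4)
})

test_that("point combination reproduces worked tier examples", {
  cfg <- toy_config()
  ## NMD-predicted nonsense, unobserved, assay-abnormal: 8 + 2 + 4 = 14
  ctx <- list(consequence = "nonsense", cds_position = 600, af_max = 0,
              sge_call = "abnormal")
  res <- interpret_variant(ctx, cfg)
  expect_equal(res$total_points, 14)
  expect_equal(res$tier, "pathogenic")
  ## common, functionally normal synonymous variant with benign scores:
  ## -4 (BS1) - 1 (BP4) - 4 (BS3) = -9
  ctx <- list(consequence = "synonymous", cds_position = 600, af_max = 1e-4,
              spliceai = 0.01, revel = NA, cadd = 3, sge_call = "normal")
  res <- interpret_variant(ctx, cfg)
  expect_equal(res$total_points, -9)
  expect_equal(res$tier, "benign")
  ## no evidence at all: VUS at 0 points
  res <- combine_points(sgemap:::no_evidence())
  expect_equal(res$total_points, 0)
  expect_equal(res$tier, "VUS")
})

test_that("combine_points equals a brute-force enumeration oracle", {
  ## oracle: independent tier mapping applied to sums over all subsets of
  ## a pool of five evidence items
  pool <- rbind(
    sgemap:::evidence_item("PVS1", "pathogenic", "very_strong"),
    sgemap:::evidence_item("PS3", "pathogenic", "strong"),
    sgemap:::evidence_item("PM2_like", "pathogenic", "moderate"),
    sgemap:::evidence_item("BP4", "benign", "supporting"),
    sgemap:::evidence_item("BS3", "benign", "strong"))
  tier_oracle <- function(total) {
    if (total >= 10) "pathogenic"
    else if (total >= 6) "likely_pathogenic"
    else if (total >= 0) "VUS"
    else if (total >= -6) "likely_benign"
    else "benign"
  }
  for (mask in 0:(2^5 - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:4)) > 0)
    ev <- pool[idx, ]
    res <- combine_points(ev)
    expect_equal(res$total_points, sum(ev$points))
    expect_equal(res$tier, tier_oracle(sum(ev$points)))
  }
})

test_that("adding evidence moves tiers monotonically", {
  tiers <- c("benign", "likely_benign", "VUS", "likely_pathogenic",
             "pathogenic")
  base <- rbind(sgemap:::evidence_item("PS3", "pathogenic", "strong"),
                sgemap:::evidence_item("PM2_like", "pathogenic", "moderate"))
  t0 <- match(combine_points(base)$tier, tiers)
  up <- combine_points(rbind(base, sgemap:::evidence_item(
    "PVS1", "pathogenic", "very_strong")))
  expect_gte(match(up$tier, tiers), t0)
  down <- combine_points(rbind(base, sgemap:::evidence_item(
    "BS1", "benign", "strong")))
  expect_lte(match(down$tier, tiers), t0)
})

test_that("every rule branch is reachable (golden suite)", {
  cfg <- toy_config()
  cases <- list(
    ## freq: unobserved / common / in between
    list(ctx = list(consequence = "intronic", cds_position = 300, af_max = 0),
         codes = "PM2_like"),
    list(ctx = list(consequence = "intronic", cds_position = 300,
                    af_max = 1e-5), codes = "BS1"),
    list(ctx = list(consequence = "intronic", cds_position = 300,
                    af_max = 1e-8), codes = character(0)),
    ## PVS1 nonsense branches
    list(ctx = list(consequence = "nonsense", cds_position = 900),
         codes = "PVS1", strength = "very_strong"),
    list(ctx = list(consequence = "nonsense", cds_position = 1782),
         codes = "PVS1", strength = "strong"),
    list(ctx = list(consequence = "nonsense", cds_position = 1900),
         codes = "PVS1", strength = "moderate"),
    ## PVS1 splice branches
    list(ctx = list(consequence = "splice_acceptor_donor",
                    cds_position = 900, exon_phase = 1),
         codes = "PVS1", strength = "very_strong"),
    list(ctx = list(consequence = "splice_acceptor_donor",
                    cds_position = 1782, exon_phase = 1),
         codes = "PVS1", strength = "strong"),
    list(ctx = list(consequence = "splice_acceptor_donor",
                    cds_position = 1900, exon_phase = 1),
         codes = "PVS1", strength = "moderate"),
    list(ctx = list(consequence = "splice_acceptor_donor",
                    cds_position = 1900, exon_phase = 0),
         codes = "PVS1", strength = "moderate"),
    ## missense composites
    list(ctx = list(consequence = "missense", cds_position = 900,
                    same_aa_change_dn_plp = TRUE),
         codes = c("PP2", "PS1")),
    list(ctx = list(consequence = "missense", cds_position = 900,
                    same_residue_dn_plp = TRUE),
         codes = c("PP2", "PM5")),
    list(ctx = list(consequence = "missense", cds_position = 900,
                    non_dn_plp_at_residue = TRUE),
         codes = c("PP2", "PP5")),
    ## PP3 / BP4
    list(ctx = list(consequence = "missense", cds_position = 900,
                    revel = 0.9), codes = c("PP2", "PP3")),
    list(ctx = list(consequence = "missense", cds_position = 900,
                    revel = 0.1, spliceai = 0.05),
         codes = c("PP2", "BP4")),
    ## PS2 both strengths
    list(ctx = list(consequence = "missense", cds_position = 900,
                    de_novo_status = "de_novo", same_variant_dn_plp = TRUE),
         codes = c("PP2", "PS2")),
    list(ctx = list(consequence = "missense", cds_position = 900,
                    de_novo_status = "unknown", same_variant_dn_plp = TRUE),
         codes = c("PP2", "PS2")),
    ## PS3 / BS3
    list(ctx = list(consequence = "missense", cds_position = 900,
                    sge_call = "abnormal"), codes = c("PP2", "PS3")),
    list(ctx = list(consequence = "missense", cds_position = 900,
                    sge_call = "normal"), codes = c("PP2", "BS3")))
  for (cs in cases) {
    res <- interpret_variant(cs$ctx, cfg)
    expect_setequal(res$evidence$code, cs$codes)
    if (!is.null(cs$strength))
      expect_equal(res$evidence$strength[res$evidence$code == "PVS1"],
                   cs$strength)
    ## points always consistent with strength and direction
    expect_equal(res$evidence$points,
                 ifelse(res$evidence$direction == "benign", -1, 1) *
                   unname(sgemap:::STRENGTH_POINTS[res$evidence$strength]))
  }
})

test_that("cohort interpretation shows the assay resolving missense VUS", {
  cfg <- toy_config()
  ## population-observed (below-threshold) functionally-normal missense
  ## variants: VUS without the assay, resolved benign-side with it
  n <- 40
  ctx <- data.frame(variant_id = sprintf("m%02d", 1:n),
                    consequence = "missense", cds_position = 900,
                    af_max = 1e-8, revel = NA, cadd = NA, spliceai = NA,
                    sge_call = "normal")
  res <- interpret_cohort(ctx, cfg)
  vus_without <- sum(res$tiers$tier_without_sge == "VUS")
  vus_with <- sum(res$tiers$tier_with_sge == "VUS")
  expect_lt(vus_with, vus_without)
  ## no assay calls: with and without are identical
  ctx$sge_call <- "unavailable"
  res <- interpret_cohort(ctx, cfg)
  expect_identical(res$tiers$tier_with_sge, res$tiers$tier_without_sge)
})

test_that("benign assay calls barely move NMD-predicted truncating variants", {
  cfg <- toy_config()
  ctx <- data.frame(variant_id = sprintf("n%02d", 1:30),
                    consequence = "nonsense", cds_position = 600,
                    af_max = 0, sge_call = "normal")
  res <- interpret_cohort(ctx, cfg)
  ## PVS1 very strong + PM2-like dominate: a benign assay call never pulls
  ## these below likely pathogenic
  expect_true(all(res$tiers$tier_without_sge == "pathogenic"))
  expect_true(all(res$tiers$tier_with_sge %in%
                    c("pathogenic", "likely_pathogenic")))
})

test_that("per-row failures are collected, not fatal", {
  cfg <- toy_config()
  ctx <- data.frame(variant_id = c("ok", "bad"),
                    consequence = c("missense", "splice_acceptor_donor"),
                    cds_position = c(900, 900), exon_phase = c(NA, NA),
                    af_max = c(0, 0))
  res <- interpret_cohort(ctx, cfg)
  expect_equal(length(res$errors), 1)
  expect_match(res$errors, "bad")
  expect_false(is.na(res$tiers$tier_with_sge[1]))
})

test_that("the prevalence constant reproduces the published 1-in-27700", {
  d <- af_threshold_derivation()
  expect_equal(signif(d$prevalence_denominator, 3), 27700)
  ## the standard-formula value is an order of magnitude above the
  ## published threshold; the discrepancy is surfaced, not hidden
  expect_equal(d$standard_formula_af, 3.25e-6, tolerance = 0.01)
  expect_gt(d$standard_formula_af / d$published_threshold, 5)
})
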