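fake_effects <- function(ids, est, se, guide = "g1", kind = "lfc_day15") {
  data.frame(variant_id = ids, guide = guide, kind = kind,
             estimate = est, se = se, z = est / se,
             p = 2 * pnorm(-abs(est / se)), pseudocount = FALSE)
}

test_that("median centering zeroes the control median and shifts all estimates", {
  ann <- data.frame(variant_id = c("s1", "s2", "s3", "m1", "m2"),
                    consequence = c("synonymous", "intronic", "synonymous",
                                    "missense", "missense"))
  eff <- fake_effects(ann$variant_id, c(-0.3, -0.2, -0.1, -2, 1), rep(0.2, 5))
  out <- median_center(eff, ann)
  ## control median -0.2 -> everything shifted by +0.2
  expect_equal(out$estimate, eff$estimate + 0.2)
  expect_equal(out$se, eff$se)
  ctrl <- out$estimate[out$variant_id %in% c("s1", "s2", "s3")]
  expect_equal(median(ctrl), 0)
  ## idempotent fixed point
  again <- median_center(out, ann)
  expect_equal(again$estimate, out$estimate)
  ## all-control library centres to median zero
  eff2 <- fake_effects(c("s1", "s2", "s3"), c(1, 2, 5), rep(0.1, 3))
  out2 <- median_center(eff2, ann)
  expect_equal(median(out2$estimate), 0)
})

test_that("centering requires controls in every guide library", {
  ann <- data.frame(variant_id = c("m1", "m2"),
                    consequence = c("missense", "missense"))
  eff <- fake_effects(ann$variant_id, c(1, 2), c(0.1, 0.1), guide = "g2")
  expect_error(median_center(eff, ann), "guide library g2")
})

test_that("inverse-variance combination matches the closed form", {
  ## x = (-1, -2), se = (0.5, 1): weights 4 and 1 -> estimate -1.2,
  ## se = 1/sqrt(5) ~ 0.4472
  eff <- rbind(fake_effects("v", -1, 0.5, guide = "g1"),
               fake_effects("v", -2, 1.0, guide = "g2"))
  cmb <- combine_guides(eff)
  expect_equal(cmb$estimate, -1.2)
  expect_equal(cmb$se, 1 / sqrt(5), tolerance = 1e-12)
  expect_equal(cmb$guides_used, 2L)
  ## z combination: w = 1/se
  w <- 1 / c(0.5, 1.0)
  z <- c(-1 / 0.5, -2 / 1.0)
  expect_equal(cmb$z, sum(w * z) / sqrt(sum(w^2)))
})

test_that("equal standard errors reduce to the simple mean and z sum rule", {
  eff <- rbind(fake_effects("v", -1, 0.3, guide = "g1"),
               fake_effects("v", -3, 0.3, guide = "g2"))
  cmb <- combine_guides(eff)
  expect_equal(cmb$estimate, -2)
  z <- eff$z
  expect_equal(cmb$z, sum(z) / sqrt(2))
})

test_that("combination is permutation-invariant and tightens the error", {
  e1 <- rbind(fake_effects(c("a", "b"), c(-1, 2), c(0.5, 0.2), guide = "g1"),
              fake_effects(c("a", "b"), c(-2, 1), c(1.0, 0.4), guide = "g2"))
  e2 <- e1[rev(seq_len(nrow(e1))), ]
  c1 <- combine_guides(e1)
  c2 <- combine_guides(e2)
  c2 <- c2[match(c1$variant_id, c2$variant_id), ]
  expect_equal(c1$estimate, c2$estimate)
  expect_equal(c1$se, c2$se)
  for (id in c1$variant_id)
    expect_lte(c1$se[c1$variant_id == id],
               min(e1$se[e1$variant_id == id]))
})

test_that("single-guide variants pass through combination unchanged", {
  eff <- fake_effects("solo", -1.5, 0.4, guide = "g2")
  cmb <- combine_guides(eff)
  expect_equal(cmb$estimate, -1.5)
  expect_equal(cmb$se, 0.4)
  expect_equal(cmb$guides_used, 1L)
})

test_that("PAM-flagged measurements are replaced by the other guide", {
  lib <- data.frame(variant_id = c("v", "v"), guide = c("g1", "g2"),
                    pam_codon_flag = c(TRUE, FALSE))
  eff <- rbind(fake_effects("v", -5, 0.5, guide = "g1"),
               fake_effects("v", -1, 0.5, guide = "g2"))
  out <- merge_pam_codon(eff, lib)
  cmb <- combine_guides(out)
  expect_equal(cmb$estimate, -1)
  expect_equal(cmb$guides_used, 1L)
  ## flagged in both guides -> dropped with reason
  lib2 <- data.frame(variant_id = c("w", "w"), guide = c("g1", "g2"),
                     pam_codon_flag = TRUE)
  eff2 <- rbind(fake_effects("w", -5, 0.5, guide = "g1"),
                fake_effects("w", -1, 0.5, guide = "g2"))
  out2 <- merge_pam_codon(eff2, lib2)
  expect_equal(nrow(out2), 0)
  expect_true("w" %in% attr(out2, "irrecoverable"))
})

test_that("PAM bookkeeping on a 155-flagged / 154-rescued fixture", {
  n <- 155
  ids <- sprintf("p%03d", seq_len(n))
  lib <- rbind(
    data.frame(variant_id = ids, guide = "g1", pam_codon_flag = TRUE),
    ## all but one also measured (unflagged) by g2
    data.frame(variant_id = ids[-n], guide = "g2", pam_codon_flag = FALSE),
    data.frame(variant_id = ids[n], guide = "g2", pam_codon_flag = TRUE))
  eff <- rbind(fake_effects(ids, -1, 0.5, guide = "g1"),
               fake_effects(ids[-n], -1, 0.5, guide = "g2"))
  out <- merge_pam_codon(eff, lib)
  expect_equal(attr(out, "n_flagged"), 155)
  expect_equal(attr(out, "n_rescued"), 154)
  expect_equal(attr(out, "irrecoverable"), ids[n])
})

test_that("BH FDR equals the brute-force step-up on small inputs", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(1:10, 1))
    expect_equal(bh_fdr(p), bh_brute_force(p))
  }
})

test_that("BH FDR dominates p and is monotone in p-rank; NA propagates", {
  set.seed(7)
  p <- runif(50)
  fdr <- bh_fdr(p)
  expect_true(all(fdr >= p))
  o <- order(p)
  expect_true(all(diff(fdr[o]) >= -1e-12))
  expect_warning(out <- bh_fdr(c(0.01, NA, 0.5)), "propagated")
  expect_true(is.na(out[2]))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("EM mixture: log-likelihood is monotone, weights sum to 1", {
  set.seed(9)
  x <- rbind(cbind(rnorm(150, -4), rnorm(150, -5)),
             cbind(rnorm(80, -1.5), rnorm(80, -2)))
  fit <- fit_gmm2(x)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_equal(sum(fit$weights), 1)
  for (k in 1:2) {
    ev <- eigen(fit$covariances[[k]])$values
    expect_true(all(ev > 0))
  }
})

test_that("well-separated depletion clusters are recovered at 95 percent", {
  set.seed(10)
  n1 <- 200; n2 <- 200
  x <- rbind(cbind(rnorm(n1, -4), rnorm(n1, -5)),     # fast
             cbind(rnorm(n2, -1.5), rnorm(n2, -2)))   # slow
  truth <- rep(c("fast", "slow"), c(n1, n2))
  fit <- fit_gmm2(x)
  fast_k <- which.min(fit$means[, 1])
  called <- ifelse(fit$posterior[, fast_k] > 0.5, "fast", "slow")
  expect_gte(mean(called == truth), 0.95)
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(11)
  x <- rbind(cbind(rnorm(150, -4), rnorm(150, -5)),
             cbind(rnorm(150, -1.5), rnorm(150, -2)))
  fit <- fit_gmm2(x)
  mc <- Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  ## same partition up to label switching
  ours <- apply(fit$posterior, 1, which.max)
  theirs <- mc$classification
  agree <- max(mean(ours == theirs), mean(ours == 3 - theirs))
  expect_gte(agree, 0.98)
})

test_that("class assignment follows the FDR, sign and mixture rules", {
  set.seed(12)
  n <- 300
  ids <- sprintf("v%03d", 1:n)
  est15 <- c(rnorm(100, -5, 0.3), rnorm(100, -1.8, 0.3), rnorm(50, 2, 0.3),
             rnorm(50, 0, 0.05))
  est7 <- c(rnorm(100, -3.5, 0.3), rnorm(100, -0.8, 0.3), rnorm(50, 1, 0.3),
            rnorm(50, 0, 0.05))
  se <- rep(0.25, n)
  d15 <- fake_effects(ids, est15, se)
  d15$kind <- "lfc_day15"
  d7 <- fake_effects(ids, est7, se)
  d7$kind <- "lfc_day7"
  cmb15 <- combine_guides(d15); cmb7 <- combine_guides(d7)
  res <- assign_classes(cmb15, cmb7, alpha = 0.01)
  calls <- res$calls
  expect_true(all(calls$sge_class[calls$fdr > 0.01] == "unchanged"))
  expect_true(all(calls$sge_class[calls$fdr <= 0.01 & calls$estimate > 0]
                  == "enriched"))
  dep <- calls$sge_class %in% c("fast_depleting", "slow_depleting")
  expect_true(all(calls$fdr[dep] <= 0.01 & calls$estimate[dep] < 0))
  ## the two generative depletion groups are recovered
  fast_ids <- ids[1:100]; slow_ids <- ids[101:200]
  expect_gte(mean(calls$sge_class[calls$variant_id %in% fast_ids]
                  == "fast_depleting"), 0.95)
  expect_gte(mean(calls$sge_class[calls$variant_id %in% slow_ids]
                  == "slow_depleting"), 0.95)
})

test_that("an insignificant variant is unchanged regardless of effect size", {
  ## fdr > alpha with a large estimate still reads unchanged
  d15 <- fake_effects(c("big", paste0("x", 1:20)),
                      c(-3, rnorm(20, 0, 0.01)),
                      c(2.0, rep(0.3, 20)))
  d7 <- d15; d7$kind <- "lfc_day7"
  res <- suppressWarnings(assign_classes(combine_guides(d15),
                                         combine_guides(d7)))
  big <- res$calls[res$calls$variant_id == "big", ]
  expect_gt(big$fdr, 0.01)
  expect_equal(big$sge_class, "unchanged")
})

test_that("fewer than 10 depleted variants skips the mixture with a warning", {
  d15 <- fake_effects(paste0("v", 1:12),
                      c(rep(-4, 4), rep(0.001, 8)),
                      c(rep(0.2, 4), rep(0.3, 8)))
  d7 <- d15; d7$kind <- "lfc_day7"
  expect_warning(res <- assign_classes(combine_guides(d15),
                                       combine_guides(d7)),
                 "mixture skipped")
  expect_true(all(res$calls$sge_class[res$calls$fdr <= 0.01 &
                                        res$calls$estimate < 0] == "depleting"))
  expect_null(res$model)
})
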