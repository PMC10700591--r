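#' Centre effect estimates on synonymous and intronic controls
#'
#' Per guide library and per effect kind, subtracts the median estimate of
#' the synonymous + intronic control variants from every variant's
#' estimate. Standard errors are unchanged. After centering, the control
#' median is exactly zero (the operation is an idempotent fixed point).
#'
#' @param effects per-guide effect table from [fit_lfc()] /
#'   [fit_lfc_trend()].
#' @param annotations table with `variant_id` and `consequence` (one row
#'   per variant is enough).
#' @param control_consequences consequences treated as functionally neutral
#'   controls.
#' @return the effect table with centred estimates and recomputed z / p.
#' @export
median_center <- function(effects, annotations,
                          control_consequences = c("synonymous", "intronic")) {
  ann <- annotations[!duplicated(annotations$variant_id), ]
  csq <- ann$consequence[match(effects$variant_id, ann$variant_id)]
  is_ctrl <- csq %in% control_consequences
  out <- effects
  for (g in unique(effects$guide)) {
    for (k in unique(effects$kind)) {
      sel <- effects$guide == g & effects$kind == k
      ctrl <- sel & is_ctrl
      if (!any(ctrl))
        stop("no synonymous/intronic control variants in guide library ", g)
      out$estimate[sel] <- effects$estimate[sel] - median(effects$estimate[ctrl])
    }
  }
  out$z <- out$estimate / out$se
  out$p <- 2 * pnorm(-abs(out$z))
  out
}

#' Combine the two guide libraries per variant
#'
#' Point estimates are combined by the inverse-variance-weighted average,
#' `sum(x_i/se_i^2) / sum(1/se_i^2)` with `se = (sum 1/se_i^2)^(-1/2)`;
#' significance by the weighted sum of z-scores,
#' `z = sum(w_i z_i) / sqrt(sum(w_i^2))` with `w_i = 1/se_i`. Variants
#' measured by a single guide pass through unchanged.
#'
#' @param effects centred per-guide effect table (both guides stacked), one
#'   kind at a time or several kinds.
#' @return data.frame `variant_id`, `kind`, `estimate`, `se`, `z`, `p`,
#'   `guides_used`.
#' @export
combine_guides <- function(effects) {
  if (length(unique(effects$kind)) > 1) {
    parts <- lapply(split(effects, effects$kind), combine_guides)
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    return(out)
  }
  sp <- split(effects, effects$variant_id)
  rows <- lapply(sp, function(d) {
    if (nrow(d) > 2) stop("variant ", d$variant_id[1], " measured by >2 guides")
    if (nrow(d) == 1) {
      data.frame(variant_id = d$variant_id, kind = d$kind,
                 estimate = d$estimate, se = d$se, z = d$z, p = d$p,
                 guides_used = 1L)
    } else {
      wiv <- 1 / d$se^2
      est <- sum(d$estimate * wiv) / sum(wiv)
      se <- sqrt(1 / sum(wiv))
      wz <- 1 / d$se
      z <- sum(wz * d$z) / sqrt(sum(wz^2))
      data.frame(variant_id = d$variant_id[1], kind = d$kind[1],
                 estimate = est, se = se, z = z,
                 p = 2 * pnorm(-abs(z)), guides_used = 2L)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exclude PAM-codon measurements and rescue from the other guide
#'
#' (variant, guide) measurements flagged as PAM-codon-specific are
#' discarded before combination; variants measured only by the flagged
#' guide are reported from the other guide's library (single-guide
#' estimate). Variants flagged in both guides are irrecoverable and
#' dropped.
#'
#' @param effects per-guide effect table.
#' @param library library table with `variant_id`, `guide`,
#'   `pam_codon_flag`.
#' @return the effect table without PAM-flagged rows; attributes
#'   `n_flagged` (measurements discarded), `n_rescued` (flagged variants
#'   still covered by the other guide) and `irrecoverable` (variant ids
#'   flagged in every guide that measured them).
#' @export
merge_pam_codon <- function(effects, library) {
  key <- paste(effects$variant_id, effects$guide)
  lkey <- paste(library$variant_id, library$guide)
  flag <- library$pam_codon_flag[match(key, lkey)]
  flag[is.na(flag)] <- FALSE
  out <- effects[!flag, ]
  rownames(out) <- NULL
  flagged_vars <- unique(effects$variant_id[flag])
  rescued <- flagged_vars[flagged_vars %in% out$variant_id]
  ## variants flagged on some guide and absent from the surviving table
  irrec <- setdiff(flagged_vars, rescued)
  ## also: variants flagged in the library for every guide (never measured)
  lib_flag <- tapply(library$pam_codon_flag, library$variant_id, all)
  irrec <- union(irrec, names(lib_flag)[lib_flag])
  attr(out, "n_flagged") <- sum(flag)
  attr(out, "n_rescued") <- length(rescued)
  attr(out, "irrecoverable") <- irrec
  out
}

#' Benjamini-Hochberg false discovery rate
#'
#' Standard step-up BH with monotonicity enforcement, applied across all
#' supplied p-values (one stratum). `NaN`/`NA` p-values propagate with a
#' warning.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of BH-adjusted FDR values, `fdr >= p` elementwise.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p))) warning("NA/NaN p-values propagated through BH")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

## ---- 2-D Gaussian mixture --------------------------------------------------

dmvnorm2 <- function(x, mean, sigma) {
  d <- sweep(x, 2, mean)
  det <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  inv <- matrix(c(sigma[2, 2], -sigma[1, 2], -sigma[2, 1], sigma[1, 1]),
                2, 2) / det
  q <- rowSums((d %*% inv) * d)
  exp(-0.5 * q) / (2 * pi * sqrt(det))
}

#' Two-component 2-D Gaussian mixture via EM
#'
#' Full-covariance EM on a two-column matrix. Initialisation is
#' deterministic: component means start at the rows whose second coordinate
#' (Day-15 cLFC) sits at the 10th and 60th percentile, covariances at the
#' pooled covariance, weights at 1/2. Convergence at relative
#' log-likelihood change below `tol`; the log-likelihood trace is
#' guaranteed non-decreasing.
#'
#' @param x numeric matrix with two columns (Day-7, Day-15 cLFC).
#' @param tol relative log-likelihood tolerance.
#' @param max_iter maximum EM iterations.
#' @param seed accepted for interface stability; the fit is deterministic.
#' @return list of class `sge_gmm2`: `means` (2x2, rows = components),
#'   `covariances` (list of 2x2), `weights`, `posterior` (n x 2),
#'   `loglik_trace`, `converged`.
#' @export
fit_gmm2 <- function(x, tol = 1e-6, max_iter = 500, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2, nrow(x) >= 4)
  q <- quantile(x[, 2], c(0.10, 0.60), type = 7)
  i1 <- which.min(abs(x[, 2] - q[1]))
  i2 <- which.min(abs(x[, 2] - q[2]))
  means <- rbind(x[i1, ], x[i2, ])
  pooled <- stats::cov(x) + diag(1e-6, 2)
  sig <- list(pooled, pooled)
  w <- c(0.5, 0.5)
  ll_trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dmvnorm2(x, means[1, ], sig[[1]])
    d2 <- w[2] * dmvnorm2(x, means[2, ], sig[[2]])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    post <- cbind(d1 / tot, d2 / tot)
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) <=
          tol * abs(ll_trace[it - 1])) { converged <- TRUE; break }
    for (k in 1:2) {
      rk <- post[, k]
      nk <- sum(rk)
      means[k, ] <- colSums(x * rk) / nk
      d <- sweep(x, 2, means[k, ])
      sig[[k]] <- crossprod(d * sqrt(rk)) / nk + diag(1e-8, 2)
      w[k] <- nk / nrow(x)
    }
  }
  structure(list(means = means, covariances = sig, weights = w,
                 posterior = post, loglik_trace = ll_trace,
                 converged = converged, seed = seed),
            class = "sge_gmm2")
}

#' Assign the four SGE functional classes
#'
#' Day-15 cLFC FDR (> alpha: unchanged), sign (positive: enriched), then a
#' two-component Gaussian mixture on (Day-7, Day-15) cLFC splits the
#' depleted variants into fast- and slow-depleting. The component with the
#' more negative Day-7 mean is labelled fast; hard assignment is by maximum
#' posterior, with posterior exactly 1/2 broken toward slow (conservative).
#' With fewer than 10 depleted variants the mixture is skipped and the
#' class is reported as `depleting` (unsplit) with a warning.
#'
#' @param combined_day15,combined_day7 combined effect tables (kinds
#'   `lfc_day15`, `lfc_day7`).
#' @param alpha FDR threshold for calling a variant changed.
#' @param seed passed to [fit_gmm2()].
#' @return list: `calls` (data.frame `variant_id`, `sge_class`, `estimate`
#'   (Day-15 cLFC), `fdr`, `posterior_fast`) and `model` (`sge_gmm2` or
#'   NULL).
#' @export
assign_classes <- function(combined_day15, combined_day7, alpha = 0.01,
                           seed = 1L) {
  d15 <- combined_day15
  d15$fdr <- bh_fdr(d15$p)
  d7 <- combined_day7[match(d15$variant_id, combined_day7$variant_id), ]
  cls <- ifelse(d15$fdr > alpha, "unchanged",
                ifelse(d15$estimate > 0, "enriched", "depleted"))
  post_fast <- rep(NA_real_, nrow(d15))
  model <- NULL
  dep <- which(cls == "depleted" & !is.na(d7$estimate))
  orphan <- which(cls == "depleted" & is.na(d7$estimate))
  if (length(dep) < 10) {
    warning("fewer than 10 depleted variants: fast/slow mixture skipped")
    cls[cls == "depleted"] <- "depleting"
  } else {
    x <- cbind(d7$estimate[dep], d15$estimate[dep])
    model <- fit_gmm2(x, seed = seed)
    fast_k <- which.min(model$means[, 1])
    pf <- model$posterior[, fast_k]
    post_fast[dep] <- pf
    cls[dep] <- ifelse(pf > 0.5, "fast_depleting", "slow_depleting")
    if (length(orphan)) cls[orphan] <- "depleting"
  }
  list(calls = data.frame(variant_id = d15$variant_id, sge_class = cls,
                          estimate = d15$estimate, fdr = d15$fdr,
                          posterior_fast = post_fast),
       model = model)
}
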